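# Minimal neural-network layer library: forward passes and hand-derived
# reverse-mode gradients over BLAS matrix products (im2col convolutions).
# Internal; the user-facing network surface lives in the branch files.
#
# Conventions
#   * a "params" list holds trainable numeric arrays plus (non-trainable)
#     integer index caches; gradients mirror the trainable leaves only.
#   * forward functions return list(out=, cache=); backward functions take
#     (dout, cache) and return list(dx=, grads=).
#   * time-domain batches are arrays (C, L, B); feature maps are (C, H, W).

# ---- im2col index caches ----------------------------------------------------

# Index matrix (C*k x L) into the zero-padded (C x (L+2p)) matrix, "same"
# padding, rows ordered channel-fastest to match matrix(W, Cout, C*k).
conv1d_index <- function(C, L, k) {
  p <- (k - 1L) %/% 2L
  pos <- outer(seq_len(L), seq_len(k) - 1L, "+")       # L x k, into padded axis
  idx <- array(0L, c(C, k, L))
  for (j in seq_len(k))
    idx[, j, ] <- rep(seq_len(C), L) + (rep(pos[, j], each = C) - 1L) * C
  list(idx = matrix(aperm(idx, c(1, 2, 3)), C * k, L), p = p, C = C, L = L,
       k = k)
}

conv1d_forward <- function(x, Wm, b, ic) {
  xp <- cbind(matrix(0, ic$C, ic$p), x, matrix(0, ic$C, ic$p))
  col <- xp[ic$idx]
  dim(col) <- c(ic$C * ic$k, ic$L)
  y <- Wm %*% col + b
  list(out = y, cache = list(col = col, Wm = Wm, ic = ic))
}

conv1d_backward <- function(dy, cache) {
  ic <- cache$ic
  dWm <- dy %*% t(cache$col)
  db <- rowSums(dy)
  dcol <- crossprod(cache$Wm, dy)
  dim(dcol) <- c(ic$C, ic$k, ic$L)
  # scatter-add by kernel offset: k dense shifted adds
  dxp <- matrix(0, ic$C, ic$L + 2L * ic$p)
  for (j in seq_len(ic$k)) {
    sl <- dcol[, j, ]
    dim(sl) <- c(ic$C, ic$L)
    dxp[, j:(j + ic$L - 1L)] <- dxp[, j:(j + ic$L - 1L)] + sl
  }
  list(dx = dxp[, (ic$p + 1L):(ic$p + ic$L), drop = FALSE],
       dW = dWm, db = db)
}

# 2-D analogue on (C, H, W) maps with kernel (kh x kw), "same" padding.
conv2d_index <- function(C, H, W, kh, kw) {
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  Hp <- H + 2L * ph; Wp <- W + 2L * pw
  n_out <- H * W
  idx <- matrix(0L, C * kh * kw, n_out)
  r <- 0L
  for (j in seq_len(kw)) for (i in seq_len(kh)) for (c in seq_len(C)) {
    r <- r + 1L
    hh <- rep(seq_len(H) + i - 1L, times = W)
    ww <- rep(seq_len(W) + j - 1L, each = H)
    idx[r, ] <- c + (hh - 1L) * C + (ww - 1L) * C * Hp
  }
  # rows are ordered (c, i, j) channel-fastest, matching
  # matrix(Warr(Cout,C,kh,kw), Cout, C*kh*kw)
  list(idx = idx, ph = ph, pw = pw, C = C, H = H, W = W, kh = kh, kw = kw)
}

conv2d_forward <- function(x, Wm, b, ic) {
  xp <- array(0, c(ic$C, ic$H + 2L * ic$ph, ic$W + 2L * ic$pw))
  xp[, (ic$ph + 1L):(ic$ph + ic$H), (ic$pw + 1L):(ic$pw + ic$W)] <- x
  col <- matrix(xp[ic$idx], nrow = ic$C * ic$kh * ic$kw)
  y <- Wm %*% col + b                                  # Cout x (H*W)
  list(out = array(y, c(nrow(Wm), ic$H, ic$W)),
       cache = list(col = col, Wm = Wm, ic = ic))
}

conv2d_backward <- function(dy, cache) {
  ic <- cache$ic
  dym <- matrix(dy, nrow = dim(dy)[1])
  dWm <- dym %*% t(cache$col)
  db <- rowSums(dym)
  dcol <- array(crossprod(cache$Wm, dym), c(ic$C, ic$kh, ic$kw, ic$H, ic$W))
  dxp <- array(0, c(ic$C, ic$H + 2L * ic$ph, ic$W + 2L * ic$pw))
  for (j in seq_len(ic$kw)) for (i in seq_len(ic$kh))
    dxp[, i:(i + ic$H - 1L), j:(j + ic$W - 1L)] <-
      dxp[, i:(i + ic$H - 1L), j:(j + ic$W - 1L), drop = FALSE] +
      array(dcol[, i, j, , ], c(ic$C, ic$H, ic$W))
  list(dx = dxp[, (ic$ph + 1L):(ic$ph + ic$H), (ic$pw + 1L):(ic$pw + ic$W),
                drop = FALSE],
       dW = dWm, db = db)
}

# ---- normalisation ----------------------------------------------------------

# Batch norm over an array whose FIRST axis is the feature axis; statistics
# are taken over all remaining axes (and the batch).  `stats` is a list
# (mean, var) of running statistics; in training mode batch statistics are
# used and the updated running stats are returned.
batchnorm_forward <- function(x, gamma, beta, stats, train, eps = 1e-5,
                              momentum = 0.1) {
  d <- dim(x); C <- d[1]; N <- prod(d) / C
  xm <- x
  dim(xm) <- c(C, N)
  if (train) {
    mu <- rowMeans(xm)
    v <- rowMeans((xm - mu)^2)
    stats$mean <- (1 - momentum) * stats$mean + momentum * mu
    stats$var <- (1 - momentum) * stats$var + momentum * v * N / max(N - 1, 1)
  } else {
    mu <- stats$mean; v <- stats$var
  }
  s <- sqrt(v + eps)
  xhat <- (xm - mu) / s
  y <- gamma * xhat + beta
  list(out = array(y, d), stats = stats,
       cache = list(xhat = xhat, s = s, gamma = gamma, d = d, train = train))
}

batchnorm_backward <- function(dy, cache) {
  d <- cache$d; C <- d[1]; N <- prod(d) / C
  dym <- dy
  dim(dym) <- c(C, N)
  dgamma <- rowSums(dym * cache$xhat)
  dbeta <- rowSums(dym)
  dxhat <- dym * cache$gamma
  if (cache$train) {
    dx <- (dxhat - rowMeans(dxhat) -
             cache$xhat * rowMeans(dxhat * cache$xhat)) / cache$s
  } else {
    dx <- dxhat / cache$s
  }
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

# Layer norm over the feature (column) axis of a (tokens x d) matrix.
layernorm_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  v <- rowMeans((x - mu)^2)
  s <- sqrt(v + eps)
  xhat <- (x - mu) / s
  y <- sweep(xhat, 2, gamma, "*")
  y <- sweep(y, 2, beta, "+")
  list(out = y, cache = list(xhat = xhat, s = s, gamma = gamma))
}

layernorm_backward <- function(dy, cache) {
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, cache$gamma, "*")
  dx <- (dxhat - rowMeans(dxhat) -
           cache$xhat * rowMeans(dxhat * cache$xhat)) / cache$s
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- simple layers ----------------------------------------------------------

linear_forward <- function(x, W, b) {
  # x: (in) vector or (in x n) matrix; y = W x + b
  list(out = W %*% x + b, cache = list(x = x, W = W))
}

linear_backward <- function(dy, cache) {
  list(dx = crossprod(cache$W, dy),
       dW = dy %*% t(cache$x),
       db = rowSums(as.matrix(dy)))
}

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(dy, mask) dy * mask

# Row-wise softmax of a matrix; backward via the standard Jacobian product.
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
softmax_rows_backward <- function(dP, P) P * (dP - rowSums(dP * P))

# Max pool over the H (second) axis of a (C,H,W) map by integer factor `f`
# (trailing remainder rows dropped).
maxpool_h_forward <- function(x, f = 2L) {
  d <- dim(x); Ho <- d[2] %/% f
  xs <- x[, seq_len(Ho * f), , drop = FALSE]
  out <- array(xs[, seq(1L, Ho * f, by = f), , drop = FALSE],
               c(d[1], Ho, d[3]))
  am <- array(1L, c(d[1], Ho, d[3]))
  for (j in seq_len(f)[-1]) {
    cand <- array(xs[, seq(j, Ho * f, by = f), , drop = FALSE],
                  c(d[1], Ho, d[3]))
    sel <- cand > out
    out[sel] <- cand[sel]
    am[sel] <- j
  }
  list(out = out, cache = list(am = am, d = d, f = f, Ho = Ho))
}

maxpool_h_backward <- function(dy, cache) {
  d <- cache$d; f <- cache$f; Ho <- cache$Ho
  dx <- array(0, d)
  for (j in seq_len(f)) {
    sel <- cache$am == j
    sub <- array(0, dim(dy)); sub[sel] <- dy[sel]
    dx[, seq(j, Ho * f, by = f), ] <- sub
  }
  dx
}

# Adaptive average pooling of a (C x L) map to T output positions.
adaptive_avgpool_forward <- function(x, T_out) {
  L <- ncol(x)
  lo <- floor((seq_len(T_out) - 1) * L / T_out) + 1L
  hi <- floor(seq_len(T_out) * L / T_out)
  out <- vapply(seq_len(T_out),
                function(t) rowMeans(x[, lo[t]:hi[t], drop = FALSE]),
                numeric(nrow(x)))
  list(out = out, cache = list(lo = lo, hi = hi, L = L))   # out: C x T
}

adaptive_avgpool_backward <- function(dy, cache) {
  dx <- matrix(0, nrow(dy), cache$L)
  for (t in seq_len(ncol(dy))) {
    span <- cache$lo[t]:cache$hi[t]
    dx[, span] <- dx[, span] + dy[, t] / length(span)
  }
  dx
}

dropout_forward <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, cache = NULL))
  mask <- (array(stats::runif(length(x)), dim(x) %||% length(x)) > p) / (1 - p)
  list(out = x * mask, cache = mask)
}
dropout_backward <- function(dy, mask) if (is.null(mask)) dy else dy * mask

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- loss -------------------------------------------------------------------

# Softmax cross-entropy on logits (n_classes x B) with labels in 0..n-1.
# Returns mean loss and dlogits.
softmax_xent <- function(logits, labels) {
  B <- ncol(logits)
  z <- sweep(logits, 2, apply(logits, 2, max))
  p <- exp(z); p <- sweep(p, 2, colSums(p), "/")
  ii <- cbind(labels + 1L, seq_len(B))
  loss <- -mean(log(pmax(p[ii], 1e-12)))
  dlogits <- p
  dlogits[ii] <- dlogits[ii] - 1
  list(loss = loss, dlogits = dlogits / B, probs = p)
}

# ---- optimiser --------------------------------------------------------------

adam_init <- function() new.env(parent = emptyenv())

# One Adam step over a params tree given a grads tree (same structure).
adam_step <- function(params, grads, opt, lr = 0.01, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  opt$t <- (opt$t %||% 0) + 1
  t <- opt$t
  map_param_tree(params, grads, function(p, g, path) {
    key_m <- paste0(path, "/m"); key_v <- paste0(path, "/v")
    m <- (opt[[key_m]] %||% 0) * beta1 + (1 - beta1) * g
    v <- (opt[[key_v]] %||% 0) * beta2 + (1 - beta2) * g^2
    opt[[key_m]] <- m; opt[[key_v]] <- v
    mh <- m / (1 - beta1^t); vh <- v / (1 - beta2^t)
    p - lr * mh / (sqrt(vh) + eps)
  })
}
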