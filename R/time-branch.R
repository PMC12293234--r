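# Time-domain stream: dynamic 1-D convolutions (input-conditioned convex
# combinations of K candidate kernels, weighted by a temperature-controlled
# softmax attention over globally pooled channel features) stacked in
# residual blocks (TDRB), followed by adaptive pooling to a fixed token
# sequence for fusion.

#' Parameters of one dynamic convolution
#'
#' Holds the K candidate kernels and the squeeze-style attention MLP that
#' scores them.  The aggregated kernel for an input x is
#' `W(x) = sum_k theta_k(x) W_k` (and likewise the bias), where
#' `theta = softmax(s / tau)` comes from global average pooling, a bottleneck
#' MLP, and a temperature-divided softmax: large `tau` keeps the kernel mix
#' near-uniform early in training, `tau = 1` is the standard softmax.
#'
#' @param in_channels,out_channels channel counts.
#' @param K number of candidate kernels.
#' @param kernel_size odd tap count ("same" padding).
#' @param reduction squeeze ratio of the attention MLP (bottleneck width
#'   `max(4, floor(in_channels / reduction))`).
#' @param tau initial temperature (> 0).
#' @return a `dynconv_params` list with elements `Wk` ((Cout*Cin*k) x K),
#'   `bk` (Cout x K), the MLP weights `W1, b1, W2, b2`, and `tau`.
#' @export
dynconv_params <- function(in_channels, out_channels, K = 10, kernel_size = 7,
                           reduction = 4, tau = 25) {
  stopifnot_scalar_pos(tau, "tau")
  if (K < 1) stop("`K` must be >= 1")
  fan <- in_channels * kernel_size
  r <- max(4L, in_channels %/% reduction)
  p <- list(
    Wk = matrix(stats::rnorm(out_channels * fan * K, sd = sqrt(2 / fan)),
                out_channels * fan, K),
    bk = matrix(0, out_channels, K),
    W1 = he_init(c(r, in_channels), in_channels), b1 = numeric(r),
    W2 = he_init(c(K, r), r), b2 = numeric(K),
    tau = tau, K = K, kernel_size = as.integer(kernel_size),
    in_channels = as.integer(in_channels),
    out_channels = as.integer(out_channels))
  class(p) <- "dynconv_params"
  p
}

#' Attention weights over the candidate kernels
#'
#' Global average pooling per input channel, a ReLU bottleneck MLP, and a
#' temperature-divided softmax produce the K-simplex weight vector used to
#' aggregate the candidate kernels.
#'
#' @param x input epoch matrix (in_channels x samples).
#' @param p a [dynconv_params()].
#' @param tau temperature override; defaults to `p$tau`.
#' @return length-K vector on the simplex (non-negative, sums to 1).
#' @export
kernel_attention <- function(x, p, tau = p$tau) {
  stopifnot_scalar_pos(tau, "tau")
  if (nrow(x) != p$in_channels) stop("channel count mismatch")
  z <- rowMeans(x)
  s1 <- relu(p$W1 %*% z + p$b1)
  s2 <- as.vector(p$W2 %*% s1 + p$b2)
  softmax(s2, tau)
}

# Internal forward with full cache for backprop.  `ic` is the conv1d index
# cache for (in_channels, ncol(x), kernel_size).
dyconv_fwd <- function(x, p, ic, tau = p$tau, theta_override = NULL) {
  z <- rowMeans(x)
  a1 <- as.vector(p$W1 %*% z + p$b1)
  m1 <- a1 > 0
  s1 <- pmax(a1, 0)
  s2 <- as.vector(p$W2 %*% s1 + p$b2)
  theta <- if (is.null(theta_override)) softmax(s2, tau) else theta_override
  Wagg <- matrix(p$Wk %*% theta, p$out_channels)
  bagg <- as.vector(p$bk %*% theta)
  cv <- conv1d_forward(x, Wagg, bagg, ic)
  list(out = cv$out,
       cache = list(conv = cv$cache, theta = theta, z = z, s1 = s1, m1 = m1,
                    x_ncol = ncol(x), tau = tau, p = p,
                    fixed_theta = !is.null(theta_override)))
}

dyconv_bwd <- function(dy, cache) {
  p <- cache$p
  cb <- conv1d_backward(dy, cache$conv)
  dWagg_vec <- as.vector(cb$dW)
  # kernel bank gradients: dWk[, k] = theta_k * dWagg
  dWk <- dWagg_vec %o% cache$theta
  dbk <- cb$db %o% cache$theta
  dx <- cb$dx
  grads <- list(Wk = dWk, bk = dbk)
  if (!cache$fixed_theta) {
    dtheta <- as.vector(crossprod(p$Wk, dWagg_vec)) +
      as.vector(crossprod(p$bk, cb$db))
    th <- cache$theta
    ds2 <- th * (dtheta - sum(dtheta * th)) / cache$tau
    ds1 <- as.vector(crossprod(p$W2, ds2)) * cache$m1
    dz <- as.vector(crossprod(p$W1, ds1))
    grads$W2 <- ds2 %o% cache$s1
    grads$b2 <- ds2
    grads$W1 <- ds1 %o% cache$z
    grads$b1 <- ds1
    dx <- dx + matrix(dz / cache$x_ncol, length(dz), cache$x_ncol)
  }
  list(dx = dx, grads = grads)
}

#' Dynamic convolution forward pass
#'
#' Aggregates the candidate kernels with the attention weights from
#' [kernel_attention()] and applies a single "same"-padded 1-D convolution
#' with the aggregated kernel and bias.
#'
#' @param x input epoch matrix (in_channels x samples).
#' @param p a [dynconv_params()].
#' @param tau temperature override.
#' @param theta optional fixed weight vector (e.g. one-hot) replacing the
#'   attention; used by the static-equivalence checks and the
#'   `no_dynamic_conv` ablation.
#' @return feature matrix (out_channels x samples) with the attention vector
#'   attached as attribute `"theta"`.
#' @export
dynamic_conv_forward <- function(x, p, tau = p$tau, theta = NULL) {
  if (nrow(x) != p$in_channels) stop("channel count mismatch")
  ic <- conv1d_index(p$in_channels, ncol(x), p$kernel_size)
  fw <- dyconv_fwd(x, p, ic, tau = tau, theta_override = theta)
  structure(fw$out, theta = fw$cache$theta)
}

#' Parameters of one time-domain dynamic residual block (TDRB)
#'
#' Two dynamic convolutions, each followed by batch normalisation, inside a
#' residual connection; when the input and output channel counts differ the
#' identity path is replaced by a learned 1x1 convolution.
#'
#' @param in_channels,out_channels channel counts.
#' @param K,kernel_size,reduction,tau forwarded to [dynconv_params()].
#' @return a `tdrb_params` list.
#' @export
tdrb_params <- function(in_channels, out_channels, K = 10, kernel_size = 7,
                        reduction = 4, tau = 25) {
  p <- list(
    dyconv1 = dynconv_params(in_channels, out_channels, K, kernel_size,
                             reduction, tau),
    dyconv2 = dynconv_params(out_channels, out_channels, K, kernel_size,
                             reduction, tau),
    bn1 = list(gamma = rep(1, out_channels), beta = rep(0, out_channels)),
    bn2 = list(gamma = rep(1, out_channels), beta = rep(0, out_channels)))
  if (in_channels != out_channels) {
    p$residual_proj <- list(Wr = he_init(c(out_channels, in_channels),
                                         in_channels),
                            br = numeric(out_channels))
  }
  class(p) <- "tdrb_params"
  p
}

new_bn_stats <- function(C) list(mean = numeric(C), var = rep(1, C))

# Batch forward of one TDRB over X (C, L, B).  `state` is the mutable
# environment holding BN running statistics under `path`.
tdrb_fwd <- function(X, p, ic1, ic2, state, path, train, tau, trace = FALSE) {
  d <- dim(X); B <- d[3]; Co <- p$dyconv1$out_channels; L <- d[2]
  H1 <- array(0, c(Co, L, B)); c1 <- vector("list", B)
  for (i in seq_len(B)) {
    xi <- X[, , i]
    dim(xi) <- d[1:2]
    fw <- dyconv_fwd(xi, p$dyconv1, ic1, tau)
    H1[, , i] <- fw$out; c1[[i]] <- fw$cache
  }
  k1 <- paste0(path, "/bn1"); k2 <- paste0(path, "/bn2")
  mom <- state[["bn_momentum"]] %||% 0.1
  if (is.null(state[[k1]])) state[[k1]] <- new_bn_stats(Co)
  bn1 <- batchnorm_forward(H1, p$bn1$gamma, p$bn1$beta, state[[k1]], train,
                           momentum = mom)
  if (train) state[[k1]] <- bn1$stats
  r1 <- relu_forward(bn1$out)
  H2 <- array(0, c(Co, L, B)); c2 <- vector("list", B)
  for (i in seq_len(B)) {
    xi <- r1$out[, , i]
    dim(xi) <- c(Co, L)
    fw <- dyconv_fwd(xi, p$dyconv2, ic2, tau)
    H2[, , i] <- fw$out; c2[[i]] <- fw$cache
  }
  if (is.null(state[[k2]])) state[[k2]] <- new_bn_stats(Co)
  bn2 <- batchnorm_forward(H2, p$bn2$gamma, p$bn2$beta, state[[k2]], train,
                           momentum = mom)
  if (train) state[[k2]] <- bn2$stats
  if (is.null(p$residual_proj)) {
    res <- X; res_cache <- NULL
  } else {
    xm <- X
    dim(xm) <- c(d[1], d[2] * d[3])
    lin <- linear_forward(xm, p$residual_proj$Wr, p$residual_proj$br)
    res <- array(lin$out, c(Co, L, B)); res_cache <- lin$cache
  }
  pre <- bn2$out + res
  ro <- relu_forward(pre)
  thetas <- if (trace) {
    list(conv1 = t(vapply(c1, function(cc) cc$theta, numeric(p$dyconv1$K))),
         conv2 = t(vapply(c2, function(cc) cc$theta, numeric(p$dyconv2$K))))
  }
  list(out = ro$out, thetas = thetas,
       cache = list(c1 = c1, c2 = c2, bn1 = bn1$cache, bn2 = bn2$cache,
                    r1 = r1$cache, ro = ro$cache, res_cache = res_cache,
                    d = d, Co = Co, p = p))
}

tdrb_bwd <- function(dY, cache) {
  p <- cache$p; d <- cache$d; B <- d[3]; Co <- cache$Co
  dpre <- relu_backward(dY, cache$ro)
  grads <- list()
  if (is.null(cache$res_cache)) {
    dX_res <- dpre
  } else {
    dprem <- dpre
    dim(dprem) <- c(Co, d[2] * d[3])
    lb <- linear_backward(dprem, cache$res_cache)
    grads$residual_proj <- list(Wr = lb$dW, br = lb$db)
    dX_res <- array(lb$dx, d)
  }
  b2 <- batchnorm_backward(dpre, cache$bn2)
  grads$bn2 <- list(gamma = b2$dgamma, beta = b2$dbeta)
  dH2 <- b2$dx
  dr1 <- array(0, c(Co, d[2], B))
  g2 <- NULL
  for (i in seq_len(B)) {
    di <- dH2[, , i]
    dim(di) <- c(Co, d[2])
    bb <- dyconv_bwd(di, cache$c2[[i]])
    dr1[, , i] <- bb$dx
    g2 <- add_grad_trees(g2, bb$grads)
  }
  grads$dyconv2 <- g2
  dbn1 <- relu_backward(dr1, cache$r1)
  b1 <- batchnorm_backward(dbn1, cache$bn1)
  grads$bn1 <- list(gamma = b1$dgamma, beta = b1$dbeta)
  dH1 <- b1$dx
  dX <- dX_res
  g1 <- NULL
  for (i in seq_len(B)) {
    di <- dH1[, , i]
    dim(di) <- c(Co, d[2])
    bb <- dyconv_bwd(di, cache$c1[[i]])
    dX[, , i] <- dX[, , i] + bb$dx
    g1 <- add_grad_trees(g1, bb$grads)
  }
  grads$dyconv1 <- g1
  list(dx = dX, grads = grads)
}

#' TDRB forward pass (single epoch)
#'
#' Evaluation-mode forward of one residual block:
#' `Y = ReLU(BN2(dyconv2(ReLU(BN1(dyconv1(X))))) + X_residual)`, with the
#' residual an identity when channel counts match and a 1x1 convolution
#' otherwise.  Running BN statistics default to (mean 0, var 1); pass `stats`
#' to pin others.
#'
#' @param x input matrix (in_channels x samples).
#' @param p a [tdrb_params()].
#' @param tau temperature for both dynamic convolutions.
#' @param stats optional list with `bn1`, `bn2` running-stat lists.
#' @return output matrix (out_channels x samples).
#' @export
tdrb_forward <- function(x, p, tau = p$dyconv1$tau, stats = NULL) {
  st <- new.env(parent = emptyenv())
  if (!is.null(stats)) { st[["t/bn1"]] <- stats$bn1; st[["t/bn2"]] <- stats$bn2 }
  ic1 <- conv1d_index(p$dyconv1$in_channels, ncol(x), p$dyconv1$kernel_size)
  ic2 <- conv1d_index(p$dyconv2$in_channels, ncol(x), p$dyconv2$kernel_size)
  fw <- tdrb_fwd(array(x, c(nrow(x), ncol(x), 1)), p, ic1, ic2, st, "t",
                 train = FALSE, tau = tau)
  matrix(fw$out, dim(fw$out)[1])
}

#' Temperature annealing schedule
#'
#' Linear decay from `tau0` at training epoch 1 to 1 at epoch 10, constant 1
#' afterwards: `tau(e) = max(1, tau0 - (tau0 - 1) * (e - 1) / 9)`.
#'
#' @param epoch training epoch (1-based).
#' @param tau0 initial temperature (>= 1).
#' @return the temperature for that epoch.
#' @export
temperature_schedule <- function(epoch, tau0 = 25) {
  if (epoch < 1) stop("`epoch` must be >= 1")
  if (tau0 < 1) stop("`tau0` must be >= 1")
  max(1, tau0 - (tau0 - 1) * (epoch - 1) / 9)
}

# Batch forward of the whole time branch: blocks then adaptive pooling to
# `tokens` positions.  Returns Xt as (width, tokens, B).
time_branch_fwd <- function(X, params, arch, state, train, tau,
                            trace = FALSE) {
  caches <- vector("list", length(params$blocks))
  thetas <- vector("list", length(params$blocks))
  H <- X
  for (bi in seq_along(params$blocks)) {
    icb <- arch$time_ic[[bi]]
    fw <- tdrb_fwd(H, params$blocks[[bi]], icb$ic1, icb$ic2, state,
                   paste0("time/block", bi), train, tau, trace)
    H <- fw$out; caches[[bi]] <- fw$cache; thetas[[bi]] <- fw$thetas
  }
  B <- dim(H)[3]
  Xt <- array(0, c(dim(H)[1], arch$tokens_t, B))
  pcs <- vector("list", B)
  for (i in seq_len(B)) {
    ap <- adaptive_avgpool_forward(matrix(H[, , i], dim(H)[1]), arch$tokens_t)
    Xt[, , i] <- ap$out; pcs[[i]] <- ap$cache
  }
  list(out = Xt, caches = caches, pool = pcs, thetas = thetas,
       hdim = dim(H))
}

time_branch_bwd <- function(dXt, fw, params) {
  B <- dim(dXt)[3]
  dH <- array(0, fw$hdim)
  for (i in seq_len(B))
    dH[, , i] <- adaptive_avgpool_backward(matrix(dXt[, , i], dim(dXt)[1]),
                                           fw$pool[[i]])
  grads <- list(blocks = vector("list", length(params$blocks)))
  for (bi in rev(seq_along(params$blocks))) {
    bb <- tdrb_bwd(dH, fw$caches[[bi]])
    dH <- bb$dx
    grads$blocks[[bi]] <- bb$grads
  }
  list(dx = dH, grads = grads)
}

#' Time-branch forward pass (single epoch)
#'
#' Sequential TDRB blocks followed by adaptive average pooling to a fixed
#' token count; evaluation mode with default BN statistics.
#'
#' @param x input matrix (channels x samples).
#' @param params list with element `blocks` (list of [tdrb_params()]).
#' @param tokens output token count.
#' @param tau temperature.
#' @param trace if `TRUE`, attach kernel-attention weights as attribute
#'   `"thetas"` (one matrix per block and conv, rows = samples).
#' @return token matrix (tokens x width).
#' @export
time_branch_forward <- function(x, params, tokens = 32, tau = NULL,
                                trace = FALSE) {
  if (!length(params$blocks)) stop("block list must be non-empty")
  if (is.null(tau)) tau <- params$blocks[[1]]$dyconv1$tau
  arch <- list(tokens_t = tokens,
               time_ic = lapply(params$blocks, function(b)
                 list(ic1 = conv1d_index(b$dyconv1$in_channels, ncol(x),
                                         b$dyconv1$kernel_size),
                      ic2 = conv1d_index(b$dyconv2$in_channels, ncol(x),
                                         b$dyconv2$kernel_size))))
  st <- new.env(parent = emptyenv())
  fw <- time_branch_fwd(array(x, c(dim(x), 1)), params, arch, st,
                        train = FALSE, tau = tau, trace = trace)
  out <- t(matrix(fw$out, dim(fw$out)[1]))         # tokens x width
  if (trace) attr(out, "thetas") <- fw$thetas
  out
}

#' Export kernel-attention traces to CSV
#'
#' Flattens per-sample attention weights collected during training or a
#' traced forward pass into long format (epoch, layer, sample, k, theta),
#' suitable for heatmap-style visualisation of how the kernel mix sharpens
#' as the temperature anneals.
#'
#' @param traces list of records with fields `epoch`, `layer`, `theta`
#'   (matrix samples x K).
#' @param file output CSV path.
#' @return invisibly, the data frame written.
#' @export
export_attention_traces <- function(traces, file) {
  rows <- do.call(rbind, lapply(traces, function(tr) {
    th <- tr$theta
    data.frame(epoch = tr$epoch, layer = tr$layer,
               sample = rep(seq_len(nrow(th)), ncol(th)),
               k = rep(seq_len(ncol(th)), each = nrow(th)),
               theta = as.vector(th))
  }))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(rows)
}
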