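# Frequency-domain stream: Hann-window STFT magnitudes per channel, a small
# 2-D CNN over the (frequency x frame) planes with the EEG channels as input
# planes, CBAM (channel then spatial multiplicative attention), and a
# multi-head Transformer encoder over the frame tokens.

#' STFT configuration
#'
#' @param n_window window length in samples (Hann window).
#' @param overlap_fraction fractional overlap in `[0, 1)`; the hop is
#'   `n_window * (1 - overlap_fraction)`.
#' @return an `stft_config`.
#' @export
stft_config <- function(n_window = 256, overlap_fraction = 0.5) {
  if (n_window < 2) stop("`n_window` must be >= 2")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("`overlap_fraction` must be in [0, 1)")
  structure(list(n_window = as.integer(n_window),
                 overlap_fraction = overlap_fraction,
                 hop = as.integer(round(n_window * (1 - overlap_fraction)))),
            class = "stft_config")
}

#' Short-time Fourier transform of a multi-channel epoch
#'
#' One-sided magnitude STFT per channel with a Hann window; the frame count
#' is `floor((samples - n_window) / hop) + 1` and the bin count
#' `n_window / 2 + 1`.
#'
#' @param epoch numeric matrix (channels x samples).
#' @param cfg an [stft_config()].
#' @param fs sampling rate in Hz (used only to label the axes).
#' @return a `spectrogram_tensor`: list with `values`
#'   (channels x freq_bins x frames), `freq_axis` (Hz) and `frame_axis`
#'   (seconds at frame centres).
#' @export
stft_transform <- function(epoch, cfg = stft_config(), fs = 256) {
  epoch <- as.matrix(epoch)
  nw <- cfg$n_window; hop <- cfg$hop
  if (ncol(epoch) < nw) stop("epoch shorter than the STFT window")
  n_frames <- (ncol(epoch) - nw) %/% hop + 1L
  n_bins <- nw %/% 2L + 1L
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nw) - 1) / (nw - 1))   # Hann
  vals <- array(0, c(nrow(epoch), n_bins, n_frames))
  for (f in seq_len(n_frames)) {
    seg <- epoch[, ((f - 1L) * hop + 1L):((f - 1L) * hop + nw), drop = FALSE]
    seg <- sweep(seg, 2, w, "*")
    sp <- stats::mvfft(t(seg))                     # nw x channels
    vals[, , f] <- t(abs(sp[seq_len(n_bins), , drop = FALSE]))
  }
  structure(list(values = vals,
                 freq_axis = (seq_len(n_bins) - 1) * fs / nw,
                 frame_axis = ((seq_len(n_frames) - 1) * hop + nw / 2) / fs),
            class = "spectrogram_tensor")
}

#' CNN front-end parameters
#'
#' Two 3x3 convolution + batch-norm + ReLU stages with max pooling on the
#' frequency axis only (frames are few), treating the EEG channels as input
#' planes.
#'
#' @param in_channels EEG channel count (input planes).
#' @param filters per-stage filter counts.
#' @return a `cnn_params` list.
#' @export
cnn_params <- function(in_channels, filters = c(16, 32)) {
  stages <- vector("list", length(filters))
  cin <- in_channels
  for (s in seq_along(filters)) {
    fan <- cin * 9
    stages[[s]] <- list(W = he_init(c(filters[s], cin * 9), fan),
                        b = numeric(filters[s]),
                        bn = list(gamma = rep(1, filters[s]),
                                  beta = rep(0, filters[s])))
    cin <- filters[s]
  }
  structure(list(stages = stages, filters = filters), class = "cnn_params")
}

cnn_fwd_batch <- function(specs, p, ics, state, train) {
  B <- length(specs)
  caches <- vector("list", length(p$stages))
  H <- specs
  for (s in seq_along(p$stages)) {
    st <- p$stages[[s]]
    convs <- lapply(H, function(x) conv2d_forward(x, st$W, st$b, ics[[s]]))
    Y <- array(0, c(dim(convs[[1]]$out), B))
    for (i in seq_len(B)) Y[, , , i] <- convs[[i]]$out
    key <- paste0("freq/cnn", s)
    if (is.null(state[[key]])) state[[key]] <- new_bn_stats(dim(Y)[1])
    bn <- batchnorm_forward(Y, st$bn$gamma, st$bn$beta, state[[key]], train,
                            momentum = state[["bn_momentum"]] %||% 0.1)
    if (train) state[[key]] <- bn$stats
    r <- relu_forward(bn$out)
    pools <- lapply(seq_len(B), function(i)
      maxpool_h_forward(array(r$out[, , , i], dim(r$out)[1:3]), 2L))
    H <- lapply(pools, `[[`, "out")
    caches[[s]] <- list(convs = lapply(convs, `[[`, "cache"), bn = bn$cache,
                        r = r$cache, pools = lapply(pools, `[[`, "cache"),
                        ydim = dim(Y))
  }
  list(out = H, caches = caches)
}

cnn_bwd_batch <- function(dH, fw, p) {
  B <- length(dH)
  grads <- list(stages = vector("list", length(p$stages)))
  for (s in rev(seq_along(p$stages))) {
    cc <- fw$caches[[s]]
    dY <- array(0, cc$ydim)
    for (i in seq_len(B))
      dY[, , , i] <- maxpool_h_backward(dH[[i]], cc$pools[[i]])
    dY <- relu_backward(dY, cc$r)
    bb <- batchnorm_backward(dY, cc$bn)
    gW <- 0; gb <- 0
    dH <- vector("list", B)
    for (i in seq_len(B)) {
      cb <- conv2d_backward(array(bb$dx[, , , i], cc$ydim[1:3]), cc$convs[[i]])
      gW <- gW + cb$dW; gb <- gb + cb$db
      dH[[i]] <- cb$dx
    }
    grads$stages[[s]] <- list(W = gW, b = gb,
                              bn = list(gamma = bb$dgamma, beta = bb$dbeta))
  }
  list(dx = dH, grads = grads)
}

#' CNN feature extraction from a spectrogram (single sample)
#'
#' Evaluation-mode forward through the convolutional stages; batch-norm uses
#' its stored running statistics (mean 0, var 1 for a fresh parameter set).
#'
#' @param spec a `spectrogram_tensor` from [stft_transform()] (or a plain
#'   (C, F, T) array).
#' @param p a [cnn_params()].
#' @return feature map (filters x reduced_freq x frames).
#' @export
cnn_feature_extract <- function(spec, p) {
  x <- if (inherits(spec, "spectrogram_tensor")) spec$values else spec
  d <- dim(x)
  ics <- cnn_index_caches(p, d)
  st <- new.env(parent = emptyenv())
  fw <- cnn_fwd_batch(list(x), p, ics, st, train = FALSE)
  fw$out[[1]]
}

cnn_index_caches <- function(p, dspec) {
  ics <- vector("list", length(p$stages))
  C <- dspec[1]; H <- dspec[2]; W <- dspec[3]
  for (s in seq_along(p$stages)) {
    ics[[s]] <- conv2d_index(C, H, W, 3L, 3L)
    C <- p$filters[s]; H <- H %/% 2L
  }
  ics
}

# ---- CBAM -------------------------------------------------------------------

#' CBAM parameters
#'
#' Standard configuration: a shared bottleneck MLP over globally avg- and
#' max-pooled per-filter descriptors for the channel gate, then a
#' `spatial_kernel` x `spatial_kernel` convolution over the channel-pooled
#' (avg, max) planes for the spatial gate; both gates are sigmoids.
#'
#' @param channels filter count of the feature map the module gates.
#' @param reduction bottleneck ratio (floored at 2).
#' @param spatial_kernel spatial convolution size (odd).
#' @return a `cbam_params` list.
#' @export
cbam_params <- function(channels, reduction = 16, spatial_kernel = 7) {
  r <- max(2L, channels %/% reduction)
  structure(list(
    W1 = he_init(c(r, channels), channels), b1 = numeric(r),
    W2 = he_init(c(channels, r), r), b2 = numeric(channels),
    Ws = matrix(stats::rnorm(2 * spatial_kernel^2,
                             sd = sqrt(2 / (2 * spatial_kernel^2))), 1),
    bs = 0,
    spatial_kernel = as.integer(spatial_kernel), channels = channels),
    class = "cbam_params")
}

cbam_fwd <- function(f, p, ic_s) {
  d <- dim(f); C <- d[1]
  fm <- matrix(f, C)
  z_avg <- rowMeans(fm)
  am <- apply(fm, 1, which.max)
  z_max <- fm[cbind(seq_len(C), am)]
  mlp <- function(z) {
    a1 <- as.vector(p$W1 %*% z + p$b1)
    list(out = as.vector(p$W2 %*% pmax(a1, 0) + p$b2), a1 = a1)
  }
  ma <- mlp(z_avg); mm <- mlp(z_max)
  gc <- sigmoid(ma$out + mm$out)                 # channel gate, length C
  f1 <- f * gc                                   # broadcast over (H,W)
  s_avg <- apply(f1, c(2, 3), mean)
  s_max <- apply(f1, c(2, 3), max)
  s_arg <- apply(f1, c(2, 3), which.max)
  smap <- array(0, c(2, d[2], d[3]))
  smap[1, , ] <- s_avg; smap[2, , ] <- s_max
  sc <- conv2d_forward(smap, p$Ws, p$bs, ic_s)
  gs <- sigmoid(array(sc$out, d[2:3]))           # spatial gate (H,W)
  f2 <- sweep(f1, c(2, 3), gs, "*")
  list(out = f2,
       cache = list(f = f, f1 = f1, gc = gc, gs = gs, ma = ma, mm = mm,
                    z_avg = z_avg, z_max = z_max, am = am, s_arg = s_arg,
                    sconv = sc$cache, d = d, p = p))
}

cbam_bwd <- function(dy, cache) {
  p <- cache$p; d <- cache$d; C <- d[1]
  # f2 = f1 * gs
  df1 <- sweep(dy, c(2, 3), cache$gs, "*")
  dgs <- apply(dy * cache$f1, c(2, 3), sum)
  dsc <- dgs * cache$gs * (1 - cache$gs)
  cb <- conv2d_backward(array(dsc, c(1, d[2], d[3])), cache$sconv)
  grads <- list(Ws = cb$dW, bs = cb$db)
  dsmap <- cb$dx                                  # (2, H, W)
  # spatial avg path
  df1 <- df1 + array(rep(dsmap[1, , ] / C, each = C), d)
  # spatial max path: route to the argmax filter at each (h, w)
  dmax <- dsmap[2, , ]
  hw <- expand.grid(h = seq_len(d[2]), w = seq_len(d[3]))
  idx <- cbind(as.vector(cache$s_arg), hw$h, hw$w)
  df1[idx] <- df1[idx] + as.vector(dmax)
  # f1 = f * gc
  df <- df1 * cache$gc
  dgc <- apply(df1 * cache$f, 1, sum)
  dpre <- dgc * cache$gc * (1 - cache$gc)
  mlp_bwd <- function(dout, m, z) {
    dh <- as.vector(crossprod(p$W2, dout)) * (m$a1 > 0)
    list(W2 = dout %o% pmax(m$a1, 0), b2 = dout,
         W1 = dh %o% z, b1 = dh,
         dz = as.vector(crossprod(p$W1, dh)))
  }
  ga <- mlp_bwd(dpre, cache$ma, cache$z_avg)
  gm <- mlp_bwd(dpre, cache$mm, cache$z_max)
  grads$W1 <- ga$W1 + gm$W1; grads$b1 <- ga$b1 + gm$b1
  grads$W2 <- ga$W2 + gm$W2; grads$b2 <- ga$b2 + gm$b2
  # z_avg = rowMeans(f); z_max via per-filter argmax
  N <- d[2] * d[3]
  df <- df + array(ga$dz / N, d)
  fm_idx <- cbind(seq_len(C), cache$am)           # into (C, H*W)
  dfm <- matrix(0, C, N); dfm[fm_idx] <- gm$dz
  df <- df + array(dfm, d)
  list(dx = df, grads = grads)
}

#' CBAM forward pass
#'
#' Sequential channel-then-spatial multiplicative attention on a feature
#' map: `f' = f (.) channel_gate(f)` broadcast over space, then
#' `f'' = f' (.) spatial_gate(f')` broadcast over filters; both gates lie
#' strictly in (0, 1) and the shape is preserved.
#'
#' @param f feature map (filters x freq x frames).
#' @param p a [cbam_params()].
#' @return gated feature map, same shape, with gates attached as attributes
#'   `"channel_gate"` and `"spatial_gate"`.
#' @export
cbam_forward <- function(f, p) {
  ic_s <- conv2d_index(2L, dim(f)[2], dim(f)[3], p$spatial_kernel,
                       p$spatial_kernel)
  fw <- cbam_fwd(f, p, ic_s)
  structure(fw$out, channel_gate = fw$cache$gc, spatial_gate = fw$cache$gs)
}

# ---- Transformer encoder ----------------------------------------------------

#' Transformer encoder configuration and parameters
#'
#' Post-norm encoder layers with multi-head self-attention and a ReLU FFN.
#'
#' @param model_width token width (divisible by `n_heads`).
#' @param n_heads attention heads.
#' @param n_layers encoder layers.
#' @param ffn_width hidden width of the feed-forward sublayer.
#' @return an `encoder_params` list.
#' @export
encoder_params <- function(model_width = 64, n_heads = 4, n_layers = 2,
                           ffn_width = 4 * model_width) {
  if (model_width %% n_heads != 0)
    stop("`model_width` must be divisible by `n_heads`")
  layer <- function() list(
    Wq = he_init(c(model_width, model_width), model_width),
    Wk = he_init(c(model_width, model_width), model_width),
    Wv = he_init(c(model_width, model_width), model_width),
    Wo = he_init(c(model_width, model_width), model_width),
    bq = numeric(model_width), bk = numeric(model_width),
    bv = numeric(model_width), bo = numeric(model_width),
    ln1 = list(gamma = rep(1, model_width), beta = rep(0, model_width)),
    ln2 = list(gamma = rep(1, model_width), beta = rep(0, model_width)),
    Wf1 = he_init(c(ffn_width, model_width), model_width),
    bf1 = numeric(ffn_width),
    Wf2 = he_init(c(model_width, ffn_width), ffn_width),
    bf2 = numeric(model_width))
  structure(list(layers = replicate(n_layers, layer(), simplify = FALSE),
                 n_heads = n_heads, model_width = model_width,
                 ffn_width = ffn_width),
            class = "encoder_params")
}

# Multi-head self-attention on X (T x d); returns output and per-head
# attention matrices.
mha_fwd <- function(X, p, n_heads) {
  d <- ncol(X); dh <- d %/% n_heads
  Q <- X %*% t(p$Wq); Q <- sweep(Q, 2, p$bq, "+")
  K <- X %*% t(p$Wk); K <- sweep(K, 2, p$bk, "+")
  V <- X %*% t(p$Wv); V <- sweep(V, 2, p$bv, "+")
  O <- matrix(0, nrow(X), d)
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    Z <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
    A <- softmax_rows(Z)
    O[, cols] <- A %*% V[, cols, drop = FALSE]
    heads[[h]] <- A
  }
  out <- O %*% t(p$Wo); out <- sweep(out, 2, p$bo, "+")
  list(out = out, A = heads,
       cache = list(X = X, Q = Q, K = K, V = V, O = O, heads = heads,
                    dh = dh, n_heads = n_heads, p = p))
}

mha_bwd <- function(dout, cache) {
  p <- cache$p; dh <- cache$dh
  grads <- list(Wo = t(dout) %*% cache$O, bo = colSums(dout))
  dO <- dout %*% p$Wo
  dQ <- matrix(0, nrow(dO), ncol(dO)); dK <- dQ; dV <- dQ
  for (h in seq_len(cache$n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    A <- cache$heads[[h]]
    dOh <- dO[, cols, drop = FALSE]
    dA <- dOh %*% t(cache$V[, cols, drop = FALSE])
    dV[, cols] <- t(A) %*% dOh
    dZ <- softmax_rows_backward(dA, A) / sqrt(dh)
    dQ[, cols] <- dZ %*% cache$K[, cols, drop = FALSE]
    dK[, cols] <- t(dZ) %*% cache$Q[, cols, drop = FALSE]
  }
  grads$Wq <- t(dQ) %*% cache$X; grads$bq <- colSums(dQ)
  grads$Wk <- t(dK) %*% cache$X; grads$bk <- colSums(dK)
  grads$Wv <- t(dV) %*% cache$X; grads$bv <- colSums(dV)
  dX <- dQ %*% p$Wq + dK %*% p$Wk + dV %*% p$Wv
  list(dx = dX, grads = grads)
}

encoder_layer_fwd <- function(X, p, n_heads) {
  at <- mha_fwd(X, p, n_heads)
  ln1 <- layernorm_forward(X + at$out, p$ln1$gamma, p$ln1$beta)
  h <- ln1$out %*% t(p$Wf1); h <- sweep(h, 2, p$bf1, "+")
  m <- h > 0; hr <- pmax(h, 0)
  f <- hr %*% t(p$Wf2); f <- sweep(f, 2, p$bf2, "+")
  ln2 <- layernorm_forward(ln1$out + f, p$ln2$gamma, p$ln2$beta)
  list(out = ln2$out, A = at$A,
       cache = list(at = at$cache, ln1 = ln1$cache, ln2 = ln2$cache,
                    X1 = ln1$out, hr = hr, m = m, p = p))
}

encoder_layer_bwd <- function(dout, cache) {
  p <- cache$p
  l2 <- layernorm_backward(dout, cache$ln2)
  grads <- list(ln2 = list(gamma = l2$dgamma, beta = l2$dbeta))
  df <- l2$dx
  grads$Wf2 <- t(df) %*% cache$hr; grads$bf2 <- colSums(df)
  dhr <- df %*% p$Wf2
  dh <- dhr * cache$m
  grads$Wf1 <- t(dh) %*% cache$X1; grads$bf1 <- colSums(dh)
  dX1 <- df + dh %*% p$Wf1
  l1 <- layernorm_backward(dX1, cache$ln1)
  grads$ln1 <- list(gamma = l1$dgamma, beta = l1$dbeta)
  mb <- mha_bwd(l1$dx, cache$at)
  grads <- c(grads, mb$grads)
  list(dx = l1$dx + mb$dx, grads = grads)
}

encoder_fwd <- function(X, p) {
  caches <- vector("list", length(p$layers))
  A <- vector("list", length(p$layers))
  for (li in seq_along(p$layers)) {
    fw <- encoder_layer_fwd(X, p$layers[[li]], p$n_heads)
    X <- fw$out; caches[[li]] <- fw$cache; A[[li]] <- fw$A
  }
  list(out = X, caches = caches, A = A)
}

encoder_bwd <- function(dout, fw) {
  grads <- list(layers = vector("list", length(fw$caches)))
  for (li in rev(seq_along(fw$caches))) {
    bb <- encoder_layer_bwd(dout, fw$caches[[li]])
    dout <- bb$dx
    grads$layers[[li]] <- bb$grads
  }
  list(dx = dout, grads = grads)
}

#' Transformer encoder forward pass
#'
#' @param tokens token matrix (sequence x model_width).
#' @param p an [encoder_params()].
#' @return encoded tokens, same shape; per-layer, per-head attention
#'   matrices (row-stochastic) attached as attribute `"attention"`.
#' @export
transformer_encode <- function(tokens, p) {
  if (ncol(tokens) != p$model_width)
    stop("token width must equal `model_width`")
  fw <- encoder_fwd(tokens, p)
  structure(fw$out, attention = fw$A)
}

# Sinusoidal positional encoding (T x d).
positional_encoding <- function(T_len, d) {
  pos <- matrix(0, T_len, d)
  for (i in seq_len(d %/% 2)) {
    ang <- (seq_len(T_len) - 1) / 10000^(2 * (i - 1) / d)
    pos[, 2 * i - 1] <- sin(ang)
    pos[, 2 * i] <- cos(ang)
  }
  pos
}

# ---- full frequency branch --------------------------------------------------

freq_branch_fwd <- function(epochs_list, params, arch, state, train,
                            no_cbam = FALSE) {
  B <- length(epochs_list)
  specs <- lapply(epochs_list, function(x)
    stft_transform(x, arch$stft, arch$fs)$values)
  cnn <- cnn_fwd_batch(specs, params$cnn, arch$cnn_ic, state, train)
  H <- cnn$out
  cb_caches <- NULL
  if (!no_cbam) {
    cb <- lapply(H, function(f) cbam_fwd(f, params$cbam, arch$cbam_ic))
    H <- lapply(cb, `[[`, "out")
    cb_caches <- lapply(cb, `[[`, "cache")
  }
  # frames are tokens: flatten (filters x freq) per frame, project to width
  tok_caches <- vector("list", B)
  enc_caches <- vector("list", B)
  Xf <- array(0, c(arch$tokens_f, arch$model_width, B))
  for (i in seq_len(B)) {
    fmap <- H[[i]]
    Tn <- dim(fmap)[3]
    M <- matrix(fmap, ncol = Tn)                   # (filters*freq) x T
    lin <- linear_forward(M, params$W_tok, params$b_tok)   # width x T
    X <- t(lin$out)
    if (arch$positional) X <- X + arch$pos_cache
    enc <- encoder_fwd(X, params$encoder)
    Xf[, , i] <- enc$out
    tok_caches[[i]] <- list(lin = lin$cache, fdim = dim(fmap))
    enc_caches[[i]] <- enc
  }
  list(out = Xf, specs = specs, cnn = cnn, cbam = cb_caches,
       tok = tok_caches, enc = enc_caches, no_cbam = no_cbam)
}

freq_branch_bwd <- function(dXf, fw, params) {
  B <- dim(dXf)[3]
  grads <- list(W_tok = 0, b_tok = 0, encoder = NULL, cbam = NULL)
  dH <- vector("list", B)
  for (i in seq_len(B)) {
    eb <- encoder_bwd(matrix(dXf[, , i], dim(dXf)[1]), fw$enc[[i]])
    grads$encoder <- add_grad_trees(grads$encoder, eb$grads)
    lb <- linear_backward(t(eb$dx), fw$tok[[i]]$lin)
    grads$W_tok <- grads$W_tok + lb$dW
    grads$b_tok <- grads$b_tok + lb$db
    dH[[i]] <- array(lb$dx, fw$tok[[i]]$fdim)
  }
  if (!fw$no_cbam) {
    g <- NULL
    for (i in seq_len(B)) {
      cbb <- cbam_bwd(dH[[i]], fw$cbam[[i]])
      dH[[i]] <- cbb$dx
      g <- add_grad_trees(g, cbb$grads)
    }
    grads$cbam <- g
  }
  cb <- cnn_bwd_batch(dH, fw$cnn, params$cnn)
  grads$cnn <- cb$grads
  grads
}

#' Frequency-branch forward pass (single epoch)
#'
#' STFT -> CNN -> CBAM -> token projection (+ sinusoidal positional
#' encoding) -> Transformer encoder; evaluation mode.
#'
#' @param epoch numeric matrix (channels x samples).
#' @param params list with `cnn`, `cbam`, `W_tok`, `b_tok`, `encoder`
#'   parameter sets (see [build_model()]).
#' @param stft_cfg an [stft_config()].
#' @param fs sampling rate in Hz.
#' @param positional add sinusoidal positional encoding.
#' @param no_cbam skip the CBAM stage (ablation).
#' @return token matrix (frames x model_width).
#' @export
freq_branch_forward <- function(epoch, params, stft_cfg = stft_config(),
                                fs = 256, positional = TRUE,
                                no_cbam = FALSE) {
  spec_dim <- c(nrow(epoch), stft_cfg$n_window %/% 2L + 1L,
                (ncol(epoch) - stft_cfg$n_window) %/% stft_cfg$hop + 1L)
  red_freq <- spec_dim[2]
  for (s in seq_along(params$cnn$stages)) red_freq <- red_freq %/% 2L
  arch <- list(stft = stft_cfg, fs = fs,
               cnn_ic = cnn_index_caches(params$cnn, spec_dim),
               cbam_ic = conv2d_index(2L, red_freq, spec_dim[3],
                                      params$cbam$spatial_kernel,
                                      params$cbam$spatial_kernel),
               tokens_f = spec_dim[3],
               model_width = params$encoder$model_width,
               positional = positional,
               pos_cache = positional_encoding(spec_dim[3],
                                               params$encoder$model_width))
  st <- new.env(parent = emptyenv())
  fw <- freq_branch_fwd(list(epoch), params, arch, st, train = FALSE,
                        no_cbam = no_cbam)
  matrix(fw$out[, , 1], arch$tokens_f)
}
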