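# End-to-end model: time stream (dynamic residual blocks) + frequency stream
# (STFT/CNN/CBAM/Transformer) + ACDA fusion + linear classification head,
# with ablation variants that swap dynamic convolutions for static ones,
# skip CBAM, replace the fusion by concatenation, or drop a stream.

#' Model architecture configuration
#'
#' Defaults give the full-size network: three residual blocks with output
#' widths (16, 32, 64), kernel size 7, K = 10 candidate kernels at initial
#' temperature 25, 32 time tokens, a (16, 32)-filter CNN front-end, and a
#' 2-layer 4-head Transformer at model width 64.  `width_scale = 0.5` halves
#' every width (blocks, CNN filters, model width) for scaled-down studies.
#'
#' @param n_channels EEG channels per epoch.
#' @param epoch_samples samples per epoch.
#' @param fs sampling rate in Hz.
#' @param widths output channels of the residual blocks.
#' @param kernel_size dynamic-convolution taps.
#' @param K candidate kernels per dynamic convolution.
#' @param tau0 initial softmax temperature.
#' @param reduction attention-MLP squeeze ratio.
#' @param tokens_t time-stream token count after adaptive pooling.
#' @param stft_window,stft_overlap STFT window length and overlap fraction.
#' @param cnn_filters CNN front-end filter counts.
#' @param cbam_reduction,cbam_spatial_kernel CBAM configuration.
#' @param enc_layers,enc_heads Transformer depth and heads.
#' @param model_width token width of the frequency stream and fusion.
#' @param ffn_mult FFN hidden width as a multiple of `model_width`.
#' @param acda_heads fusion attention heads.
#' @param dropout dropout probability before the classification head.
#' @param positional use sinusoidal positional encoding on frame tokens.
#' @param ablation character vector drawn from `no_dynamic_conv`, `no_cbam`,
#'   `no_acda`, `only_time`, `only_freq`.
#' @param width_scale multiplier applied to all widths (e.g. 0.5).
#' @return a `model_config`.
#' @export
model_config <- function(n_channels, epoch_samples, fs = 256,
                         widths = c(16, 32, 64), kernel_size = 7, K = 10,
                         tau0 = 25, reduction = 4, tokens_t = 32,
                         stft_window = 256, stft_overlap = 0.5,
                         cnn_filters = c(16, 32), cbam_reduction = 16,
                         cbam_spatial_kernel = 7, enc_layers = 2,
                         enc_heads = 4, model_width = 64, ffn_mult = 4,
                         acda_heads = 4, dropout = 0.25, positional = TRUE,
                         ablation = character(0), width_scale = 1) {
  known <- c("no_dynamic_conv", "no_cbam", "no_acda", "only_time",
             "only_freq")
  if (length(setdiff(ablation, known)))
    stop("unknown ablation flag(s): ",
         paste(setdiff(ablation, known), collapse = ", "))
  if (all(c("only_time", "only_freq") %in% ablation))
    stop("`only_time` and `only_freq` are mutually exclusive")
  sc <- function(x) pmax(4L, as.integer(round(x * width_scale)))
  widths <- sc(widths); cnn_filters <- sc(cnn_filters)
  model_width <- max(enc_heads, sc(model_width))
  model_width <- (model_width %/% enc_heads) * enc_heads
  structure(list(n_channels = as.integer(n_channels),
                 epoch_samples = as.integer(epoch_samples), fs = fs,
                 widths = widths, kernel_size = as.integer(kernel_size),
                 K = as.integer(K), tau0 = tau0, reduction = reduction,
                 tokens_t = as.integer(tokens_t),
                 stft_window = as.integer(stft_window),
                 stft_overlap = stft_overlap, cnn_filters = cnn_filters,
                 cbam_reduction = cbam_reduction,
                 cbam_spatial_kernel = as.integer(cbam_spatial_kernel),
                 enc_layers = as.integer(enc_layers),
                 enc_heads = as.integer(enc_heads),
                 model_width = as.integer(model_width),
                 ffn_mult = ffn_mult, acda_heads = as.integer(acda_heads),
                 dropout = dropout, positional = positional,
                 ablation = ablation),
            class = "model_config")
}

has_time <- function(cfg) !("only_freq" %in% cfg$ablation)
has_freq <- function(cfg) !("only_time" %in% cfg$ablation)
has_acda <- function(cfg) has_time(cfg) && has_freq(cfg) &&
  !("no_acda" %in% cfg$ablation)

# Width of the pre-head fused feature.
fused_width <- function(cfg) {
  wt <- cfg$widths[length(cfg$widths)]
  if (!has_time(cfg)) return(cfg$model_width)
  if (!has_freq(cfg)) return(wt)
  if (!has_acda(cfg)) return(wt + cfg$model_width)
  cfg$model_width
}

#' Build a model from its configuration
#'
#' Initialises every parameter set the configuration calls for (ablated
#' components get no parameters at all), precomputes convolution index
#' caches, and attaches fresh mutable state (batch-norm running statistics)
#' and optimiser slots.
#'
#' @param cfg a [model_config()].
#' @param seed initialisation seed.
#' @return an `eegfuse_model`.
#' @export
build_model <- function(cfg, seed = 1L) {
  K_eff <- if ("no_dynamic_conv" %in% cfg$ablation) 1L else cfg$K
  params <- list()
  arch <- list(tokens_t = cfg$tokens_t,
               stft = stft_config(cfg$stft_window, cfg$stft_overlap),
               fs = cfg$fs, positional = cfg$positional)
  with_seed(seed, {
    if (has_time(cfg)) {
      widths <- c(cfg$n_channels, cfg$widths)
      blocks <- lapply(seq_along(cfg$widths), function(i)
        tdrb_params(widths[i], widths[i + 1], K = K_eff,
                    kernel_size = cfg$kernel_size, reduction = cfg$reduction,
                    tau = cfg$tau0))
      params$time <- list(blocks = blocks)
      arch$time_ic <- lapply(seq_along(blocks), function(i)
        list(ic1 = conv1d_index(widths[i], cfg$epoch_samples,
                                cfg$kernel_size),
             ic2 = conv1d_index(widths[i + 1], cfg$epoch_samples,
                                cfg$kernel_size)))
    }
    if (has_freq(cfg)) {
      spec_dim <- c(cfg$n_channels, cfg$stft_window %/% 2L + 1L,
                    (cfg$epoch_samples - cfg$stft_window) %/%
                      arch$stft$hop + 1L)
      params$freq <- list(cnn = cnn_params(cfg$n_channels, cfg$cnn_filters))
      arch$cnn_ic <- cnn_index_caches(params$freq$cnn, spec_dim)
      red_freq <- spec_dim[2]
      for (s in seq_along(cfg$cnn_filters)) red_freq <- red_freq %/% 2L
      f_last <- cfg$cnn_filters[length(cfg$cnn_filters)]
      if (!("no_cbam" %in% cfg$ablation)) {
        params$freq$cbam <- cbam_params(f_last, cfg$cbam_reduction,
                                        cfg$cbam_spatial_kernel)
        arch$cbam_ic <- conv2d_index(2L, red_freq, spec_dim[3],
                                     cfg$cbam_spatial_kernel,
                                     cfg$cbam_spatial_kernel)
      }
      tok_in <- f_last * red_freq
      params$freq$W_tok <- he_init(c(cfg$model_width, tok_in), tok_in)
      params$freq$b_tok <- numeric(cfg$model_width)
      params$freq$encoder <- encoder_params(cfg$model_width, cfg$enc_heads,
                                            cfg$enc_layers,
                                            cfg$ffn_mult * cfg$model_width)
      arch$tokens_f <- spec_dim[3]
      arch$model_width <- cfg$model_width
      arch$pos_cache <- positional_encoding(spec_dim[3], cfg$model_width)
    }
    if (has_acda(cfg)) {
      params$acda <- acda_params(cfg$widths[length(cfg$widths)],
                                 cfg$model_width, cfg$model_width,
                                 cfg$acda_heads)
    }
    fd <- fused_width(cfg)
    params$head <- list(W = he_init(c(2, fd), fd), b = numeric(2))
  })
  structure(list(params = params, arch = arch, cfg = cfg,
                 state = new.env(parent = emptyenv()),
                 opt = adam_init(), tau = cfg$tau0, seed = seed),
            class = "eegfuse_model")
}

#' @export
print.eegfuse_model <- function(x, ...) {
  n_par <- 0
  count <- function(p) {
    if (is.list(p)) {
      for (q in p) count(q)
    } else if (is.numeric(p)) n_par <<- n_par + length(p)
  }
  count(x$params)
  cat(sprintf(paste0("<eegfuse_model> %d ch x %d samples; widths (%s); ",
                     "K=%d tau=%g; model width %d; %s%d parameters\n"),
              x$cfg$n_channels, x$cfg$epoch_samples,
              paste(x$cfg$widths, collapse = ","),
              x$cfg$K, x$tau, x$cfg$model_width,
              if (length(x$cfg$ablation))
                paste0("ablation [", paste(x$cfg$ablation, collapse = ","),
                       "]; ") else "",
              n_par))
  invisible(x)
}

# Forward over a batch.  `xb`: array (B, C, S) or list of (C x S) matrices.
model_forward <- function(model, xb, train = FALSE, tau = model$tau,
                          trace = FALSE) {
  cfg <- model$cfg; p <- model$params; arch <- model$arch
  if (is.array(xb) && length(dim(xb)) == 3) {
    B <- dim(xb)[1]
    xl <- lapply(seq_len(B), function(i) matrix(xb[i, , ], dim(xb)[2]))
  } else {
    xl <- xb; B <- length(xl)
  }
  tfw <- NULL; ffw <- NULL
  if (has_time(cfg)) {
    Xb <- array(0, c(cfg$n_channels, cfg$epoch_samples, B))
    for (i in seq_len(B)) Xb[, , i] <- xl[[i]]
    tfw <- time_branch_fwd(Xb, p$time, arch, model$state, train, tau, trace)
  }
  if (has_freq(cfg)) {
    ffw <- freq_branch_fwd(xl, p$freq, arch, model$state, train,
                           no_cbam = "no_cbam" %in% cfg$ablation)
  }
  fd <- fused_width(cfg)
  feats <- matrix(0, fd, B)
  acda_caches <- NULL; alphas <- NULL
  if (has_acda(cfg)) {
    acda_caches <- vector("list", B); alphas <- numeric(B)
    for (i in seq_len(B)) {
      fw <- acda_fwd(t(matrix(tfw$out[, , i], dim(tfw$out)[1])),
                     matrix(ffw$out[, , i], dim(ffw$out)[1]), p$acda)
      feats[, i] <- fw$out; alphas[i] <- fw$alpha
      acda_caches[[i]] <- fw$cache
    }
  } else {
    for (i in seq_len(B)) {
      v <- c(if (has_time(cfg)) rowMeans(matrix(tfw$out[, , i],
                                                dim(tfw$out)[1])),
             if (has_freq(cfg)) colMeans(matrix(ffw$out[, , i],
                                                dim(ffw$out)[1])))
      feats[, i] <- v
    }
  }
  dp <- dropout_forward(feats, cfg$dropout, train)
  head <- linear_forward(dp$out, p$head$W, p$head$b)
  list(logits = head$out, features = feats, alphas = alphas,
       cache = list(tfw = tfw, ffw = ffw, acda = acda_caches, dp = dp$cache,
                    head = head$cache, B = B))
}

model_backward <- function(dlogits, fw, model) {
  cfg <- model$cfg; p <- model$params
  cc <- fw$cache; B <- cc$B
  hb <- linear_backward(dlogits, cc$head)
  grads <- list(head = list(W = hb$dW, b = hb$db))
  dfeat <- dropout_backward(hb$dx, cc$dp)
  dXt <- NULL; dXf <- NULL
  if (has_acda(cfg)) {
    d <- dim(cc$tfw$out); dXt <- array(0, d)
    df <- dim(cc$ffw$out); dXf <- array(0, df)
    ga <- NULL
    for (i in seq_len(B)) {
      ab <- acda_bwd(dfeat[, i], cc$acda[[i]])
      dXt[, , i] <- t(ab$dXt)
      dXf[, , i] <- ab$dXf
      ga <- add_grad_trees(ga, ab$grads)
    }
    grads$acda <- ga
  } else {
    wt <- if (has_time(cfg)) cfg$widths[length(cfg$widths)] else 0L
    if (has_time(cfg)) {
      d <- dim(cc$tfw$out); dXt <- array(0, d)
      for (i in seq_len(B))
        dXt[, , i] <- matrix(dfeat[seq_len(wt), i] / d[2], d[1], d[2])
    }
    if (has_freq(cfg)) {
      df <- dim(cc$ffw$out); dXf <- array(0, df)
      for (i in seq_len(B))
        dXf[, , i] <- matrix(dfeat[(wt + 1):nrow(dfeat), i] / df[1],
                             df[1], df[2], byrow = TRUE)
    }
  }
  if (has_time(cfg)) {
    tb <- time_branch_bwd(dXt, cc$tfw, p$time)
    grads$time <- tb$grads
  }
  if (has_freq(cfg)) {
    grads$freq <- freq_branch_bwd(dXf, cc$ffw, p$freq)
  }
  grads
}

#' Recalibrate batch-norm running statistics
#'
#' Replaces the momentum-lagged running statistics accumulated during
#' training by equal-weighted averages over one pass of the given epochs:
#' batch b contributes with weight 1/b, so after the pass every stored mean
#' and variance is the plain average of the per-batch statistics under the
#' final parameters.  Evaluation-mode predictions then see the same
#' normalisation the trained parameters were shaped by.
#'
#' @param model a trained model.
#' @param epochs an [epoch_set()] (typically the training split).
#' @param ids epoch indices to calibrate on.
#' @param batch_size forward batch size.
#' @return the model, with refreshed state.
#' @export
calibrate_bn_stats <- function(model, epochs, ids = NULL, batch_size = 32) {
  if (is.null(ids)) ids <- seq_len(dim(epochs$epochs)[1])
  for (key in ls(model$state)) rm(list = key, envir = model$state)
  b <- 0L
  for (start in seq(1, length(ids), by = batch_size)) {
    b <- b + 1L
    model$state[["bn_momentum"]] <- 1 / b
    ii <- ids[start:min(start + batch_size - 1, length(ids))]
    model_forward(model, epochs$epochs[ii, , , drop = FALSE], train = TRUE,
                  tau = model$tau)
  }
  rm("bn_momentum", envir = model$state)
  model
}

#' Predict class labels for an epoch set
#'
#' @param model a trained [build_model()] object.
#' @param epochs an [epoch_set()] (or a (B, C, S) array).
#' @param batch_size forward batch size.
#' @return list with `labels` (0/1) and `probs` (n x 2 matrix).
#' @export
predict_model <- function(model, epochs, batch_size = 32) {
  xb <- if (inherits(epochs, "epoch_set")) epochs$epochs else epochs
  n <- dim(xb)[1]
  probs <- matrix(0, n, 2)
  for (start in seq(1, n, by = batch_size)) {
    ii <- start:min(start + batch_size - 1, n)
    fw <- model_forward(model, xb[ii, , , drop = FALSE], train = FALSE,
                        tau = model$tau)
    z <- sweep(fw$logits, 2, apply(fw$logits, 2, max))
    pz <- exp(z); pz <- sweep(pz, 2, colSums(pz), "/")
    probs[ii, ] <- t(pz)
  }
  list(labels = as.integer(probs[, 2] > probs[, 1]), probs = probs)
}

#' Extract fused features for hybrid classification
#'
#' Runs the network in evaluation mode and returns the pre-head fused
#' feature (the ACDA output `O`, or the corresponding pooled features for
#' ablated variants), one row per epoch, row-aligned with the labels.
#'
#' @param model a trained model.
#' @param epochs an [epoch_set()].
#' @param batch_size forward batch size.
#' @return numeric matrix (n_epochs x fused width) with attribute
#'   `"labels"`.
#' @export
extract_features <- function(model, epochs, batch_size = 32) {
  xb <- if (inherits(epochs, "epoch_set")) epochs$epochs else epochs
  n <- dim(xb)[1]
  out <- matrix(0, n, fused_width(model$cfg))
  for (start in seq(1, n, by = batch_size)) {
    ii <- start:min(start + batch_size - 1, n)
    fw <- model_forward(model, xb[ii, , , drop = FALSE], train = FALSE,
                        tau = model$tau)
    out[ii, ] <- t(fw$features)
  }
  if (inherits(epochs, "epoch_set")) attr(out, "labels") <- epochs$labels
  out
}
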