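# Training protocol: Adam on softmax cross-entropy, mini-batches of 32,
# learning rate 0.01, with the dynamic-convolution temperature annealed from
# tau0 to 1 across the first 10 training epochs; k-fold cross-validation at
# the epoch level by default with an optional subject-level mode.

#' Training configuration
#'
#' @param batch_size mini-batch size.
#' @param epochs training epochs (full passes over the training split).
#' @param lr Adam learning rate.
#' @param folds cross-validation folds.
#' @param seed base seed; each fold re-initialises its model from
#'   `seed + fold_index`.
#' @param K dynamic-kernel count (forwarded to the model).
#' @param tau0 initial temperature (forwarded to the model and schedule).
#' @param ablation ablation flags (see [model_config()]).
#' @param subject_level if `TRUE`, folds split whole subjects so no subject
#'   contributes epochs to both a train and a test set.
#' @param clip_norm global gradient-norm ceiling per step (`Inf` disables, default 1);
#'   standard stabiliser for attention models under a large learning rate.
#' @return a `train_config`.
#' @export
train_config <- function(batch_size = 32, epochs = 100, lr = 0.01,
                         folds = 5, seed = 1L, K = 10, tau0 = 25,
                         ablation = character(0), subject_level = FALSE,
                         clip_norm = 1) {
  if (folds < 2) stop("`folds` must be >= 2")
  for (nm in c("batch_size", "epochs", "lr", "K", "tau0"))
    stopifnot_scalar_pos(get(nm), nm)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 folds = as.integer(folds), seed = as.integer(seed),
                 K = as.integer(K), tau0 = tau0, ablation = ablation,
                 subject_level = subject_level, clip_norm = clip_norm),
            class = "train_config")
}

#' Partition epochs into cross-validation folds
#'
#' Random near-equal partition (test-set sizes differ by at most 1),
#' deterministic under the seed.  In subject-level mode whole subjects are
#' assigned to folds, so no subject's epochs are split across folds.
#'
#' @param epochs an [epoch_set()], or an integer epoch count.
#' @param k number of folds (>= 2, <= number of epochs).
#' @param seed partition seed.
#' @param subject_level split whole subjects rather than epochs.
#' @return list of `fold_split` lists with `fold_index`, `train_ids`,
#'   `test_ids`.
#' @export
make_folds <- function(epochs, k = 5, seed = 1L, subject_level = FALSE) {
  n <- if (inherits(epochs, "epoch_set")) dim(epochs$epochs)[1]
       else as.integer(epochs)
  if (k > n) stop("more folds than epochs")
  if (subject_level) {
    if (!inherits(epochs, "epoch_set"))
      stop("subject-level folds need an epoch_set with subject ids")
    subjects <- unique(epochs$subject_ids)
    if (k > length(subjects)) stop("more folds than subjects")
    perm <- with_seed(seed, sample(subjects))
    groups <- split(perm, rep(seq_len(k), length.out = length(perm)))
    test_sets <- lapply(groups, function(g)
      which(epochs$subject_ids %in% g))
  } else {
    perm <- with_seed(seed, sample.int(n))
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    test_sets <- split(perm, rep(seq_len(k), times = sizes))
  }
  lapply(seq_len(k), function(i)
    structure(list(fold_index = i,
                   train_ids = sort(setdiff(seq_len(n), test_sets[[i]])),
                   test_ids = sort(test_sets[[i]])),
              class = "fold_split"))
}

# Mean cross-entropy of a model on a subset of an epoch set.
evaluate_loss <- function(model, epochs, ids, batch_size = 32) {
  tot <- 0
  for (start in seq(1, length(ids), by = batch_size)) {
    ii <- ids[start:min(start + batch_size - 1, length(ids))]
    fw <- model_forward(model, epochs$epochs[ii, , , drop = FALSE],
                        train = FALSE, tau = model$tau)
    tot <- tot + softmax_xent(fw$logits, epochs$labels[ii])$loss * length(ii)
  }
  tot / length(ids)
}

#' Train the model on one fold
#'
#' Minimises softmax cross-entropy with Adam over the training ids for
#' `cfg$epochs` passes; every dynamic convolution's temperature follows
#' [temperature_schedule()].  Evaluation on the test ids yields the fold's
#' [compute_metrics()] report.
#'
#' @param epochs an [epoch_set()].
#' @param split a `fold_split` from [make_folds()].
#' @param cfg a [train_config()].
#' @param model_cfg a [model_config()]; its `K`, `tau0` and `ablation`
#'   fields are overridden by `cfg`.
#' @param trace_attention collect kernel-attention traces per training
#'   epoch (first batch of each epoch).
#' @param verbose print per-epoch loss and temperature.
#' @return list with `model`, `metrics`, `history` (data frame of epoch,
#'   mean training loss, tau) and optionally `traces`.
#' @export
train_fold <- function(epochs, split, cfg, model_cfg,
                       trace_attention = FALSE, verbose = FALSE) {
  if (!length(split$train_ids)) stop("empty training set")
  model_cfg$K <- cfg$K
  model_cfg$tau0 <- cfg$tau0
  model_cfg$ablation <- cfg$ablation
  mcfg <- do.call(model_config, model_cfg[setdiff(names(model_cfg), "class")])
  seed <- cfg$seed + split$fold_index
  model <- build_model(mcfg, seed = seed)
  history <- data.frame(epoch = integer(), loss = double(), tau = double())
  traces <- list()
  set.seed(seed)
  for (ep in seq_len(cfg$epochs)) {
    tau <- temperature_schedule(ep, cfg$tau0)
    model$tau <- tau
    ids <- sample(split$train_ids)
    ep_loss <- 0
    first <- TRUE
    for (start in seq(1, length(ids), by = cfg$batch_size)) {
      ii <- ids[start:min(start + cfg$batch_size - 1, length(ids))]
      fw <- model_forward(model, epochs$epochs[ii, , , drop = FALSE],
                          train = TRUE, tau = tau,
                          trace = trace_attention && first)
      sx <- softmax_xent(fw$logits, epochs$labels[ii])
      ep_loss <- ep_loss + sx$loss * length(ii)
      grads <- model_backward(sx$dlogits, fw, model)
      if (is.finite(cfg$clip_norm %||% Inf)) {
        gn <- sqrt(grad_sq_norm(grads))
        if (gn > cfg$clip_norm)
          grads <- scale_grad_tree(grads, cfg$clip_norm / gn)
      }
      model$params <- adam_step(model$params, grads, model$opt, lr = cfg$lr)
      if (trace_attention && first && !is.null(fw$cache$tfw)) {
        for (bi in seq_along(fw$cache$tfw$thetas)) {
          th <- fw$cache$tfw$thetas[[bi]]
          if (!is.null(th)) {
            traces[[length(traces) + 1]] <-
              list(epoch = ep, layer = paste0("block", bi, "/conv1"),
                   theta = th$conv1)
            traces[[length(traces) + 1]] <-
              list(epoch = ep, layer = paste0("block", bi, "/conv2"),
                   theta = th$conv2)
          }
        }
      }
      first <- FALSE
    }
    ep_loss <- ep_loss / length(ids)
    history <- rbind(history,
                     data.frame(epoch = ep, loss = ep_loss, tau = tau))
    if (verbose)
      message(sprintf("fold %d epoch %3d  loss %.4f  tau %.2f",
                      split$fold_index, ep, ep_loss, tau))
  }
  model <- calibrate_bn_stats(model, epochs, split$train_ids,
                              cfg$batch_size)
  pred <- predict_model(model, epochs$epochs[split$test_ids, , ,
                                             drop = FALSE],
                        batch_size = cfg$batch_size)
  metrics <- compute_metrics(epochs$labels[split$test_ids], pred$labels)
  out <- list(model = model, metrics = metrics, history = history)
  if (trace_attention) out$traces <- traces
  out
}

#' k-fold cross-validation
#'
#' Trains one model per fold (re-initialised from `seed + fold_index`) and
#' aggregates the per-fold metric reports: their mean and the sample
#' variance of accuracy across folds.
#'
#' @param epochs an [epoch_set()].
#' @param cfg a [train_config()].
#' @param model_cfg a [model_config()].
#' @param verbose print per-epoch progress.
#' @return a `metrics_aggregate`; attribute `"folds"` holds the per-fold
#'   train results (without models, to bound memory).
#' @export
cross_validate <- function(epochs, cfg, model_cfg, verbose = FALSE) {
  splits <- make_folds(epochs, cfg$folds, cfg$seed,
                       subject_level = cfg$subject_level)
  fold_runs <- lapply(splits, function(sp) {
    r <- train_fold(epochs, sp, cfg, model_cfg, verbose = verbose)
    list(metrics = r$metrics, history = r$history)
  })
  agg <- aggregate_metrics(lapply(fold_runs, `[[`, "metrics"))
  attr(agg, "folds") <- fold_runs
  agg
}

#' Grid search over the dynamic-convolution hyperparameters
#'
#' Trains one model per (K, tau0) combination on the first fold of the data
#' and selects the pair with the minimum held-out cross-entropy; ties break
#' towards smaller K, then smaller tau0.
#'
#' @param epochs an [epoch_set()].
#' @param K_grid candidate kernel counts.
#' @param tau0_grid candidate initial temperatures.
#' @param cfg a [train_config()]; `cfg$epochs` bounds the per-combination
#'   training budget.
#' @param model_cfg a [model_config()].
#' @return list with `K`, `tau0`, and the loss table (`data.frame`).
#' @export
grid_search <- function(epochs, K_grid, tau0_grid, cfg, model_cfg) {
  if (!length(K_grid) || !length(tau0_grid)) stop("empty grid")
  split <- make_folds(epochs, cfg$folds, cfg$seed,
                      subject_level = cfg$subject_level)[[1]]
  tab <- expand.grid(K = sort(K_grid), tau0 = sort(tau0_grid))
  tab$loss <- NA_real_
  for (i in seq_len(nrow(tab))) {
    ci <- cfg; ci$K <- tab$K[i]; ci$tau0 <- tab$tau0[i]
    r <- train_fold(epochs, split, ci, model_cfg)
    tab$loss[i] <- evaluate_loss(r$model, epochs, split$test_ids,
                                 cfg$batch_size)
  }
  best <- tab[order(tab$loss, tab$K, tab$tau0), ][1, ]
  list(K = best$K, tau0 = best$tau0, table = tab)
}
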