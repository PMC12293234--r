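# EEG preprocessing chain: resample -> Butterworth bandpass -> ICA artifact
# rejection -> whole-head average reference -> mains notch -> per-channel
# z-score -> non-overlapping fixed-length epoching.  Stage order follows the
# clinical pipeline this package reproduces; every stage can be disabled from
# the config so partial chains are testable.

#' Preprocessing configuration
#'
#' @param target_fs resampling target in Hz (`NULL` disables resampling).
#' @param bandpass `c(low, high)` Butterworth band edges in Hz (`NULL`
#'   disables).
#' @param butter_order Butterworth order (applied forward-backward, so the
#'   effective attenuation is doubled).
#' @param notch_freq mains notch frequency in Hz, typically 50 or 60
#'   (0 disables).
#' @param notch_q notch quality factor (centre frequency / -3 dB width).
#' @param ica logical: run ICA artifact rejection.
#' @param ica_components number of components, or `"all"`.
#' @param ica_reject list with `cor_threshold` (absolute correlation with the
#'   frontal surrogate — the mean of the first two channels — above which a
#'   component is rejected), `kurtosis_threshold` (excess kurtosis above which
#'   a component is rejected), and `enabled`.
#' @param average_ref logical: apply whole-head average reference.
#' @param zscore logical: per-channel z-score over the whole recording.
#' @param epoch_len epoch length in seconds.
#' @param seed seed for the ICA random initialisation.
#' @return a `preprocess_config`.
#' @export
preprocess_config <- function(target_fs = 256, bandpass = c(0.5, 100),
                              butter_order = 4, notch_freq = 50, notch_q = 30,
                              ica = TRUE, ica_components = "all",
                              ica_reject = list(cor_threshold = 0.8,
                                                kurtosis_threshold = 10,
                                                enabled = TRUE),
                              average_ref = TRUE, zscore = TRUE,
                              epoch_len = 2, seed = 1L) {
  cfg <- list(target_fs = target_fs, bandpass = bandpass,
              butter_order = butter_order, notch_freq = notch_freq,
              notch_q = notch_q, ica = ica, ica_components = ica_components,
              ica_reject = ica_reject, average_ref = average_ref,
              zscore = zscore, epoch_len = epoch_len, seed = as.integer(seed))
  fs_ref <- if (is.null(target_fs)) Inf else target_fs
  if (!is.null(bandpass)) {
    if (!(bandpass[1] > 0 && bandpass[1] < bandpass[2] &&
          bandpass[2] < fs_ref / 2))
      stop("bandpass edges must satisfy 0 < low < high < target_fs/2")
  }
  if (notch_freq > 0 && notch_freq >= fs_ref / 2)
    stop("`notch_freq` must lie below the Nyquist frequency")
  stopifnot_scalar_pos(epoch_len, "epoch_len")
  structure(cfg, class = "preprocess_config")
}

#' Resample a recording (downsampling only)
#'
#' Polyphase anti-aliased resampling by the rational factor
#' `target_fs / fs`; the output length is `round(n * target_fs / fs)`.
#'
#' @param rec an [eeg_recording()].
#' @param target_fs new sampling rate in Hz; must not exceed `rec$fs`.
#' @return the resampled recording.
#' @export
resample_recording <- function(rec, target_fs) {
  if (target_fs > rec$fs)
    stop("upsampling (target_fs > fs) is not supported")
  if (target_fs == rec$fs) return(rec)
  frac <- ratio_to_integers(target_fs / rec$fs)
  n_out <- round(ncol(rec$data) * target_fs / rec$fs)
  out <- t(apply(rec$data, 1, function(ch) {
    y <- signal::resample(ch, frac[1], frac[2])
    length(y) <- n_out            # pad/trim to the rounded length
    y[is.na(y)] <- 0
    y
  }))
  eeg_recording(out, target_fs, rec$channel_names, rec$subject_id, rec$label)
}

# Smallest integer p/q representation of a ratio in (0, 1].
ratio_to_integers <- function(r, max_den = 10000L) {
  for (q in seq_len(max_den)) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) return(c(as.integer(round(p)), q))
  }
  stop("sampling-rate ratio has no small rational representation")
}

#' Zero-phase Butterworth bandpass filter
#'
#' @param rec an [eeg_recording()].
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param order Butterworth order (forward-backward application doubles the
#'   effective attenuation).
#' @return the filtered recording (same shape).
#' @export
bandpass_filter <- function(rec, low = 0.5, high = 100, order = 4) {
  nyq <- rec$fs / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("band edges must satisfy 0 < low < high < fs/2")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  # demean first: with a very low high-pass edge the forward-backward
  # transient otherwise leaks a fraction of any DC offset through
  out <- t(apply(rec$data, 1, function(ch) signal::filtfilt(bf, ch - mean(ch))))
  eeg_recording(out, rec$fs, rec$channel_names, rec$subject_id, rec$label)
}

#' Zero-phase mains notch filter
#'
#' Standard constant-gain biquad notch at `freq` with quality factor `q`,
#' applied forward-backward per channel.
#'
#' @param rec an [eeg_recording()].
#' @param freq notch centre frequency in Hz (must be below Nyquist).
#' @param q quality factor.
#' @return the filtered recording.
#' @export
notch_filter <- function(rec, freq = 50, q = 30) {
  if (freq >= rec$fs / 2) stop("notch frequency must be below Nyquist")
  w0 <- 2 * pi * freq / rec$fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  out <- t(apply(rec$data, 1, function(ch)
    signal::filtfilt(signal::Arma(b = b, a = a), ch)))
  eeg_recording(out, rec$fs, rec$channel_names, rec$subject_id, rec$label)
}

#' ICA-based artifact removal
#'
#' FastICA decomposition of the recording; components whose absolute
#' correlation with the frontal surrogate (mean of the first two channels)
#' exceeds `cor_threshold`, or whose excess kurtosis exceeds
#' `kurtosis_threshold`, are zeroed before inverting the mixing.  If the
#' decomposition does not converge the recording is passed through unchanged
#' with a warning.
#'
#' @param rec an [eeg_recording()] with at least 2 channels.
#' @param cfg a [preprocess_config()].
#' @return the cleaned recording; attribute `"rejected"` lists the zeroed
#'   component indices.
#' @export
ica_artifact_removal <- function(rec, cfg = preprocess_config()) {
  if (nrow(rec$data) < 2) stop("ICA needs at least 2 channels")
  nc <- if (identical(cfg$ica_components, "all")) nrow(rec$data)
        else min(cfg$ica_components, nrow(rec$data))
  X <- t(rec$data)                               # samples x channels
  mu <- colMeans(X)
  dec <- with_seed(cfg$seed,
                   try(ica::icafast(X, nc = nc, maxit = 300, tol = 1e-4),
                       silent = TRUE))
  if (inherits(dec, "try-error") || !isTRUE(dec$converged)) {
    warning("ICA did not converge; recording passed through unfiltered")
    return(rec)
  }
  rejected <- integer(0)
  if (isTRUE(cfg$ica_reject$enabled)) {
    frontal <- colMeans(rec$data[1:2, , drop = FALSE])
    for (k in seq_len(ncol(dec$S))) {
      ck <- abs(stats::cor(dec$S[, k], frontal))
      kk <- e1071::kurtosis(dec$S[, k])
      if (ck > cfg$ica_reject$cor_threshold ||
          kk > cfg$ica_reject$kurtosis_threshold)
        rejected <- c(rejected, k)
    }
  }
  S <- dec$S
  if (length(rejected)) S[, rejected] <- 0
  Xhat <- S %*% t(dec$M)
  out <- eeg_recording(t(sweep(Xhat, 2, mu, "+")), rec$fs,
                       rec$channel_names, rec$subject_id, rec$label)
  attr(out, "rejected") <- rejected
  out
}

#' Whole-head average reference
#'
#' Subtracts the instantaneous mean over channels from every channel, so the
#' per-timepoint channel mean is exactly zero.
#'
#' @param rec an [eeg_recording()] with at least 2 channels.
#' @return the re-referenced recording.
#' @export
average_reference <- function(rec) {
  if (nrow(rec$data) < 2) stop("average reference needs at least 2 channels")
  out <- sweep(rec$data, 2, colMeans(rec$data))
  eeg_recording(out, rec$fs, rec$channel_names, rec$subject_id, rec$label)
}

#' Per-channel z-score normalisation
#'
#' Each channel is centred and scaled to unit standard deviation over the
#' whole recording (before segmentation, so epoch statistics remain
#' comparable within a subject).
#'
#' @param rec an [eeg_recording()].
#' @return the normalised recording.
#' @export
zscore_normalize <- function(rec) {
  sds <- apply(rec$data, 1, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad))
    stop("zero-variance channel(s): ",
         paste(rec$channel_names[bad], collapse = ", "))
  out <- (rec$data - rowMeans(rec$data)) / sds
  eeg_recording(out, rec$fs, rec$channel_names, rec$subject_id, rec$label)
}

#' Construct an epoch set
#'
#' @param epochs numeric array `n_epochs x channels x samples`.
#' @param labels integer class vector of length `n_epochs`.
#' @param subject_ids character vector of length `n_epochs`.
#' @param fs sampling rate in Hz.
#' @return an `epoch_set`.
#' @export
epoch_set <- function(epochs, labels, subject_ids, fs) {
  if (length(labels) != dim(epochs)[1] || length(subject_ids) != dim(epochs)[1])
    stop("labels/subject_ids must match the epoch count")
  structure(list(epochs = epochs, labels = as.integer(labels),
                 subject_ids = subject_ids, fs = fs),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %d epochs x %d ch x %d samples @ %g Hz; labels: %s\n",
              d[1], d[2], d[3], x$fs,
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = " ")))
  invisible(x)
}

#' Segment a recording into non-overlapping fixed-length epochs
#'
#' Contiguous non-overlapping windows of `epoch_len` seconds; the trailing
#' remainder is dropped.  Each epoch carries the recording's label and
#' subject id.
#'
#' @param rec an [eeg_recording()].
#' @param epoch_len window length in seconds.
#' @return an [epoch_set()].
#' @export
segment_epochs <- function(rec, epoch_len = 2) {
  spe <- round(rec$fs * epoch_len)
  n_ep <- ncol(rec$data) %/% spe
  if (n_ep < 1) stop("recording shorter than one epoch")
  eps <- array(0, c(n_ep, nrow(rec$data), spe))
  for (i in seq_len(n_ep))
    eps[i, , ] <- rec$data[, ((i - 1) * spe + 1):(i * spe)]
  epoch_set(eps, rep(rec$label, n_ep), rep(rec$subject_id, n_ep), rec$fs)
}

# Concatenate epoch sets from several recordings.
combine_epoch_sets <- function(sets) {
  n <- sum(vapply(sets, function(s) dim(s$epochs)[1], 0L))
  d <- dim(sets[[1]]$epochs)
  eps <- array(0, c(n, d[2], d[3]))
  labels <- integer(n); ids <- character(n)
  at <- 0L
  for (s in sets) {
    k <- dim(s$epochs)[1]
    eps[(at + 1):(at + k), , ] <- s$epochs
    labels[(at + 1):(at + k)] <- s$labels
    ids[(at + 1):(at + k)] <- s$subject_ids
    at <- at + k
  }
  epoch_set(eps, labels, ids, sets[[1]]$fs)
}

#' Run the full preprocessing chain over a cohort
#'
#' Applies, in order: resampling, Butterworth bandpass, ICA artifact
#' rejection, whole-head average reference, mains notch, per-channel
#' z-score, and non-overlapping epoching; stages disabled in the config are
#' skipped.  Per-stage summaries are emitted with `message()` when
#' `verbose = TRUE`.
#'
#' @param recs list of [eeg_recording()] objects.
#' @param cfg a [preprocess_config()].
#' @param verbose emit per-stage log lines.
#' @return an [epoch_set()] pooling all subjects' epochs.
#' @export
preprocess_pipeline <- function(recs, cfg = preprocess_config(),
                                verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  sets <- lapply(recs, function(rec) {
    if (!is.null(cfg$target_fs) && cfg$target_fs != rec$fs) {
      rec <- resample_recording(rec, cfg$target_fs)
      say("%s: resampled to %g Hz", rec$subject_id, rec$fs)
    }
    if (!is.null(cfg$bandpass)) {
      rec <- bandpass_filter(rec, cfg$bandpass[1], cfg$bandpass[2],
                             cfg$butter_order)
      say("%s: bandpass %g-%g Hz", rec$subject_id,
          cfg$bandpass[1], cfg$bandpass[2])
    }
    if (isTRUE(cfg$ica)) {
      rec <- ica_artifact_removal(rec, cfg)
      say("%s: ICA rejected %d component(s)", rec$subject_id,
          length(attr(rec, "rejected")))
    }
    if (isTRUE(cfg$average_ref)) rec <- average_reference(rec)
    if (cfg$notch_freq > 0) rec <- notch_filter(rec, cfg$notch_freq, cfg$notch_q)
    if (isTRUE(cfg$zscore)) rec <- zscore_normalize(rec)
    segment_epochs(rec, cfg$epoch_len)
  })
  combine_epoch_sets(sets)
}
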