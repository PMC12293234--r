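# Shared fixtures: tiny cohorts, single-tone recordings and a scaled-down
# model configuration small enough for exact/numeric checks.

tone_recording <- function(freq, fs = 256, duration = 10, n_channels = 2) {
  t <- (seq_len(fs * duration) - 1) / fs
  data <- t(vapply(seq_len(n_channels),
                   function(ch) sin(2 * pi * freq * t + (ch - 1) * pi / 4),
                   numeric(length(t))))
  eeg_recording(data, fs, subject_id = sprintf("tone%g", freq), label = 0L)
}

small_cohort_config <- function(n_per_class = 2, ...) {
  synthetic_cohort_config(n_per_class = n_per_class, n_channels = 4,
                          fs = 128, duration = 6, seed = 7, ...)
}

# Tiny architecture: 32-sample epochs, 16-sample STFT window, width-4 blocks.
tiny_model_config <- function(...) {
  model_config(n_channels = 2, epoch_samples = 32, fs = 16,
               widths = c(4, 4, 6), kernel_size = 3, K = 2, tau0 = 2,
               tokens_t = 4, stft_window = 16, stft_overlap = 0.5,
               cnn_filters = c(4, 4), cbam_reduction = 2,
               cbam_spatial_kernel = 3, enc_layers = 1, enc_heads = 2,
               model_width = 4, ffn_mult = 2, acda_heads = 2, dropout = 0,
               ...)
}

rms <- function(x) sqrt(mean(x^2))
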