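# Preprocessing chain: each stage against a direct frequency-response or
# algebraic oracle on single-tone and synthetic inputs.

test_that("resampling halves the sample count and preserves tone frequency", {
  rec <- tone_recording(10, fs = 512, duration = 2)
  out <- resample_recording(rec, 256)
  expect_equal(ncol(out$data), 512)
  expect_equal(out$fs, 256)
  pk <- band_power(out$data[1, ], 256, 9, 11)
  rest <- band_power(out$data[1, ], 256, 20, 100)
  expect_gt(pk, rest * 100)
  expect_identical(resample_recording(rec, 512)$data, rec$data)
  expect_error(resample_recording(rec, 1024), "upsampling")
})

test_that("Butterworth bandpass removes DC, passes 10 Hz, kills 120 Hz", {
  n <- 2560; t <- (0:(n - 1)) / 256
  dc <- eeg_recording(matrix(1, 2, n), 256)
  expect_lt(rms(bandpass_filter(dc, 0.5, 100, 4)$data[1, ]), 0.01)
  inband <- tone_recording(10)
  out <- bandpass_filter(inband, 0.5, 100, 4)
  mid <- 501:2000                       # avoid filtfilt edge transients
  expect_lt(abs(rms(out$data[1, mid]) / rms(inband$data[1, mid]) - 1), 0.05)
  hi <- eeg_recording(matrix(sin(2 * pi * 120 * t), 1), 256)
  att <- 20 * log10(rms(bandpass_filter(hi, 0.5, 100, 4)$data[1, ]) /
                      rms(hi$data[1, ]))
  expect_lt(att, -20)
  expect_error(bandpass_filter(inband, 0.5, 130, 4), "fs/2")
})

test_that("notch attenuates its centre >= 20 dB and is flat in-band", {
  r50 <- tone_recording(50)
  att <- 20 * log10(rms(notch_filter(r50, 50, 30)$data[1, ]) /
                      rms(r50$data[1, ]))
  expect_lt(att, -20)
  r10 <- tone_recording(10)
  out <- notch_filter(r10, 50, 30)
  expect_lt(abs(rms(out$data[1, ]) / rms(r10$data[1, ]) - 1), 0.05)
  zero <- eeg_recording(matrix(0, 2, 512), 256)
  expect_equal(notch_filter(zero, 50, 30)$data, zero$data)
})

test_that("average reference zeroes per-timepoint channel means", {
  rec <- generate_recording(small_cohort_config(), 0L, 1)
  out <- average_reference(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-10)
  expect_equal(average_reference(out)$data, out$data, tolerance = 1e-12)
  two <- eeg_recording(rbind(a = c(1, 2, 3), b = c(3, 2, 1)), 10)
  ref <- average_reference(two)
  expect_equal(ref$data[1, ], (two$data[1, ] - two$data[2, ]) / 2)
  expect_equal(ref$data[2, ], -ref$data[1, ])
})

test_that("z-score gives unit per-channel moments and is affine-invariant", {
  rec <- generate_recording(small_cohort_config(), 1L, 2)
  out <- zscore_normalize(rec)
  expect_lt(max(abs(rowMeans(out$data))), 1e-8)
  expect_lt(max(abs(apply(out$data, 1, sd) - 1)), 1e-8)
  shifted <- rec; shifted$data <- 3 * rec$data + 5
  expect_equal(zscore_normalize(shifted)$data, out$data, tolerance = 1e-10)
  flat <- eeg_recording(rbind(rep(1, 100), rnorm(100)), 10,
                        channel_names = c("bad", "ok"))
  expect_error(zscore_normalize(flat), "bad")
})

test_that("epoching counts, remainder dropping and concatenation hold", {
  rec <- eeg_recording(matrix(rnorm(2 * 256 * 150), 2), 256)
  ep <- segment_epochs(rec, 2)
  expect_equal(dim(ep$epochs), c(75, 2, 512))
  short <- eeg_recording(matrix(rnorm(2 * round(256 * 5.5)), 2), 256)
  eps <- segment_epochs(short, 2)
  expect_equal(dim(eps$epochs)[1], 2)
  recat <- cbind(t(eps$epochs[1, 1, , drop = TRUE]),
                 t(eps$epochs[2, 1, , drop = TRUE]))
  expect_equal(as.vector(recat), short$data[1, 1:1024])
  tiny <- eeg_recording(matrix(rnorm(2 * 100), 2), 256)
  expect_error(segment_epochs(tiny, 2), "shorter")
})

test_that("ICA reduces frontal artifact correlation and reconstructs cleanly", {
  # strong frontal half-sine bumps so the rejection rule has a target
  cfg <- synthetic_cohort_config(n_per_class = 1, n_channels = 6, fs = 128,
                                 duration = 20, artifact_rate = 30,
                                 line_noise_freq = 0, noise_sd = 0.3,
                                 seed = 5)
  rec <- generate_recording(cfg, 0L, 1)
  clean_cfg <- cfg; clean_cfg$artifact_rate <- 0
  clean <- generate_recording(clean_cfg, 0L, 1)
  template <- rec$data[1, ] - clean$data[1, ]   # the injected artifact
  filt <- bandpass_filter(rec, 0.5, 60, 4)
  out <- ica_artifact_removal(filt, preprocess_config(seed = 5))
  if (length(attr(out, "rejected"))) {
    pre <- abs(cor(filt$data[1, ], template))
    post <- abs(cor(out$data[1, ], template))
    expect_lt(post, pre)
  }
  expect_equal(dim(out$data), dim(rec$data))
  # nothing flagged and rejection disabled -> reconstruction is near-exact
  cfg0 <- preprocess_config(seed = 5,
                            ica_reject = list(cor_threshold = 1,
                                              kurtosis_threshold = Inf,
                                              enabled = FALSE))
  out0 <- ica_artifact_removal(filt, cfg0)
  expect_lt(max(abs(out0$data - filt$data)), 1e-6)
})

test_that("the full pipeline epochs a small cohort with bookkeeping intact", {
  cfg <- synthetic_cohort_config(n_per_class = 2, n_channels = 4, fs = 128,
                                 duration = 10, seed = 9)
  recs <- generate_cohort(cfg)
  ep <- preprocess_pipeline(recs, preprocess_config(target_fs = 128,
                                                    bandpass = c(0.5, 60),
                                                    notch_freq = 50))
  expect_equal(dim(ep$epochs), c(4 * 5, 4, 256))
  expect_equal(as.vector(table(ep$labels)), c(10, 10))
  expect_equal(length(unique(ep$subject_ids)), 4)
  # disabling every stage reduces the pipeline to plain segmentation
  raw_cfg <- preprocess_config(target_fs = NULL, bandpass = NULL,
                               notch_freq = 0, ica = FALSE,
                               average_ref = FALSE, zscore = FALSE)
  ep_raw <- preprocess_pipeline(recs, raw_cfg)
  expect_equal(ep_raw$epochs[1, , ], recs[[1]]$data[, 1:256])
})
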