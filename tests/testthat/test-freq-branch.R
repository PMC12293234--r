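# Frequency stream: STFT against a direct windowed-DFT oracle, CNN shape
# contracts, CBAM against the standard hand-written formulas, Transformer
# encoder algebra.

naive_windowed_dft <- function(x, nw, hop) {
  # independent direct-summation STFT magnitude (one channel)
  n_frames <- (length(x) - nw) %/% hop + 1L
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nw) - 1) / (nw - 1))
  out <- matrix(0, nw %/% 2L + 1L, n_frames)
  for (f in seq_len(n_frames)) {
    seg <- x[((f - 1L) * hop + 1L):((f - 1L) * hop + nw)] * w
    for (k in 0:(nw %/% 2L)) {
      re <- sum(seg * cos(-2 * pi * k * (seq_len(nw) - 1) / nw))
      im <- sum(seg * sin(-2 * pi * k * (seq_len(nw) - 1) / nw))
      out[k + 1L, f] <- sqrt(re^2 + im^2)
    }
  }
  out
}

test_that("STFT matches frame/bin arithmetic and the naive DFT oracle", {
  ep <- matrix(sin(2 * pi * 10 * (0:511) / 256), 1)
  sp <- stft_transform(ep, stft_config(256, 0.5), fs = 256)
  expect_equal(dim(sp$values), c(1, 129, 3))
  expect_equal(sp$freq_axis[11], 10)             # 1 Hz resolution
  for (f in 1:3)
    expect_equal(which.max(sp$values[1, , f]) - 1L, 10L)
  oracle <- naive_windowed_dft(ep[1, ], 256L, 128L)
  expect_lt(max(abs(sp$values[1, , ] - oracle)), 1e-6)
  expect_equal(max(abs(stft_transform(matrix(0, 2, 512),
                                      stft_config())$values)), 0)
  expect_error(stft_transform(matrix(0, 1, 100), stft_config(256)),
               "shorter")
})

test_that("frame/bin count formulas hold for randomised shapes", {
  set.seed(8)
  for (i in 1:10) {
    nw <- 2L * sample(4:32, 1)
    ov <- sample(c(0, 0.25, 0.5, 0.75), 1)
    hop <- as.integer(round(nw * (1 - ov)))
    n <- nw + sample(0:200, 1)
    sp <- stft_transform(matrix(rnorm(n), 1), stft_config(nw, ov), fs = 100)
    expect_equal(dim(sp$values)[2], nw %/% 2L + 1L)
    expect_equal(dim(sp$values)[3], (n - nw) %/% hop + 1L)
  }
})

test_that("the CNN front-end keeps its declared shape and is input-sensitive", {
  set.seed(9)
  p <- cnn_params(2, filters = c(4, 6))
  spec <- array(abs(rnorm(2 * 33 * 3)), c(2, 33, 3))
  f <- cnn_feature_extract(spec, p)
  expect_equal(dim(f), c(6, 33 %/% 2 %/% 2, 3))
  # zero input propagates only the biases (constant over space per filter)
  f0 <- cnn_feature_extract(array(0, c(2, 33, 3)), p)
  expect_equal(max(apply(f0, 1, function(v) diff(range(v)))), 0)
  expect_false(isTRUE(all.equal(cnn_feature_extract(2 * spec, p), f)))
})

test_that("CBAM matches the standard channel/spatial formulas computed by hand", {
  set.seed(10)
  C <- 4
  p <- cbam_params(C, reduction = 2, spatial_kernel = 3)
  f <- array(rnorm(C * 5 * 3), c(C, 5, 3))
  out <- cbam_forward(f, p)
  # hand computation of the standard CBAM gates
  fm <- matrix(f, C)
  z_avg <- rowMeans(fm); z_max <- apply(fm, 1, max)
  mlp <- function(z) as.vector(p$W2 %*% pmax(p$W1 %*% z + p$b1, 0) + p$b2)
  gc <- 1 / (1 + exp(-(mlp(z_avg) + mlp(z_max))))
  f1 <- f * gc
  smap <- array(0, c(2, 5, 3))
  smap[1, , ] <- apply(f1, c(2, 3), mean)
  smap[2, , ] <- apply(f1, c(2, 3), max)
  ic <- conv2d_index(2L, 5L, 3L, 3L, 3L)
  gs <- 1 / (1 + exp(-array(conv2d_forward(smap, p$Ws, p$bs, ic)$out,
                            c(5, 3))))
  expect_equal(unclass(out), sweep(f1, c(2, 3), gs, "*"),
               ignore_attr = TRUE, tolerance = 1e-12)
  # shape preserved, gates strictly inside (0, 1)
  expect_equal(dim(out), dim(f))
  expect_true(all(attr(out, "channel_gate") > 0 &
                    attr(out, "channel_gate") < 1))
  expect_true(all(attr(out, "spatial_gate") > 0 &
                    attr(out, "spatial_gate") < 1))
})

test_that("saturated CBAM gates give identity; one-hot channel gate masks", {
  set.seed(11)
  p <- cbam_params(3, reduction = 2, spatial_kernel = 3)
  f <- array(rnorm(3 * 4 * 3), c(3, 4, 3))
  p1 <- p; p1$b2 <- rep(60, 3); p1$bs <- 60
  expect_equal(unclass(cbam_forward(f, p1)), f, ignore_attr = TRUE,
               tolerance = 1e-10)
  fm <- f
  gate <- c(1, 0, 0)
  expect_equal(max(abs((fm * gate)[2:3, , ])), 0)
})

test_that("encoder attention is row-stochastic and permutation-equivariant", {
  set.seed(12)
  p <- encoder_params(model_width = 8, n_heads = 4, n_layers = 2,
                      ffn_width = 16)
  X <- matrix(rnorm(6 * 8), 6)
  out <- transformer_encode(X, p)
  expect_equal(dim(out), dim(X))
  for (layer in attr(out, "attention")) for (A in layer) {
    expect_equal(rowSums(A), rep(1, 6), tolerance = 1e-6)
    expect_true(all(A >= 0))
  }
  perm <- sample(6)
  expect_equal(unclass(transformer_encode(X[perm, ], p)),
               unclass(out)[perm, ], ignore_attr = TRUE, tolerance = 1e-10)
  expect_error(transformer_encode(matrix(0, 3, 6), p), "model_width")
  expect_error(encoder_params(model_width = 9, n_heads = 4), "divisible")
})

test_that("the full frequency branch emits the fusion-contract shape", {
  set.seed(13)
  params <- list(cnn = cnn_params(2, c(4, 4)),
                 cbam = cbam_params(4, 2, 3),
                 W_tok = he_init(c(4, 4 * 2), 8), b_tok = numeric(4),
                 encoder = encoder_params(4, 2, 1, 8))
  ep <- matrix(rnorm(2 * 64), 2)
  xf <- freq_branch_forward(ep, params, stft_config(16, 0.5), fs = 32)
  expect_equal(dim(xf), c((64 - 16) %/% 8 + 1, 4))  # frames x width
  expect_equal(freq_branch_forward(ep, params, stft_config(16, 0.5),
                                   fs = 32), xf)
  # no-CBAM ablation changes the output but not the shape
  xf2 <- freq_branch_forward(ep, params, stft_config(16, 0.5), fs = 32,
                             no_cbam = TRUE)
  expect_equal(dim(xf2), dim(xf))
  expect_false(isTRUE(all.equal(xf2, xf)))
})
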