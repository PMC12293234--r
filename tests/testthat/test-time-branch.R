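# Dynamic convolution, kernel attention, residual blocks and the
# temperature schedule, checked against static-convolution and
# per-kernel-sum oracles.

test_that("kernel attention lies on the simplex with the right limits", {
  set.seed(1)
  p <- dynconv_params(3, 4, K = 4, kernel_size = 5, tau = 1)
  for (i in 1:20) {
    th <- kernel_attention(matrix(rnorm(3 * 32), 3), p)
    expect_true(all(th >= 0))
    expect_equal(sum(th), 1, tolerance = 1e-6)
  }
  # K = 1: softmax of a single score
  p1 <- dynconv_params(3, 4, K = 1, kernel_size = 5)
  expect_equal(as.vector(kernel_attention(matrix(rnorm(3 * 32), 3), p1)), 1)
  # high-temperature limit: near-uniform
  th <- kernel_attention(matrix(rnorm(3 * 32), 3), p, tau = 1e6)
  expect_lt(max(abs(th - 1 / 4)), 1e-3)
  # hand case s = (2, 0), tau = 1
  expect_equal(softmax(c(2, 0), 1), c(0.8808, 0.1192), tolerance = 1e-4)
  expect_error(kernel_attention(matrix(rnorm(3 * 8), 3), p, tau = 0), "tau")
})

test_that("dynamic convolution equals its per-kernel linear-combination oracle", {
  set.seed(2)
  for (rep in 1:5) {
    C <- sample(2:4, 1); K <- sample(2:5, 1); L <- sample(16:64, 1)
    Co <- sample(2:4, 1)
    p <- dynconv_params(C, Co, K = K, kernel_size = 5, tau = 2)
    x <- matrix(rnorm(C * L), C)
    y <- dynamic_conv_forward(x, p)
    th <- attr(y, "theta")
    ic <- conv1d_index(C, L, 5L)
    oracle <- 0
    for (k in seq_len(K))
      oracle <- oracle + th[k] *
        conv1d_forward(x, matrix(p$Wk[, k], Co), p$bk[, k], ic)$out
    expect_lt(max(abs(y - oracle)), 1e-5)
  }
})

test_that("K = 1 and one-hot attention reduce to a static convolution", {
  set.seed(3)
  C <- 2; L <- 24; Co <- 3
  ic <- conv1d_index(C, L, 7L)
  p1 <- dynconv_params(C, Co, K = 1, kernel_size = 7)
  x <- matrix(rnorm(C * L), C)
  static <- conv1d_forward(x, matrix(p1$Wk[, 1], Co), p1$bk[, 1], ic)$out
  expect_equal(unclass(dynamic_conv_forward(x, p1)), static,
               ignore_attr = TRUE, tolerance = 1e-12)
  p3 <- dynconv_params(C, Co, K = 3, kernel_size = 7)
  onehot <- c(0, 1, 0)
  static2 <- conv1d_forward(x, matrix(p3$Wk[, 2], Co), p3$bk[, 2], ic)$out
  expect_equal(unclass(dynamic_conv_forward(x, p3, theta = onehot)), static2,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(dynamic_conv_forward(matrix(rnorm(3 * 8), 3), p3), "channel")
})

test_that("TDRB reduces to ReLU(x) under zeroed convolutions and identity BN", {
  set.seed(4)
  p <- tdrb_params(3, 3, K = 2, kernel_size = 3)
  for (cc in c("dyconv1", "dyconv2")) { p[[cc]]$Wk[] <- 0; p[[cc]]$bk[] <- 0 }
  x <- matrix(rnorm(3 * 20), 3)
  expect_equal(tdrb_forward(x, p), pmax(x, 0), tolerance = 1e-6)
  expect_null(p$residual_proj)
})

test_that("TDRB uses a 1x1 projection exactly when channel counts differ", {
  set.seed(5)
  p <- tdrb_params(2, 5, K = 2, kernel_size = 3)
  expect_false(is.null(p$residual_proj))
  for (cc in c("dyconv1", "dyconv2")) { p[[cc]]$Wk[] <- 0; p[[cc]]$bk[] <- 0 }
  x <- matrix(rnorm(2 * 16), 2)
  y <- tdrb_forward(x, p)
  expect_equal(dim(y), c(5, 16))                 # same length, new width
  # with the conv weights zeroed the output is exactly ReLU of the projection
  proj <- p$residual_proj$Wr %*% x + p$residual_proj$br
  expect_equal(y, pmax(proj, 0), tolerance = 1e-6)
  p$residual_proj$Wr[] <- 0; p$residual_proj$br[] <- 0
  expect_equal(max(abs(tdrb_forward(x, p))), 0)
})

test_that("temperature schedule hits the printed endpoints and clamps", {
  expect_equal(temperature_schedule(1, 25), 25)
  expect_equal(temperature_schedule(10, 25), 1)
  expect_equal(temperature_schedule(50, 25), 1)
  expect_true(all(diff(vapply(1:15, temperature_schedule, 0, tau0 = 25)) <= 0))
  expect_error(temperature_schedule(0, 25), "epoch")
})

test_that("annealing makes attention entropy non-increasing for frozen scores", {
  set.seed(6)
  s <- rnorm(6)                                   # frozen MLP scores
  entropy <- function(th) -sum(th * log(th + 1e-12))
  ent <- vapply(1:12, function(e) entropy(softmax(s, temperature_schedule(e, 25))), 0)
  expect_true(all(diff(ent) <= 1e-12))
})

test_that("the time branch honours shape contracts, traces and determinism", {
  set.seed(7)
  params <- list(blocks = list(tdrb_params(2, 4, K = 3, kernel_size = 3),
                               tdrb_params(4, 8, K = 3, kernel_size = 3)))
  x <- matrix(rnorm(2 * 64), 2)
  xt <- time_branch_forward(x, params, tokens = 8, trace = TRUE)
  expect_equal(dim(xt), c(8, 8))                 # tokens x final width
  th <- attr(xt, "thetas")
  expect_length(th, 2)
  for (b in th) for (m in b) {
    expect_true(all(m >= 0))
    expect_equal(rowSums(m), rep(1, nrow(m)), tolerance = 1e-6)
  }
  xt2 <- time_branch_forward(x, params, tokens = 8)
  expect_equal(unclass(xt2), unclass(xt), ignore_attr = TRUE)
  expect_error(time_branch_forward(x, list(blocks = list())), "non-empty")
})

test_that("attention traces export to long-format CSV", {
  tr <- list(list(epoch = 1, layer = "block1/conv1",
                  theta = matrix(c(0.7, 0.3, 0.2, 0.8), 2, byrow = TRUE)))
  f <- file.path(tempdir(), "traces.csv")
  df <- export_attention_traces(tr, f)
  expect_true(file.exists(f))
  expect_equal(nrow(df), 4)
  expect_named(df, c("epoch", "layer", "sample", "k", "theta"))
})
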