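# Cross-domain attention fusion: row-stochasticity, gate range, convexity,
# directional weighting, and a step-by-step hand oracle.

test_that("cross-attention handles degenerate key sets correctly", {
  set.seed(14)
  Q <- matrix(rnorm(3 * 4), 3)
  # single key/value: attention collapses to an all-ones column
  K1 <- matrix(rnorm(4), 1); V1 <- matrix(rnorm(4), 1)
  r <- cross_attention(Q, K1, V1)
  expect_equal(as.vector(r$A), rep(1, 3))
  expect_equal(r$O, matrix(rep(V1, each = 3), 3))
  # identical keys: uniform rows 1/L
  K3 <- matrix(rep(rnorm(4), each = 3), 3); V3 <- matrix(rnorm(3 * 4), 3)
  r3 <- cross_attention(Q, K3, V3)
  expect_equal(r3$A, matrix(1 / 3, 3, 3), tolerance = 1e-12)
  expect_error(cross_attention(Q, matrix(0, 2, 5), matrix(0, 2, 4)),
               "width")
  expect_error(cross_attention(Q, matrix(0, 2, 4), matrix(0, 3, 4)),
               "length")
})

test_that("a 2-query x 3-key instance matches the hand-computed softmax", {
  Q <- matrix(c(1, 0, 0, 1), 2, 2)
  K <- matrix(c(1, 2, 0, 0, 1, 1), 3, 2)
  V <- matrix(c(1, 0, 2, 3, 1, 0), 3, 2)
  r <- cross_attention(Q, K, V, dk = 2)
  Z <- Q %*% t(K) / sqrt(2)
  A <- t(apply(Z, 1, function(z) exp(z - max(z)) / sum(exp(z - max(z)))))
  expect_lt(max(abs(r$A - A)), 1e-6)
  expect_lt(max(abs(r$O - A %*% V)), 1e-6)
})

test_that("directional weighting scales the attention map elementwise", {
  A <- matrix(c(0.2, 0.8, 0.5, 0.5), 2, byrow = TRUE)
  expect_equal(directional_weight(A, 1), A)
  expect_equal(directional_weight(A, 0), 0 * A)
  expect_equal(directional_weight(A, 2), 2 * A)
  V <- matrix(rnorm(4), 2)
  expect_equal(cross_attention(diag(2), diag(2), V, W = 0)$O,
               matrix(0, 2, 2))
})

test_that("adaptive fusion is a sigmoid-gated convex combination", {
  Ot <- c(1, 2); Of <- c(3, 4)
  # zero gate logit -> alpha = 0.5, exact midpoint
  f <- adaptive_fuse(Ot, Of, w_alpha = c(0, 0), b_alpha = 0)
  expect_equal(f$alpha, 0.5)
  expect_equal(f$O, (Ot + Of) / 2)
  # saturated gate -> O == Ot
  f1 <- adaptive_fuse(Ot, Of, w_alpha = c(0, 0), b_alpha = 20)
  expect_lt(max(abs(f1$O - Ot)), 1e-6)
  # saturated gate cuts the frequency path: perturbing Of leaves O fixed
  f2 <- adaptive_fuse(Ot, Of + 5, w_alpha = c(0, 0), b_alpha = 20)
  expect_lt(max(abs(f2$O - f1$O)), 1e-6)
  # degenerate convexity: Ot == Of -> O == Ot for any gate
  f3 <- adaptive_fuse(Ot, Ot, w_alpha = rnorm(2), b_alpha = rnorm(1))
  expect_equal(f3$O, Ot)
  expect_error(adaptive_fuse(Ot, c(1, 2, 3), c(0, 0)), "equal length")
})

test_that("acda_forward obeys its algebraic contracts", {
  set.seed(15)
  p <- acda_params(width_t = 5, width_f = 6, model_width = 8, n_heads = 2)
  Xt <- matrix(rnorm(4 * 5), 4); Xf <- matrix(rnorm(3 * 6), 3)
  r <- acda_forward(Xt, Xf, p)
  expect_length(r$O, 8)
  expect_true(r$alpha > 0 && r$alpha < 1)
  for (A in r$A_tf) expect_equal(rowSums(A), rep(1, 4), tolerance = 1e-6)
  for (A in r$A_ft) expect_equal(rowSums(A), rep(1, 3), tolerance = 1e-6)
  # O is a componentwise convex combination of the pooled attended features
  lo <- pmin(r$Ot, r$Of); hi <- pmax(r$Ot, r$Of)
  expect_true(all(r$O >= lo - 1e-12 & r$O <= hi + 1e-12))
})

test_that("a one-head hand-sized instance matches step-by-step evaluation", {
  set.seed(16)
  p <- acda_params(4, 4, model_width = 4, n_heads = 1)
  Xt <- matrix(rnorm(2 * 4), 2); Xf <- matrix(rnorm(2 * 4), 2)
  r <- acda_forward(Xt, Xf, p)
  lin <- function(X, W, b) sweep(X %*% t(W), 2, b, "+")
  Qt <- lin(Xt, p$proj_t$Wq, p$proj_t$bq)
  Kt <- lin(Xt, p$proj_t$Wk, p$proj_t$bk)
  Vt <- lin(Xt, p$proj_t$Wv, p$proj_t$bv)
  Qf <- lin(Xf, p$proj_f$Wq, p$proj_f$bq)
  Kf <- lin(Xf, p$proj_f$Wk, p$proj_f$bk)
  Vf <- lin(Xf, p$proj_f$Wv, p$proj_f$bv)
  sm <- function(Z) t(apply(Z, 1, function(z) exp(z - max(z)) /
                              sum(exp(z - max(z)))))
  A_tf <- sm(Qt %*% t(Kf) / 2)                   # sqrt(dk) = 2
  A_ft <- sm(Qf %*% t(Kt) / 2)
  Ot <- colMeans((p$Wt * A_tf) %*% Vf)
  Of <- colMeans((p$Wf * A_ft) %*% Vt)
  alpha <- 1 / (1 + exp(-(sum(p$w_alpha * Ot) + p$b_alpha)))
  expect_lt(max(abs(r$A_tf[[1]] - A_tf)), 1e-6)
  expect_lt(max(abs(r$O - (alpha * Ot + (1 - alpha) * Of))), 1e-6)
  expect_lt(abs(r$alpha - alpha), 1e-6)
})
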