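# Adaptive cross-domain attention (ACDA): bidirectional scaled dot-product
# attention between the time-domain and frequency-domain token sequences,
# learnable per-direction scalar weights applied to the post-softmax
# attention maps, mean pooling, and a sigmoid-gated convex fusion of the two
# attended features.

#' ACDA parameters
#'
#' Linear maps producing (Q, K, V) for each domain, per-direction scalar
#' weights `Wt`, `Wf` (initialised to 1), and the fusion gate `w_alpha`,
#' `b_alpha`.  The per-direction weights are scalars so the fusion stage adds
#' almost no parameters.
#'
#' @param width_t token width of the time-domain sequence.
#' @param width_f token width of the frequency-domain sequence.
#' @param model_width common projected width (divisible by `n_heads`).
#' @param n_heads attention heads.
#' @return an `acda_params` list.
#' @export
acda_params <- function(width_t, width_f, model_width = 64, n_heads = 4) {
  if (model_width %% n_heads != 0)
    stop("`model_width` must be divisible by `n_heads`")
  proj <- function(win) list(Wq = he_init(c(model_width, win), win),
                             Wk = he_init(c(model_width, win), win),
                             Wv = he_init(c(model_width, win), win),
                             bq = numeric(model_width),
                             bk = numeric(model_width),
                             bv = numeric(model_width))
  structure(list(proj_t = proj(width_t), proj_f = proj(width_f),
                 Wt = 1, Wf = 1,
                 w_alpha = stats::rnorm(model_width,
                                        sd = 1 / sqrt(model_width)),
                 b_alpha = 0,
                 n_heads = as.integer(n_heads),
                 model_width = as.integer(model_width),
                 dk = as.integer(model_width %/% n_heads)),
            class = "acda_params")
}

#' Scaled dot-product cross-attention (single head)
#'
#' `A = softmax(Q K^T / sqrt(dk))` row-wise over the other domain's keys,
#' optionally scaled by a directional weight `W` after the softmax, then
#' `O = A' V`.
#'
#' @param Q query matrix (n_q x dk).
#' @param K key matrix (n_k x dk); same width as `Q`.
#' @param V value matrix (n_k x dv).
#' @param dk key width used in the scaling (defaults to `ncol(K)`).
#' @param W directional weight scalar applied to `A` post-softmax.
#' @return list with `A` (post-softmax, pre-weighting; rows sum to 1),
#'   `A_weighted`, and `O`.
#' @export
cross_attention <- function(Q, K, V, dk = ncol(K), W = 1) {
  if (ncol(Q) != ncol(K)) stop("query/key width mismatch")
  if (nrow(K) != nrow(V)) stop("key/value length mismatch")
  A <- softmax_rows(Q %*% t(K) / sqrt(dk))
  Aw <- directional_weight(A, W)
  list(A = A, A_weighted = Aw, O = Aw %*% V)
}

#' Directional weighting of an attention map
#'
#' Elementwise scaling of a post-softmax attention map by the direction's
#' learnable scalar; note this deliberately breaks row-stochasticity of the
#' weighted map (no re-normalisation).
#'
#' @param A attention matrix.
#' @param W scalar weight.
#' @return `A * W`.
#' @export
directional_weight <- function(A, W) A * W

#' Sigmoid-gated adaptive fusion
#'
#' `alpha = sigmoid(w_alpha . Ot + b_alpha)`; `O = alpha Ot + (1-alpha) Of`.
#' The gate is computed from the time-attended feature, and the output is a
#' componentwise convex combination, so `O` always lies on the segment
#' between `Ot` and `Of`.
#'
#' @param Ot,Of pooled feature vectors of equal length.
#' @param w_alpha gate weight vector (length of `Ot`).
#' @param b_alpha gate bias scalar.
#' @return a `fused_feature` list with `O`, `alpha`, `Ot`, `Of`.
#' @export
adaptive_fuse <- function(Ot, Of, w_alpha, b_alpha = 0) {
  if (length(Ot) != length(Of)) stop("`Ot` and `Of` must have equal length")
  alpha <- sigmoid(sum(w_alpha * Ot) + b_alpha)
  structure(list(O = alpha * Ot + (1 - alpha) * Of, alpha = alpha,
                 Ot = Ot, Of = Of),
            class = "fused_feature")
}

# Internal multi-head forward with cache.  Xt: (Tt x wt), Xf: (Tf x wf).
acda_fwd <- function(Xt, Xf, p) {
  lin6 <- function(X, pr) {
    list(Q = sweep(X %*% t(pr$Wq), 2, pr$bq, "+"),
         K = sweep(X %*% t(pr$Wk), 2, pr$bk, "+"),
         V = sweep(X %*% t(pr$Wv), 2, pr$bv, "+"))
  }
  t6 <- lin6(Xt, p$proj_t); f6 <- lin6(Xf, p$proj_f)
  nh <- p$n_heads; dk <- p$dk
  Tt <- nrow(Xt); Tf <- nrow(Xf)
  Ot <- matrix(0, Tt, p$model_width); Of <- matrix(0, Tf, p$model_width)
  A_tf <- vector("list", nh); A_ft <- vector("list", nh)
  for (h in seq_len(nh)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    A_tf[[h]] <- softmax_rows(t6$Q[, cols, drop = FALSE] %*%
                                t(f6$K[, cols, drop = FALSE]) / sqrt(dk))
    Ot[, cols] <- (p$Wt * A_tf[[h]]) %*% f6$V[, cols, drop = FALSE]
    A_ft[[h]] <- softmax_rows(f6$Q[, cols, drop = FALSE] %*%
                                t(t6$K[, cols, drop = FALSE]) / sqrt(dk))
    Of[, cols] <- (p$Wf * A_ft[[h]]) %*% t6$V[, cols, drop = FALSE]
  }
  ot <- colMeans(Ot); of <- colMeans(Of)
  pre <- sum(p$w_alpha * ot) + p$b_alpha
  alpha <- sigmoid(pre)
  O <- alpha * ot + (1 - alpha) * of
  list(out = O, alpha = alpha, Ot = Ot, Of = Of, A_tf = A_tf, A_ft = A_ft,
       cache = list(Xt = Xt, Xf = Xf, t6 = t6, f6 = f6, A_tf = A_tf,
                    A_ft = A_ft, Ot = Ot, Of = Of, ot = ot, of = of,
                    alpha = alpha, p = p))
}

acda_bwd <- function(dO, cache) {
  p <- cache$p; nh <- p$n_heads; dk <- p$dk
  alpha <- cache$alpha
  dot <- alpha * dO
  dof <- (1 - alpha) * dO
  dalpha <- sum(dO * (cache$ot - cache$of))
  dpre <- dalpha * alpha * (1 - alpha)
  grads <- list(w_alpha = dpre * cache$ot, b_alpha = dpre)
  dot <- dot + dpre * p$w_alpha
  Tt <- nrow(cache$Ot); Tf <- nrow(cache$Of)
  dOt <- matrix(dot / Tt, Tt, length(dot), byrow = TRUE)
  dOf <- matrix(dof / Tf, Tf, length(dof), byrow = TRUE)
  t6 <- cache$t6; f6 <- cache$f6
  dQt <- matrix(0, Tt, p$model_width); dKt <- matrix(0, Tf, 0)
  dKf <- matrix(0, Tf, p$model_width); dVf <- dKf
  dQf <- matrix(0, Tf, p$model_width)
  dKt <- matrix(0, Tt, p$model_width); dVt <- dKt
  dWt <- 0; dWf <- 0
  for (h in seq_len(nh)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    A <- cache$A_tf[[h]]
    dOh <- dOt[, cols, drop = FALSE]
    dAw <- dOh %*% t(f6$V[, cols, drop = FALSE])
    dVf[, cols] <- t(p$Wt * A) %*% dOh
    dWt <- dWt + sum(dAw * A)
    dZ <- softmax_rows_backward(p$Wt * dAw, A) / sqrt(dk)
    dQt[, cols] <- dZ %*% f6$K[, cols, drop = FALSE]
    dKf[, cols] <- t(dZ) %*% t6$Q[, cols, drop = FALSE]
    A <- cache$A_ft[[h]]
    dOh <- dOf[, cols, drop = FALSE]
    dAw <- dOh %*% t(t6$V[, cols, drop = FALSE])
    dVt[, cols] <- t(p$Wf * A) %*% dOh
    dWf <- dWf + sum(dAw * A)
    dZ <- softmax_rows_backward(p$Wf * dAw, A) / sqrt(dk)
    dQf[, cols] <- dZ %*% t6$K[, cols, drop = FALSE]
    dKt[, cols] <- t(dZ) %*% f6$Q[, cols, drop = FALSE]
  }
  grads$Wt <- dWt; grads$Wf <- dWf
  grads$proj_t <- list(Wq = t(dQt) %*% cache$Xt, bq = colSums(dQt),
                       Wk = t(dKt) %*% cache$Xt, bk = colSums(dKt),
                       Wv = t(dVt) %*% cache$Xt, bv = colSums(dVt))
  grads$proj_f <- list(Wq = t(dQf) %*% cache$Xf, bq = colSums(dQf),
                       Wk = t(dKf) %*% cache$Xf, bk = colSums(dKf),
                       Wv = t(dVf) %*% cache$Xf, bv = colSums(dVf))
  dXt <- dQt %*% p$proj_t$Wq + dKt %*% p$proj_t$Wk + dVt %*% p$proj_t$Wv
  dXf <- dQf %*% p$proj_f$Wq + dKf %*% p$proj_f$Wk + dVf %*% p$proj_f$Wv
  list(dXt = dXt, dXf = dXf, grads = grads)
}

#' ACDA forward pass
#'
#' Projects both token sequences to Q/K/V, computes the bidirectional
#' multi-head cross-attention (time queries over frequency keys and vice
#' versa), applies the per-direction scalar weights post-softmax, pools the
#' attended sequences, and fuses them with the sigmoid gate.
#'
#' @param Xt time-domain tokens (sequence x width_t).
#' @param Xf frequency-domain tokens (sequence x width_f).
#' @param p an [acda_params()].
#' @return a `fused_feature` list with `O` (fused vector), `alpha`, pooled
#'   and unpooled `Ot`, `Of`, and the per-head attention lists `A_tf`,
#'   `A_ft` (row-stochastic, pre-weighting).
#' @export
acda_forward <- function(Xt, Xf, p) {
  fw <- acda_fwd(Xt, Xf, p)
  structure(list(O = fw$out, alpha = fw$alpha,
                 Ot = colMeans(fw$Ot), Of = colMeans(fw$Of),
                 Ot_tokens = fw$Ot, Of_tokens = fw$Of,
                 A_tf = fw$A_tf, A_ft = fw$A_ft),
            class = "fused_feature")
}
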