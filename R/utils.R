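# Shared numeric helpers and seeded-stream utilities.

#' Numerically stable softmax
#'
#' @param x numeric vector of scores.
#' @param tau temperature divisor; `tau = 1` is the standard softmax, large
#'   `tau` flattens the distribution towards uniform.
#' @return numeric vector on the simplex (non-negative, sums to 1).
#' @export
softmax <- function(x, tau = 1) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("`tau` must be a single positive number")
  z <- x / tau
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Logistic sigmoid
#' @param x numeric.
#' @return 1 / (1 + exp(-x)), elementwise.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Evaluate an expression under a temporary RNG state; the caller's stream is
# untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic 31-bit sub-stream seed derived from a base seed and a set of
# string/integer tags.  Used so each (subject, signal component) pair owns a
# named random stream: resizing a cohort never shifts another subject's draws.
substream_seed <- function(seed, ...) {
  tags <- vapply(list(...), as.character, character(1))
  h <- as.double(seed %% 2147483647L)
  for (tag in tags) {
    for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# He-style Gaussian init for a weight array whose fan-in is `fan_in`.
he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

# Walk two parallel nested lists of numeric arrays (params and grads),
# applying f(param, grad, path) and returning the updated param tree.
map_param_tree <- function(params, grads, f, path = character()) {
  if (is.list(params)) {
    out <- params
    keys <- if (is.null(names(params))) seq_along(params) else names(params)
    for (nm in keys) {
      if (is.null(grads[[nm]])) next
      out[[nm]] <- map_param_tree(params[[nm]], grads[[nm]], f,
                                  c(path, as.character(nm)))
    }
    return(out)
  }
  f(params, grads, paste(path, collapse = "/"))
}

# Sum two grad trees with identical structure (missing entries treated as 0).
add_grad_trees <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    out <- a
    keys <- if (is.null(names(a))) seq_len(max(length(a), length(b)))
            else union(names(a), names(b))
    for (nm in keys)
      out[[nm]] <- add_grad_trees(a[[nm]], b[[nm]])
    return(out)
  }
  a + b
}

# Sum of squared entries over all leaves of a grad tree.
grad_sq_norm <- function(g) {
  if (is.list(g)) return(sum(vapply(g, grad_sq_norm, 0)))
  if (is.null(g)) return(0)
  sum(g^2)
}

# Scale every leaf of a grad tree.
scale_grad_tree <- function(g, s) {
  if (is.list(g)) return(lapply(g, scale_grad_tree, s = s))
  g * s
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive finite number", name))
  invisible(x)
}
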