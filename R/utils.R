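#' @importFrom rlang abort warn inform %||%
#' @importFrom stats rnorm runif median sd cor complete.cases
#' @importFrom utils head tail modifyList
NULL

# deterministic 32-bit sub-seed derived from a base seed and index words
derive_seed <- function(base, ...) {
  words <- c(base, ...)
  s <- 0
  for (w in words) s <- (s * 69069 + as.numeric(w) + 1) %% 2147483647
  as.integer(s)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# Euclidean distances from each row of `a` (n x 3) to point `p`
dist_to_point <- function(a, p) {
  sqrt((a[, 1] - p[1])^2 + (a[, 2] - p[2])^2 + (a[, 3] - p[3])^2)
}

# all-pairs distance matrix between two n x 3 coordinate sets
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}
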