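# Internal numeric and RNG helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer.", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a base seed and an index; stays below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + as.numeric(index)) %% 2147483629)
}

#' Round half away from zero
#'
#' Display convention for the percentage tables (base `round()` rounds
#' half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(96.995) # 97.00, where round() gives 96.99 or 97 by parity
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Moore-Penrose pseudo-inverse via SVD (minimum-norm least squares).
pinv <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * max(s$d) * .Machine$double.eps
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

#' Dice similarity coefficient between two binary masks
#'
#' Set-overlap statistic `2|A ∩ B| / (|A| + |B|)` on the foreground
#' (non-zero) pixels of two label masks of equal shape. Returns 1 when both
#' masks are empty (perfect agreement on the empty set).
#'
#' @param a,b Integer or logical matrices of identical dimensions; any
#'   non-zero entry counts as foreground.
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' m1 <- matrix(c(1, 1, 0, 0), 2)
#' m2 <- matrix(c(1, 0, 0, 0), 2)
#' dice_coefficient(m1, m2) # 2/3
dice_coefficient <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("masks must have identical dimensions", call. = FALSE)
  fa <- a != 0
  fb <- b != 0
  denom <- sum(fa) + sum(fb)
  if (denom == 0) return(1)
  2 * sum(fa & fb) / denom
}

# Uniform draws in [lo, hi] using the current RNG stream.
runif_in <- function(n, lo, hi) lo + stats::runif(n) * (hi - lo)

`%||%` <- function(a, b) if (is.null(a)) b else a
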