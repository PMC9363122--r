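#' Saturating Hill activation and repression
#'
#' `hill_up()` is the canonical saturating activation
#' \eqn{x^n / (K^n + x^n)}; `hill_down()` is its repressive complement
#' \eqn{K^n / (K^n + x^n)}. Both are used throughout the model to realize
#' concentration thresholds for signaling activity: `K` is the
#' half-saturation threshold and `n` the steepness (Hill) exponent.
#'
#' @param x Nonnegative input concentration (vectorised).
#' @param K Half-saturation threshold, strictly positive.
#' @param n Hill exponent, at least 1.
#' @return Numeric vector of the same length as `x`; `hill_up()` lies in
#'   `[0, 1)` and is strictly increasing in `x`, `hill_down()` lies in
#'   `(0, 1]` and is strictly decreasing. They sum to 1 exactly.
#' @examples
#' hill_up(2, K = 1, n = 1)   # 2/3
#' hill_down(0, K = 1, n = 2) # 1
#' @export
hill_up <- function(x, K, n) {
  check_hill_args(x, K, n)
  xn <- x^n
  xn / (K^n + xn)
}

#' @rdname hill_up
#' @export
hill_down <- function(x, K, n) {
  check_hill_args(x, K, n)
  Kn <- K^n
  Kn / (Kn + x^n)
}

check_hill_args <- function(x, K, n) {
  if (any(!is.finite(K)) || any(K <= 0)) {
    stop("Hill threshold `K` must be positive and finite.", call. = FALSE)
  }
  if (any(!is.finite(n)) || any(n < 1)) {
    stop("Hill exponent `n` must be >= 1.", call. = FALSE)
  }
  if (any(x < 0)) {
    stop("Hill input `x` must be nonnegative.", call. = FALSE)
  }
  invisible(TRUE)
}

# Normalized, amplitude-bounded regulatory multipliers.
#
# reg_act(x) = (1 + amp * hill_up(x, K, n)) / (1 + amp * hill_up(1, K, n))
# reg_rep(x) analogously with hill_down. Both equal 1 at the homeostatic
# input x = 1, so every regulated rate keeps its baseline value at the
# premenopausal reference state; `amp` bounds the total fold-change a
# coupling can exert.
reg_act <- function(x, K, n, amp) {
  (1 + amp * hill_up(x, K, n)) / (1 + amp * hill_up(1, K, n))
}

reg_rep <- function(x, K, n, amp) {
  (1 + amp * hill_down(x, K, n)) / (1 + amp * hill_down(1, K, n))
}
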