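#' Hill activation and repression
#'
#' Saturable Hill response used throughout the molecular network. Activation
#' returns `x^n / (K^n + x^n)`, repression returns `K^n / (K^n + x^n)`; at equal
#' arguments the two modes sum to one.
#'
#' @param x Non-negative input concentration (vectorised).
#' @param K Half-saturation constant, strictly positive.
#' @param n Hill coefficient, `n >= 1`.
#' @param mode `"activation"` or `"repression"`.
#' @return A fraction in `[0, 1]`, same length as `x`.
#' @examples
#' hill(1, K = 1, n = 2)                      # 0.5 at half saturation
#' hill(3, K = 1, n = 4)                      # 81/82
#' hill(0.4, K = 1, n = 2, mode = "repression")
#' @export
hill <- function(x, K, n, mode = c("activation", "repression")) {
  mode <- match.arg(mode)
  if (any(!is.finite(K)) || any(K <= 0)) {
    stop("invalid parameter: Hill constant `K` must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(n)) || any(n < 1)) {
    stop("invalid parameter: Hill coefficient `n` must be >= 1", call. = FALSE)
  }
  if (any(x < 0, na.rm = TRUE)) {
    stop("invalid input: `x` must be non-negative", call. = FALSE)
  }
  # computed on the (x/K) scale to avoid overflow for large n
  r <- (x / K)^n
  a <- r / (1 + r)
  a[is.infinite(r)] <- 1
  if (mode == "activation") a else 1 - a
}
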