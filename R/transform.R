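#' Shrunken logit (M-value) transform of beta values
#'
#' Extreme beta values are first shrunk towards 0.5,
#' \eqn{B' = (B (f - 1) + 0.5) / f}, then logit-transformed in base 2,
#' \eqn{m = \log_2(B' / (1 - B'))}.  The shrinkage keeps the transform finite
#' at B = 0 and B = 1 while leaving mid-range values essentially unchanged
#' (\eqn{|B' - B| \le 0.5 / f}).
#'
#' @param B numeric vector/matrix of beta values in `[0, 1]` (`NA` allowed).
#' @param f shrinkage factor, `>= 2`; 1000 is the panel default, 2000 for
#'   datasets that include CpH sites.
#' @return m values, same shape as `B`.
#' @examples
#' betaToM(c(0, 0.5, 1), f = 1000)
#' @export
betaToM <- function(B, f = 1000) {
  stopIfNot(f >= 2, "shrinkage factor must be >= 2")
  stopIfNot(all(B >= 0 & B <= 1, na.rm = TRUE), "beta values must be in [0, 1]")
  Bp <- (B * (f - 1) + 0.5) / f
  log2(Bp / (1 - Bp))
}

#' Inverse of the M-value transform
#'
#' \eqn{B = 2^m / (2^m + 1)}.  Composed with [betaToM()] it returns the
#' shrunken value \eqn{B'}, not the raw input.
#'
#' @param m numeric vector/matrix of m values.
#' @return beta values in `(0, 1)`.
#' @export
mToBeta <- function(m) {
  ## plogis on the natural-log scale equals 2^m/(2^m+1) and never overflows
  plogis(m * log(2))
}
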