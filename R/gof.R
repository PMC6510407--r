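#' Empirical distribution function of a window sample
#'
#' Returns the right-continuous step function `t -> fraction of values <= t`
#' rising from 0 to 1 in steps of `1/L` at the order statistics.
#'
#' @param values numeric vector of window coefficients (length >= 2).
#' @return a function of one argument, vectorized over `t`.
#' @export
#' @examples
#' f <- local_edf(c(1, 2, 3, 4))
#' f(2.5)  # 0.5
local_edf <- function(values) {
  v <- as.numeric(values)
  if (length(v) < 2L) stop("window must contain at least 2 values")
  if (any(!is.finite(v))) stop("window contains non-finite values")
  stats::ecdf(v)
}

#' Anderson-Darling statistic of a sample against a reference CDF
#'
#' Tail-weighted squared distance between the sample's EDF and the reference
#' CDF, in the standard computational form on ascending order statistics
#' z_(1..L):
#' `tau = -L - (1/L) sum_t (2t - 1) [ln F(z_(t)) + ln(1 - F(z_(L+1-t)))]`.
#' Reference CDF values are clipped to `[eps, 1 - eps]` before the logs so
#' extreme outliers yield a finite (large) statistic. Large `tau` rejects
#' the reference distribution.
#'
#' @param values numeric vector, length `L >= 2` (the l*l window contents).
#' @param ref a `reference_cdf` (default standard normal).
#' @param eps log-guard for CDF clipping (default 1e-10).
#' @return the statistic `tau` (a single number, `tau >= -L`).
#' @export
#' @examples
#' ad_statistic(rep(0, 25))  # -25 + 50 log(2), about 9.657
ad_statistic <- function(values, ref = standard_reference_cdf(),
                         eps = 1e-10) {
  v <- as.numeric(values)
  if (any(!is.finite(v))) stop("window contains non-finite values")
  z <- sort(v)
  L <- length(z)
  if (L < 2L) stop("window must contain at least 2 values")
  F <- pmin(pmax(ref$evaluator(z), eps), 1 - eps)
  t <- seq_len(L)
  s <- sum((2 * t - 1) * (log(F) + log(1 - rev(F))))
  -L - s / L
}

#' Sliding-window Anderson-Darling map of a subband
#'
#' Computes `tau` for the centered `l x l` window of every coefficient of a
#' subband, with periodic (circular) boundary extension so every window
#' contains `l^2` genuine coefficients. The reference is the standard
#' normal CDF (subbands are tested after normalization). Implemented in
#' C++.
#'
#' @param subband numeric matrix of normalized coefficients.
#' @param window_side odd window side `l >= 3` (default 5).
#' @param eps log-guard, see [ad_statistic()].
#' @return numeric matrix of `tau` values, same shape as `subband`.
#' @export
ad_statistic_map <- function(subband, window_side = 5L, eps = 1e-10) {
  window_side <- as.integer(window_side)
  if (window_side %% 2 == 0 || window_side < 3L)
    stop("window side must be odd and >= 3")
  if (any(!is.finite(subband))) stop("subband contains non-finite values")
  .ad_tau_map_cpp(subband, window_side, eps)
}

#' GoF hard-decision thresholding of one subband
#'
#' For every coefficient, the AD statistic of its centered `l x l` window is
#' compared with the scale threshold `T`: the coefficient is kept verbatim
#' if `tau > T` (window looks unlike pure noise, i.e. signal) and set to 0
#' otherwise. This is a pure hard decision: retained coefficients are
#' bit-identical to their inputs.
#'
#' @param subband numeric matrix of normalized coefficients.
#' @param threshold positive scale threshold `T`.
#' @param window_side odd window side `l >= 3` (default 5).
#' @param ref reserved; the reference is the standard normal CDF.
#' @return list with `subband` (thresholded matrix) and `mask` (binary
#'   matrix, 1 = retained).
#' @export
threshold_subband <- function(subband, threshold, window_side = 5L,
                              ref = standard_reference_cdf()) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  tau <- ad_statistic_map(subband, window_side)
  mask <- (tau > threshold) * 1
  list(subband = subband * mask, mask = mask)
}
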