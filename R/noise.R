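#' Robust noise standard-deviation estimate (MAD on the finest diagonal band)
#'
#' The classical wavelet-domain estimator: the finest-scale diagonal detail
#' band of an image is essentially pure noise, so
#' `sigma_hat = median(|coefficients|) / 0.6745` (0.6745 is the median of
#' |Z| for standard normal Z), robust to the sparse signal coefficients
#' present in the band.
#'
#' @param diagonal_band numeric matrix (or vector) of finest-scale diagonal
#'   DWT coefficients.
#' @return object of class `noise_estimate` with fields `sigma` and
#'   `source_band`.
#' @export
#' @examples
#' estimate_sigma(matrix(rnorm(1e4, sd = 10), 100, 100))$sigma  # close to 10
estimate_sigma <- function(diagonal_band) {
  v <- as.numeric(diagonal_band)
  if (length(v) == 0L) stop("empty band")
  if (any(!is.finite(v))) stop("band contains non-finite values")
  structure(list(sigma = stats::median(abs(v)) / 0.6745,
                 source_band = "diagonal_scale1"),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("<noise_estimate> sigma = %.4f (from %s)\n",
              x$sigma, x$source_band))
  invisible(x)
}

# sigma estimate for a raw image: 1-level DWT, diagonal band
estimate_sigma_image <- function(image, wavelet_name = "db8") {
  p <- decompose_dwt(image, wavelet_name, 1L)
  estimate_sigma(p$detail[[1]]$diagonal)
}

resolve_gains <- function(pyramid, band_gains) {
  if (is.null(band_gains)) {
    lapply(seq_len(pyramid$levels), function(j) {
      g <- rep(1, length(pyramid$detail[[j]]))
      names(g) <- names(pyramid$detail[[j]])
      g
    })
  } else band_gains
}

#' Normalize a pyramid to unit noise variance
#'
#' Divides every detail coefficient by `sigma * band_gain` so that, when the
#' input image carries additive Gaussian noise of standard deviation
#' `sigma`, every detail band has unit noise variance and the GoF test can
#' use a single standard normal reference. For the orthonormal DWT all band
#' gains are 1 (the operation is simply `W / sigma`); for the redundant
#' DT-CWT the per-band gains from [dtcwt_band_gains()] are required. The
#' approximation band is left untouched.
#'
#' @param pyramid a [gof_pyramid].
#' @param estimate a `noise_estimate` (or a positive number).
#' @param band_gains `NULL` (all 1) or a per-scale list of named per-band
#'   positive gains.
#' @return the normalized pyramid.
#' @export
normalize_pyramid <- function(pyramid, estimate, band_gains = NULL) {
  sigma <- if (inherits(estimate, "noise_estimate")) estimate$sigma else estimate
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be positive (noise-free input should short-circuit upstream)")
  gains <- resolve_gains(pyramid, band_gains)
  for (j in seq_len(pyramid$levels))
    for (b in names(pyramid$detail[[j]]))
      pyramid$detail[[j]][[b]] <- pyramid$detail[[j]][[b]] / (sigma * gains[[j]][[b]])
  pyramid
}

#' Undo [normalize_pyramid()]
#'
#' Multiplies every detail coefficient by `sigma * band_gain`; exact inverse
#' of the normalization, applied after thresholding and before the inverse
#' transform.
#'
#' @inheritParams normalize_pyramid
#' @return the denormalized pyramid.
#' @export
denormalize_pyramid <- function(pyramid, estimate, band_gains = NULL) {
  sigma <- if (inherits(estimate, "noise_estimate")) estimate$sigma else estimate
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  gains <- resolve_gains(pyramid, band_gains)
  for (j in seq_len(pyramid$levels))
    for (b in names(pyramid$detail[[j]]))
      pyramid$detail[[j]][[b]] <- pyramid$detail[[j]][[b]] * (sigma * gains[[j]][[b]])
  pyramid
}

#' Reference noise distribution for the GoF test
#'
#' After normalization the noise in every detail band is (approximately)
#' standard normal, so the reference CDF is the standard normal CDF.
#'
#' @return object of class `reference_cdf` with fields `mean`, `sigma` and
#'   `evaluator` (a vectorized function t -> P(Z <= t)).
#' @export
standard_reference_cdf <- function() {
  structure(list(mean = 0, sigma = 1,
                 evaluator = function(t) stats::pnorm(t)),
            class = "reference_cdf")
}
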