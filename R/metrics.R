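#' Mean squared error between two images
#'
#' Mean over pixels of the squared intensity difference, computed on the
#' raw (unclipped) floating-point values.
#'
#' @param reference,estimate numeric matrices of equal dimensions.
#' @return nonnegative scalar (intensity^2 units).
#' @export
mse <- function(reference, estimate) {
  if (!all(dim(reference) == dim(estimate)))
    stop("image dimensions differ")
  mean((reference - estimate)^2)
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(255^2 / MSE)` in dB, for the 8-bit intensity range.
#' Identical images give `Inf`.
#'
#' @inheritParams mse
#' @return scalar in dB.
#' @export
#' @examples
#' # sigma = 10 Gaussian noise has MSE ~ 100, i.e. ~ 28.13 dB
#' 10 * log10(255^2 / 100)
psnr <- function(reference, estimate) {
  m <- mse(reference, estimate)
  if (m == 0) return(Inf)
  10 * log10(255^2 / m)
}

# separable Gaussian blur with periodic boundary (helper for SSIM)
gauss_blur <- function(x, sd = 1.5, half = 5L) {
  k <- stats::dnorm(-half:half, sd = sd)
  k <- k / sum(k)
  pad <- function(m) {
    n <- nrow(m)
    i <- ((-half:(n + half - 1)) %% n) + 1
    m[i, , drop = FALSE]
  }
  along <- function(m) {
    mp <- pad(m)
    out <- matrix(0, nrow(m), ncol(m))
    for (t in seq_along(k)) out <- out + k[t] * mp[t:(t + nrow(m) - 1), , drop = FALSE]
    out
  }
  t(along(t(along(x))))
}

#' Structural similarity index (mean SSIM)
#'
#' Standard single-scale SSIM with an 11-tap Gaussian window (sd 1.5) and
#' the usual stabilizers `C1 = (0.01 * 255)^2`, `C2 = (0.03 * 255)^2`.
#' Provided for reporting convenience.
#'
#' @inheritParams mse
#' @param dynamic_range intensity range (default 255).
#' @return scalar in [-1, 1] (1 for identical images).
#' @export
ssim_metric <- function(reference, estimate, dynamic_range = 255) {
  if (!all(dim(reference) == dim(estimate)))
    stop("image dimensions differ")
  C1 <- (0.01 * dynamic_range)^2
  C2 <- (0.03 * dynamic_range)^2
  mx <- gauss_blur(reference); my <- gauss_blur(estimate)
  sxx <- gauss_blur(reference^2) - mx^2
  syy <- gauss_blur(estimate^2) - my^2
  sxy <- gauss_blur(reference * estimate) - mx * my
  mean(((2 * mx * my + C1) * (2 * sxy + C2)) /
       ((mx^2 + my^2 + C1) * (sxx + syy + C2)))
}

#' Metric report for a denoising result
#'
#' @param reference clean image.
#' @param estimate denoised (or noisy) image.
#' @param ssim include SSIM (default FALSE).
#' @return list with `mse`, `psnr` and optionally `ssim`.
#' @export
metric_report <- function(reference, estimate, ssim = FALSE) {
  out <- list(mse = mse(reference, estimate),
              psnr = psnr(reference, estimate))
  if (ssim) out$ssim <- ssim_metric(reference, estimate)
  out
}
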