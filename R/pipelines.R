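#' Denoising run configuration
#'
#' Collects every tunable of the two pipelines. Defaults: db8 wavelet, 5
#' decomposition levels, 5 x 5 GoF windows, probability of false alarm
#' 0.005, 16 cycle-spin shifts, self-calibrated thresholds.
#'
#' @param transform `"dwt_ti"` (DWT + cycle spinning) or `"dtcwt"`.
#' @param wavelet_name DWT filter identifier (default `"db8"`).
#' @param levels decomposition depth `J` (default 5).
#' @param window_side odd GoF window side (default 5).
#' @param pfa probability of false alarm in (0, 0.5] (default 0.005).
#' @param shifts cycle-spin shift set (two-column matrix; `dwt_ti` only).
#' @param calibration `"auto"` (session-cached self-calibration),
#'   `"builtin"` (fixed polynomial; DWT only), or a `threshold_curve`.
#' @param seed optional integer recorded with results.
#' @return object of class `gof_config`.
#' @export
gof_config <- function(transform = c("dwt_ti", "dtcwt"),
                       wavelet_name = "db8", levels = 5L, window_side = 5L,
                       pfa = 0.005, shifts = shift_grid(4L),
                       calibration = "auto", seed = NULL) {
  transform <- match.arg(transform)
  levels <- as.integer(levels)
  window_side <- as.integer(window_side)
  if (levels < 1L) stop("levels must be >= 1")
  if (window_side %% 2 == 0 || window_side < 3L)
    stop("window side must be odd and >= 3")
  if (!is.numeric(pfa) || pfa <= 0 || pfa > 0.5)
    stop("pfa must be in (0, 0.5]")
  if (inherits(calibration, "threshold_curve")) {
    want <- if (transform == "dwt_ti") "dwt" else "dtcwt"
    if (calibration$transform != want ||
        calibration$levels != levels ||
        calibration$window_side != window_side)
      stop("calibration curve scope does not match the configuration")
  } else if (!calibration %in% c("auto", "builtin")) {
    stop("calibration must be \"auto\", \"builtin\", or a threshold_curve")
  }
  if (identical(calibration, "builtin") && transform == "dtcwt")
    stop("the builtin polynomial is a DWT default; DT-CWT needs a curve")
  structure(list(transform = transform, wavelet_name = wavelet_name,
                 levels = levels, window_side = window_side, pfa = pfa,
                 shifts = as.matrix(shifts), calibration = calibration,
                 seed = seed),
            class = "gof_config")
}

config_thresholds <- function(config) {
  tag <- if (config$transform == "dwt_ti") "dwt" else "dtcwt"
  if (identical(config$calibration, "builtin"))
    threshold_for_pfa(config$pfa, "builtin", config$levels)
  else if (inherits(config$calibration, "threshold_curve"))
    threshold_for_pfa(config$pfa, config$calibration)
  else
    threshold_for_pfa(config$pfa,
                      default_curve(tag, config$wavelet_name, config$levels,
                                    config$window_side))
}

new_denoise_result <- function(image, sigma_hat, masks, retained, config,
                               thresholds) {
  structure(list(image = image, sigma_hat = sigma_hat, masks = masks,
                 retained = retained, config = config,
                 thresholds = thresholds),
            class = "denoise_result")
}

#' @export
print.denoise_result <- function(x, ...) {
  cat(sprintf("<denoise_result> %s, %d x %d, sigma_hat = %.3f\n",
              x$config$transform, nrow(x$image), ncol(x$image),
              x$sigma_hat$sigma))
  if (!is.null(x$retained))
    cat(sprintf("  retained coefficients: %.3f%% overall\n",
                100 * mean(unlist(x$retained))))
  invisible(x)
}

retained_fractions <- function(masks) {
  lapply(masks, function(scale) vapply(scale, mean, numeric(1)))
}

#' Single-pass DWT GoFShrink
#'
#' One pass of the DWT-domain GoF denoiser, without cycle spinning:
#' decompose, estimate the noise level from the finest diagonal band,
#' normalize, test every coefficient's window with the AD statistic against
#' the per-scale threshold, zero the windows that look like pure noise,
#' denormalize and invert. The approximation band is passed through
#' untouched. A noise-free input (`sigma_hat = 0`) is returned unchanged
#' with a message.
#'
#' @param image numeric matrix.
#' @param config a [gof_config()] (transform `"dwt_ti"`).
#' @param sigma optional fixed noise estimate (used by the cycle-spinning
#'   wrapper so all shifts share one estimate).
#' @param thresholds optional fixed per-scale thresholds.
#' @return a `denoise_result`.
#' @export
gofshrink_dwt_once <- function(image, config = gof_config("dwt_ti"),
                               sigma = NULL, thresholds = NULL) {
  p <- decompose_dwt(image, config$wavelet_name, config$levels)
  if (is.null(sigma)) sigma <- estimate_sigma(p$detail[[1]]$diagonal)
  if (sigma$sigma == 0) {
    message("noise-free input (sigma_hat = 0); returning the input unchanged")
    return(new_denoise_result(image, sigma, NULL, NULL, config, NULL))
  }
  if (is.null(thresholds)) thresholds <- config_thresholds(config)
  p <- normalize_pyramid(p, sigma)
  masks <- vector("list", config$levels)
  for (j in seq_len(config$levels)) {
    masks[[j]] <- list()
    for (b in names(p$detail[[j]])) {
      th <- threshold_subband(p$detail[[j]][[b]], thresholds[j],
                              config$window_side)
      p$detail[[j]][[b]] <- th$subband
      masks[[j]][[b]] <- th$mask
    }
  }
  p <- denormalize_pyramid(p, sigma)
  new_denoise_result(reconstruct_dwt(p), sigma, masks,
                     retained_fractions(masks), config, thresholds)
}

#' Translation-invariant GoFShrink (DWT + cycle spinning)
#'
#' Wraps [gofshrink_dwt_once()] in cycle spinning over the configured shift
#' set. The noise level and the per-scale thresholds are estimated once on
#' the unshifted image and reused for every shift.
#'
#' @param image numeric matrix.
#' @param config a [gof_config()] with `transform = "dwt_ti"`.
#' @return a `denoise_result` (masks and retained fractions are those of
#'   the unshifted pass).
#' @export
gofshrink_ti <- function(image, config = gof_config("dwt_ti")) {
  stopifnot(config$transform == "dwt_ti")
  p1 <- decompose_dwt(image, config$wavelet_name, config$levels)
  sigma <- estimate_sigma(p1$detail[[1]]$diagonal)
  if (sigma$sigma == 0) {
    message("noise-free input (sigma_hat = 0); returning the input unchanged")
    return(new_denoise_result(image, sigma, NULL, NULL, config, NULL))
  }
  thresholds <- config_thresholds(config)
  base <- gofshrink_dwt_once(image, config, sigma, thresholds)
  out <- cycle_spin(function(x)
    gofshrink_dwt_once(x, config, sigma, thresholds)$image,
    image, config$shifts)
  new_denoise_result(out, sigma, base$masks, base$retained, config,
                     thresholds)
}

#' Dual-tree GoFShrink
#'
#' The DT-CWT pipeline: decompose into six oriented complex subbands per
#' scale, normalize by the noise estimate times the per-band Monte-Carlo
#' noise gain, run the windowed AD test independently on every real-part
#' and imaginary-part grid with per-(scale, part) calibrated thresholds,
#' hard-zero the noise windows, denormalize and invert. The noise level
#' comes from the same finest-diagonal DWT estimator as the DWT pipeline.
#'
#' @param image numeric matrix.
#' @param config a [gof_config()] with `transform = "dtcwt"`.
#' @return a `denoise_result`.
#' @export
gofshrink_dt <- function(image, config = gof_config("dtcwt")) {
  stopifnot(config$transform == "dtcwt")
  sigma <- estimate_sigma_image(image, config$wavelet_name)
  if (sigma$sigma == 0) {
    message("noise-free input (sigma_hat = 0); returning the input unchanged")
    return(new_denoise_result(image, sigma, NULL, NULL, config, NULL))
  }
  thresholds <- config_thresholds(config)
  gains <- dtcwt_band_gains(config$levels)
  p <- decompose_dtcwt(image, config$levels)
  p <- normalize_pyramid(p, sigma, gains)
  masks <- vector("list", config$levels)
  for (j in seq_len(config$levels)) {
    masks[[j]] <- list()
    for (b in names(p$detail[[j]])) {
      part <- if (grepl("_im$", b)) "im" else "re"
      th <- threshold_subband(p$detail[[j]][[b]], thresholds[[j]][[part]],
                              config$window_side)
      p$detail[[j]][[b]] <- th$subband
      masks[[j]][[b]] <- th$mask
    }
  }
  p <- denormalize_pyramid(p, sigma, gains)
  new_denoise_result(reconstruct_dtcwt(p), sigma, masks,
                     retained_fractions(masks), config, thresholds)
}
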