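# Threshold calibration: Monte-Carlo estimation of the null distribution of
# the windowed AD statistic on wavelet-decomposed white Gaussian noise, and
# the mapping from a probability of false alarm to a scale threshold.

#' Built-in threshold polynomial (DWT convenience default)
#'
#' A fixed degree-8 polynomial model `T(Pfa)` for the DWT configuration
#' (db8, 5 x 5 windows), shipped as a convenience default. Self-calibration
#' with [estimate_pfa_curve()] is the recommended path, because the
#' threshold-versus-Pfa relation depends on the exact statistic
#' implementation and windowing scheme.
#'
#' @return numeric vector of nine coefficients, highest degree first.
#' @export
builtin_threshold_poly <- function() {
  c(42950, -193200, 357600, -351900, 198400, -64360, 11470, -1047, 81.76)
}

polyval <- function(coeffs, x) {
  out <- 0
  for (c0 in coeffs) out <- out * x + c0
  out
}

family_name <- function(transform, scale, band) {
  if (transform == "dwt") paste0("scale", scale)
  else paste0("scale", scale, "_",
              if (grepl("_im$", band)) "im" else "re")
}

#' Monte-Carlo threshold-versus-Pfa curve
#'
#' Decomposes large white-Gaussian-noise fields with the requested
#' transform, computes the sliding-window AD statistic map of every detail
#' band (the same windows used at denoising time), and tabulates the
#' empirical false-alarm probability `pfa(T) = #(tau >= T) / #windows` on a
#' grid of thresholds. DWT curves are pooled across scales and orientations
#' (white noise is iid in every band of an orthonormal transform, so the
#' null distribution is scale free); per-scale curves are recorded alongside
#' for inspection. DT-CWT curves are estimated per (scale, part) with the
#' six orientations pooled, because the redundant transform's coefficients
#' are spatially correlated in a scale-dependent way.
#'
#' @param transform_tag `"dwt"` or `"dtcwt"`.
#' @param wavelet_name DWT filter identifier (ignored for DT-CWT).
#' @param levels decomposition depth (default 5).
#' @param window_side odd GoF window side (default 5).
#' @param noise_field_size side of the square noise fields (default 1024).
#' @param threshold_grid `NULL` (default: 200 log-spaced points spanning the
#'   pooled null statistic's 50th..99.999th percentiles) or a numeric grid.
#' @param seed RNG seed; identical seeds give identical curves.
#' @param realizations number of independent noise fields (default 4).
#' @return object of class `threshold_curve` with the (threshold, pfa)
#'   pairs per family, scope metadata, and the seed.
#' @export
estimate_pfa_curve <- function(transform_tag = c("dwt", "dtcwt"),
                               wavelet_name = "db8", levels = 5L,
                               window_side = 5L,
                               noise_field_size = 1024L,
                               threshold_grid = NULL, seed = 1L,
                               realizations = 4L) {
  transform_tag <- match.arg(transform_tag)
  levels <- as.integer(levels)
  n <- as.integer(noise_field_size)
  coarsest <- (n / 2^levels)^2 *
    (if (transform_tag == "dwt") 3 else 6) * realizations
  if (coarsest < 1e4)
    warning(sprintf(paste0("only %d windows at the coarsest scale; ",
                           "increase noise_field_size or realizations"),
                    as.integer(coarsest)))
  gains <- if (transform_tag == "dtcwt") dtcwt_band_gains(levels) else NULL

  tau_fam <- list()
  with_seed(seed, {
    for (r in seq_len(realizations)) {
      x <- matrix(stats::rnorm(n * n), n, n)
      p <- if (transform_tag == "dwt")
        decompose_dwt(x, wavelet_name, levels)
      else decompose_dtcwt(x, levels)
      for (j in seq_len(levels)) {
        for (b in names(p$detail[[j]])) {
          band <- p$detail[[j]][[b]]
          if (!is.null(gains)) band <- band / gains[[j]][[b]]
          tau <- .ad_tau_map_cpp(band, as.integer(window_side), 1e-10)
          fam <- family_name(transform_tag, j, b)
          tau_fam[[fam]] <- c(tau_fam[[fam]], as.numeric(tau))
        }
      }
    }
  })

  pooled <- unlist(tau_fam, use.names = FALSE)
  if (is.null(threshold_grid)) {
    qs <- stats::quantile(pooled, c(0.5, 0.99999), names = FALSE)
    threshold_grid <- if (qs[1] > 0)
      exp(seq(log(qs[1]), log(qs[2]), length.out = 200))
    else seq(qs[1], qs[2], length.out = 200)
  }
  make_pairs <- function(tau) {
    srt <- sort(tau)
    m <- length(srt)
    pfa <- (m - findInterval(threshold_grid, srt, left.open = FALSE)) / m
    data.frame(threshold = threshold_grid, pfa = pfa)
  }
  families <- lapply(tau_fam, make_pairs)
  if (transform_tag == "dwt") families$pooled <- make_pairs(pooled)

  curve <- structure(
    list(transform = transform_tag,
         wavelet = if (transform_tag == "dwt") wavelet_name else "qshift",
         levels = levels, window_side = as.integer(window_side),
         noise_field_size = n, realizations = as.integer(realizations),
         seed = as.integer(seed), families = families, poly = NULL),
    class = "threshold_curve")
  curve$poly <- suppressWarnings(
    tryCatch(fit_threshold_polynomial(curve), error = function(e) NULL))
  curve
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat(sprintf(
    "<threshold_curve> %s (%s), J=%d, window %dx%d, seed %d, %d family(ies)\n",
    x$transform, x$wavelet, x$levels, x$window_side, x$window_side,
    x$seed, length(x$families)))
  invisible(x)
}

#' Fit a polynomial threshold model to an empirical curve
#'
#' Degree-`degree` least-squares polynomial `T(pfa)` per curve family over
#' a validity interval (by default the curve's pfa range clipped to
#' [0.002, 0.45]: the empirical curve steepens like an extreme-quantile
#' function as pfa shrinks, which a raw polynomial cannot track). The
#' staircase of empirical pairs is resampled uniformly in pfa, and the fit
#' is damped by the smallest ridge penalty (searched over a fixed ladder)
#' that makes the fitted curve monotone decreasing on the interval — an
#' undamped degree-8 fit oscillates slightly. If no damped fit is both
#' monotone and within 2% RMS of the threshold range, the polynomial is
#' dropped with a warning and lookups use the empirical pairs (which they
#' do by default anyway; the polynomial is a compact summary).
#'
#' @param curve a `threshold_curve`.
#' @param degree polynomial degree (default 8).
#' @param pfa_range validity interval to fit over (intersected with the
#'   curve's own pfa range).
#' @return named list per family: `coeffs` (highest degree first, `NULL`
#'   when no acceptable fit exists) and `range` (pfa validity interval).
#' @export
fit_threshold_polynomial <- function(curve, degree = 8L,
                                     pfa_range = c(0.002, 0.45)) {
  lapply(curve$families, function(df) {
    df <- df[df$pfa > 0, ]
    if (length(unique(df$pfa)) < degree + 2)
      stop("too few distinct (pfa, threshold) points for the fit")
    agg <- stats::aggregate(threshold ~ pfa, df, max)
    lo <- max(pfa_range[1], min(agg$pfa))
    hi <- min(pfa_range[2], max(agg$pfa))
    pg <- seq(lo, hi, length.out = 250)
    Tg <- stats::approx(agg$pfa, agg$threshold, xout = pg)$y
    s <- pg / hi
    X <- outer(s, degree:0, `^`)
    grid <- seq(lo, hi, length.out = 800)
    Xg <- outer(grid / hi, degree:0, `^`)
    for (lam in c(0, 10^seq(-9, -3, by = 0.5))) {
      Xa <- rbind(X, sqrt(lam) * diag(degree + 1))
      cf <- tryCatch(qr.solve(Xa, c(Tg, numeric(degree + 1))),
                     error = function(e) NULL)
      if (is.null(cf)) next
      fitg <- as.numeric(Xg %*% cf)
      rms <- sqrt(mean((as.numeric(X %*% cf) - Tg)^2))
      if (all(diff(fitg) < 0) && rms <= 0.02 * diff(range(Tg))) {
        # rescale coefficients back to the pfa variable
        out <- as.numeric(cf) / hi^(degree:0)
        return(list(coeffs = out, range = c(lo, hi)))
      }
    }
    warning("no monotone polynomial fit; lookups use the empirical pairs")
    list(coeffs = NULL, range = c(lo, hi))
  })
}

curve_family_lookup <- function(curve, pfa, family) {
  df <- curve$families[[family]]
  if (is.null(df)) stop("curve has no family '", family, "'")
  df <- df[df$pfa > 0, ]
  agg <- stats::aggregate(threshold ~ pfa, df, max)   # unique, monotone
  if (pfa < min(agg$pfa) || pfa > max(agg$pfa))
    stop(sprintf("pfa = %g outside the curve's validity interval [%g, %g]",
                 pfa, min(agg$pfa), max(agg$pfa)))
  stats::approx(log(agg$pfa), agg$threshold, xout = log(pfa))$y
}

#' Threshold for a target probability of false alarm
#'
#' Maps `pfa` to per-scale decision thresholds. With a `threshold_curve`
#' the empirical pairs are interpolated (DWT: the pooled, scale-free curve,
#' one shared threshold for all scales; DT-CWT: per scale, separately for
#' real and imaginary parts). With `curve = "builtin"` the fixed polynomial
#' of [builtin_threshold_poly()] is evaluated (valid for `pfa` in [0, 1]).
#'
#' @param pfa probability of false alarm, in (0, 0.5] for curves
#'   (`[0, 1]` for the builtin polynomial).
#' @param curve a `threshold_curve`, or `"builtin"`.
#' @param levels number of scales to report when `curve = "builtin"`.
#' @return DWT/builtin: numeric vector of per-scale thresholds. DT-CWT:
#'   list per scale with elements `re` and `im`.
#' @export
#' @examples
#' threshold_for_pfa(0, "builtin", levels = 1)  # 81.76, the constant term
threshold_for_pfa <- function(pfa, curve = "builtin", levels = 5L) {
  if (identical(curve, "builtin")) {
    if (pfa < 0 || pfa > 1) stop("pfa outside [0, 1] for the builtin polynomial")
    return(rep(polyval(builtin_threshold_poly(), pfa), levels))
  }
  if (!inherits(curve, "threshold_curve"))
    stop("curve must be a threshold_curve or \"builtin\"")
  if (curve$transform == "dwt") {
    rep(curve_family_lookup(curve, pfa, "pooled"), curve$levels)
  } else {
    lapply(seq_len(curve$levels), function(j)
      c(re = curve_family_lookup(curve, pfa, paste0("scale", j, "_re")),
        im = curve_family_lookup(curve, pfa, paste0("scale", j, "_im"))))
  }
}

#' Session-cached self-calibrated curve for a configuration
#'
#' Computes (once per session, then caches) the Monte-Carlo threshold curve
#' for a transform scope with a fixed internal seed, so pipelines are
#' reproducible without the user managing curve files.
#'
#' @param transform_tag,wavelet_name,levels,window_side curve scope.
#' @return a `threshold_curve`.
#' @export
default_curve <- function(transform_tag, wavelet_name = "db8", levels = 5L,
                          window_side = 5L) {
  key <- paste("curve", transform_tag, wavelet_name, levels, window_side,
               sep = "_")
  if (is.null(.gof_cache[[key]])) {
    .gof_cache[[key]] <- estimate_pfa_curve(
      transform_tag, wavelet_name, levels, window_side,
      noise_field_size = 1024L, seed = 760102L,
      realizations = if (transform_tag == "dwt") 4L else 2L)
  }
  .gof_cache[[key]]
}

#' Write a threshold curve to disk
#'
#' Writes `<prefix>.csv` (columns family, threshold, pfa) plus
#' `<prefix>.json` with the scope metadata and seed; [read_threshold_curve()]
#' restores the object. Lookups on a restored curve refuse mismatched
#' scopes implicitly because the scope travels with the file.
#'
#' @param curve a `threshold_curve`.
#' @param prefix path prefix (without extension).
#' @return `prefix`, invisibly.
#' @export
write_threshold_curve <- function(curve, prefix) {
  rows <- do.call(rbind, lapply(names(curve$families), function(f)
    cbind(family = f, curve$families[[f]])))
  utils::write.csv(rows, paste0(prefix, ".csv"), row.names = FALSE)
  meta <- curve[c("transform", "wavelet", "levels", "window_side",
                  "noise_field_size", "realizations", "seed")]
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' Read a threshold curve written by [write_threshold_curve()]
#' @param prefix path prefix (without extension).
#' @return a `threshold_curve`.
#' @export
read_threshold_curve <- function(prefix) {
  rows <- utils::read.csv(paste0(prefix, ".csv"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  families <- lapply(split(rows, rows$family), function(df)
    data.frame(threshold = df$threshold, pfa = df$pfa))
  structure(c(meta, list(families = families, poly = NULL)),
            class = "threshold_curve")
}
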