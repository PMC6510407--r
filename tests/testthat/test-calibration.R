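test_that("empirical pfa curve has the right limits and monotonicity", {
  curve <- suppressWarnings(
    estimate_pfa_curve("dwt", levels = 2, noise_field_size = 128,
                       threshold_grid = c(0, 2, 4, 6, Inf),
                       seed = 11, realizations = 1))
  df <- curve$families$pooled
  expect_equal(df$pfa[df$threshold == Inf], 0)
  expect_gt(df$pfa[df$threshold == 0], 0.8)  # tau >= 0 for most windows
  expect_true(all(diff(df$pfa) <= 0))
  expect_true(all(df$pfa >= 0 & df$pfa <= 1))
})

test_that("curves are reproducible bit-for-bit under a fixed seed", {
  a <- suppressWarnings(estimate_pfa_curve("dwt", levels = 2,
         noise_field_size = 128, seed = 12, realizations = 1))
  b <- suppressWarnings(estimate_pfa_curve("dwt", levels = 2,
         noise_field_size = 128, seed = 12, realizations = 1))
  expect_identical(a$families, b$families)
})

test_that("DWT curves agree across scales within Monte-Carlo error", {
  curve <- dwt_curve()
  # compare per-scale thresholds at a moderate pfa: the null distribution is
  # scale free for an orthonormal transform
  p0 <- 0.01
  th <- vapply(paste0("scale", 1:4), function(f)
    gofshrink:::curve_family_lookup(curve, p0, f), numeric(1))
  # scale-to-scale spread small relative to the threshold value
  expect_lt((max(th) - min(th)) / mean(th), 0.10)
})

test_that("polynomial refit recovers an exact polynomial model", {
  coeffs <- builtin_threshold_poly()
  pfa <- seq(0.002, 0.45, length.out = 250)
  fake <- structure(list(
    transform = "dwt", wavelet = "db8", levels = 1, window_side = 5,
    families = list(pooled = data.frame(
      threshold = gofshrink:::polyval(coeffs, pfa), pfa = pfa))),
    class = "threshold_curve")
  fit <- fit_threshold_polynomial(fake, degree = 8)
  expect_equal(fit$pooled$coeffs, coeffs, tolerance = 1e-6)
})

test_that("fitted threshold model is monotone with small residuals", {
  curve <- dwt_curve()
  fit <- suppressWarnings(fit_threshold_polynomial(curve))$pooled
  expect_false(is.null(fit$coeffs))
  df <- curve$families$pooled
  df <- stats::aggregate(threshold ~ pfa, df[df$pfa > 0, ], max)
  # residual against the empirical curve, weighted uniformly in pfa over
  # the validity interval
  grid <- seq(fit$range[1], fit$range[2], length.out = 400)
  emp <- stats::approx(df$pfa, df$threshold, xout = grid)$y
  pred <- gofshrink:::polyval(fit$coeffs, grid)
  rms <- sqrt(mean((pred - emp)^2))
  expect_lt(rms, 0.02 * diff(range(emp)))
  expect_true(all(diff(pred) < 0))
})

test_that("builtin polynomial evaluates to its printed endpoints", {
  expect_equal(threshold_for_pfa(0, "builtin", 1), 81.76)
  expect_equal(threshold_for_pfa(1, "builtin", 1), -5.24, tolerance = 1e-10)
  expect_error(threshold_for_pfa(1.5, "builtin"), "outside")
})

test_that("lookup refuses pfa outside the curve's validity interval", {
  curve <- dwt_curve()
  expect_error(threshold_for_pfa(1e-9, curve), "validity")
})

test_that("curve files round trip through disk", {
  curve <- suppressWarnings(estimate_pfa_curve("dwt", levels = 2,
             noise_field_size = 128, seed = 13, realizations = 1))
  prefix <- file.path(tempdir(), "curve_rt")
  write_threshold_curve(curve, prefix)
  back <- read_threshold_curve(prefix)
  expect_equal(back$transform, "dwt")
  expect_equal(back$levels, 2)
  for (p0 in c(0.01, 0.05))
    expect_equal(threshold_for_pfa(p0, back), threshold_for_pfa(p0, curve))
})

test_that("too few coarse-scale windows triggers a warning", {
  expect_warning(
    estimate_pfa_curve("dwt", levels = 3, noise_field_size = 128,
                       threshold_grid = c(1, 5), seed = 14,
                       realizations = 1),
    "coarsest")
})
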