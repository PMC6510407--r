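cfg_fast_ti <- function(...) gof_config("dwt_ti", levels = 3,
                                        shifts = shift_grid(2), ...)

test_that("configuration is validated", {
  expect_error(gof_config("dwt_ti", pfa = 0), "pfa")
  expect_error(gof_config("dwt_ti", pfa = 0.7), "pfa")
  expect_error(gof_config("dwt_ti", window_side = 4), "odd")
  expect_error(gof_config("dtcwt", calibration = "builtin"), "DWT")
  curve <- dwt_curve()
  expect_error(gof_config("dwt_ti", levels = 3, calibration = curve),
               "scope")
  expect_silent(gof_config("dwt_ti", calibration = curve))
})

test_that("noise-free inputs short-circuit unchanged", {
  z <- matrix(0, 64, 64)
  expect_message(r <- gofshrink_dwt_once(z, cfg_fast_ti()), "noise-free")
  expect_identical(r$image, z)
  expect_message(r <- gofshrink_ti(z, cfg_fast_ti()), "noise-free")
  expect_identical(r$image, z)
  expect_message(r <- gofshrink_dt(z, gof_config("dtcwt", levels = 3)),
                 "noise-free")
  expect_identical(r$image, z)
})

test_that("pure noise is almost entirely suppressed by both pipelines", {
  noisy <- add_gaussian_noise(matrix(128, 128, 128), 20, seed = 21)
  r1 <- gofshrink_dwt_once(noisy, cfg_fast_ti())
  expect_lt(var(as.numeric(r1$image)), 0.10 * var(as.numeric(noisy)))
  r2 <- gofshrink_dt(noisy, gof_config("dtcwt", levels = 3))
  expect_lt(var(as.numeric(r2$image)), 0.10 * var(as.numeric(noisy)))
})

test_that("cycle spinning with only the zero shift equals a single pass", {
  noisy <- add_gaussian_noise(
    make_phantom(phantom_spec("piecewise_constant_shapes", 64, 1)),
    20, seed = 22)
  cfg <- gof_config("dwt_ti", levels = 3, shifts = matrix(c(0, 0), 1))
  a <- gofshrink_ti(noisy, cfg)
  b <- gofshrink_dwt_once(noisy, cfg)
  expect_equal(a$image, b$image, tolerance = 1e-12)
})

test_that("pipelines are deterministic", {
  noisy <- add_gaussian_noise(
    make_phantom(phantom_spec("mri_like_ellipses", 64, 2)), 15, seed = 23)
  cfg <- gof_config("dtcwt", levels = 3)
  expect_identical(gofshrink_dt(noisy, cfg)$image,
                   gofshrink_dt(noisy, cfg)$image)
  cfgt <- cfg_fast_ti()
  expect_identical(gofshrink_ti(noisy, cfgt)$image,
                   gofshrink_ti(noisy, cfgt)$image)
})

test_that("results expose sigma, thresholds, masks and retained fractions", {
  noisy <- add_gaussian_noise(
    make_phantom(phantom_spec("piecewise_constant_shapes", 64, 3)),
    20, seed = 24)
  r <- gofshrink_dwt_once(noisy, cfg_fast_ti())
  expect_lt(abs(r$sigma_hat$sigma - 20) / 20, 0.25)
  expect_length(r$masks, 3)
  expect_named(r$masks[[1]], c("horizontal", "vertical", "diagonal"))
  expect_true(all(unlist(r$retained) >= 0 & unlist(r$retained) <= 1))
  r2 <- gofshrink_dt(noisy, gof_config("dtcwt", levels = 3))
  expect_length(r2$masks[[1]], 12)
})

test_that("raising pfa toward 0.5 moves the output toward the noisy input", {
  clean <- make_phantom(phantom_spec("piecewise_constant_shapes", 128, 4))
  noisy <- add_gaussian_noise(clean, 10, seed = 25)
  close_db <- vapply(c(0.005, 0.05, 0.2, 0.45), function(p0) {
    r <- gofshrink_dwt_once(noisy, gof_config("dwt_ti", levels = 3, pfa = p0))
    psnr(noisy, r$image)
  }, numeric(1))
  expect_true(all(diff(close_db) > 0))
})
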