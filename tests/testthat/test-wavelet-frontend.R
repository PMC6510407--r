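test_that("constant images have zero detail coefficients", {
  x <- matrix(128, 64, 64)
  p <- decompose_dwt(x, "db8", 1)
  for (b in p$detail[[1]]) expect_lt(max(abs(b)), 1e-10)
  q <- decompose_dtcwt(x, 2)
  for (j in 1:2) for (b in q$detail[[j]]) expect_lt(max(abs(b)), 1e-9)
})

test_that("round trips are exact to tolerance across random images", {
  for (seed in 1:3) {
    x <- test_image(96, seed)
    p <- decompose_dwt(x, "db8", 3)
    expect_lt(max(abs(reconstruct_dwt(p) - x)), 1e-8)
    q <- decompose_dtcwt(x, 3)
    expect_lt(max(abs(reconstruct_dtcwt(q) - x)), 1e-6)
  }
})

test_that("odd-sized images round trip via per-level padding", {
  set.seed(4)
  x <- matrix(runif(97 * 83) * 255, 97, 83)
  p <- decompose_dwt(x, "db4", 3)
  expect_lt(max(abs(reconstruct_dwt(p) - x)), 1e-8)
  q <- decompose_dtcwt(x, 3)
  expect_lt(max(abs(reconstruct_dtcwt(q) - x)), 1e-6)
})

test_that("orthonormal DWT preserves energy and noise variance", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- matrix(rnorm(512 * 512), 512, 512)
    p <- decompose_dwt(x, "db8", 3)
    energy <- sum(unlist(lapply(p$detail, function(d) sum(unlist(d)^2)))) +
      sum(p$approx^2)
    expect_equal(energy, sum(x^2), tolerance = 1e-6)
    for (j in 1:3) for (b in p$detail[[j]])
      expect_true(var(as.numeric(b)) > 0.95 && var(as.numeric(b)) < 1.05)
  }
})

test_that("DT-CWT per-band noise gains are stable across seeds", {
  sds <- lapply(1:3, function(seed) {
    set.seed(seed)
    x <- matrix(rnorm(512 * 512), 512, 512)
    p <- decompose_dtcwt(x, 2)
    unlist(lapply(p$detail, function(d) vapply(d, sd, numeric(1))))
  })
  m <- do.call(rbind, sds)
  rel_spread <- apply(m, 2, function(v) (max(v) - min(v)) / mean(v))
  expect_lt(max(rel_spread), 0.05)
})

test_that("zero pyramids reconstruct to zero and transforms are linear", {
  x <- test_image(64, 5)
  p <- decompose_dwt(x, "db8", 2)
  p$approx[] <- 0
  for (j in 1:2) for (b in names(p$detail[[j]])) p$detail[[j]][[b]][] <- 0
  expect_equal(max(abs(reconstruct_dwt(p))), 0)
  q <- decompose_dtcwt(x, 2)
  a <- 2.7182
  q2 <- q
  q2$trees <- lapply(q2$trees, function(m) a * m)
  for (j in 1:2) for (b in names(q2$detail[[j]]))
    q2$detail[[j]][[b]] <- a * q2$detail[[j]][[b]]
  expect_lt(max(abs(reconstruct_dtcwt(q2) - a * reconstruct_dtcwt(q))), 1e-9)
})

test_that("zeroing detail bands of a noise image reduces variance", {
  set.seed(6)
  x <- matrix(rnorm(128 * 128, sd = 30), 128, 128)
  p <- decompose_dwt(x, "db8", 2)
  for (j in 1:2) for (b in names(p$detail[[j]])) p$detail[[j]][[b]][] <- 0
  y <- reconstruct_dwt(p)
  expect_lt(var(as.numeric(y)), var(as.numeric(x)))
})

test_that("dimension and configuration errors are explicit", {
  x <- matrix(1, 8, 8)
  expect_error(decompose_dwt(x, "db8", 4), "too small")
  expect_error(decompose_dwt(x, "nosuch", 1), "unknown wavelet")
  expect_error(decompose_dwt(matrix(c(1, NA, 1, 1), 2), "db1", 1),
               "non-finite")
})

test_that("cycle spinning: identity, single shift, equivariance, oracle", {
  x <- test_image(32, 7)
  expect_identical(cycle_spin(identity, x, shift_grid(3)), x)

  blur <- function(m) circ_conv_sep(m, c(1, 2, 1) / 4)
  expect_identical(cycle_spin(blur, x, matrix(c(0, 0), 1)), blur(x))

  # a circularly shift-equivariant denoiser makes the shift set irrelevant
  r1 <- cycle_spin(blur, x, shift_grid(2))
  r2 <- cycle_spin(blur, x, shift_grid(4))
  expect_lt(max(abs(r1 - r2)), 1e-9)
  expect_lt(max(abs(r1 - blur(x))), 1e-9)

  expect_error(cycle_spin(identity, x, matrix(numeric(0), 0, 2)),
               "non-empty")

  # full-grid cycle spinning of the J=1 Haar lowpass projection equals the
  # stationary-transform result: circular convolution with [1,2,1]/4 x 2
  haar_lp <- function(m) {
    p <- decompose_dwt(m, "haar", 1)
    for (b in names(p$detail[[1]])) p$detail[[1]][[b]][] <- 0
    reconstruct_dwt(p)
  }
  y <- cycle_spin(haar_lp, test_image(16, 8), shift_grid(2))
  oracle <- circ_conv_sep(test_image(16, 8), c(1, 2, 1) / 4)
  expect_lt(max(abs(y - oracle)), 1e-10)
})
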