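# Independent oracles and shared fixtures for the test suite.

# Numerical-quadrature oracle for the Anderson-Darling statistic: integrates
# L * (F_edf(t) - Phi(t))^2 / (Phi(t) (1 - Phi(t))) dPhi(t) piecewise
# between the order statistics (where the EDF is constant), in the t domain
# with dPhi = phi(t) dt. Independent of the closed-form implementation.
ad_quadrature_oracle <- function(values) {
  z <- sort(values)
  L <- length(z)
  # +-7 sigma: the truncated tail mass is ~1e-11, far below the comparison
  # tolerance, and stays clear of CDF underflow
  knots <- c(-7, z, 7)
  total <- 0
  for (k in seq_len(L + 1)) {
    lo <- knots[k]; hi <- knots[k + 1]
    if (hi <= lo) next
    Fn <- (k - 1) / L
    f <- function(t) {
      Ft <- stats::pnorm(t)
      (Fn - Ft)^2 / (Ft * (1 - Ft)) * stats::dnorm(t)
    }
    total <- total + stats::integrate(f, lo, hi, rel.tol = 1e-10,
                                      abs.tol = 1e-12)$value
  }
  L * total
}

# 2D circular convolution with a small centered separable kernel (oracle for
# linear smoothing / stationary-Haar checks)
circ_conv_sep <- function(x, k) {
  half <- (length(k) - 1) / 2
  along <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (t in seq_along(k)) {
      sh <- t - 1 - half
      idx <- ((seq_len(n) - 1 + sh) %% n) + 1
      out <- out + k[t] * m[idx, , drop = FALSE]
    }
    out
  }
  t(along(t(along(x))))
}

test_image <- function(n = 64, seed = 1) {
  set.seed(seed)
  matrix(runif(n * n) * 255, n, n)
}

# shared session-cached calibration (identical object across test files)
dwt_curve <- function() suppressWarnings(default_curve("dwt"))
dt_curve <- function() suppressWarnings(default_curve("dtcwt"))
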