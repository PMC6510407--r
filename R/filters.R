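#' Orthonormal Daubechies scaling filter
#'
#' Constructs the extremal-phase Daubechies lowpass (scaling) filter with
#' `A` vanishing moments (filter length `2 * A`) by analytic spectral
#' factorization: the binomial halfband polynomial is factored through its
#' roots in the variable `y = (1 - cos w) / 2`, so the high-multiplicity
#' zeros at z = -1 never enter a numerical root finder and the filter is
#' orthonormal to machine precision.
#'
#' @param moments number of vanishing moments `A` (filter length `2A`),
#'   between 1 and 12.
#' @return numeric vector `h0` with `sum(h0) = sqrt(2)` and unit 2-norm.
#' @keywords internal
daubechies_filter <- function(moments) {
  A <- as.integer(moments)
  if (is.na(A) || A < 1L || A > 12L)
    stop("daubechies_filter: moments must be an integer in 1..12")
  if (A == 1L) return(c(1, 1) / sqrt(2))

  # P(y) = sum_{k=0}^{A-1} C(A-1+k, k) y^k ; roots come in conjugate pairs.
  p_coef <- choose(A - 1 + 0:(A - 1), 0:(A - 1))
  yr <- polyroot(p_coef)
  # Newton refinement on P (coefficients are exact integers).
  dp <- p_coef[-1] * seq_len(A - 1)
  for (it in 1:3) {
    num <- vapply(yr, function(y) sum(p_coef * y^(0:(A - 1))), complex(1))
    den <- vapply(yr, function(y) sum(dp * y^(0:(A - 2))), complex(1))
    yr <- yr - num / den
  }
  # Map each y-root to the z-root inside the unit circle:
  # y = (2 - z - 1/z)/4  =>  z^2 - (2 - 4y) z + 1 = 0.
  zr <- vapply(yr, function(y) {
    b <- 2 - 4 * y
    d <- sqrt(b * b - 4 + 0i)
    z1 <- (b + d) / 2; z2 <- (b - d) / 2
    if (Mod(z1) < 1) z1 else z2
  }, complex(1))
  b <- 1 + 0i
  for (z in zr) b <- conv(b, c(1, -z))
  b <- Re(b)
  h <- conv(choose(A, 0:A), b)
  h <- h / sqrt(sum(h^2))
  if (sum(h) < 0) h <- -h
  h
}

#' Conjugate quadrature (highpass) mate of an even-length lowpass filter
#' @keywords internal
#' @noRd
cqf_highpass <- function(h0) {
  n <- length(h0)
  if (n %% 2 != 0) stop("cqf_highpass: filter length must be even")
  (-1)^(seq_len(n) - 1) * rev(h0)
}

# plain polynomial convolution
conv <- function(a, b) {
  n <- length(a) + length(b) - 1
  out <- vector(mode = if (is.complex(a) || is.complex(b)) "complex" else "numeric", n)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# Thiran maximally-flat fractional-delay allpass denominator, order n,
# total delay tau; returned as the monic FIR coefficient vector d (d[1]=1).
thiran_denominator <- function(n, tau) {
  d <- numeric(n + 1)
  d[1] <- 1
  for (k in seq_len(n)) {
    prod <- 1
    for (m in 0:n) prod <- prod * (tau - n + m) / (tau - n + k + m)
    d[k + 1] <- (-1)^k * choose(n, k) * prod
  }
  d
}

#' Q-shift filter pair for the dual-tree complex wavelet transform
#'
#' Designs the two orthonormal lowpass filters used at decomposition levels
#' two and deeper of the dual tree: tree-b's filter approximates a
#' half-sample delayed copy of tree-a's, which is what makes the recombined
#' subbands (approximately) analytic and hence near shift invariant. The
#' construction is the allpass common-factor method: both filters share a
#' factor `Q(z)` with `K` zeros at z = -1; tree a multiplies it by the
#' Thiran maximally-flat half-sample-delay FIR factor `D(z)` and tree b by
#' its time reverse. The remaining symmetric factor of `Q` is obtained by
#' solving the exact halfband (orthonormality) conditions as a linear system
#' and spectral-factorizing the result, so both filters are orthonormal to
#' numerical precision by construction.
#'
#' @param vanishing_moments zeros at z = -1 shared by both trees (default 2).
#' @param allpass_order order of the Thiran half-sample-delay factor
#'   (default 3).
#' @return list with even-length lowpass filters `h0` (tree a), `g0`
#'   (tree b), each with unit 2-norm and sum `sqrt(2)`.
#' @keywords internal
qshift_filters <- function(vanishing_moments = 2L, allpass_order = 3L) {
  K <- as.integer(vanishing_moments)
  L <- as.integer(allpass_order)
  if (K < 1L || L < 1L) stop("qshift_filters: orders must be >= 1")
  d <- thiran_denominator(L, 0.5)
  P <- conv(d, rev(d))                       # D(z) D(1/z), center index L+1
  B <- 1
  for (i in seq_len(K)) B <- conv(B, c(1, 2, 1))  # (1+z)(1+1/z) powers

  # symmetric unknown factor U, half-degree M chosen so the halfband
  # conditions determine it exactly
  M <- 0L
  while (M + 1L != (K + M + L) %/% 2L + 1L) M <- M + 1L
  nF <- K + M + L
  basis <- lapply(0:M, function(k) {
    u <- numeric(2 * M + 1)
    u[M + 1 + k] <- 1; u[M + 1 - k] <- 1
    if (k == 0) u[M + 1] <- 1
    conv(B, conv(u, P))                      # length 2 nF + 1, center nF + 1
  })
  lags <- seq(0L, nF, by = 2L)
  Amat <- t(vapply(lags, function(lg)
    vapply(basis, function(b) b[nF + 1 + lg], numeric(1)), numeric(M + 1)))
  rhs <- as.numeric(lags == 0L)
  u <- solve(Amat, rhs)
  U <- numeric(2 * M + 1)
  U[M + 1 + 0:M] <- u
  U[M + 1 - 0:M] <- u

  # spectral factor of U (roots come in reciprocal pairs, none on the circle
  # for these orders; verified at design time)
  rts <- polyroot(U)
  inside <- rts[Mod(rts) < 1]
  if (length(inside) != M)
    stop("qshift_filters: spectral factorization failed (roots on the circle)")
  um <- 1 + 0i
  for (z in inside) um <- conv(um, c(1, -z))
  um <- Re(um)
  auto <- conv(um, rev(um))
  um <- um * sqrt(U[M + 1] / auto[length(um)])

  q <- conv(choose(K, 0:K), um)
  h0 <- conv(q, d)
  g0 <- conv(q, rev(d))
  if (length(h0) %% 2 != 0) { h0 <- c(h0, 0); g0 <- c(g0, 0) }
  h0 <- h0 / sqrt(sum(h0^2)); if (sum(h0) < 0) h0 <- -h0
  g0 <- g0 / sqrt(sum(g0^2)); if (sum(g0) < 0) g0 <- -g0
  list(h0 = h0, g0 = g0)
}

#' Resolve a wavelet name to its analysis filter pair
#'
#' @param name filter identifier: `"dbN"` for the Daubechies family
#'   (N = vanishing moments, filter length 2N), e.g. the default `"db8"`,
#'   or `"haar"` (= `"db1"`).
#' @return list with `h0` (lowpass) and `h1` (highpass) filters.
#' @export
#' @examples
#' f <- wavelet_filter("db8")
#' sum(f$h0^2)  # 1: orthonormal
wavelet_filter <- function(name) {
  name <- tolower(as.character(name)[1])
  if (name == "haar") name <- "db1"
  m <- regmatches(name, regexec("^db([0-9]+)$", name))[[1]]
  if (length(m) != 2)
    stop("unknown wavelet '", name, "' (supported: haar, db1..db12)")
  h0 <- daubechies_filter(as.integer(m[2]))
  list(h0 = h0, h1 = cqf_highpass(h0), name = name)
}
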