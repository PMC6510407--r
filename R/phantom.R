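#' Phantom specification
#'
#' @param kind one of `"piecewise_constant_shapes"`, `"smooth_gradient"`,
#'   `"mri_like_ellipses"`, `"multifocus_texture"`.
#' @param size image side in pixels (>= 64).
#' @param seed RNG seed for the randomized kinds (default 1).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("piecewise_constant_shapes",
                                  "smooth_gradient", "mri_like_ellipses",
                                  "multifocus_texture"),
                         size = 256L, seed = 1L) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (size < 64L) stop("phantom size must be >= 64")
  structure(list(kind = kind, size = size, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Synthetic grayscale test phantoms
#'
#' Deterministic (seeded) clean test images in [0, 255] containing both
#' smooth regions and oriented edges, so the directional subbands of the
#' dual-tree transform are exercised. Kinds:
#' \describe{
#'   \item{piecewise_constant_shapes}{constant background with randomly
#'     placed axis-aligned and rotated rectangles and disks of distinct
#'     constant intensities.}
#'   \item{smooth_gradient}{a smooth two-dimensional intensity ramp plus a
#'     diagonal ridge.}
#'   \item{mri_like_ellipses}{nested rotated ellipses of distinct
#'     intensities on a dark background, loosely evoking a brain slice.}
#'   \item{multifocus_texture}{oriented sinusoidal gratings of different
#'     frequencies in the four quadrants.}
#' }
#'
#' @param spec a [phantom_spec()].
#' @return numeric matrix `size x size` with values in [0, 255].
#' @export
#' @examples
#' x <- make_phantom(phantom_spec("mri_like_ellipses", 128, seed = 7))
#' range(x)
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("unknown phantom specification")
  n <- spec$size
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  rr <- matrix(g$r, n, n); cc <- matrix(g$c, n, n)
  u <- (cc - 1) / (n - 1); v <- (rr - 1) / (n - 1)   # in [0,1]

  img <- with_seed(spec$seed, switch(spec$kind,
    piecewise_constant_shapes = {
      x <- matrix(40, n, n)
      for (i in 1:6) {   # rotated rectangles
        ang <- stats::runif(1, 0, pi)
        cx <- stats::runif(1, 0.2, 0.8); cy <- stats::runif(1, 0.2, 0.8)
        w <- stats::runif(1, 0.08, 0.25); h <- stats::runif(1, 0.08, 0.25)
        lev <- stats::runif(1, 80, 240)
        du <- (u - cx) * cos(ang) + (v - cy) * sin(ang)
        dv <- -(u - cx) * sin(ang) + (v - cy) * cos(ang)
        x[abs(du) < w & abs(dv) < h] <- lev
      }
      for (i in 1:4) {   # disks
        cx <- stats::runif(1, 0.2, 0.8); cy <- stats::runif(1, 0.2, 0.8)
        rad <- stats::runif(1, 0.05, 0.18)
        lev <- stats::runif(1, 60, 250)
        x[(u - cx)^2 + (v - cy)^2 < rad^2] <- lev
      }
      x
    },
    smooth_gradient = {
      base <- 60 + 120 * u * v + 50 * sin(pi * u)
      ridge <- 70 * exp(-((u - v) / 0.05)^2)
      base + ridge
    },
    mri_like_ellipses = {
      x <- matrix(15, n, n)
      ell <- function(cx, cy, a, b, ang, lev) {
        du <- (u - cx) * cos(ang) + (v - cy) * sin(ang)
        dv <- -(u - cx) * sin(ang) + (v - cy) * cos(ang)
        x[(du / a)^2 + (dv / b)^2 < 1] <<- lev
      }
      ell(0.5, 0.5, 0.40, 0.32, 0.1, 200)   # skull
      ell(0.5, 0.5, 0.36, 0.28, 0.1, 110)   # cortex
      ell(0.42, 0.45, 0.10, 0.16, 0.35, 160)
      ell(0.60, 0.50, 0.09, 0.14, -0.30, 70)
      ell(0.50, 0.62, 0.07, 0.05, 0.0, 230)
      ell(0.46, 0.38, 0.03, 0.05, 0.6, 40)
      x
    },
    multifocus_texture = {
      q <- matrix(0, n, n)
      tl <- rr <= n / 2 & cc <= n / 2
      tr <- rr <= n / 2 & cc > n / 2
      bl <- rr > n / 2 & cc <= n / 2
      q[tl] <- 128 + 90 * sin(2 * pi * 8 * (u + v))[tl]
      q[tr] <- 128 + 90 * sin(2 * pi * 12 * (u - v))[tr]
      q[bl] <- 128 + 90 * sin(2 * pi * 10 * u)[bl]
      q[!(tl | tr | bl)] <- 128 + 60 * sin(2 * pi * 5 * v)[!(tl | tr | bl)]
      q
    }))
  pmin(pmax(img, 0), 255)
}

#' Add white Gaussian noise to an image
#'
#' Returns `image + N(0, sigma^2)` pixelwise, unclipped (metrics and the
#' pipelines operate on unclipped intensities; clipping happens only when
#' an image is written to disk).
#'
#' @param image numeric matrix.
#' @param sigma noise standard deviation in intensity units (>= 0).
#' @param seed optional RNG seed.
#' @return numeric matrix, same dimensions.
#' @export
add_gaussian_noise <- function(image, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(image)
  noise <- if (is.null(seed))
    stats::rnorm(length(image), sd = sigma)
  else with_seed(seed, stats::rnorm(length(image), sd = sigma))
  image + matrix(noise, nrow(image), ncol(image))
}
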