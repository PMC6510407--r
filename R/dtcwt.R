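# Dual-tree complex wavelet transform.
#
# Four separable 2D trees are run in parallel, indexed by which filter set
# processes rows and columns: tree "a" and tree "b". At level 1 both trees
# use the same orthonormal Daubechies bank with tree b offset by one sample;
# at deeper levels tree a uses the q-shift lowpass and tree b its
# half-sample-delayed mate. Oriented complex subbands are formed from the
# four real subbands of each type by the unitary combination
#   w+ = (aa - bb)/sqrt(2) + i (ab + ba)/sqrt(2)
#   w- = (aa + bb)/sqrt(2) + i (ab - ba)/sqrt(2)
# giving six orientations per scale (two from each of the three subband
# types), whose real and imaginary parts are stored as 12 separate grids.
# Each tree is an exactly orthonormal transform, so inversion is the adjoint
# per tree followed by averaging the four reconstructions.

dt_first_level <- function() {
  f <- wavelet_filter("db5")
  list(h0 = f$h0, h1 = f$h1)
}

dt_filters <- function() {
  qs <- qshift_filters()
  list(first = dt_first_level(),
       a = list(h0 = qs$h0, h1 = cqf_highpass(qs$h0)),
       b = list(h0 = qs$g0, h1 = cqf_highpass(qs$g0)))
}

# band-type -> orientation-pair labels (nominal degrees)
dt_orient <- list(lh = c("d15", "d165"), hl = c("d75", "d105"),
                  hh = c("d45", "d135"))

dt_level_filters <- function(filters, tree, level) {
  if (level == 1L) {
    list(f = filters$first, off = if (tree == "a") 0L else 1L)
  } else {
    list(f = filters[[tree]], off = 0L)
  }
}

#' Forward dual-tree complex wavelet transform
#'
#' Decomposes a grayscale image into six oriented complex detail subbands
#' per scale (nominal orientations 15, 45, 75, 105, 135, 165 degrees), with
#' real and imaginary parts exposed as 12 separate real grids per scale.
#' The transform is 4:1 redundant, near shift invariant and directionally
#' selective, and reconstructs the input to numerical precision. Boundary
#' handling is periodized; dimensions must be even at every level
#' (odd dims are edge-padded per level and cropped on reconstruction).
#'
#' @param image numeric matrix.
#' @param levels decomposition depth `J >= 1`.
#' @return a [gof_pyramid] with `transform = "dtcwt"`, detail bands named
#'   `d15_re, d15_im, ..., d165_im`.
#' @export
decompose_dtcwt <- function(image, levels = 5L) {
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  check_image(image, levels)
  filters <- dt_filters()
  orig_dim <- dim(image)

  trees <- list(aa = image, ab = image, ba = image, bb = image)
  tree_bands <- lapply(trees, function(x) vector("list", levels))
  pads <- vector("list", levels)
  for (j in seq_len(levels)) {
    pads[[j]] <- dim(trees$aa)
    for (key in names(trees)) {
      rt <- substr(key, 1, 1); ct <- substr(key, 2, 2)
      fr <- dt_level_filters(filters, rt, j)
      fc <- dt_level_filters(filters, ct, j)
      x <- pad_even(trees[[key]])
      lo <- .conv_down_per_cpp(x, fr$f$h0, fr$off)
      hi <- .conv_down_per_cpp(x, fr$f$h1, fr$off)
      ll <- t(.conv_down_per_cpp(t(lo), fc$f$h0, fc$off))
      lh <- t(.conv_down_per_cpp(t(lo), fc$f$h1, fc$off))
      hl <- t(.conv_down_per_cpp(t(hi), fc$f$h0, fc$off))
      hh <- t(.conv_down_per_cpp(t(hi), fc$f$h1, fc$off))
      trees[[key]] <- ll
      tree_bands[[key]][[j]] <- list(lh = lh, hl = hl, hh = hh)
    }
  }

  detail <- vector("list", levels)
  for (j in seq_len(levels)) {
    bands <- list()
    for (typ in names(dt_orient)) {
      aa <- tree_bands$aa[[j]][[typ]]; bb <- tree_bands$bb[[j]][[typ]]
      ab <- tree_bands$ab[[j]][[typ]]; ba <- tree_bands$ba[[j]][[typ]]
      lab <- dt_orient[[typ]]
      s2 <- sqrt(2)
      bands[[paste0(lab[1], "_re")]] <- (aa - bb) / s2
      bands[[paste0(lab[1], "_im")]] <- (ab + ba) / s2
      bands[[paste0(lab[2], "_re")]] <- (aa + bb) / s2
      bands[[paste0(lab[2], "_im")]] <- (ab - ba) / s2
    }
    detail[[j]] <- bands
  }
  approx <- Reduce(`+`, trees) / 4
  p <- new_pyramid("dtcwt", "qshift", levels, detail, approx, orig_dim,
                   trees = trees)
  p$pads <- pads
  p
}

#' Inverse dual-tree complex wavelet transform
#'
#' Exact inverse of [decompose_dtcwt()]: the unitary orientation combination
#' is undone, each of the four orthonormal trees is inverted by its adjoint,
#' and the four reconstructions are averaged.
#'
#' @param pyramid a [gof_pyramid] produced by [decompose_dtcwt()].
#' @return numeric matrix with the original image dimensions.
#' @export
reconstruct_dtcwt <- function(pyramid) {
  if (!inherits(pyramid, "gof_pyramid") || pyramid$transform != "dtcwt")
    stop("reconstruct_dtcwt expects a DT-CWT pyramid")
  filters <- dt_filters()
  levels <- pyramid$levels
  s2 <- sqrt(2)

  recs <- lapply(names(pyramid$trees), function(key) {
    rt <- substr(key, 1, 1); ct <- substr(key, 2, 2)
    ll <- pyramid$trees[[key]]
    for (j in rev(seq_len(levels))) {
      bands <- pyramid$detail[[j]]
      tb <- list()
      for (typ in names(dt_orient)) {
        lab <- dt_orient[[typ]]
        re1 <- bands[[paste0(lab[1], "_re")]]; im1 <- bands[[paste0(lab[1], "_im")]]
        re2 <- bands[[paste0(lab[2], "_re")]]; im2 <- bands[[paste0(lab[2], "_im")]]
        y <- switch(key,
          aa = (re2 + re1) / s2,
          bb = (re2 - re1) / s2,
          ab = (im1 + im2) / s2,
          ba = (im1 - im2) / s2)
        tb[[typ]] <- y
      }
      if (!all(dim(tb$lh) == dim(ll)))
        stop("inconsistent band shapes in pyramid")
      fr <- dt_level_filters(filters, rt, j)
      fc <- dt_level_filters(filters, ct, j)
      nc2 <- 2L * ncol(ll)
      lo <- t(.conv_up_per_cpp(t(ll), fc$f$h0, nc2, fc$off) +
              .conv_up_per_cpp(t(tb$lh), fc$f$h1, nc2, fc$off))
      hi <- t(.conv_up_per_cpp(t(tb$hl), fc$f$h0, nc2, fc$off) +
              .conv_up_per_cpp(t(tb$hh), fc$f$h1, nc2, fc$off))
      nr2 <- 2L * nrow(ll)
      ll <- .conv_up_per_cpp(lo, fr$f$h0, nr2, fr$off) +
            .conv_up_per_cpp(hi, fr$f$h1, nr2, fr$off)
      pre <- pyramid$pads[[j]]
      ll <- ll[seq_len(pre[1]), seq_len(pre[2]), drop = FALSE]
    }
    ll
  })
  Reduce(`+`, recs) / 4
}

# cache environment for Monte-Carlo band gains and default curves
.gof_cache <- new.env(parent = emptyenv())

#' Per-band noise gains of the dual-tree transform
#'
#' The DT-CWT is redundant, so its oriented real/imaginary part grids do not
#' carry unit variance when the input is unit-variance white noise (the four
#' trees are individually orthonormal but correlated with one another).
#' The per-(scale, band) standard deviation under white noise is estimated
#' once by Monte Carlo for a given depth and cached for the session; it is
#' the `band_gains` input of [normalize_pyramid()].
#'
#' @param levels decomposition depth.
#' @param size side of the square noise fields (default 256).
#' @param nsim number of noise realizations (default 8).
#' @param seed RNG seed for the estimation (fixed default so gains are
#'   reproducible across sessions).
#' @return list of length `levels`; element `j` is a named numeric vector of
#'   standard deviations, one per part grid.
#' @export
dtcwt_band_gains <- function(levels = 5L, size = 256L, nsim = 8L,
                             seed = 760101L) {
  key <- sprintf("gains_%d_%d_%d_%d", levels, size, nsim, seed)
  if (!is.null(.gof_cache[[key]])) return(.gof_cache[[key]])
  acc <- NULL
  with_seed(seed, {
    for (s in seq_len(nsim)) {
      x <- matrix(stats::rnorm(size * size), size, size)
      p <- decompose_dtcwt(x, levels)
      ss <- lapply(p$detail, function(bands)
        vapply(bands, function(b) c(sum(b^2), length(b)), numeric(2)))
      acc <- if (is.null(acc)) ss else
        Map(function(a, b) a + b, acc, ss)
    }
  })
  gains <- lapply(acc, function(m) {
    g <- sqrt(m[1, ] / m[2, ])
    names(g) <- colnames(m)
    g
  })
  .gof_cache[[key]] <- gains
  gains
}
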