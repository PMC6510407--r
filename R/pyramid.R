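#' Wavelet pyramid objects
#'
#' A `gof_pyramid` is the uniform container for both transforms. Fields:
#' \describe{
#'   \item{transform}{`"dwt"` or `"dtcwt"`.}
#'   \item{wavelet}{filter identifier (DWT) or `"qshift"` (DT-CWT).}
#'   \item{levels}{decomposition depth `J`.}
#'   \item{detail}{list of length `J`; element `j` is a named list of real
#'     2D coefficient matrices. DWT: `horizontal`, `vertical`, `diagonal`.
#'     DT-CWT: the six oriented bands split into parts,
#'     `d15_re, d15_im, ..., d165_im` (12 matrices).}
#'   \item{approx}{the scale-`J` approximation band (DWT: one matrix;
#'     DT-CWT: the average of the four tree lowpass bands, for display).}
#'   \item{trees}{DT-CWT only: the four per-tree lowpass bands needed for
#'     exact inversion.}
#'   \item{dim}{original image dimensions.}
#' }
#'
#' @name gof_pyramid
NULL

new_pyramid <- function(transform, wavelet, levels, detail, approx, dim,
                        trees = NULL) {
  structure(list(transform = transform, wavelet = wavelet,
                 levels = levels, detail = detail, approx = approx,
                 dim = dim, trees = trees),
            class = "gof_pyramid")
}

#' @export
print.gof_pyramid <- function(x, ...) {
  cat(sprintf("<gof_pyramid> %s (%s), %d level(s), image %d x %d\n",
              x$transform, x$wavelet, x$levels, x$dim[1], x$dim[2]))
  for (j in seq_len(x$levels)) {
    d <- x$detail[[j]]
    cat(sprintf("  scale %d: %d band(s) of %d x %d\n", j, length(d),
                nrow(d[[1]]), ncol(d[[1]])))
  }
  invisible(x)
}

#' Names of the detail bands at each scale of a pyramid
#' @param pyramid a `gof_pyramid`
#' @return character vector of band labels
#' @export
band_names <- function(pyramid) names(pyramid$detail[[1]])

#' Serialize a pyramid to a directory of plain band files
#'
#' Debugging aid: each band is written as `scaleJ_label.csv` (plain text,
#' band label to array) together with an `index.json` describing the scope.
#'
#' @param pyramid a `gof_pyramid`
#' @param dir directory to create/fill
#' @return `dir`, invisibly
#' @export
write_pyramid <- function(pyramid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(transform = pyramid$transform, wavelet = pyramid$wavelet,
               levels = pyramid$levels, dim = pyramid$dim,
               bands = band_names(pyramid))
  jsonlite::write_json(meta, file.path(dir, "index.json"), auto_unbox = TRUE)
  for (j in seq_len(pyramid$levels))
    for (b in names(pyramid$detail[[j]]))
      utils::write.table(pyramid$detail[[j]][[b]],
                         file.path(dir, sprintf("scale%d_%s.csv", j, b)),
                         sep = ",", row.names = FALSE, col.names = FALSE)
  ap <- if (is.list(pyramid$approx)) Reduce(`+`, pyramid$approx) /
          length(pyramid$approx) else pyramid$approx
  utils::write.table(ap, file.path(dir, sprintf("scale%d_approx.csv",
                                                pyramid$levels)),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

check_image <- function(image, levels) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix")
  if (any(!is.finite(image))) stop("image contains non-finite values")
  if (min(dim(image)) < 2^levels)
    stop(sprintf("image dimensions %d x %d too small for %d levels (need >= %d)",
                 nrow(image), ncol(image), levels, 2^levels))
  invisible(TRUE)
}

# pad odd dimensions to even by edge replication; returns padded matrix and
# the original dims for cropping on reconstruction
pad_even <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  if (nr %% 2 == 1) x <- rbind(x, x[nr, , drop = FALSE])
  if (nc %% 2 == 1) x <- cbind(x, x[, ncol(x), drop = FALSE])
  x
}
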