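#' Cycle-spinning shift grids
#'
#' The decimated DWT is not translation invariant; averaging denoised,
#' circularly shifted copies of the image approximates the stationary
#' transform and suppresses Gibbs-type artifacts near edges. The default is
#' the 4 x 4 grid of shifts `{0..3} x {0..3}` (16 shifts); returns a
#' two-column integer matrix of (row, col) shifts including `(0, 0)`.
#'
#' @param k grid side (shifts `0..k-1` in each axis), between 1 and 8.
#' @return integer matrix with columns `row`, `col`.
#' @export
shift_grid <- function(k = 4L) {
  k <- as.integer(k)
  if (k < 1L || k > 8L) stop("shift grid side must be in 1..8")
  as.matrix(expand.grid(row = 0:(k - 1), col = 0:(k - 1)))
}

circshift <- function(x, s) {
  s <- as.integer(s)
  n <- nrow(x); m <- ncol(x)
  i <- ((seq_len(n) - 1 + s[1]) %% n) + 1
  j <- ((seq_len(m) - 1 + s[2]) %% m) + 1
  x[i, j, drop = FALSE]
}

#' Cycle spinning around an arbitrary denoiser
#'
#' Applies `denoiser` to each circularly shifted copy of `image`, un-shifts
#' the results and averages them.
#'
#' @param denoiser a function mapping a matrix to a matrix of the same
#'   dimensions.
#' @param image numeric matrix.
#' @param shifts two-column matrix of integer (row, col) shifts, e.g. from
#'   [shift_grid()].
#' @return numeric matrix, same dimensions as `image`.
#' @export
#' @examples
#' x <- matrix(rnorm(64), 8, 8)
#' identical(cycle_spin(identity, x, shift_grid(2)), x)
cycle_spin <- function(denoiser, image, shifts) {
  shifts <- as.matrix(shifts)
  if (nrow(shifts) == 0L) stop("shift set must be non-empty")
  acc <- matrix(0, nrow(image), ncol(image))
  for (r in seq_len(nrow(shifts))) {
    s <- shifts[r, ]
    y <- denoiser(circshift(image, s))
    if (!all(dim(y) == dim(image)))
      stop("denoiser changed the image dimensions")
    acc <- acc + circshift(y, -s)
  }
  acc / nrow(shifts)
}
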