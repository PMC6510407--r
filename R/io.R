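# Grayscale image reading and writing: PNG, TIFF, PGM (P2/P5).
# Images travel through the package as plain numeric matrices in [0, 255];
# clipping and 8-bit quantization happen only at write time.

img_ext <- function(path) tolower(tools::file_ext(path))

collapse_gray <- function(a) {
  if (length(dim(a)) == 3) {
    warning("multi-channel image; averaging the first three channels")
    a <- (a[, , 1] + a[, , min(2, dim(a)[3])] + a[, , min(3, dim(a)[3])]) / 3
  }
  a
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0) stop("truncated PGM file")
      if (ch == "#") { repeat { c2 <- readChar(con, 1, useBytes = TRUE)
        if (length(c2) == 0 || c2 == "\n") break } ; next }
      if (!grepl("[[:space:]]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0 || grepl("[[:space:]]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  if (!magic %in% c("P2", "P5")) stop("not a PGM (P2/P5) file")
  w <- as.integer(tok()); h <- as.integer(tok()); maxv <- as.integer(tok())
  if (magic == "P5") {
    if (maxv < 256) {
      v <- as.integer(readBin(con, "raw", n = w * h))
    } else {
      v <- readBin(con, "integer", n = w * h, size = 2, signed = FALSE,
                   endian = "big")
    }
  } else {
    v <- integer(0)
    while (length(v) < w * h) v <- c(v, as.integer(tok()))
  }
  m <- matrix(v, nrow = h, ncol = w, byrow = TRUE)
  list(m = m, maxv = maxv)
}

#' Read a grayscale image
#'
#' Supports PNG, TIFF and PGM (both ASCII P2 and binary P5). Returns
#' intensities on the 8-bit scale [0, 255]; 16-bit inputs are rescaled to
#' that range with a warning, multi-channel inputs are averaged to
#' luminance with a warning.
#'
#' @param path image file path.
#' @return numeric matrix.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  ext <- img_ext(path)
  if (ext == "png") {
    a <- collapse_gray(png::readPNG(path))
    a * 255
  } else if (ext %in% c("tif", "tiff")) {
    a <- collapse_gray(tiff::readTIFF(path))
    a * 255
  } else if (ext == "pgm") {
    p <- read_pgm(path)
    if (p$maxv > 255) {
      warning("16-bit PGM rescaled to [0, 255]")
      p$m * (255 / p$maxv)
    } else p$m * 1.0
  } else stop("unsupported image format '.", ext, "'")
}

#' Write a grayscale image
#'
#' Clips to [0, 255] and quantizes to 8 bits, then writes PNG, TIFF or
#' binary PGM according to the file extension.
#'
#' @param image numeric matrix.
#' @param path output path (.png, .tif/.tiff or .pgm).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  q <- round(pmin(pmax(image, 0), 255))
  ext <- img_ext(path)
  if (ext == "png") {
    png::writePNG(q / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(q / 255, path)
  } else if (ext == "pgm") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(q), nrow(q)), con,
              eos = NULL)
    writeBin(as.raw(as.integer(t(q))), con)
  } else stop("unsupported image format '.", ext, "'")
  invisible(path)
}
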