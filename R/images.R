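#' @importFrom stats dist fft median optim quantile rnorm runif sd var setNames
#' @importFrom utils head modifyList write.csv read.csv
NULL

# Internal image containers.
#
# All images are plain R matrices indexed [row, col] with the origin at the
# top-left: x = column index, y = row index, both 1-based. Every module in
# the package shares this convention. EBImage stores images transposed
# ([x, y]); the two helpers below convert at the boundary.

#' Construct a grayscale image
#'
#' A `gray_image` is a numeric matrix (rows = y, columns = x) tagged with a
#' processing `stage`: `"raw"` images hold intensities in \[0, 255\];
#' `"normalized"` images hold real values produced by
#' [normalize_image()].
#'
#' @param pixels numeric matrix of intensities.
#' @param stage `"raw"` or `"normalized"`.
#' @return A `gray_image` object.
#' @export
gray_image <- function(pixels, stage = c("raw", "normalized")) {
  stage <- match.arg(stage)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_lfp("invalid_image", "gray_image requires a numeric matrix")
  if (any(!is.finite(pixels)))
    stop_lfp("invalid_image", "gray_image pixels must be finite")
  if (identical(stage, "raw") && (min(pixels) < 0 || max(pixels) > 255))
    stop_lfp("invalid_image", "raw gray_image values must lie in [0, 255]")
  structure(list(pixels = pixels, stage = stage), class = "gray_image")
}

#' Construct a binary (0/1) image
#'
#' @param pixels matrix whose entries are all 0 or 1.
#' @param ridge_is_one logical flag asserting that 1 encodes ridge pixels
#'   (set by [ensure_ridge_polarity()]).
#' @return A `binary_image` object.
#' @export
binary_image <- function(pixels, ridge_is_one = FALSE) {
  if (!is.matrix(pixels))
    stop_lfp("invalid_image", "binary_image requires a matrix")
  storage.mode(pixels) <- "integer"
  if (!all(pixels == 0L | pixels == 1L))
    stop_lfp("invalid_image", "binary_image pixels must be exactly 0 or 1")
  structure(list(pixels = pixels, ridge_is_one = isTRUE(ridge_is_one)),
            class = "binary_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %dx%d stage=%s range=[%.1f, %.1f]>\n",
              nrow(x$pixels), ncol(x$pixels), x$stage,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image %dx%d ridge_is_one=%s foreground=%d px>\n",
              nrow(x$pixels), ncol(x$pixels), x$ridge_is_one,
              sum(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
dim.binary_image <- function(x) dim(x$pixels)

# Classed conditions so callers can distinguish failure modes.
stop_lfp <- function(class, msg, ...) {
  stop(structure(class = c(paste0("lfp_", class), "lfp_error",
                           "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# matrix [row, col] -> EBImage grayscale Image and back
as_ebimage <- function(m) EBImage::Image(t(m), colormode = "Grayscale")
from_ebimage <- function(img) t(EBImage::imageData(img)[, , drop = TRUE])

#' Read a fingerprint image from disk
#'
#' Reads PNG, TIFF or JPEG (8-bit grayscale or RGB). RGB input is returned
#' as an H x W x 3 array of 0--255 intensities suitable for
#' [to_grayscale()]; grayscale input is promoted to three identical
#' channels so both kinds flow through the same pipeline entry.
#'
#' @param path file path.
#' @return H x W x 3 numeric array with values in \[0, 255\].
#' @export
read_fingerprint_image <- function(path) {
  if (!file.exists(path))
    stop_lfp("io", "cannot read image: no such file '%s'", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    stop_lfp("io", "cannot read image '%s': %s",
                             path, conditionMessage(e)))
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 2L) {
    m <- t(d) * 255
    arr <- array(m, c(dim(m), 3L))
  } else {
    nch <- dim(d)[3]
    if (nch < 3L) {
      m <- t(d[, , 1]) * 255
      arr <- array(m, c(dim(m), 3L))
    } else {
      arr <- array(0, c(dim(d)[2], dim(d)[1], 3L))
      for (k in 1:3) arr[, , k] <- t(d[, , k]) * 255
    }
  }
  arr
}

#' Write a grayscale or binary image as PNG
#'
#' @param img `gray_image`, `binary_image`, or a numeric matrix.
#' @param path output path (PNG).
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  m <- if (inherits(img, "gray_image")) img$pixels
       else if (inherits(img, "binary_image")) img$pixels * 255
       else img
  rng <- range(m)
  m01 <- if (rng[1] >= 0 && rng[2] <= 255) m / 255
         else (m - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  png::writePNG(pmin(pmax(m01, 0), 1), path)
  invisible(path)
}
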