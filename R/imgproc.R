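# Three-phase preprocessing: color photograph -> grayscale -> normalized ->
# binary ridge model. This is the front end every downstream stage consumes.

#' Convert an RGB photograph to grayscale
#'
#' Luma conversion with Rec.601 weights (0.299 R + 0.587 G + 0.114 B),
#' rounded to integer intensities. Achromatic input (r = g = b) maps to the
#' shared channel value exactly.
#'
#' @param img H x W x 3 numeric array with channel values in \[0, 255\],
#'   e.g. from [read_fingerprint_image()].
#' @return A raw-stage [gray_image()].
#' @export
to_grayscale <- function(img) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 3L))
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop_lfp("invalid_image", "to_grayscale expects an H x W x 3 array")
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stop_lfp("invalid_image", "empty image")
  if (min(img) < 0 || max(img) > 255)
    stop_lfp("invalid_image", "channel values must lie in [0, 255]")
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  gray_image(round(g), stage = "raw")
}

#' Mean/variance normalization of a grayscale image
#'
#' Pixel-wise affine normalization about the image mean: a pixel at
#' intensity `I` maps to `m0 + sqrt(v0 / v) * (I - m)` where `(m, v)` are
#' the image's mean and (population) variance and `(m0, v0)` the targets.
#' The output has sample mean `target_mean` and variance `target_variance`
#' exactly (up to floating point), which makes images taken under different
#' lighting comparable before thresholding.
#'
#' @param img raw-stage `gray_image` with non-zero variance.
#' @param target_mean desired output mean (default 128).
#' @param target_variance desired output variance (default 2000).
#' @return A normalized-stage `gray_image`.
#' @export
normalize_image <- function(img, target_mean = 128, target_variance = 2000) {
  stopifnot(inherits(img, "gray_image"))
  if (!identical(img$stage, "raw"))
    stop_lfp("precondition", "normalize_image expects a raw-stage image")
  if (target_variance <= 0)
    stop_lfp("config", "target_variance must be positive")
  p <- img$pixels
  m <- mean(p)
  v <- mean((p - m)^2)
  if (v <= .Machine$double.eps * 255^2)
    stop_lfp("degenerate_image",
             "cannot normalize a constant image (zero variance)")
  out <- target_mean + sqrt(target_variance / v) * (p - m)
  gray_image(out, stage = "normalized")
}

# Otsu threshold: exhaustive maximization of between-class variance over
# the 256 candidate thresholds of an 8-bit histogram, computed with
# cumulative moments. Returns the threshold t such that pixels > t are
# class 1. Ties resolved toward the smallest maximizing t.
otsu_threshold <- function(values) {
  rng <- range(values)
  if (diff(rng) <= .Machine$double.eps)
    stop_lfp("degenerate_image", "cannot threshold a constant image")
  is8bit <- rng[1] >= 0 && rng[2] <= 255 && all(values == round(values))
  if (is8bit) {
    bins <- as.integer(values)
    to_value <- function(t) t
  } else {
    # quantize arbitrary real-valued images onto 256 levels
    bins <- as.integer(round((values - rng[1]) / diff(rng) * 255))
    to_value <- function(t) rng[1] + (t + 0.5) / 255 * diff(rng)
  }
  h <- tabulate(bins + 1L, nbins = 256L)
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(h)                      # count of pixels <= t
  s0 <- cumsum(h * lev)                # intensity sum of pixels <= t
  stot <- s0[256]
  valid <- w0 > 0 & w0 < n             # both classes non-empty
  mu0 <- s0 / w0
  mu1 <- (stot - s0) / (n - w0)
  sb <- (w0 / n) * (1 - w0 / n) * (mu0 - mu1)^2
  sb[!valid] <- -Inf
  t <- lev[which.max(sb)]
  list(threshold = to_value(t), between_class_variance = max(sb))
}

#' Binarize a grayscale image
#'
#' Classifies every pixel into 0 or 1 by a global intensity threshold.
#' With `method = "otsu"` the threshold maximizes the between-class
#' variance over all 256 candidate thresholds of the (quantized) 8-bit
#' histogram; `method = "fixed"` uses the supplied threshold;
#' `method = "adaptive"` applies Otsu per tile (for uneven illumination),
#' falling back to the global threshold in near-constant tiles.
#' Pixels strictly above the threshold become 1.
#'
#' @param img a `gray_image` (raw or normalized stage).
#' @param method `"otsu"`, `"fixed"` or `"adaptive"`.
#' @param threshold threshold for `method = "fixed"`.
#' @param block_size tile size in pixels for `method = "adaptive"`.
#' @return A [binary_image()] (polarity not yet asserted; see
#'   [ensure_ridge_polarity()]).
#' @export
binarize <- function(img, method = c("otsu", "fixed", "adaptive"),
                     threshold = 128, block_size = 16) {
  stopifnot(inherits(img, "gray_image"))
  method <- match.arg(method)
  p <- img$pixels
  if (method == "fixed") {
    b <- (p > threshold) + 0L
  } else if (method == "otsu") {
    b <- (p > otsu_threshold(as.vector(p))$threshold) + 0L
  } else {
    tg <- otsu_threshold(as.vector(p))$threshold
    b <- matrix(0L, nrow(p), ncol(p))
    ri <- split(seq_len(nrow(p)), ceiling(seq_len(nrow(p)) / block_size))
    ci <- split(seq_len(ncol(p)), ceiling(seq_len(ncol(p)) / block_size))
    for (r in ri) for (cc in ci) {
      tile <- p[r, cc, drop = FALSE]
      t <- if (diff(range(tile)) < 1e-6 * max(1, abs(mean(tile)))) tg
           else otsu_threshold(as.vector(tile))$threshold
      b[r, cc] <- (tile > t) + 0L
    }
  }
  if (sum(b) == 0L || sum(b) == length(b))
    stop_lfp("degenerate_image", "binarization produced a single class")
  binary_image(b, ridge_is_one = FALSE)
}

#' Assert ridge polarity of a binary image
#'
#' Decides which binary class is ridge and flips the image if needed so
#' that 1 always encodes ridge. Inked controls carry dark ridges on a
#' light card; powder-developed prints fluoresce, so their ridges are the
#' brighter class. The decision compares the mean grayscale intensity of
#' the two binary classes; the operation is idempotent.
#'
#' @param bin `binary_image` derived from `gray`.
#' @param gray the `gray_image` the binary was thresholded from.
#' @param modality `"inked_control"` (ridges dark) or
#'   `"fluorescent_sample"` (ridges bright).
#' @return A `binary_image` with `ridge_is_one = TRUE`.
#' @export
ensure_ridge_polarity <- function(bin, gray,
                                  modality = c("inked_control",
                                               "fluorescent_sample")) {
  stopifnot(inherits(bin, "binary_image"), inherits(gray, "gray_image"))
  modality <- match.arg(modality)
  if (!all(dim(bin$pixels) == dim(gray$pixels)))
    stop_lfp("precondition", "binary and gray image dimensions differ")
  b <- bin$pixels
  m1 <- mean(gray$pixels[b == 1L])
  m0 <- mean(gray$pixels[b == 0L])
  ones_brighter <- m1 > m0
  want_bright_ridge <- modality == "fluorescent_sample"
  if (ones_brighter != want_bright_ridge) b <- 1L - b
  binary_image(b, ridge_is_one = TRUE)
}

#' Run the full preprocessing chain
#'
#' Grayscale conversion, mean/variance normalization, binarization and
#' ridge-polarity assertion in one call.
#'
#' @param img H x W x 3 array, or a `gray_image`.
#' @param modality see [ensure_ridge_polarity()].
#' @param config an [lfp_config()] list (defaults used when `NULL`).
#' @return list with elements `gray`, `normalized`, `binary`.
#' @export
preprocess_image <- function(img, modality = c("inked_control",
                                               "fluorescent_sample"),
                             config = NULL) {
  modality <- match.arg(modality)
  cfg <- resolve_config(config)
  g <- if (inherits(img, "gray_image")) img else to_grayscale(img)
  nrm <- normalize_image(g, cfg$imgproc$target_mean,
                         cfg$imgproc$target_variance)
  b <- binarize(nrm, method = cfg$imgproc$binarize_method,
                threshold = cfg$imgproc$fixed_threshold,
                block_size = cfg$imgproc$adaptive_block)
  b <- ensure_ridge_polarity(b, nrm, modality)
  list(gray = g, normalized = nrm, binary = b)
}
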