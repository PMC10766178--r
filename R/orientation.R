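# Block-wise ridge orientation field and Poincare-index singularity
# detection. The orientation field lives on a block lattice; angles are
# ridge orientations in [0, pi) (mod pi), with a per-block coherence in
# [0, 1] measuring how anisotropic the local gradient structure is.

#' Construct an orientation field object
#'
#' @param theta matrix of ridge orientations in \[0, pi) (block lattice).
#' @param coherence matrix of per-block reliabilities in \[0, 1\].
#' @param block_size block edge length in pixels.
#' @return An `orientation_field` object. Element `[i, j]` describes the
#'   block whose pixel center is `block_center(i, j, block_size)`.
#' @export
orientation_field <- function(theta, coherence, block_size) {
  stopifnot(is.matrix(theta), all(dim(theta) == dim(coherence)))
  if (any(coherence < -1e-9) || any(coherence > 1 + 1e-9))
    stop_lfp("precondition", "coherence must lie in [0, 1]")
  structure(list(theta = theta %% pi,
                 coherence = pmin(pmax(coherence, 0), 1),
                 block_size = block_size),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("<orientation_field %dx%d blocks of %d px, mean coherence %.2f>\n",
              nrow(x$theta), ncol(x$theta), x$block_size,
              mean(x$coherence)))
  invisible(x)
}

block_center <- function(i, j, block_size) {
  c(x = (j - 0.5) * block_size + 0.5, y = (i - 0.5) * block_size + 0.5)
}

#' Estimate the block-wise ridge orientation field
#'
#' Least-squares gradient orientation: central-difference gradients are
#' pooled per block into the structure tensor (Gxx, Gyy, Gxy); the ridge
#' orientation is perpendicular to the dominant gradient direction,
#' `theta = atan2(2 Gxy, Gxx - Gyy) / 2 + pi/2` (mod pi). Coherence is the
#' normalized eigenvalue spread `sqrt((Gxx-Gyy)^2 + 4 Gxy^2) / (Gxx+Gyy)`:
#' 1 for perfect stripes, 0 for isotropic texture.
#'
#' @param img a `gray_image`.
#' @param block_size block edge length in pixels (default 16).
#' @return An [orientation_field()].
#' @export
estimate_orientation <- function(img, block_size = 16) {
  stopifnot(inherits(img, "gray_image"))
  p <- img$pixels
  h <- nrow(p); w <- ncol(p)
  if (block_size > h || block_size > w)
    stop_lfp("config", "block_size exceeds image dimensions")
  if (diff(range(p)) <= .Machine$double.eps)
    stop_lfp("degenerate_image", "constant image has no orientation")
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (p[, 3:w] - p[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (p[3:h, ] - p[1:(h - 2), ]) / 2
  nbr <- floor(h / block_size); nbc <- floor(w / block_size)
  ridx <- rep(seq_len(nbr), each = block_size)
  cidx <- rep(seq_len(nbc), each = block_size)
  pool <- function(m) {
    m <- m[seq_along(ridx), seq_along(cidx), drop = FALSE]
    t(rowsum(t(rowsum(m, ridx)), cidx))
  }
  gxx <- pool(gx * gx); gyy <- pool(gy * gy); gxy <- pool(gx * gy)
  theta <- atan2(2 * gxy, gxx - gyy) / 2 + pi / 2
  coh <- sqrt((gxx - gyy)^2 + 4 * gxy^2) / pmax(gxx + gyy, 1e-12)
  coh[gxx + gyy < 1e-9] <- 0
  orientation_field(theta, coh, block_size)
}

# Smooth an orientation field by averaging doubled-angle vectors
# (coherence-weighted) with an iterated 3x3 box kernel. Doubling removes
# the mod-pi discontinuity.
smooth_orientation <- function(field, iterations = 2) {
  th <- field$theta; coh <- field$coherence
  cx <- coh * cos(2 * th); sx <- coh * sin(2 * th)
  box <- function(m) {
    padded <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
    padded <- cbind(padded[, 1, drop = FALSE], padded,
                    padded[, ncol(padded), drop = FALSE])
    r <- nrow(m); cc <- ncol(m)
    out <- matrix(0, r, cc)
    for (dr in 0:2) for (dc in 0:2)
      out <- out + padded[dr + seq_len(r), dc + seq_len(cc)]
    out / 9
  }
  for (k in seq_len(iterations)) { cx <- box(cx); sx <- box(sx) }
  orientation_field(atan2(sx, cx) / 2, field$coherence, field$block_size)
}

# Wrap an angle difference of a mod-pi orientation into (-pi/2, pi/2].
wrap_half <- function(d) {
  d <- (d + pi / 2) %% pi - pi / 2
  d[d <= -pi / 2] <- d[d <= -pi / 2] + pi
  d
}

#' Poincare index of an orientation field at one block node
#'
#' Sums the wrapped orientation changes around the 8-neighborhood of block
#' `(i, j)` (counter-clockwise circuit), divided by 2 pi. For a mod-pi
#' ridge field the index is +1 at a whorl core, +1/2 at a loop core, -1/2
#' at a delta and 0 in regular regions.
#'
#' @param field an `orientation_field`.
#' @param i,j block row/column (must be interior).
#' @return The index (a half-integer up to numerical noise).
#' @export
poincare_index <- function(field, i, j) {
  th <- field$theta
  if (i <= 1 || j <= 1 || i >= nrow(th) || j >= ncol(th))
    stop_lfp("precondition", "Poincare index needs an interior block")
  # circuit of increasing atan2(dy, dx): the positive orientation of the
  # coordinate frame shared with the field constructions
  dj <- c(1, 1, 0, -1, -1, -1, 0, 1)
  di <- c(0, 1, 1, 1, 0, -1, -1, -1)
  ring <- th[cbind(i + di, j + dj)]
  sum(wrap_half(diff(c(ring, ring[1])))) / (2 * pi)
}

# Dense-ring Poincare index: samples the doubled-angle field on a circle
# of `radius` blocks (bilinear interpolation, `ns` samples), so each step
# subtends far less than pi/2 even for a whorl whose singularity sits
# right next to a lattice node. Used by detect_core for classification.
dense_ring_index <- function(field, i, j, ns = 16, radius = 1.5) {
  th <- field$theta
  nr <- nrow(th); nc <- ncol(th)
  cx <- cos(2 * th); sx <- sin(2 * th)
  tt <- 2 * pi * (seq_len(ns) - 1) / ns
  si <- i + radius * sin(tt)
  sj <- j + radius * cos(tt)
  if (any(si < 1) || any(si > nr) || any(sj < 1) || any(sj > nc))
    return(NA_real_)
  i0 <- pmin(floor(si), nr - 1); j0 <- pmin(floor(sj), nc - 1)
  fi <- si - i0; fj <- sj - j0
  bil <- function(m) {
    (1 - fi) * (1 - fj) * m[cbind(i0, j0)] +
      (1 - fi) * fj * m[cbind(i0, j0 + 1)] +
      fi * (1 - fj) * m[cbind(i0 + 1, j0)] +
      fi * fj * m[cbind(i0 + 1, j0 + 1)]
  }
  ring <- atan2(bil(sx), bil(cx)) / 2
  sum(wrap_half(diff(c(ring, ring[1])))) / (2 * pi)
}

#' Detect core and delta points from an orientation field
#'
#' Scans every interior block node of a (smoothed) orientation field for a
#' non-zero Poincare index. Nodes classify as whorl core (index ~ +1),
#' loop core (~ +1/2) or delta (~ -1/2). Results are sorted by decreasing
#' |index|, ties broken by coherence-weighted centrality (nearer the
#' coherence centroid of the field ranks first); the top-ranked core is
#' the `(a, b)` anchor used by the matcher.
#'
#' @param field an `orientation_field`.
#' @param min_coherence blocks below this mean local coherence are not
#'   eligible (suppresses spurious singularities in noise), default 0.15.
#' @param smooth number of smoothing passes applied before indexing.
#' @return A list of `core_point` objects (possibly empty), each with
#'   fields `a`, `b` (pixel coordinates of the block center), `kind`
#'   (`"core"` or `"delta"`) and `poincare_index`.
#' @export
detect_core <- function(field, min_coherence = 0.15, smooth = 2) {
  sm <- if (smooth > 0) smooth_orientation(field, smooth) else field
  th <- sm$theta
  nr <- nrow(th); nc <- ncol(th)
  if (nr < 3 || nc < 3) return(list())
  found <- list()
  coh <- field$coherence
  wsum <- sum(coh)
  ci <- if (wsum > 0) sum(row(coh) * coh) / wsum else (nr + 1) / 2
  cj <- if (wsum > 0) sum(col(coh) * coh) / wsum else (nc + 1) / 2
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    idx <- poincare_index(sm, i, j)
    if (abs(idx) < 0.2) next
    # confirm and classify on a dense interpolated ring, which resolves
    # the +/- pi/2 step ambiguity a whorl can create on the 8-ring
    dense <- dense_ring_index(sm, i, j)
    if (!is.na(dense)) idx <- dense
    cls <- NA_character_
    if (abs(idx - 1) < 0.26) cls <- "core"
    else if (abs(idx - 0.5) < 0.26) cls <- "core"
    else if (abs(idx + 0.5) < 0.26) cls <- "delta"
    if (is.na(cls)) next
    local_coh <- mean(coh[max(1, i - 1):min(nr, i + 1),
                          max(1, j - 1):min(nc, j + 1)])
    if (local_coh < min_coherence) next
    ctr <- block_center(i, j, field$block_size)
    found[[length(found) + 1]] <- structure(
      list(a = ctr[["x"]], b = ctr[["y"]], kind = cls,
           poincare_index = round(idx * 2) / 2,
           centrality = sqrt((i - ci)^2 + (j - cj)^2),
           block = c(i, j)),
      class = "core_point")
  }
  if (!length(found)) return(found)
  # merge detections of one singularity spread over adjacent nodes: a
  # whorl core frequently reads as two half-index cores a few pixels
  # apart, and their mean position (with summed index) is the better
  # estimate of the one singularity
  ord <- order(-abs(vapply(found, `[[`, 0, "poincare_index")),
               vapply(found, `[[`, 0, "centrality"))
  found <- found[ord]
  kept <- list()
  for (f in found) {
    merged <- FALSE
    for (k in seq_along(kept)) {
      if (kept[[k]]$kind == f$kind &&
          max(abs(kept[[k]]$block - f$block)) <= 3) {
        n <- kept[[k]]$n_merged
        kept[[k]]$a <- (kept[[k]]$a * n + f$a) / (n + 1)
        kept[[k]]$b <- (kept[[k]]$b * n + f$b) / (n + 1)
        kept[[k]]$block <- round((kept[[k]]$block * n + f$block) / (n + 1))
        # the dense ring reports the total index inside its radius, so
        # overlapping detections of one singularity agree and a ring
        # enclosing both halves of a split whorl already reads +1: keep
        # the largest-magnitude reading
        if (abs(f$poincare_index) > abs(kept[[k]]$poincare_index))
          kept[[k]]$poincare_index <- f$poincare_index
        kept[[k]]$n_merged <- n + 1
        merged <- TRUE
        break
      }
    }
    if (!merged) { f$n_merged <- 1; kept[[length(kept) + 1]] <- f }
  }
  kept[order(-abs(vapply(kept, `[[`, 0, "poincare_index")),
             vapply(kept, `[[`, 0, "centrality"))]
}

#' @export
print.core_point <- function(x, ...) {
  cat(sprintf("<core_point %s (a=%.1f, b=%.1f) index=%+.1f>\n",
              x$kind, x$a, x$b, x$poincare_index))
  invisible(x)
}
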