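# Ridge-mask thinning and the crossing-number operator. Feature typing
# needs one-pixel-wide ridges; Zhang-Suen thinning provides them while
# preserving 8-connectivity.

# neighbor shift: value of the pixel (dr, dc) away, zero outside the image
shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# the 8-neighborhood in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW)
# in image coordinates: north = smaller row index
zs_offsets <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
                    dc = c(0, 1, 1, 1, 0, -1, -1, -1))

neighbor_stack <- function(m) {
  lapply(seq_len(8), function(k)
    shift_mat(m, zs_offsets[k, 1], zs_offsets[k, 2]))
}

#' Thin a binary ridge mask to a one-pixel skeleton
#'
#' Zhang-Suen iterative thinning: two sub-iterations per pass delete
#' boundary pixels whose neighborhood satisfies the connectivity and
#' end-point conditions, until no pixel changes. The skeleton is a subset
#' of the ridge mask, preserves 8-connected component count, and is one
#' pixel wide almost everywhere.
#'
#' @param bin a `binary_image` with `ridge_is_one = TRUE`.
#' @return A `binary_image` skeleton (ridge_is_one stays TRUE).
#' @export
skeletonize <- function(bin) {
  stopifnot(inherits(bin, "binary_image"))
  if (!bin$ridge_is_one)
    stop_lfp("precondition", "skeletonize requires ridge polarity (1 = ridge)")
  m <- bin$pixels
  if (sum(m) == 0L)
    stop_lfp("degenerate_image", "empty foreground: nothing to thin")
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      nb <- neighbor_stack(m)
      B <- Reduce(`+`, nb)
      seq9 <- c(nb, nb[1])
      A <- matrix(0L, nrow(m), ncol(m))
      for (k in 1:8) A <- A + (seq9[[k]] == 0L & seq9[[k + 1]] == 1L)
      p2 <- nb[[1]]; p4 <- nb[[3]]; p6 <- nb[[5]]; p8 <- nb[[7]]
      if (phase == 1) {
        cond <- m == 1L & B >= 2L & B <= 6L & A == 1L &
          (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- m == 1L & B >= 2L & B <= 6L & A == 1L &
          (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  binary_image(m, ridge_is_one = TRUE)
}

#' Crossing number at a skeleton pixel
#'
#' `CN = 0.5 * sum |p_k - p_{k+1}|` over the cyclic 8-neighborhood of the
#' pixel. On a one-pixel skeleton, CN 0/1/2/3 corresponds to isolated
#' point / ridge ending / ridge interior / bifurcation; CN >= 4 marks
#' trifurcation or crossover candidates.
#'
#' @param skel a skeleton `binary_image`.
#' @param x,y pixel coordinates (1-based column / row) of a skeleton pixel.
#' @return Integer crossing number.
#' @export
crossing_number <- function(skel, x, y) {
  m <- skel$pixels
  if (y < 1 || y > nrow(m) || x < 1 || x > ncol(m) || m[y, x] != 1L)
    stop_lfp("precondition", "(%d, %d) is not a skeleton pixel", x, y)
  cn_map(m)[y, x]
}

# vectorized crossing-number map (meaningful on skeleton pixels only)
cn_map <- function(m) {
  nb <- neighbor_stack(m)
  seq9 <- c(nb, nb[1])
  acc <- matrix(0L, nrow(m), ncol(m))
  for (k in 1:8) acc <- acc + abs(seq9[[k]] - seq9[[k + 1]])
  acc %/% 2L
}

# 8-connected component count
count_components <- function(m) {
  if (sum(m) == 0L) return(0L)
  lab <- label_components(m)
  max(lab)
}

# 8-connected labelling via two-pass union-find on shifted matrices
label_components <- function(m) {
  h <- nrow(m); w <- ncol(m)
  idx <- which(m == 1L)
  if (!length(idx)) return(matrix(0L, h, w))
  lab <- matrix(0L, h, w)
  lab[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  rr <- ((idx - 1) %% h) + 1; cc <- ((idx - 1) %/% h) + 1
  for (k in 1:4) {  # N, NW, NE, W neighbors suffice for a raster scan
    dr <- c(-1, -1, -1, 0)[k]; dc <- c(0, -1, 1, -1)[k]
    r2 <- rr + dr; c2 <- cc + dc
    ok <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= w
    ok[ok] <- m[cbind(r2[ok], c2[ok])] == 1L
    if (any(ok)) {
      a <- lab[cbind(rr[ok], cc[ok])]
      b <- lab[cbind(r2[ok], c2[ok])]
      for (q in seq_along(a)) union2(a[q], b[q])
    }
  }
  roots <- vapply(seq_along(idx), find, 0L)
  lab[idx] <- match(roots, sort(unique(roots)))
  lab
}
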