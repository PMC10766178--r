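# Shared fixtures, all built in code.

# deterministic pseudo-random 8-bit image
random_gray <- function(h, w, seed) {
  set.seed(seed)
  gray_image(matrix(sample(0:255, h * w, replace = TRUE), h, w))
}

# horizontal/vertical stripe images with the given period
stripe_image <- function(h, w, period, vertical = FALSE) {
  if (vertical) {
    m <- matrix(rep(127.5 + 127.5 * sin(2 * pi * seq_len(w) / period),
                    each = h), h, w)
  } else {
    m <- matrix(rep(127.5 + 127.5 * sin(2 * pi * seq_len(h) / period),
                    times = w), h, w)
  }
  gray_image(round(m))
}

# blank canvas for hand-built skeletons
blank_skel <- function(h = 40, w = 40) matrix(0L, h, w)

as_skel <- function(m) binary_image(m, ridge_is_one = TRUE)

# draw a straight 8-connected segment into a skeleton matrix
draw_seg <- function(m, y0, x0, y1, x1) {
  n <- max(abs(y1 - y0), abs(x1 - x0))
  ys <- round(seq(y0, y1, length.out = n + 1))
  xs <- round(seq(x0, x1, length.out = n + 1))
  m[cbind(ys, xs)] <- 1L
  m
}

# brute-force Otsu oracle: evaluate the between-class variance of every
# candidate threshold with a plain loop
otsu_oracle <- function(values) {
  best_t <- NA; best_v <- -Inf
  n <- length(values)
  for (t in 0:255) {
    lo <- values[values <= t]; hi <- values[values > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / n; w1 <- length(hi) / n
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# brute-force crossing-number oracle: count 0->1 transitions around the
# cyclic neighborhood directly from the 8 neighbor bits (p2..p9 order)
cn_oracle <- function(bits) {
  s <- c(bits, bits[1])
  sum(abs(diff(s))) / 2
}

# brute-force optimal assignment (exhaustive over permutations) for small
# correspondence instances; returns the pairing that minimizes total
# distance among pairings of maximum feasible size
assignment_oracle <- function(d) {
  nz <- nrow(d); nx <- ncol(d)
  best <- NULL; best_cost <- Inf; best_n <- 0
  perm_rec <- function(zi, used, pairs, cost) {
    if (zi > nz) {
      n <- nrow(pairs)
      if (n > best_n || (n == best_n && cost < best_cost - 1e-12)) {
        best <<- pairs; best_cost <<- cost; best_n <<- n
      }
      return(invisible())
    }
    perm_rec(zi + 1, used, pairs, cost)  # leave zi unpaired
    for (xi in seq_len(nx)) {
      if (used[xi] || !is.finite(d[zi, xi])) next
      used[xi] <- TRUE
      perm_rec(zi + 1, used, rbind(pairs, c(zi, xi)), cost + d[zi, xi])
      used[xi] <- FALSE
    }
  }
  perm_rec(1, rep(FALSE, nx), matrix(0L, 0, 2), 0)
  list(pairs = best, cost = best_cost, n = best_n)
}

# a small feature matrix at given polar positions around a core
fm_from_polar <- function(r, phi, core = c(60, 60)) {
  df <- data.frame(x = core[1] + r * cos(phi), y = core[2] + r * sin(phi),
                   type = "termination", quality = 1)
  ms <- minutia_set(df, core = structure(
    list(a = core[1], b = core[2], kind = "core", poincare_index = 1),
    class = "core_point"))
  build_feature_matrix(ms)
}
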