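# Seeded synthetic fingerprint pairs with exact ground truth.
#
# The generator builds a smooth orientation field with the requested
# level-1 topology (arch / loop / whorl), renders a quasi-stationary ridge
# pattern by iterated oriented band-pass (Gabor) filtering of seeded
# noise, reduces it to a clean one-pixel skeleton, plants minutiae by
# editing that skeleton, and re-dilates the edited skeleton into the
# definitive ridge mask. Because the mask is constructed from the
# skeleton, the skeleton's crossing-number census IS the ground truth:
# every termination/bifurcation of the rendered pair is known exactly,
# with the planted subset flagged. Control (dark ink on light card) and
# sample (bright fluorescing ridges on dark textured substrate) renderings
# are derived from the same mask, the sample under a known rigid
# transform and configurable degradations.

#' Synthetic-generation parameters
#'
#' @param pattern level-1 class: `"arch"`, `"loop"` or `"whorl"`.
#' @param image_size image edge length in pixels (square), default 192 --
#'   about a 500 dpi crop of the core region, ~21 ridge periods across.
#' @param ridge_period ridge wavelength in pixels (default 9).
#' @param n_minutiae number of minutiae to plant (default 12).
#' @param pore_rate pores to plant per 100 px of skeleton (default 0).
#' @param substrate background archetype for the developed sample.
#' @param smudge_prob probability of each candidate smudge patch.
#' @param background_texture_amp substrate texture amplitude in \[0, 1\].
#' @param contrast ridge/background contrast multiplier for the sample.
#' @param occlusion_frac fraction of the sample area occluded in \[0, 1).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return A `synth_params` list.
#' @export
synth_params <- function(pattern = "whorl", image_size = 192,
                         ridge_period = 9, n_minutiae = 12, pore_rate = 0,
                         substrate = "paper", smudge_prob = 0.1,
                         background_texture_amp = 0.2, contrast = 0.9,
                         occlusion_frac = 0.1, seed = 1) {
  p <- list(pattern = pattern, image_size = image_size,
            ridge_period = ridge_period, n_minutiae = n_minutiae,
            pore_rate = pore_rate, substrate = substrate,
            degradation = list(smudge_prob = smudge_prob,
                               background_texture_amp = background_texture_amp,
                               contrast = contrast,
                               occlusion_frac = occlusion_frac),
            seed = as.integer(seed))
  if (p$ridge_period < 4) stop_lfp("config", "ridge_period must be >= 4")
  if (occlusion_frac < 0 || occlusion_frac >= 1)
    stop_lfp("config", "occlusion_frac must lie in [0, 1)")
  if (!pattern %in% c("arch", "loop", "whorl"))
    stop_lfp("config", "pattern must be arch, loop or whorl")
  structure(p, class = c("synth_params", "list"))
}

#' Analytic orientation field for a fingerprint pattern class
#'
#' Zero-pole (rational) construction: each core contributes half the
#' argument of `(z - z_core)`, each delta subtracts half of its argument,
#' so the Poincare index is +1 at a whorl core (two coincident
#' half-poles, realized as concentric-circle orientations), +1/2 at a
#' loop core and -1/2 at its delta; an arch has no singularity.
#'
#' @param pattern `"arch"`, `"loop"` or `"whorl"`.
#' @param size image edge length (pixels).
#' @param core optional `c(x, y)` core position (defaults near center).
#' @param delta optional `c(x, y)` delta position (loop only).
#' @return An [orientation_field()] on the 16-px block lattice, with the
#'   per-pixel orientation matrix in attribute `theta_pixel` and the
#'   singularity positions in attributes `core_xy` / `delta_xy`.
#' @export
make_orientation_field <- function(pattern, size, core = NULL, delta = NULL) {
  cx <- (size + 1) / 2
  if (is.null(core)) core <- c(cx, cx)
  if (any(core <= 1) || any(core >= size))
    stop_lfp("config", "core must lie inside the image")
  X <- matrix(rep(seq_len(size), each = size), size, size)  # x = col
  Y <- matrix(rep(seq_len(size), times = size), size, size) # y = row
  if (pattern == "whorl") {
    th <- atan2(Y - core[2], X - core[1]) + pi / 2
    delta <- NULL
  } else if (pattern == "loop") {
    if (is.null(delta)) delta <- core + c(0.22 * size, 0.28 * size)
    if (any(delta <= 1) || any(delta >= size))
      stop_lfp("config", "delta must lie inside the image")
    th <- 0.5 * atan2(Y - core[2], X - core[1]) -
      0.5 * atan2(Y - delta[2], X - delta[1]) + pi / 2
  } else { # arch: smooth singularity-free flow, ridges arcing over
    sigma <- size / 4
    th <- atan(1.6 * ((X - core[1]) / sigma) *
                 exp(-(X - core[1])^2 / (2 * sigma^2)))
    core <- NULL; delta <- NULL
  }
  th <- th %% pi
  bs <- 16L
  nb <- floor(size / bs)
  sub <- function(m) {
    idx <- rep(seq_len(nb), each = bs)
    cx2 <- cos(2 * m[seq_along(idx), seq_along(idx), drop = FALSE])
    sx2 <- sin(2 * m[seq_along(idx), seq_along(idx), drop = FALSE])
    pool <- function(z) t(rowsum(t(rowsum(z, idx)), idx)) / bs^2
    atan2(pool(sx2), pool(cx2)) / 2
  }
  f <- orientation_field(sub(th), matrix(1, nb, nb), bs)
  attr(f, "theta_pixel") <- th
  attr(f, "core_xy") <- core
  attr(f, "delta_xy") <- delta
  f
}

gabor_kernel <- function(theta, period) {
  R <- ceiling(1.4 * period)
  xs <- -R:R
  X <- matrix(rep(xs, each = length(xs)), length(xs))  # col offset
  Y <- matrix(rep(xs, times = length(xs)), length(xs)) # row offset
  u <- X * cos(theta) + Y * sin(theta)    # along the ridge
  v <- -X * sin(theta) + Y * cos(theta)   # across the ridge
  su <- 0.6 * period; sv <- 0.6 * period  # ~1.2 cycles: sharp freq tuning
  k <- exp(-(u^2 / (2 * su^2) + v^2 / (2 * sv^2))) *
    cos(2 * pi * v / period)
  k - mean(k)
}

#' Render a ridge pattern from an orientation field
#'
#' Iterated oriented band-pass synthesis: seeded white noise is repeatedly
#' filtered with Gabor kernels tuned to the local orientation (12
#' quantized orientation bins, blended per pixel) and frequency
#' `1/ridge_period`, converging to a quasi-stationary ridge pattern whose
#' dominant spatial frequency sits at the tuning frequency.
#'
#' @param field output of [make_orientation_field()] (needs the per-pixel
#'   `theta_pixel` attribute).
#' @param ridge_period ridge wavelength in pixels.
#' @param seed RNG seed.
#' @param iterations filtering passes (default 5).
#' @return list: `gray` (a raw-stage `gray_image`, bright ridges),
#'   `ridge_mask` (a `binary_image`, 1 = ridge).
#' @export
render_ridge_image <- function(field, ridge_period, seed, iterations = 5) {
  thp <- attr(field, "theta_pixel")
  if (is.null(thp))
    stop_lfp("precondition",
             "field lacks per-pixel orientations (use make_orientation_field)")
  h <- nrow(thp); w <- ncol(thp)
  set.seed(seed)
  I <- matrix(rnorm(h * w), h, w)
  nbins <- 12
  centers <- (seq_len(nbins) - 1) * pi / nbins
  kernels <- lapply(centers, gabor_kernel, period = ridge_period)
  weights <- lapply(centers, function(b) {
    wgt <- pmax(cos(2 * (thp - b)), 0)^4
    wgt
  })
  wsum <- Reduce(`+`, weights)
  weights <- lapply(weights, function(wgt) wgt / pmax(wsum, 1e-12))
  for (it in seq_len(iterations)) {
    acc <- matrix(0, h, w)
    for (o in seq_len(nbins)) {
      if (max(weights[[o]]) < 1e-9) next
      # as_ebimage transposes, so hand filter2 the transposed kernel
      f <- from_ebimage(EBImage::filter2(as_ebimage(I), t(kernels[[o]]),
                                         boundary = "circular"))
      acc <- acc + weights[[o]] * f
    }
    I <- acc / max(sd(acc), 1e-12)
  }
  gray <- gray_image(round(pmin(pmax(128 + 80 * tanh(I), 0), 255)),
                     stage = "raw")
  mask <- binary_image((I > 0) + 0L, ridge_is_one = TRUE)
  list(gray = gray, ridge_mask = mask)
}

# ---- skeleton editing helpers --------------------------------------------

skeleton_neighbors <- function(m, r, c) {
  rr <- r + zs_offsets[, 1]; cc <- c + zs_offsets[, 2]
  ok <- rr >= 1 & rr <= nrow(m) & cc >= 1 & cc <= ncol(m)
  ok[ok] <- m[cbind(rr[ok], cc[ok])] == 1L
  cbind(rr[ok], cc[ok])
}

# walk along a CN=2 ridge from (r, c) starting toward (r1, c1); returns
# the visited pixels (excluding the start) up to n steps
walk_ridge <- function(m, r, c, r1, c1, n) {
  path <- matrix(0L, 0, 2)
  prev <- c(r, c); cur <- c(r1, c1)
  for (s in seq_len(n)) {
    path <- rbind(path, cur)
    nb <- skeleton_neighbors(m, cur[1], cur[2])
    nb <- nb[!(abs(nb[, 1] - prev[1]) <= 1 & abs(nb[, 2] - prev[2]) <= 1) |
               (nb[, 1] == prev[1] & nb[, 2] == prev[2]), , drop = FALSE]
    nb <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), , drop = FALSE]
    if (nrow(nb) != 1) break
    prev <- cur; cur <- c(nb[1, 1], nb[1, 2])
  }
  path
}

# prune short dead-end branches and tiny components from a skeleton
clean_skeleton <- function(m, min_component = 25, prune_len = 7,
                           passes = 2) {
  for (p in seq_len(passes)) {
    cn <- cn_map(m); cn[m == 0L] <- -1L
    ends <- which(cn == 1L)
    for (w in ends) {
      r <- ((w - 1) %% nrow(m)) + 1; c <- ((w - 1) %/% nrow(m)) + 1
      if (m[r, c] != 1L) next
      nb <- skeleton_neighbors(m, r, c)
      if (nrow(nb) != 1) next
      path <- rbind(c(r, c), walk_ridge(m, r, c, nb[1, 1], nb[1, 2],
                                        prune_len + 1))
      last <- path[nrow(path), ]
      cnl <- cn_map(m)
      if (nrow(path) <= prune_len + 1 && cnl[last[1], last[2]] >= 3) {
        m[path[-nrow(path), , drop = FALSE]] <- 0L
      }
    }
    m[cn_map(m) == 0L & m == 1L] <- 0L  # isolated pixels
    lab <- label_components(m)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0], nbins = max(lab))
      small <- which(sizes < min_component)
      if (length(small)) m[lab %in% small] <- 0L
    }
  }
  m
}

# draw an 8-connected straight segment; stops early when the next pixel
# would touch skeleton not belonging to the segment start (returns the
# drawn pixels and whether/where it fused with existing skeleton)
draw_branch <- function(m, r0, c0, dir, max_len, avoid_radius = 2) {
  pts <- matrix(0L, 0, 2)
  hit <- NULL
  pos <- c(r0, c0)
  for (s in seq_len(max_len)) {
    nxt <- c(round(r0 + s * dir[1]), round(c0 + s * dir[2]))
    if (nxt[1] < 2 || nxt[1] > nrow(m) - 1 ||
        nxt[2] < 2 || nxt[2] > ncol(m) - 1) break
    if (m[nxt[1], nxt[2]] == 1L) {
      if (s > avoid_radius) hit <- nxt
      break
    }
    # fuse if adjacent to foreign skeleton (counts as reaching it)
    nb <- skeleton_neighbors(m, nxt[1], nxt[2])
    if (nrow(nb) > 0 && s > avoid_radius) {
      far <- nb[(abs(nb[, 1] - r0) + abs(nb[, 2] - c0)) > avoid_radius + 1,
                , drop = FALSE]
      if (nrow(far) > 0) { pts <- rbind(pts, nxt); hit <- c(far[1, 1], far[1, 2]); break }
    }
    pts <- rbind(pts, nxt)
    pos <- nxt
  }
  list(pixels = pts, hit = hit)
}

#' Plant minutiae into a rendered skeleton
#'
#' Performs local skeleton edits with exact bookkeeping: a *cut* removes a
#' short run of ridge pixels, creating two terminations at the new
#' endpoints; a *bridge* draws a branch from a ridge toward its neighbor,
#' creating two bifurcations (or, if the branch ends free and long, a
#' bifurcation plus a termination); a *spur* is a deliberately short free
#' branch; *pores* are recorded for later punching into the ridge mask.
#' Edits keep a guard distance from the border, the core and each other.
#' If the skeleton has no room for the requested count, fewer are planted
#' and the returned set reports exactly what was done.
#'
#' @param skel skeleton matrix (0/1) to edit.
#' @param n_minutiae number of feature points to plant.
#' @param types vector of planting kinds cycled through, from
#'   `c("cut", "bridge", "spur")`.
#' @param seed RNG seed.
#' @param core_xy optional core position to keep clear of.
#' @param n_pores number of pores to record (punched by the caller).
#' @return list: `skeleton` (edited matrix), `planted` (a `minutia_set`
#'   of created points), `pores` (x/y data.frame to punch).
#' @export
plant_minutiae <- function(skel, n_minutiae, types = c("cut", "bridge"),
                           seed = 1, core_xy = NULL, n_pores = 0) {
  set.seed(seed)
  m <- skel
  h <- nrow(m); w <- ncol(m)
  margin <- 20
  guard <- 18
  planted <- list()
  placed_xy <- matrix(0, 0, 2)
  cnm <- cn_map(m); cnm[m == 0L] <- -1L
  candidate_ok <- function(r, c) {
    if (r <= margin || r > h - margin || c <= margin || c > w - margin)
      return(FALSE)
    if (!is.null(core_xy) &&
        sqrt((c - core_xy[1])^2 + (r - core_xy[2])^2) < 16) return(FALSE)
    if (nrow(placed_xy) &&
        min((placed_xy[, 1] - c)^2 + (placed_xy[, 2] - r)^2) < guard^2)
      return(FALSE)
    # quiet neighborhood: no existing events within 8 px
    rr <- max(1, r - 8):min(h, r + 8); cc <- max(1, c - 8):min(w, c + 8)
    all(cnm[rr, cc] <= 2L)
  }
  ridge_dir <- function(r, c) {
    nb <- skeleton_neighbors(m, r, c)
    if (nrow(nb) != 2) return(NULL)
    p1 <- walk_ridge(m, r, c, nb[1, 1], nb[1, 2], 5)
    p2 <- walk_ridge(m, r, c, nb[2, 1], nb[2, 2], 5)
    if (nrow(p1) < 4 || nrow(p2) < 4) return(NULL)
    v <- c(p1[nrow(p1), 1] - p2[nrow(p2), 1],
           p1[nrow(p1), 2] - p2[nrow(p2), 2])
    v / sqrt(sum(v^2))
  }
  record <- function(r, c, type) {
    planted[[length(planted) + 1]] <<- data.frame(x = c, y = r, type = type,
                                                  quality = 1)
    placed_xy <<- rbind(placed_xy, c(c, r))
  }
  count_planted <- function() length(planted)
  pool <- which(m == 1L & cnm == 2L)
  pool <- pool[sample.int(length(pool))]
  ti <- 0
  for (wpx in pool) {
    if (count_planted() >= n_minutiae) break
    r <- ((wpx - 1) %% h) + 1; c <- ((wpx - 1) %/% h) + 1
    if (m[r, c] != 1L || !candidate_ok(r, c)) next
    kind <- types[(ti %% length(types)) + 1]
    dirv <- ridge_dir(r, c)
    if (is.null(dirv)) next
    if (kind == "cut") {
      nb <- skeleton_neighbors(m, r, c)
      if (nrow(nb) != 2) next
      p1 <- walk_ridge(m, r, c, nb[1, 1], nb[1, 2], 7)
      p2 <- walk_ridge(m, r, c, nb[2, 1], nb[2, 2], 7)
      if (nrow(p1) < 7 || nrow(p2) < 7) next
      m[r, c] <- 0L
      m[p1[1:6, , drop = FALSE]] <- 0L
      m[p2[1:6, , drop = FALSE]] <- 0L
      record(p1[7, 1], p1[7, 2], "termination")
      record(p2[7, 1], p2[7, 2], "termination")
      ti <- ti + 1
    } else if (kind == "bridge" || kind == "spur") {
      perp <- c(-dirv[2], dirv[1])
      if (runif(1) < 0.5) perp <- -perp
      maxl <- if (kind == "bridge") 14 else 6
      br <- draw_branch(m, r, c, perp, maxl)
      if (kind == "bridge") {
        if (is.null(br$hit) || nrow(br$pixels) < 3) next
        m[br$pixels] <- 1L
        record(r, c, "bifurcation")
        record(br$hit[1], br$hit[2], "bifurcation")
      } else {
        if (!is.null(br$hit) || nrow(br$pixels) < 5) next
        m[br$pixels] <- 1L
        record(r, c, "spur")
      }
      ti <- ti + 1
    }
  }
  pores <- data.frame(x = numeric(), y = numeric())
  if (n_pores > 0) {
    cnm2 <- cn_map(m); cnm2[m == 0L] <- -1L
    pool2 <- which(m == 1L & cnm2 == 2L)
    pool2 <- pool2[sample.int(length(pool2))]
    for (wpx in pool2) {
      if (nrow(pores) >= n_pores) break
      r <- ((wpx - 1) %% h) + 1; c <- ((wpx - 1) %/% h) + 1
      if (!candidate_ok(r, c)) next
      pores <- rbind(pores, data.frame(x = c, y = r))
      placed_xy <- rbind(placed_xy, c(c, r))
    }
  }
  df <- if (length(planted)) do.call(rbind, planted)
        else data.frame(x = numeric(), y = numeric(), type = character(),
                        quality = numeric())
  list(skeleton = m, planted = minutia_set(df), pores = pores)
}

# dilate a skeleton into a ridge mask of the given width; a box brush of
# width 3 leaves 6-px valleys at the 9-px default period, wide enough
# that rendering blur cannot bridge converging ridges
skeleton_to_mask <- function(skel, width = 3) {
  eb <- EBImage::dilate(as_ebimage(skel),
                        EBImage::makeBrush(as.integer(width), "box"))
  matrix(as.integer(from_ebimage(eb) > 0.5), nrow(skel), ncol(skel))
}

low_freq_noise <- function(h, w, sigma) {
  n <- matrix(rnorm(h * w), h, w)
  f <- from_ebimage(EBImage::gblur(as_ebimage(n), sigma))
  f / max(sd(f), 1e-12)
}

#' Render the inked-control appearance of a ridge mask
#'
#' Dark ridges on a light card with mild ink-spread blur, smooth pressure
#' non-uniformity and sensor noise.
#'
#' @param mask 0/1 ridge-mask matrix (1 = ridge).
#' @param seed RNG seed.
#' @return A raw-stage `gray_image`.
#' @export
simulate_control <- function(mask, seed = 1) {
  set.seed(seed)
  h <- nrow(mask); w <- ncol(mask)
  press <- 18 * low_freq_noise(h, w, 24)
  img <- 225 - 170 * mask + press * mask
  img <- from_ebimage(EBImage::gblur(as_ebimage(img), 0.8))
  img <- img + matrix(rnorm(h * w, 0, 5), h, w)
  gray_image(round(pmin(pmax(img, 0), 255)), stage = "raw")
}

#' Rigid transform helpers
#'
#' `make_rigid_transform` builds a rotation-plus-translation between the
#' control and sample frames; `transform_points` applies it to an n x 2
#' matrix of (x, y); `invert_transform` returns the inverse transform.
#'
#' @param rotation radians (counter-clockwise in image coordinates).
#' @param tx,ty translation in pixels.
#' @param center `c(x, y)` rotation center.
#' @return A `rigid_transform` list.
#' @export
make_rigid_transform <- function(rotation = 0, tx = 0, ty = 0,
                                 center = c(0, 0)) {
  structure(list(rotation = rotation, tx = tx, ty = ty, center = center),
            class = "rigid_transform")
}

#' @rdname make_rigid_transform
#' @param tf a `rigid_transform`.
#' @param xy n x 2 matrix of (x, y) coordinates.
#' @export
transform_points <- function(tf, xy) {
  xy <- matrix(xy, ncol = 2)
  co <- cos(tf$rotation); si <- sin(tf$rotation)
  dx <- xy[, 1] - tf$center[1]; dy <- xy[, 2] - tf$center[2]
  cbind(tf$center[1] + co * dx - si * dy + tf$tx,
        tf$center[2] + si * dx + co * dy + tf$ty)
}

#' @rdname make_rigid_transform
#' @export
invert_transform <- function(tf) {
  co <- cos(-tf$rotation); si <- sin(-tf$rotation)
  t2 <- c(-(co * tf$tx - si * tf$ty), -(si * tf$tx + co * tf$ty))
  make_rigid_transform(-tf$rotation, t2[1], t2[2], tf$center)
}

# resample a mask under a rigid transform; bilinear interpolation gives
# anti-aliased ridge edges (values in [0, 1]) instead of staircased ones
warp_mask <- function(mask, tf) {
  h <- nrow(mask); w <- ncol(mask)
  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), times = w), h, w)
  inv <- invert_transform(tf)
  src <- transform_points(inv, cbind(as.vector(X), as.vector(Y)))
  sx <- src[, 1]; sy <- src[, 2]
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  val <- function(yy, xx) {
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    v <- numeric(length(yy))
    v[ok] <- mask[cbind(yy[ok], xx[ok])]
    v
  }
  out <- (1 - fx) * (1 - fy) * val(y0, x0) +
    fx * (1 - fy) * val(y0, x0 + 1) +
    (1 - fx) * fy * val(y0 + 1, x0) +
    fx * fy * val(y0 + 1, x0 + 1)
  matrix(out, h, w)
}

substrate_texture <- function(substrate, h, w, amp) {
  base <- switch(substrate,
    paper = 120 * low_freq_noise(h, w, 10),
    metal = {
      n <- matrix(rnorm(h * w), h, w)
      k <- matrix(1, 1, 21) / 21
      s <- from_ebimage(EBImage::filter2(as_ebimage(n), t(k),
                                         boundary = "circular"))
      110 * s / max(sd(s), 1e-12)
    },
    plastic = {
      f <- low_freq_noise(h, w, 30)
      130 * pmax(f, 0)
    },
    glass = 40 * matrix(rnorm(h * w), h, w) / 1,
    wood = {
      X <- matrix(rep(seq_len(w), each = h), h, w)
      wob <- 6 * low_freq_noise(h, w, 16)
      90 * sin(2 * pi * (X + wob) / 18)
    },
    stop_lfp("config", "unknown substrate '%s'", substrate))
  amp * base
}

#' Render the powder-developed sample appearance of a ridge mask
#'
#' Applies the rigid transform, inverts polarity (fluorescing bright
#' ridges on a dark substrate), and adds substrate texture, powder
#' granularity, optional smudges and partial occlusion.
#'
#' @param mask 0/1 ridge-mask matrix in the control frame.
#' @param substrate one of paper/metal/plastic/glass/wood.
#' @param degradation list with `smudge_prob`, `background_texture_amp`,
#'   `contrast`, `occlusion_frac`.
#' @param transform a `rigid_transform` (control -> sample frame).
#' @param seed RNG seed.
#' @return A raw-stage `gray_image`; attributes `warped_mask` (the
#'   transformed ridge mask) and `occlusion_mask` support accounting.
#' @export
simulate_development <- function(mask, substrate = "paper",
                                 degradation = list(smudge_prob = 0.1,
                                                    background_texture_amp = 0.2,
                                                    contrast = 0.9,
                                                    occlusion_frac = 0.1),
                                 transform = make_rigid_transform(),
                                 seed = 1) {
  set.seed(seed)
  h <- nrow(mask); w <- ncol(mask)
  wmc <- warp_mask(mask, transform)       # continuous coverage in [0, 1]
  wm <- matrix(as.integer(wmc > 0.5), h, w)
  amp <- degradation$background_texture_amp
  tex <- substrate_texture(substrate, h, w, amp)
  occl <- matrix(FALSE, h, w)
  if (degradation$occlusion_frac > 0) {
    X <- matrix(rep(seq_len(w), each = h), h, w)
    Y <- matrix(rep(seq_len(h), times = w), h, w)
    while (mean(occl) < degradation$occlusion_frac) {
      cx <- runif(1, 1, w); cy <- runif(1, 1, h); rad <- runif(1, 10, 18)
      occl <- occl | ((X - cx)^2 + (Y - cy)^2 <= rad^2)
    }
  }
  cov <- wmc * !occl                      # visible ridge coverage
  ridge_level <- 190 * degradation$contrast
  img <- (45 + tex) * (1 - cov) +
    cov * (ridge_level + matrix(rnorm(h * w, 0, 22), h, w))
  if (degradation$smudge_prob > 0) {
    X <- matrix(rep(seq_len(w), each = h), h, w)
    Y <- matrix(rep(seq_len(h), times = w), h, w)
    for (k in 1:5) {
      if (runif(1) >= degradation$smudge_prob) next
      cx <- runif(1, 1, w); cy <- runif(1, 1, h); rad <- runif(1, 8, 14)
      disc <- (X - cx)^2 + (Y - cy)^2 <= rad^2
      img[disc] <- 0.4 * img[disc] + 0.6 * 70
    }
  }
  img <- from_ebimage(EBImage::gblur(as_ebimage(img), 0.6))
  img <- img + matrix(rnorm(h * w, 0, 6), h, w)
  out <- gray_image(round(pmin(pmax(img, 0), 255)), stage = "raw")
  attr(out, "warped_mask") <- wm
  attr(out, "occlusion_mask") <- occl
  out
}

#' Generate a paired synthetic fingerprint with ground truth
#'
#' End-to-end seeded generation: orientation field, Gabor rendering,
#' skeleton cleanup, minutia planting, mask construction, inked-control
#' and powder-developed renderings related by a known rigid transform.
#'
#' @param params a [synth_params()] (or an `lfp_config`, whose `synthgen`
#'   section is used).
#' @return A `synth_pair`: list with `control` and `sample` (raw-stage
#'   `gray_image`s) and `truth` -- a list holding `minutiae` (full
#'   crossing-number census of the defining skeleton, control frame, with
#'   `planted` flag), `core`, `delta`, `transform`, `ridge_mask`,
#'   `skeleton`, `params`.
#' @export
generate_pair <- function(params = synth_params()) {
  if (inherits(params, "lfp_config"))
    params <- do.call(synth_params, c(params$synthgen["pattern"],
      params$synthgen[c("image_size", "ridge_period", "n_minutiae",
                        "pore_rate", "substrate", "seed")],
      params$synthgen[c("smudge_prob", "background_texture_amp",
                        "contrast", "occlusion_frac")]))
  stopifnot(inherits(params, "synth_params"))
  s <- params$seed
  size <- params$image_size
  set.seed(s + 101L)
  jit <- runif(2, -10, 10)
  core <- if (params$pattern == "arch") NULL
          else c((size + 1) / 2 + jit[1], (size + 1) / 2 + jit[2])
  field <- make_orientation_field(params$pattern, size, core = core)
  rend <- render_ridge_image(field, params$ridge_period, seed = s + 101L)
  skel0 <- skeletonize(rend$ridge_mask)$pixels
  skel0 <- clean_skeleton(skel0)
  if (sum(skel0) == 0L)
    stop_lfp("degenerate_image", "rendered pattern yielded no skeleton")
  n_pores <- round(params$pore_rate * sum(skel0) / 100)
  pl <- plant_minutiae(skel0, params$n_minutiae, seed = s + 202L,
                       core_xy = attr(field, "core_xy"),
                       n_pores = n_pores)
  mask <- skeleton_to_mask(pl$skeleton, width = 3)
  if (nrow(pl$pores)) {
    # a sweat pore sits inside ridge material: widen the ridge locally
    # into a blob, then punch the pore hole through its middle
    X <- matrix(rep(seq_len(size), each = size), size, size)
    Y <- matrix(rep(seq_len(size), times = size), size, size)
    for (i in seq_len(nrow(pl$pores))) {
      d2 <- (X - pl$pores$x[i])^2 + (Y - pl$pores$y[i])^2
      mask[d2 <= 9] <- 1L
      mask[d2 <= 1.7] <- 0L
    }
  }
  # ground truth: the feature census of the defining skeleton, with the
  # same compound-structure semantics the extractor reports
  skelb <- binary_image(pl$skeleton, ridge_is_one = TRUE)
  census <- as.data.frame(classify_compound(extract_minutiae(skelb), skelb))
  census$planted <- FALSE
  if (nrow(pl$planted)) {
    pd <- as.data.frame(pl$planted)
    d2 <- outer(census$x, pd$x, `-`)^2 + outer(census$y, pd$y, `-`)^2
    census$planted <- apply(d2 <= 4, 1, any)
  }
  if (nrow(pl$pores))
    census <- rbind(census,
                    data.frame(x = pl$pores$x, y = pl$pores$y,
                               type = "pore", quality = 1, planted = TRUE))
  set.seed(s + 505L)
  tf <- make_rigid_transform(rotation = runif(1, -0.1, 0.1),
                             tx = runif(1, -8, 8), ty = runif(1, -8, 8),
                             center = c((size + 1) / 2, (size + 1) / 2))
  control <- simulate_control(mask, seed = s + 303L)
  sample <- simulate_development(mask, substrate = params$substrate,
                                 degradation = params$degradation,
                                 transform = tf, seed = s + 404L)
  # visibility bookkeeping: a truth point whose sample-frame position is
  # occluded (or pushed outside the frame) cannot be recovered from the
  # developed image; flag it so degraded-recall studies can condition on
  # what the degradation left recoverable
  occl <- attr(sample, "occlusion_mask")
  occl_wide <- from_ebimage(EBImage::dilate(as_ebimage(occl + 0L),
                                            EBImage::makeBrush(9, "disc"))) > 0.5
  if (nrow(census)) {
    sxy <- transform_points(tf, cbind(census$x, census$y))
    inb <- sxy[, 1] >= 1 & sxy[, 1] <= size & sxy[, 2] >= 1 & sxy[, 2] <= size
    census$visible <- inb
    idx <- cbind(pmin(pmax(round(sxy[inb, 2]), 1), size),
                 pmin(pmax(round(sxy[inb, 1]), 1), size))
    census$visible[inb] <- !occl_wide[idx]
  } else census$visible <- logical(0)
  core_pt <- if (!is.null(attr(field, "core_xy")))
    structure(list(a = attr(field, "core_xy")[1],
                   b = attr(field, "core_xy")[2],
                   kind = "core",
                   poincare_index = if (params$pattern == "whorl") 1 else 0.5),
              class = "core_point") else NULL
  delta_pt <- if (!is.null(attr(field, "delta_xy")))
    structure(list(a = attr(field, "delta_xy")[1],
                   b = attr(field, "delta_xy")[2],
                   kind = "delta", poincare_index = -0.5),
              class = "core_point") else NULL
  structure(list(
    control = control, sample = sample,
    truth = list(minutiae = census, core = core_pt, delta = delta_pt,
                 transform = tf,
                 ridge_mask = binary_image(mask, ridge_is_one = TRUE),
                 skeleton = pl$skeleton, params = params)),
    class = "synth_pair")
}

# raw crossing-number census of a skeleton matrix (data.frame form)
skeleton_census <- function(m) {
  cn <- cn_map(m); cn[m == 0L] <- -1L
  h <- nrow(m)
  out <- lapply(list(c(1L, "termination"), c(3L, "bifurcation")),
                function(tt) {
                  w <- which(cn == as.integer(tt[1]))
                  if (!length(w)) return(NULL)
                  data.frame(x = ((w - 1) %/% h) + 1,
                             y = ((w - 1) %% h) + 1,
                             type = tt[2], quality = 1)
                })
  w4 <- which(cn >= 4L)
  if (length(w4))
    out <- c(out, list(data.frame(x = ((w4 - 1) %/% h) + 1,
                                  y = ((w4 - 1) %% h) + 1,
                                  type = "trifurcation", quality = 1)))
  df <- do.call(rbind, out)
  if (is.null(df)) data.frame(x = numeric(), y = numeric(),
                              type = character(), quality = numeric())
  else df[order(df$y, df$x), , drop = FALSE]
}

#' Score an extraction against ground truth
#'
#' Greedy nearest matching between extracted and true minutiae at a pixel
#' tolerance, restricted to the interior of the image (both sets filtered
#' by `margin`); type labels are not compared. Returns recall (fraction
#' of truth recovered) and precision (fraction of extracted points that
#' are true).
#'
#' @param extracted a `minutia_set` or data.frame with x/y.
#' @param truth data.frame with x/y (e.g. `truth$minutiae` of a
#'   [generate_pair()] result).
#' @param dim_img `c(rows, cols)`.
#' @param tol match tolerance in pixels (default 5).
#' @param margin interior margin in pixels (default 16).
#' @param exclude optional logical matrix of evaluation-exempt pixels
#'   (e.g. a dilated occlusion mask): points falling there are dropped
#'   from both sets, the convention for boundary zones where neither a
#'   hit nor a miss is meaningful.
#' @return list with `recall`, `precision`, `n_truth`, `n_extracted`,
#'   `n_matched`.
#' @export
score_extraction <- function(extracted, truth, dim_img, tol = 5,
                             margin = 16, exclude = NULL) {
  inside <- function(df) {
    df <- df[df$x > margin & df$x <= dim_img[2] - margin &
               df$y > margin & df$y <= dim_img[1] - margin, , drop = FALSE]
    if (!is.null(exclude) && nrow(df)) {
      idx <- cbind(pmin(pmax(round(df$y), 1), dim_img[1]),
                   pmin(pmax(round(df$x), 1), dim_img[2]))
      df <- df[!exclude[idx], , drop = FALSE]
    }
    df
  }
  ex <- inside(as.data.frame(extracted))
  tr <- inside(as.data.frame(truth))
  if (!nrow(tr) || !nrow(ex))
    return(list(recall = 0, precision = 0, n_truth = nrow(tr),
                n_extracted = nrow(ex), n_matched = 0))
  d <- sqrt(outer(ex$x, tr$x, `-`)^2 + outer(ex$y, tr$y, `-`)^2)
  d[d > tol] <- Inf
  matched <- 0
  while (is.finite(min(d))) {
    k <- arrayInd(which.min(d), dim(d))
    matched <- matched + 1
    d[k[1], ] <- Inf; d[, k[2]] <- Inf
  }
  list(recall = matched / nrow(tr), precision = matched / nrow(ex),
       n_truth = nrow(tr), n_extracted = nrow(ex), n_matched = matched)
}
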