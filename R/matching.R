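# Core-anchored similarity between a developed latent print (sample, Z)
# and an inked control (X). Feature-point coordinates become m x 2
# matrices anchored at each image's core (a, b); the score compares, pair
# by pair, the squared Euclidean distance of a sample point from its core
# with that of the corresponding control point from its core:
#
#   rho_i  = ((z_i1 - a_Z)^2 + (z_i2 - b_Z)^2) /
#            ((x_i1 - a_X)^2 + (x_i2 - b_X)^2)
#   term_i = 1 / (|rho_i - 1| + 1)
#   P      = (1/m) * sum(term_i),   percent = 100 * P
#
# Each term lies in (0, 1]; P = 1 exactly when every distance ratio is 1,
# i.e. when the two matrices match precisely, and larger P means closer
# resemblance. The published typesetting of this score is garbled; the
# form above is this package's reconstruction, chosen because it uses the
# named core-anchored Euclidean distances, attains 1 exactly at a perfect
# match, is bounded in (0, 1], and yields percentage-scale scores. The
# direction is asymmetric (sample is compared against control) and fixed.

#' Build the m x 2 feature matrix of a minutia set
#'
#' Takes the non-pore feature points of a set (pores are level-3
#' reference data, excluded by default), drops any point within `r_min`
#' pixels of the core, and orders rows canonically by polar angle about
#' the core, then radius, so the matrix is independent of extraction
#' order. The core `(a, b)` is the set's detected core; when absent, the
#' minutiae centroid is used and flagged.
#'
#' @param ms a `minutia_set`.
#' @param include_pores include level-3 pores as rows (default FALSE).
#' @param r_min exclusion radius around the core in pixels (default 3).
#' @return A `feature_matrix`: list with `coords` (m x 2 matrix of x, y),
#'   `core` (a, b), `m`, `core_fallback` flag.
#' @export
build_feature_matrix <- function(ms, include_pores = FALSE, r_min = 3) {
  stopifnot(inherits(ms, "minutia_set"))
  df <- as.data.frame(ms)
  if (!include_pores) df <- df[df$type != "pore", , drop = FALSE]
  df <- df[df$type != "core", , drop = FALSE]
  if (!nrow(df))
    stop_lfp("no_features", "no feature points to build a matrix from")
  core <- attr(ms, "core")
  fallback <- is.null(core)
  if (fallback) {
    core <- list(a = mean(df$x), b = mean(df$y), kind = "centroid",
                 poincare_index = NA_real_)
  }
  dx <- df$x - core$a; dy <- df$y - core$b
  r <- sqrt(dx^2 + dy^2)
  ok <- r > r_min
  if (!any(ok))
    stop_lfp("degenerate_geometry",
             "all feature points lie within r_min of the core")
  df <- df[ok, , drop = FALSE]
  phi <- atan2(dy[ok], dx[ok]) %% (2 * pi)
  ord <- order(phi, r[ok], df$x, df$y)
  structure(list(coords = cbind(x = df$x[ord], y = df$y[ord]),
                 types = df$type[ord],
                 core = core, m = sum(ok), core_fallback = fallback),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix m=%d core=(%.1f, %.1f)%s>\n", x$m,
              x$core$a, x$core$b,
              if (x$core_fallback) " [centroid fallback]" else ""))
  invisible(x)
}

polar_about_core <- function(fm) {
  dx <- fm$coords[, 1] - fm$core$a
  dy <- fm$coords[, 2] - fm$core$b
  cbind(r = sqrt(dx^2 + dy^2), phi = atan2(dy, dx))
}

wrap_pi <- function(d) ((d + pi) %% (2 * pi)) - pi

#' Establish point correspondence between two feature matrices
#'
#' Pairs sample rows with control rows in core-centered polar coordinates
#' `(r, phi)`: a candidate pair must satisfy `|r_Z - r_X| <= tol_r` and
#' `|phi_Z - phi_X| <= tol_phi` (angle wrapped); accepted pairs are chosen
#' greedily by ascending polar distance
#' `sqrt(dr^2 + (r_mean * dphi)^2)`, each index used at most once, which
#' makes every accepted pair a mutual nearest neighbor among the points
#' still unpaired. Deterministic.
#'
#' @param Zc sample `feature_matrix`; `Xc` control.
#' @param tol_r radial tolerance in pixels (default 8).
#' @param tol_phi angular tolerance in radians (default 0.4).
#' @return A `correspondence`: list with `pairs` (2-column matrix of
#'   sample/control row indices), `unpaired_sample`, `unpaired_control`.
#' @export
establish_correspondence <- function(Zc, Xc, tol_r = 8, tol_phi = 0.4) {
  stopifnot(inherits(Zc, "feature_matrix"), inherits(Xc, "feature_matrix"))
  pz <- polar_about_core(Zc); px <- polar_about_core(Xc)
  nz <- nrow(pz); nx <- nrow(px)
  dr <- outer(pz[, "r"], px[, "r"], `-`)
  dphi <- wrap_pi(outer(pz[, "phi"], px[, "phi"], `-`))
  rbar <- outer(pz[, "r"], px[, "r"], `+`) / 2
  d <- sqrt(dr^2 + (rbar * dphi)^2)
  d[abs(dr) > tol_r | abs(dphi) > tol_phi] <- Inf
  pairs <- matrix(0L, 0, 2)
  while (is.finite(min(d))) {
    k <- arrayInd(which.min(d), dim(d))
    pairs <- rbind(pairs, k)
    d[k[1], ] <- Inf
    d[, k[2]] <- Inf
  }
  if (!nrow(pairs))
    stop_lfp("no_overlap", "no feature-point pairs within tolerance")
  colnames(pairs) <- c("sample", "control")
  structure(list(pairs = pairs,
                 unpaired_sample = setdiff(seq_len(nz), pairs[, 1]),
                 unpaired_control = setdiff(seq_len(nx), pairs[, 2])),
            class = "correspondence")
}

identity_correspondence <- function(m) {
  structure(list(pairs = cbind(sample = seq_len(m), control = seq_len(m)),
                 unpaired_sample = integer(), unpaired_control = integer()),
            class = "correspondence")
}

#' Core-anchored similarity score between sample and control
#'
#' For each corresponding pair, forms the ratio `rho_i` of squared
#' core-centered Euclidean distances (sample over control) and scores it
#' as `1 / (|rho_i - 1| + 1)`; `P` is the mean of the per-pair terms and
#' `percent = 100 P`. `P = 1` exactly when every ratio is 1 -- in
#' particular whenever the two matrices (with their cores) coincide. The
#' score is invariant to rotating the sample about its core and to
#' translating an image together with its core. With
#' `penalize_unpaired = TRUE`, unpaired points contribute zero-valued
#' terms (off by default: unpaired points are reported but not scored).
#'
#' @param Zc sample `feature_matrix` (Z); `Xc` control (X).
#' @param corr a `correspondence`; identity pairing used when `NULL` and
#'   both matrices have equal row counts.
#' @param penalize_unpaired logical (default FALSE).
#' @return A `match_result`: list with `P`, `percent`, `m_used`,
#'   `per_point_terms`, `correspondence`.
#' @export
similarity_score <- function(Zc, Xc, corr = NULL, penalize_unpaired = FALSE) {
  stopifnot(inherits(Zc, "feature_matrix"), inherits(Xc, "feature_matrix"))
  if (is.null(corr)) {
    if (Zc$m != Xc$m)
      stop_lfp("precondition",
               "identity correspondence needs equal point counts")
    corr <- identity_correspondence(Zc$m)
  }
  iz <- corr$pairs[, 1]; ix <- corr$pairs[, 2]
  if (!length(iz))
    stop_lfp("precondition", "correspondence holds no pairs")
  dz2 <- (Zc$coords[iz, 1] - Zc$core$a)^2 + (Zc$coords[iz, 2] - Zc$core$b)^2
  dx2 <- (Xc$coords[ix, 1] - Xc$core$a)^2 + (Xc$coords[ix, 2] - Xc$core$b)^2
  if (any(dx2 == 0) || any(dz2 == 0))
    stop_lfp("degenerate_geometry", "feature point coincides with its core")
  rho <- dz2 / dx2
  terms <- 1 / (abs(rho - 1) + 1)
  if (penalize_unpaired) {
    terms <- c(terms, rep(0, length(corr$unpaired_sample) +
                            length(corr$unpaired_control)))
  }
  P <- mean(terms)
  structure(list(P = P, percent = 100 * P, m_used = length(iz),
                 per_point_terms = terms, correspondence = corr),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result P=%.4f (%.2f%%) over m=%d pairs>\n",
              x$P, x$percent, x$m_used))
  invisible(x)
}

#' Extract matcher-ready features from one grayscale image
#'
#' Runs normalization, orientation estimation, segmentation, binarization,
#' polarity assertion, thinning, crossing-number extraction, compound
#' re-labelling, pore detection, artifact filtering and core detection.
#'
#' @param gray a raw-stage `gray_image` (or H x W x 3 array).
#' @param modality `"inked_control"` or `"fluorescent_sample"`.
#' @param config an [lfp_config()] (defaults when `NULL`).
#' @return list: `minutiae` (a `minutia_set` with core attached), `core`,
#'   `skeleton`, `binary`, `mask`, `field`, `stages` (stage reports).
#' @export
extract_features <- function(gray, modality = c("inked_control",
                                                "fluorescent_sample"),
                             config = NULL) {
  modality <- match.arg(modality)
  cfg <- resolve_config(config)
  t0 <- proc.time()[3]
  stages <- list()
  note <- function(name, params = list()) {
    stages[[length(stages) + 1]] <<- stage_report(name, params,
                                                  proc.time()[3] - t0)
  }
  pre <- preprocess_image(gray, modality, cfg)
  note("preprocess", cfg$imgproc)
  nrm <- pre$normalized
  field <- estimate_orientation(nrm, cfg$ridges$block_size)
  note("orientation", list(block_size = cfg$ridges$block_size))
  mask <- segment_foreground(nrm, cfg$ridges$block_size,
                             cfg$ridges$segment_quantile)
  bin <- pre$binary
  bpix <- bin$pixels
  bpix[!mask] <- 0L
  if (sum(bpix) == 0L)
    stop_lfp("degenerate_image", "segmentation removed all ridge pixels")
  bpix <- despeckle_binary(bpix, cfg$ridges$min_object_area,
                           cfg$ridges$fill_hole_area)
  bin <- binary_image(bpix, ridge_is_one = TRUE)
  note("segmentation", list(quantile = cfg$ridges$segment_quantile))
  skel <- skeletonize(bin)
  # prune end-cap forks and specks the thinning leaves behind; the prune
  # length stays below any genuine spur so real branches survive
  skel <- binary_image(clean_skeleton(skel$pixels,
                                      min_component = cfg$ridges$min_object_area,
                                      prune_len = cfg$ridges$prune_len,
                                      passes = 2),
                       ridge_is_one = TRUE)
  note("skeletonize", list(prune_len = cfg$ridges$prune_len))
  qual <- upsample_blocks(field$coherence, field$block_size, dim(nrm$pixels))
  ms <- extract_minutiae(skel, quality = qual)
  ms <- classify_compound(ms, skel,
                          L_eye = cfg$ridges$L_eye,
                          L_spur = cfg$ridges$L_spur,
                          L_short = cfg$ridges$L_short)
  pores <- detect_pores(bin, cfg$ridges$pore_area_min,
                        cfg$ridges$pore_area_max)
  if (nrow(pores))
    ms <- minutia_set(rbind(as.data.frame(ms), as.data.frame(pores)))
  ms <- filter_minutiae(ms, dim(nrm$pixels),
                        border_margin = cfg$ridges$border_margin,
                        min_separation = cfg$ridges$min_separation,
                        mask = mask, mask_margin = cfg$ridges$mask_margin)
  note("minutiae", cfg$ridges[c("L_eye", "L_spur", "L_short",
                                "border_margin", "min_separation")])
  cores <- detect_core(field, min_coherence = cfg$ridges$core_min_coherence)
  cores <- lapply(cores, refine_core, img = nrm)
  cores <- Filter(function(cp) {
    iy <- pmin(pmax(round(cp$b + (-8:8)), 1), nrow(mask))
    ix <- pmin(pmax(round(cp$a + (-8:8)), 1), ncol(mask))
    any(mask[iy, ix])
  }, cores)
  core <- Filter(function(cp) cp$kind == "core", cores)
  core <- if (length(core)) core[[1]] else NULL
  ms <- set_core(ms, core)
  note("core", list(found = !is.null(core)))
  list(minutiae = ms, core = core, skeleton = skel, binary = bin,
       mask = mask, field = field, stages = stages)
}

# Binary hygiene: drop foreground specks below min_object_area and fill
# background holes below fill_hole_area (kept well under the pore window
# so genuine sweat pores survive).
despeckle_binary <- function(m, min_object_area = 20, fill_hole_area = 4) {
  lab <- label_components(m)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(sizes < min_object_area)
    if (length(drop)) m[lab %in% drop] <- 0L
  }
  bg <- 1L - m
  labb <- from_ebimage(EBImage::bwlabel(as_ebimage(bg)))
  if (max(labb) > 0) {
    border <- unique(c(labb[1, ], labb[nrow(labb), ],
                       labb[, 1], labb[, ncol(labb)]))
    sizes <- tabulate(labb[labb > 0], nbins = max(labb))
    fill <- setdiff(which(sizes < fill_hole_area), border)
    if (length(fill)) m[labb %in% fill] <- 1L
  }
  m
}

# Refine a block-lattice core to sub-block accuracy by fitting the
# analytic singularity model to the fine-lattice orientation field: near
# a singularity of index s/2 the doubled orientation angle follows
# 2*theta(p) = s * arg(p - c) + beta. For a candidate center c the phase
# offset beta has a closed form (circular mean), leaving a smooth
# 2-parameter minimization of the circular residual over c.
refine_core <- function(cp, img, fine_block = 8, window = 44) {
  f <- tryCatch(estimate_orientation(img, fine_block),
                error = function(e) NULL)
  if (is.null(f)) return(cp)
  sm <- smooth_orientation(f, 1)
  nr <- nrow(sm$theta); nc <- ncol(sm$theta)
  px <- (col(sm$theta) - 0.5) * fine_block + 0.5
  py <- (row(sm$theta) - 0.5) * fine_block + 0.5
  keep <- abs(px - cp$a) <= window & abs(py - cp$b) <= window
  d2c <- sqrt((px - cp$a)^2 + (py - cp$b)^2)
  keep <- keep & d2c > 2  # the node on top of the core carries no phase
  if (sum(keep) < 12) return(cp)
  th2 <- 2 * sm$theta[keep]
  wts <- pmax(sm$coherence[keep], 0.05)
  xs <- px[keep]; ys <- py[keep]
  resid_s <- function(c0, s) {
    ph <- th2 - s * atan2(ys - c0[2], xs - c0[1])
    1 - Mod(sum(wts * exp(1i * ph))) / sum(wts)
  }
  # try the loop (s = 1) and whorl (s = 2) winding models for cores --
  # a noisy whorl often presents as a split pair of half-index cores
  # whose far field still winds by 2 pi -- and the delta model (s = -1)
  # for deltas; grid initialization, then local polish; the merged
  # Poincare position is trusted to about a block (move cap 16 px)
  ss <- if (cp$kind == "delta") -1 else
    if (abs(cp$poincare_index) >= 0.75) c(2, 1) else c(1, 2)
  best <- NULL
  for (s in ss) {
    resid <- function(c0) resid_s(c0, s)
    grid <- expand.grid(a = cp$a + seq(-12, 12, by = 4),
                        b = cp$b + seq(-12, 12, by = 4))
    gv <- apply(grid, 1, resid)
    start <- as.numeric(grid[which.min(gv), ])
    fit <- tryCatch(stats::optim(start, resid, method = "Nelder-Mead",
                                 control = list(maxit = 200)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (max(abs(fit$par - c(cp$a, cp$b))) > 16) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!is.null(best) &&
      best$value <= min(resid_s(c(cp$a, cp$b), 1),
                        resid_s(c(cp$a, cp$b), 2))) {
    cp$a <- best$par[1]; cp$b <- best$par[2]
  }
  cp
}

# Foreground segmentation at pixel resolution: ridge-bearing areas carry
# strong band-pass (ridge-frequency) energy, while blank background,
# smooth texture and occluded patches do not. The energy map is the
# locally averaged squared high-pass response; the mask keeps pixels
# above a fixed fraction of the strong-energy quantile, with small holes
# and islands cleaned up.
segment_foreground <- function(nrm, block_size = 16, frac = 0.45) {
  p <- nrm$pixels
  lp <- from_ebimage(EBImage::gblur(as_ebimage(p), 6))
  hp <- p - lp
  en <- from_ebimage(EBImage::gblur(as_ebimage(hp^2), 4))
  thr <- frac^2 * quantile(en, 0.95)
  mk <- matrix(as.integer(en >= thr), nrow(p), ncol(p))
  mk <- despeckle_binary(mk, min_object_area = 200, fill_hole_area = 60)
  # pull the mask boundary back to where the energy support really ends:
  # smoothing bleeds energy a few pixels into dead regions
  mk <- from_ebimage(EBImage::erode(as_ebimage(mk),
                                    EBImage::makeBrush(7, "disc")))
  matrix(mk > 0.5, nrow(p), ncol(p))
}

# expand a block-lattice matrix to pixel resolution (nearest block)
upsample_blocks <- function(bm, block_size, dims, nearest = TRUE) {
  ri <- pmin(ceiling(seq_len(dims[1]) / block_size), nrow(bm))
  ci <- pmin(ceiling(seq_len(dims[2]) / block_size), ncol(bm))
  bm[ri, ci, drop = FALSE]
}

#' Match pre-extracted minutia sets
#'
#' @param ms_sample,ms_control `minutia_set`s (cores attached when known).
#' @param config an [lfp_config()].
#' @return A `match_result`.
#' @export
match_minutiae <- function(ms_sample, ms_control, config = NULL) {
  cfg <- resolve_config(config)
  Zc <- build_feature_matrix(ms_sample,
                             include_pores = cfg$matching$include_pores,
                             r_min = cfg$matching$r_min)
  Xc <- build_feature_matrix(ms_control,
                             include_pores = cfg$matching$include_pores,
                             r_min = cfg$matching$r_min)
  corr <- establish_correspondence(Zc, Xc, tol_r = cfg$matching$tol_r,
                                   tol_phi = cfg$matching$tol_phi)
  similarity_score(Zc, Xc, corr,
                   penalize_unpaired = cfg$matching$penalize_unpaired)
}

#' Compare a developed latent print against an inked control
#'
#' The full pipeline: both photographs are preprocessed (the sample with
#' fluorescent-powder polarity, the control with inked polarity), features
#' are extracted from each, and the core-anchored similarity is computed.
#'
#' @param sample_img path or H x W x 3 array: the developed latent print.
#' @param control_img path or array: the inked control.
#' @param config an [lfp_config()].
#' @return A `match_result` with attribute `artifacts` holding both
#'   extraction results and the stage reports.
#' @export
compare_images <- function(sample_img, control_img, config = NULL) {
  cfg <- resolve_config(config)
  load_side <- function(obj, side) {
    if (is.character(obj)) {
      obj <- tryCatch(read_fingerprint_image(obj), error = function(e) {
        stop_lfp("io", "[stage %s/read] %s", side, conditionMessage(e))
      })
    }
    obj
  }
  run_stage <- function(expr, side) {
    tryCatch(expr, lfp_error = function(e) {
      stop_lfp("stage", "[stage %s] %s", side, conditionMessage(e))
    })
  }
  s <- load_side(sample_img, "sample")
  x <- load_side(control_img, "control")
  fs <- run_stage(extract_features(s, "fluorescent_sample", cfg), "sample")
  fx <- run_stage(extract_features(x, "inked_control", cfg), "control")
  res <- run_stage(match_minutiae(fs$minutiae, fx$minutiae, cfg), "match")
  attr(res, "artifacts") <- list(sample = fs, control = fx)
  res
}
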