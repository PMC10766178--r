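core_at <- function(a, b) structure(
  list(a = a, b = b, kind = "core", poincare_index = 1),
  class = "core_point")

test_that("feature matrices are canonical m x 2 coordinate lists", {
  df <- data.frame(x = c(10, 30, 50, 20, 40), y = c(15, 35, 25, 45, 5),
                   type = "termination", quality = 1)
  ms <- minutia_set(df, core = core_at(30, 25))
  fm <- build_feature_matrix(ms)
  expect_identical(dim(fm$coords), c(5L, 2L))
  expect_identical(fm$m, 5L)

  # permuting the input leaves the matrix unchanged
  ms2 <- minutia_set(df[c(4, 2, 5, 1, 3), ], core = core_at(30, 25))
  expect_identical(build_feature_matrix(ms2)$coords, fm$coords)

  # pores are excluded by default ...
  dfp <- data.frame(x = c(10, 60), y = c(15, 60), type = "pore", quality = 1)
  expect_error(build_feature_matrix(minutia_set(dfp, core = core_at(30, 25))),
               class = "lfp_no_features")
  # ... unless asked for
  expect_identical(build_feature_matrix(
    minutia_set(dfp, core = core_at(30, 25)), include_pores = TRUE)$m, 2L)

  # points inside r_min of the core are dropped; all-inside is degenerate
  near <- data.frame(x = c(30.5, 31), y = c(25, 25.5), type = "termination",
                     quality = 1)
  expect_error(build_feature_matrix(minutia_set(near, core = core_at(30, 25))),
               class = "lfp_degenerate_geometry")

  # centroid fallback is flagged when no core is present
  fb <- build_feature_matrix(minutia_set(df))
  expect_true(fb$core_fallback)
})

test_that("correspondence pairs identical sets identically and isolates outliers", {
  fm <- fm_from_polar(r = c(20, 30, 40, 25), phi = c(0, 1, 2, 4))
  corr <- establish_correspondence(fm, fm)
  expect_identical(corr$pairs[, 1], corr$pairs[, 2])
  expect_length(corr$unpaired_sample, 0)
  expect_length(corr$unpaired_control, 0)

  # an extra far-away control point stays unpaired
  fmx <- fm_from_polar(r = c(20, 30, 40, 25, 55), phi = c(0, 1, 2, 4, 5.5))
  corr2 <- establish_correspondence(fm, fmx)
  expect_identical(nrow(corr2$pairs), 4L)
  expect_identical(corr2$unpaired_control, 5L)

  # disjoint geometry: no overlap at all
  far <- fm_from_polar(r = c(20, 30), phi = c(0, 1))
  off <- fm_from_polar(r = c(45, 55), phi = c(2.5, 3.5))
  expect_error(establish_correspondence(far, off, tol_r = 5, tol_phi = 0.3),
               class = "lfp_no_overlap")
})

test_that("greedy polar pairing agrees with brute-force optimal assignment on jittered instances", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(6:9, 1)
    r <- runif(n, 15, 60)
    # angularly well-separated points: the jitter below is then far
    # smaller than any inter-point distance, so the optimal pairing is
    # unique and recoverable
    phi <- 2 * pi * (seq_len(n) - 1) / n + runif(n, -0.1, 0.1)
    ctrl <- fm_from_polar(r, phi)
    rz <- r + runif(n, -2, 2)
    pz <- phi + runif(n, -0.03, 0.03)
    samp <- fm_from_polar(rz, pz)
    corr <- establish_correspondence(samp, ctrl, tol_r = 5, tol_phi = 0.2)
    # oracle: exhaustive max-cardinality min-cost assignment on the same
    # tolerance-masked polar distance matrix
    pzm <- cbind(r = rz, phi = pz); pxm <- cbind(r = r, phi = phi)
    dr <- outer(pzm[, 1], pxm[, 1], `-`)
    dphi <- lfpmatch:::wrap_pi(outer(pzm[, 2], pxm[, 2], `-`))
    rbar <- outer(pzm[, 1], pxm[, 1], `+`) / 2
    d <- sqrt(dr^2 + (rbar * dphi)^2)
    d[abs(dr) > 5 | abs(dphi) > 0.2] <- Inf
    oracle <- assignment_oracle(d)
    expect_identical(nrow(corr$pairs), as.integer(oracle$n))  # all n recovered
    expect_identical(as.integer(oracle$n), as.integer(n))
    # same pairing (jitter is far smaller than point spacing)
    expect_identical(as.integer(corr$pairs[order(corr$pairs[, 1]), 2]),
                     as.integer(oracle$pairs[order(oracle$pairs[, 1]), 2]))
  }
})

test_that("the similarity score is exactly 1 on a self-match", {
  fm <- fm_from_polar(r = c(12, 25, 37, 44), phi = c(0.3, 1.7, 3, 5))
  res <- similarity_score(fm, fm)
  expect_identical(res$P, 1)            # bit-exact, not within tolerance
  expect_identical(res$percent, 100)
  expect_true(all(res$per_point_terms == 1))
})

test_that("the score follows the adopted core-anchored distance-ratio form", {
  # control points (1,0) and (0,2) about core (0,0); sample (2,0), (0,2):
  # rho = (4, 1), terms (0.25, 1), P = 0.625 by hand
  mk <- function(xs, ys) {
    ms <- minutia_set(data.frame(x = xs + 50, y = ys + 50,
                                 type = "termination", quality = 1),
                      core = core_at(50, 50))
    build_feature_matrix(ms, r_min = 0.5)
  }
  Z <- mk(c(2, 0), c(0, 2))
  X <- mk(c(1, 0), c(0, 2))
  res <- similarity_score(Z, X, lfpmatch:::identity_correspondence(2))
  expect_equal(sort(res$per_point_terms), c(0.25, 1))
  expect_equal(res$P, 0.625)
  expect_equal(res$percent, 62.5)
})

test_that("score invariances: rotation about the core, joint translation, P bounds", {
  set.seed(21)
  r <- runif(10, 10, 50); phi <- runif(10, 0, 2 * pi)
  X <- fm_from_polar(r, phi)
  # rotate the sample's points about its core, keeping row order fixed
  rotate_fm <- function(fm, ang) {
    dx <- fm$coords[, 1] - fm$core$a; dy <- fm$coords[, 2] - fm$core$b
    fm$coords <- cbind(x = fm$core$a + cos(ang) * dx - sin(ang) * dy,
                       y = fm$core$b + sin(ang) * dx + cos(ang) * dy)
    fm
  }
  for (ang in c(0.3, 1.2, pi / 2, 4)) {
    res <- similarity_score(rotate_fm(X, ang), X,
                            lfpmatch:::identity_correspondence(10))
    expect_equal(res$P, 1, tolerance = 1e-12)
  }
  # joint translation of points and core
  Z2 <- X
  Z2$coords <- Z2$coords + cbind(rep(31.5, 10), rep(-12.25, 10))
  Z2$core$a <- Z2$core$a + 31.5; Z2$core$b <- Z2$core$b - 12.25
  res2 <- similarity_score(Z2, X, lfpmatch:::identity_correspondence(10))
  expect_equal(res2$P, 1, tolerance = 1e-12)

  # general pairs: P in (0, 1], terms in (0, 1], P is the mean of terms
  for (seed in 1:5) {
    set.seed(seed)
    Z3 <- fm_from_polar(runif(8, 10, 50), sort(runif(8, 0, 2 * pi)))
    X3 <- fm_from_polar(runif(8, 10, 50), sort(runif(8, 0, 2 * pi)))
    r3 <- similarity_score(Z3, X3, lfpmatch:::identity_correspondence(8))
    expect_true(all(r3$per_point_terms > 0 & r3$per_point_terms <= 1))
    expect_gt(r3$P, 0); expect_lte(r3$P, 1)
    expect_equal(r3$P, mean(r3$per_point_terms))
    expect_equal(r3$percent, 100 * r3$P)
  }
})

test_that("uniform radial scaling follows the closed form 1/(|s^2-1|+1)", {
  set.seed(8)
  r <- runif(9, 10, 40); phi <- sort(runif(9, 0, 2 * pi))
  X <- fm_from_polar(r, phi)
  for (s in c(1, sqrt(2), 2, 3)) {
    Z <- fm_from_polar(s * r, phi)
    res <- similarity_score(Z, X, lfpmatch:::identity_correspondence(9))
    expect_equal(res$P, 1 / (abs(s^2 - 1) + 1), tolerance = 1e-12)
  }
  # strictly decreasing in s >= 1
  Ps <- sapply(c(1, 1.2, 1.5, 2, 3), function(s)
    similarity_score(fm_from_polar(s * r, phi), X,
                     lfpmatch:::identity_correspondence(9))$P)
  expect_true(all(diff(Ps) < 0))
})

test_that("score direction is fixed (asymmetric in sample and control)", {
  set.seed(13)
  r <- runif(7, 10, 40); phi <- sort(runif(7, 0, 2 * pi))
  Z <- fm_from_polar(1.5 * r, phi)
  X <- fm_from_polar(r, phi)
  id <- lfpmatch:::identity_correspondence(7)
  expect_false(isTRUE(all.equal(similarity_score(Z, X, id)$P,
                                similarity_score(X, Z, id)$P)))
})

test_that("degenerate geometry near the core raises errors", {
  fm <- fm_from_polar(r = c(20, 30), phi = c(0, 2))
  bad <- fm
  bad$coords[1, ] <- c(bad$core$a, bad$core$b)  # point on the core
  expect_error(similarity_score(bad, fm, lfpmatch:::identity_correspondence(2)),
               class = "lfp_degenerate_geometry")
})

test_that("comparing an image with itself gives P = 1 and errors name the stage", {
  pair <- generate_pair(synth_params(seed = 31, occlusion_frac = 0,
                                     smudge_prob = 0))
  tmp <- tempfile(fileext = ".png")
  write_image_png(pair$control, tmp)
  # same image on both sides: modalities differ, so force a config where
  # both sides read the print the same way by matching the control twice
  arr <- read_fingerprint_image(tmp)
  fx <- extract_features(arr, "inked_control")
  res <- match_minutiae(fx$minutiae, fx$minutiae)
  expect_identical(res$P, 1)
  expect_identical(res$percent, 100)

  expect_error(compare_images("no/such/file.png", tmp), class = "lfp_io")
  unlink(tmp)
})
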