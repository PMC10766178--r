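test_that("synthetic parameters are validated", {
  expect_error(synth_params(ridge_period = 2), class = "lfp_config")
  expect_error(synth_params(occlusion_frac = 1), class = "lfp_config")
  expect_error(synth_params(pattern = "tent"), class = "lfp_config")
})

test_that("generated orientation fields carry the advertised singularities", {
  # whorl: detect_core finds a +1 core within one block of the center
  fw <- make_orientation_field("whorl", 160, core = c(80, 84))
  cw <- detect_core(fw, min_coherence = 0)
  expect_gte(length(cw), 1)
  expect_equal(cw[[1]]$poincare_index, 1)
  expect_lt(sqrt((cw[[1]]$a - 80)^2 + (cw[[1]]$b - 84)^2), 24)

  # loop: exactly one +1/2 core and one -1/2 delta
  fl <- make_orientation_field("loop", 160, core = c(64, 64),
                               delta = c(100, 110))
  idx <- vapply(detect_core(fl, min_coherence = 0), `[[`, 0,
                "poincare_index")
  expect_identical(sum(idx == 0.5), 1L)
  expect_identical(sum(idx == -0.5), 1L)

  # arch: none
  expect_length(detect_core(make_orientation_field("arch", 160),
                            min_coherence = 0), 0)

  expect_error(make_orientation_field("whorl", 100, core = c(0, 50)),
               class = "lfp_config")
})

test_that("rendering locks to the requested ridge frequency and is seeded", {
  f <- make_orientation_field("whorl", 128)
  r1 <- render_ridge_image(f, 9, seed = 17)
  r2 <- render_ridge_image(f, 9, seed = 17)
  expect_identical(r1$gray$pixels, r2$gray$pixels)     # determinism
  expect_identical(r1$ridge_mask$pixels, r2$ridge_mask$pixels)

  # radial power spectrum peaks within 15% of 1/period
  g <- r1$gray$pixels - mean(r1$gray$pixels)
  pw <- Mod(fft(g))^2
  n <- nrow(g)
  fy <- (seq_len(n) - 1) / n; fy[fy > 0.5] <- fy[fy > 0.5] - 1
  fr <- sqrt(outer(fy^2, rep(1, n)) + outer(rep(1, n), fy^2))
  bins <- findInterval(as.vector(fr), seq(0.02, 0.5, by = 0.01))
  rad <- tapply(as.vector(pw), bins, sum)
  rad <- rad[names(rad) != "0"]
  peak <- 0.02 + (as.integer(names(rad)[which.max(rad)]) - 0.5) * 0.01
  expect_lt(abs(peak - 1 / 9), 0.15 / 9)

  # a uniform field renders parallel stripes at the right orientation
  fu <- orientation_field(matrix(0, 8, 8), matrix(1, 8, 8), 16)
  attr(fu, "theta_pixel") <- matrix(0, 128, 128)
  ru <- render_ridge_image(fu, 9, seed = 3)
  est <- estimate_orientation(ru$gray, 16)
  # mean orientation (doubled-angle average) within 5 degrees of target
  mean_theta <- atan2(mean(sin(2 * est$theta)), mean(cos(2 * est$theta))) / 2
  expect_lt(abs(sin(mean_theta)), sin(5 * pi / 180))
  # and almost every block individually within 10 degrees
  expect_gt(mean(abs(sin(est$theta)) < sin(10 * pi / 180)), 0.95)
})

test_that("minutia planting edits the skeleton with honest bookkeeping", {
  f <- make_orientation_field("arch", 160)
  r <- render_ridge_image(f, 9, seed = 23)
  sk <- lfpmatch:::clean_skeleton(skeletonize(r$ridge_mask)$pixels)

  # request zero: unchanged
  p0 <- plant_minutiae(sk, 0, seed = 1)
  expect_identical(p0$skeleton, sk)
  expect_identical(nrow(p0$planted), 0L)

  # cuts raise the skeleton's endpoint (CN = 1) census by 2 per cut
  before <- sum(lfpmatch:::cn_map(sk)[sk == 1L] == 1L)
  pc <- plant_minutiae(sk, 6, types = "cut", seed = 2)
  after <- sum(lfpmatch:::cn_map(pc$skeleton)[pc$skeleton == 1L] == 1L)
  expect_identical(nrow(pc$planted), 6L)
  expect_true(all(pc$planted$type == "termination"))
  expect_identical(after - before, 6L)

  # planted sets come back in canonical order
  expect_identical(order(pc$planted$y, pc$planted$x),
                   seq_len(nrow(pc$planted)))
})

test_that("control and sample renderings respect their polarity contracts", {
  pair <- generate_pair(synth_params(seed = 5))
  mask <- pair$truth$ridge_mask$pixels
  ctrl <- pair$control$pixels
  expect_lt(mean(ctrl[mask == 1L]), mean(ctrl[mask == 0L]))  # ink: dark ridges

  samp <- pair$sample$pixels
  wm <- attr(pair$sample, "warped_mask")
  occl <- attr(pair$sample, "occlusion_mask")
  vis <- wm == 1L & !occl
  expect_gt(mean(samp[vis]), mean(samp[wm == 0L & !occl]))   # powder: bright

  # seeded determinism of the full pair
  pair2 <- generate_pair(synth_params(seed = 5))
  expect_identical(pair$control$pixels, pair2$control$pixels)
  expect_identical(pair$sample$pixels, pair2$sample$pixels)
  expect_identical(pair$truth$minutiae, pair2$truth$minutiae)
})

test_that("occlusion accounting matches the requested fraction", {
  p <- synth_params(seed = 9, occlusion_frac = 0.3)
  pair <- generate_pair(p)
  wm <- attr(pair$sample, "warped_mask")
  occl <- attr(pair$sample, "occlusion_mask")
  visible_frac <- sum(wm == 1L & !occl) / sum(wm == 1L)
  expect_lt(abs(visible_frac - 0.7), 0.05)
})

test_that("the rigid transform round-trips control to sample and back", {
  tf <- make_rigid_transform(rotation = 0.08, tx = -5.5, ty = 3.25,
                             center = c(96, 96))
  set.seed(2)
  pts <- cbind(runif(40, 1, 192), runif(40, 1, 192))
  there <- transform_points(tf, pts)
  back <- transform_points(invert_transform(tf), there)
  expect_lt(max(abs(back - pts)), 0.5)

  # truth minutiae land on the warped ridge pattern
  pair <- generate_pair(synth_params(seed = 11, occlusion_frac = 0))
  tr <- pair$truth
  # without occlusion, exactly the points the transform keeps in-frame
  # are visible
  sxy <- transform_points(tr$transform, cbind(tr$minutiae$x, tr$minutiae$y))
  inb <- sxy[, 1] >= 1 & sxy[, 1] <= 192 & sxy[, 2] >= 1 & sxy[, 2] <= 192
  expect_identical(tr$minutiae$visible, inb)
  onmask <- mapply(function(x, y) {
    ys <- pmin(pmax(round(y) + (-2:2), 1), 192)
    xs <- pmin(pmax(round(x) + (-2:2), 1), 192)
    any(tr$ridge_mask$pixels[ys, xs] == 1L)
  }, tr$minutiae$x, tr$minutiae$y)
  expect_true(all(onmask))
})

test_that("planted pores materialize as enclosed holes the detector finds", {
  p <- synth_params(seed = 13, pore_rate = 0.12, occlusion_frac = 0,
                    smudge_prob = 0)
  pair <- generate_pair(p)
  truth_pores <- subset(pair$truth$minutiae, type == "pore")
  expect_gte(nrow(truth_pores), 3)
  det <- detect_pores(pair$truth$ridge_mask)
  d <- sqrt(outer(det$x, truth_pores$x, `-`)^2 +
              outer(det$y, truth_pores$y, `-`)^2)
  hits <- sum(apply(d, 2, min) <= 3)
  expect_gte(hits, nrow(truth_pores) - 1)
})
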