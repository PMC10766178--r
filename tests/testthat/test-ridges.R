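test_that("orientation estimation recovers stripe direction and coherence", {
  hor <- estimate_orientation(stripe_image(64, 64, 8), 16)
  # horizontal stripes: ridge orientation ~ 0 (mod pi)
  dev <- abs(sin(hor$theta))          # 0 when theta is 0 or pi
  expect_lt(max(dev), 0.05)
  expect_gt(mean(hor$coherence), 0.95)

  ver <- estimate_orientation(stripe_image(64, 64, 8, vertical = TRUE), 16)
  expect_lt(max(abs(cos(ver$theta))), 0.05)

  # isotropic noise is less coherent than stripes
  set.seed(99)
  cohs <- replicate(20, {
    g <- random_gray(64, 64, seed = sample.int(1e6, 1))
    mean(estimate_orientation(g, 16)$coherence)
  })
  expect_lt(mean(cohs), mean(hor$coherence))

  expect_error(estimate_orientation(stripe_image(8, 8, 4), 16),
               class = "lfp_config")
})

test_that("Poincare index flags whorl cores, loop core/delta pairs, and nothing in uniform fields", {
  # uniform field: zero index everywhere, no singularities
  unif <- orientation_field(matrix(pi / 3, 8, 8), matrix(1, 8, 8), 16)
  for (i in 2:7) for (j in 2:7)
    expect_equal(poincare_index(unif, i, j), 0, tolerance = 1e-12)
  expect_length(detect_core(unif), 0)

  # synthetic whorl: one +1 core within a block of the center
  size <- 160
  fw <- make_orientation_field("whorl", size)
  cw <- detect_core(fw)
  expect_gte(length(cw), 1)
  expect_equal(cw[[1]]$poincare_index, 1)
  expect_lt(max(abs(c(cw[[1]]$a, cw[[1]]$b) - (size + 1) / 2)), 16)

  # synthetic loop: one +1/2 core and one -1/2 delta
  fl <- make_orientation_field("loop", size, core = c(70, 70),
                               delta = c(110, 120))
  cl <- detect_core(fl, min_coherence = 0)
  kinds <- vapply(cl, `[[`, "", "kind")
  idx <- vapply(cl, `[[`, 0, "poincare_index")
  expect_true(any(kinds == "core" & idx == 0.5))
  expect_true(any(kinds == "delta" & idx == -0.5))

  # arch: no singularity at all
  fa <- make_orientation_field("arch", size)
  expect_length(detect_core(fa, min_coherence = 0), 0)

  # indices over any generated field are half-integers
  for (i in 2:(nrow(fw$theta) - 1)) for (j in 2:(ncol(fw$theta) - 1)) {
    idx <- poincare_index(fw, i, j)
    expect_lt(abs(idx - round(idx * 2) / 2), 0.3)
  }
})

test_that("thinning yields unit-width skeletons and preserves topology", {
  # a 5-pixel-wide bar thins to a centerline of the same extent
  m <- matrix(0L, 20, 30)
  m[8:12, 5:25] <- 1L
  sk <- skeletonize(binary_image(m, ridge_is_one = TRUE))
  expect_true(all(sk$pixels[m == 0L] == 0L))  # subset of the mask
  rows_used <- unique(which(sk$pixels == 1L, arr.ind = TRUE)[, 1])
  expect_lte(length(rows_used), 2)            # essentially one row
  xs <- range(which(sk$pixels == 1L, arr.ind = TRUE)[, 2])
  expect_lte(abs(xs[1] - 5), 3)
  expect_lte(abs(xs[2] - 25), 3)

  # single pixel is a fixed point
  m1 <- matrix(0L, 9, 9); m1[5, 5] <- 1L
  expect_identical(skeletonize(binary_image(m1, TRUE))$pixels, m1)

  # 8-connected component count is preserved on random blobby masks
  set.seed(4)
  for (k in 1:10) {
    n <- matrix(rnorm(48 * 48), 48, 48)
    sm <- lfpmatch:::from_ebimage(EBImage::gblur(lfpmatch:::as_ebimage(n), 3))
    mm <- matrix(as.integer(sm > quantile(sm, 0.6)), 48, 48)
    if (sum(mm) == 0) next
    before <- lfpmatch:::count_components(mm)
    after <- lfpmatch:::count_components(
      skeletonize(binary_image(mm, TRUE))$pixels)
    expect_identical(before, after)
  }

  expect_error(skeletonize(binary_image(matrix(0L, 8, 8), TRUE)),
               class = "lfp_degenerate_image")
})

test_that("crossing number matches its definition on canonical shapes", {
  m <- blank_skel()
  m <- draw_seg(m, 20, 5, 20, 35)          # straight line
  sk <- as_skel(m)
  expect_identical(crossing_number(sk, 20, 20), 2L)  # interior
  expect_identical(crossing_number(sk, 5, 20), 1L)   # endpoint

  iso <- blank_skel(); iso[10, 10] <- 1L
  expect_identical(crossing_number(as_skel(iso), 10, 10), 0L)

  cross <- blank_skel()
  cross <- draw_seg(cross, 20, 5, 20, 35)
  cross <- draw_seg(cross, 5, 20, 35, 20)
  expect_identical(crossing_number(as_skel(cross), 20, 20), 4L)

  expect_error(crossing_number(sk, 1, 1), class = "lfp_precondition")
})

test_that("crossing number agrees with brute force on all 256 neighborhoods", {
  # exhaustive oracle over every possible 8-neighborhood pattern
  for (code in 0:255) {
    bits <- as.integer(intToBits(code))[1:8]  # p2..p9
    m <- matrix(0L, 5, 5)
    m[3, 3] <- 1L
    # zs_offsets order: N, NE, E, SE, S, SW, W, NW
    offs <- lfpmatch:::zs_offsets
    for (k in 1:8) if (bits[k] == 1L) m[3 + offs[k, 1], 3 + offs[k, 2]] <- 1L
    expect_identical(crossing_number(binary_image(m, TRUE), 3, 3),
                     as.integer(cn_oracle(bits)))
  }
})

test_that("minutiae extraction types by crossing number deterministically", {
  seg <- blank_skel()
  seg <- draw_seg(seg, 20, 10, 20, 19)     # length-10 straight segment
  ms <- extract_minutiae(as_skel(seg))
  expect_identical(sum(ms$type == "termination"), 2L)
  expect_identical(sum(ms$type == "bifurcation"), 0L)

  ys <- blank_skel()
  ys <- draw_seg(ys, 30, 20, 20, 20)       # stem
  ys <- draw_seg(ys, 20, 20, 10, 12)       # left arm
  ys <- draw_seg(ys, 20, 20, 10, 28)       # right arm
  msy <- extract_minutiae(as_skel(ys))
  expect_identical(sum(msy$type == "bifurcation"), 1L)
  expect_identical(sum(msy$type == "termination"), 3L)

  # determinism: same skeleton, same set
  expect_identical(as.data.frame(extract_minutiae(as_skel(ys))),
                   as.data.frame(msy))

  expect_error(extract_minutiae(as_skel(blank_skel())),
               class = "lfp_no_features")
})

test_that("minutiae extraction is translation-equivariant", {
  base <- blank_skel(60, 60)
  base <- draw_seg(base, 30, 10, 30, 40)
  base <- draw_seg(base, 30, 25, 15, 35)
  ms0 <- extract_minutiae(as_skel(base))
  for (sh in list(c(3, 5), c(7, 2), c(10, 10))) {
    shifted <- matrix(0L, 60, 60)
    shifted[(sh[1] + 1):60, (sh[2] + 1):60] <-
      base[1:(60 - sh[1]), 1:(60 - sh[2])]
    mss <- extract_minutiae(as_skel(shifted))
    expect_equal(mss$x, ms0$x + sh[2])
    expect_equal(mss$y, ms0$y + sh[1])
    expect_identical(mss$type, ms0$type)
  }
})

test_that("compound structures are re-labelled by the graph walk", {
  # enclosure: a ridge splits into two arms that re-join (cycle ~ 20 px)
  eye <- blank_skel(40, 60)
  eye <- draw_seg(eye, 20, 5, 20, 20)
  eye <- draw_seg(eye, 20, 20, 16, 25)
  eye <- draw_seg(eye, 16, 25, 20, 30)
  eye <- draw_seg(eye, 20, 20, 24, 25)
  eye <- draw_seg(eye, 24, 25, 20, 30)
  eye <- draw_seg(eye, 20, 30, 20, 45)
  sk <- as_skel(eye)
  out <- classify_compound(extract_minutiae(sk), sk, L_eye = 30)
  expect_identical(sum(out$type == "eye"), 1L)
  expect_identical(sum(out$type == "bifurcation"), 0L)

  # spur: a 4-px branch off a long through-ridge
  sp <- blank_skel(40, 60)
  sp <- draw_seg(sp, 20, 5, 20, 50)
  sp <- draw_seg(sp, 19, 25, 16, 28)
  sk2 <- as_skel(sp)
  out2 <- classify_compound(extract_minutiae(sk2), sk2, L_spur = 8)
  expect_identical(sum(out2$type == "spur"), 1L)
  # the branch termination was consumed; the two ridge ends remain
  expect_identical(sum(out2$type == "termination"), 2L)

  # short ridge: an isolated 8-px fragment
  sr <- blank_skel(40, 60)
  sr <- draw_seg(sr, 10, 10, 10, 17)
  sk3 <- as_skel(sr)
  out3 <- classify_compound(extract_minutiae(sk3), sk3, L_short = 15)
  expect_identical(sum(out3$type == "short_ridge"), 1L)
  expect_identical(nrow(out3), 1L)

  # a plain bifurcation with long arms is untouched
  ys <- blank_skel(60, 60)
  ys <- draw_seg(ys, 50, 30, 30, 30)
  ys <- draw_seg(ys, 30, 30, 10, 15)
  ys <- draw_seg(ys, 30, 30, 10, 45)
  sk4 <- as_skel(ys)
  out4 <- classify_compound(extract_minutiae(sk4), sk4)
  expect_identical(sort(unique(out4$type)), c("bifurcation", "termination"))
  expect_identical(sum(out4$type == "bifurcation"), 1L)
})

test_that("pore detection finds enclosed holes within the area window", {
  bar <- matrix(0L, 30, 40)
  bar[10:20, 5:35] <- 1L
  bar[14:15, 20] <- 0L                     # 2-px hole
  pores <- detect_pores(binary_image(bar, TRUE), A_min = 1, A_max = 20)
  expect_identical(nrow(pores), 1L)
  expect_identical(pores$type, "pore")
  expect_lt(abs(pores$x - 20) + abs(pores$y - 14.5), 3)

  # a hole larger than A_max is not a pore
  bar2 <- matrix(0L, 40, 40)
  bar2[5:35, 5:35] <- 1L
  bar2[15:25, 15:25] <- 0L                 # 121 px hole
  expect_identical(nrow(detect_pores(binary_image(bar2, TRUE))), 0L)

  # valleys touching the border are not pores
  expect_identical(nrow(detect_pores(binary_image(bar, TRUE), A_max = 500)), 1L)
})

test_that("minutiae filtering drops border points and facing terminations", {
  df <- data.frame(
    x = c(2, 50, 52, 100, 30),
    y = c(2, 50, 50, 100, 90),
    type = c("termination", "termination", "termination", "bifurcation",
             "eye"),
    quality = 1)
  ms <- minutia_set(df)
  out <- filter_minutiae(ms, c(120, 120), border_margin = 10,
                         min_separation = 5)
  # (2,2) removed by the border rule; the facing pair at distance 2 removed
  expect_identical(nrow(out), 2L)
  expect_setequal(out$type, c("bifurcation", "eye"))

  # a far-apart valid set passes unchanged
  ok <- minutia_set(data.frame(x = c(30, 60, 90), y = c(30, 60, 90),
                               type = "termination", quality = 1))
  expect_identical(nrow(filter_minutiae(ok, c(120, 120), 10, 5)), 3L)
})
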