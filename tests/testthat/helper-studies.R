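# Shared simulation-study cache: the discrimination and recovery studies
# draw on the same seeded synthetic pairs, so each pair is generated and
# extracted once per test run and the slim results are memoized.

.study_cache <- new.env(parent = emptyenv())

study_case <- function(seed) {
  key <- paste0("s", seed)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  pair <- generate_pair(synth_params(seed = seed))
  fx <- extract_features(pair$control, "inked_control")
  fs <- extract_features(pair$sample, "fluorescent_sample")
  occl <- attr(pair$sample, "occlusion_mask")
  occl_zone <- lfpmatch:::from_ebimage(
    EBImage::dilate(lfpmatch:::as_ebimage(occl + 0L),
                    EBImage::makeBrush(9, "disc"))) > 0.5
  out <- list(
    ms_control = fx$minutiae, ms_sample = fs$minutiae,
    truth = pair$truth$minutiae, transform = pair$truth$transform,
    ridge_mask = pair$truth$ridge_mask$pixels,
    occl_zone = occl_zone, dim = dim(pair$control$pixels))
  .study_cache[[key]] <- out
  out
}

truth_in_sample_frame <- function(case) {
  tr <- case$truth
  xy <- transform_points(case$transform, cbind(tr$x, tr$y))
  tr$x <- xy[, 1]; tr$y <- xy[, 2]
  tr
}

match_P <- function(ms_a, ms_b) {
  tryCatch(match_minutiae(ms_a, ms_b)$P, lfp_error = function(e) NA_real_)
}
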