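# Configuration: one nested list carrying every tunable of the pipeline,
# validated strictly (unknown keys are rejected so typos cannot silently
# fall back to defaults), serializable to YAML, echoed into reports.

CONFIG_VERSION <- "1"

#' Default pipeline configuration
#'
#' Returns the full configuration with defaults. Supply overrides as a
#' nested list, e.g. `lfp_config(list(matching = list(tol_r = 10)))`.
#' Unknown keys and out-of-range values raise a configuration error
#' naming the key.
#'
#' @param overrides nested list of settings to change.
#' @return An `lfp_config` list.
#' @export
lfp_config <- function(overrides = NULL) {
  cfg <- list(
    version = CONFIG_VERSION,
    imgproc = list(
      target_mean = 128, target_variance = 2000,
      binarize_method = "adaptive", fixed_threshold = 128,
      adaptive_block = 16),
    ridges = list(
      block_size = 16, segment_quantile = 0.45, core_min_coherence = 0.15,
      L_eye = 30, L_spur = 8, L_short = 15,
      pore_area_min = 1, pore_area_max = 20,
      min_object_area = 20, fill_hole_area = 5, prune_len = 3,
      border_margin = 12, min_separation = 5, mask_margin = 3),
    matching = list(
      r_min = 3, tol_r = 8, tol_phi = 0.4,
      include_pores = FALSE, penalize_unpaired = TRUE),
    synthgen = list(
      pattern = "whorl", image_size = 192, ridge_period = 9,
      n_minutiae = 12, pore_rate = 0.0, substrate = "paper",
      smudge_prob = 0.1, background_texture_amp = 0.2,
      contrast = 0.9, occlusion_frac = 0.1, seed = 1)
  )
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides, "")
  validate_config(cfg)
  structure(cfg, class = c("lfp_config", "list"))
}

merge_config <- function(base, over, path) {
  if (!is.list(over))
    stop_lfp("config", "config section '%s' must be a list", path)
  for (k in names(over)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base))
      stop_lfp("config", "unknown config key '%s'", full)
    if (is.list(base[[k]])) base[[k]] <- merge_config(base[[k]], over[[k]], full)
    else base[[k]] <- over[[k]]
  }
  base
}

validate_config <- function(cfg) {
  chk <- function(cond, key, what) {
    if (!cond) stop_lfp("config", "config key '%s' %s", key, what)
  }
  chk(cfg$imgproc$target_variance > 0, "imgproc.target_variance",
      "must be positive")
  chk(cfg$imgproc$binarize_method %in% c("otsu", "fixed", "adaptive"),
      "imgproc.binarize_method", "must be otsu, fixed or adaptive")
  chk(cfg$ridges$block_size >= 4, "ridges.block_size", "must be >= 4")
  chk(cfg$matching$r_min >= 0, "matching.r_min", "must be non-negative")
  chk(cfg$matching$tol_r > 0, "matching.tol_r", "must be positive")
  chk(cfg$matching$tol_phi > 0, "matching.tol_phi", "must be positive")
  chk(cfg$synthgen$ridge_period >= 4, "synthgen.ridge_period",
      "must be >= 4")
  chk(cfg$synthgen$occlusion_frac >= 0 && cfg$synthgen$occlusion_frac < 1,
      "synthgen.occlusion_frac", "must lie in [0, 1)")
  chk(cfg$synthgen$pattern %in% c("arch", "loop", "whorl"),
      "synthgen.pattern", "must be arch, loop or whorl")
  chk(cfg$synthgen$substrate %in% c("paper", "metal", "plastic", "glass",
                                    "wood"),
      "synthgen.substrate", "must be a known substrate archetype")
  invisible(cfg)
}

resolve_config <- function(config) {
  if (is.null(config)) return(lfp_config())
  if (inherits(config, "lfp_config")) return(config)
  lfp_config(config)
}

#' Load a configuration from YAML
#'
#' Missing file or empty YAML yields all defaults; present keys override
#' them; unknown keys raise an error naming the key.
#'
#' @param path YAML file path, or `NULL` for defaults.
#' @return An `lfp_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(lfp_config())
  if (!file.exists(path))
    stop_lfp("io", "config file not found: %s", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) return(lfp_config())
  y$version <- NULL
  lfp_config(y)
}

#' Save a configuration to YAML
#'
#' @param cfg an `lfp_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

stage_report <- function(name, params, elapsed, warnings = character()) {
  list(stage = name, parameters = params,
       elapsed_seconds = round(elapsed, 3), warnings = warnings)
}
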