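#' Pipeline run configuration
#'
#' Collects every tunable constant of the pipeline with its standard
#' default: 40-frame stride-1 windows at 160 fps, 2 mm/s / 5-frame speed
#' bouts, call bouts exceeding 5 frames, PCA at 0.95 retained variance
#' (random state 2023), a 100-tree forest, a 90/10 stratified split, and
#' 0.25 s (acoustic) / 1.0 s (visual) response windows. Values can be
#' overridden programmatically, from a YAML file, or from CLI flags (flag
#' > file > default).
#'
#' @param plate_format `"P24"` or `"P96"`.
#' @param ... overrides of the defaults listed above.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(plate_format = "P24", ...) {
  cfg <- list(
    plate_format = plate_format,
    W = 40L, stride = 1L, fps = 160,
    pixel_pitch_um = 37.8,
    speed_threshold_mm_s = 2, speed_min_frames = 5L,
    min_call_run = 5L,
    pca_variance = 0.95, pca_seed = 2023L,
    ntree = 100L, forest_seed = 2023L,
    kmeans_k = 9L, kmeans_seed = 2023L,
    train_fraction = 0.9, split_seed = 2023L,
    response_window_tap_s = 0.25, response_window_dark_flash_s = 1.0,
    stimulus_onset_s = 5,
    seed = 2023L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file of `run_config` fields.
#' @param base configuration the file overrides.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, base = run_config()) {
  y <- yaml::read_yaml(path)
  do.call(run_config, utils::modifyList(
    list(plate_format = base$plate_format),
    utils::modifyList(unclass(base)[setdiff(names(base), "plate_format")], y)))
}

# set all stage seeds coherently from one master seed
.reseed_config <- function(cfg, seed) {
  seed <- as.integer(seed)
  cfg$seed <- seed
  cfg$pca_seed <- cfg$forest_seed <- cfg$kmeans_seed <- cfg$split_seed <- seed
  cfg
}
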