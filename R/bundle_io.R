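# Model-bundle persistence: a directory with a human-readable JSON
# manifest plus the exact numeric state (normalizer constants, PCA center
# and basis, fitted forest) serialized as RDS, because predictions must
# round-trip bitwise and decimal text caps out at ~15 significant digits.

#' Save / load a model bundle
#'
#' @param bundle a `model_bundle` from [train_behavior_model()].
#' @param dir bundle directory (created if missing).
#' @return `save_model_bundle()` returns `dir` invisibly;
#'   `load_model_bundle()` the restored `model_bundle`.
#' @export
save_model_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format_version = 1L,
    plate_format = bundle$plate_format, class_set = bundle$class_set,
    W = bundle$W, stride = bundle$stride,
    flatten_order = bundle$flatten_order,
    fps = bundle$fps, pixel_pitch_um = bundle$pixel_pitch_um,
    normalizer = list(scale = bundle$normalizer$scale,
                      offset = bundle$normalizer$offset,
                      plate_format = bundle$normalizer$plate_format),
    pca = bundle$pca[c("ncomp", "explained", "variance_target",
                       "random_state", "whiten")],
    meta = bundle$meta[c("ntree", "forest_seed", "class_counts")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(list(normalizer = bundle$normalizer,
               pca_center = bundle$pca$center,
               pca_rotation = bundle$pca$rotation),
          file.path(dir, "constants.rds"))
  saveRDS(bundle$forest, file.path(dir, "forest.rds"))
  invisible(dir)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("not a model bundle: ", dir, call. = FALSE)
  m <- jsonlite::read_json(mf, simplifyVector = TRUE)
  cst <- readRDS(file.path(dir, "constants.rds"))
  forest <- readRDS(file.path(dir, "forest.rds"))
  structure(list(
    plate_format = m$plate_format, class_set = m$class_set,
    W = m$W, stride = m$stride, flatten_order = m$flatten_order,
    fps = m$fps, pixel_pitch_um = m$pixel_pitch_um,
    normalizer = cst$normalizer,
    pca = list(center = cst$pca_center, rotation = cst$pca_rotation,
               ncomp = m$pca$ncomp,
               explained = m$pca$explained,
               variance_target = m$pca$variance_target,
               random_state = m$pca$random_state, whiten = m$pca$whiten),
    forest = forest, meta = m$meta),
    class = "model_bundle")
}
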