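# The semi-supervised classifier core: KMeans clip mining, stratified
# splitting, PCA (95 percent retained variance, no whitening) + random
# forest per plate format, inference and evaluation.

#' Motor-call class set for a plate format
#'
#' 24-well models distinguish five behaviors; in 96-well plates scoots
#' and routine turns cannot be resolved reliably and are merged into a
#' single `"movement"` class. The label order is fixed and serialized
#' with the model.
#'
#' @param plate_format `"P24"` or `"P96"`.
#' @return character vector of class labels.
#' @export
class_set <- function(plate_format = c("P24", "P96")) {
  switch(match.arg(plate_format),
         P24 = c("stationary", "scoot", "turn", "AsLB", "VsLB"),
         P96 = c("stationary", "movement", "AsLB", "VsLB"))
}

#' KMeans clip mining
#'
#' Clusters flattened behavior windows with k-means (default k = 9) and
#' flags clusters whose members are, on average, stationary: mean
#' within-window center path length below `stationary_path_mm`. The
#' flags mine movement vs stationary clips for manual review; they are
#' never final labels.
#'
#' @param features n x p feature matrix (normalized, flattened windows).
#' @param path_mm optional per-window center path length in mm (from
#'   [featurize_track()]); required for stationary flagging.
#' @param k number of clusters (default 9).
#' @param seed RNG seed (default 2023).
#' @param stationary_path_mm displacement threshold (default 0.5 mm per
#'   window).
#' @return list with `cluster` (assignments), `centers`, `sizes`,
#'   `stationary` (logical per cluster, or NULL without `path_mm`).
#' @export
kmeans_mine <- function(features, path_mm = NULL, k = 9, seed = 2023,
                        stationary_path_mm = 0.5) {
  features <- as.matrix(features)
  if (nrow(features) < k)
    stop("fewer feature vectors (", nrow(features), ") than k = ", k,
         call. = FALSE)
  if (nrow(unique(features)) < k)
    stop("fewer than k distinct feature vectors; clustering is degenerate",
         call. = FALSE)
  set.seed(seed)
  km <- stats::kmeans(features, centers = k, nstart = 10, iter.max = 100)
  stationary <- NULL
  if (!is.null(path_mm)) {
    stopifnot(length(path_mm) == nrow(features))
    stationary <- as.vector(tapply(path_mm, factor(km$cluster, levels = 1:k),
                                   mean)) < stationary_path_mm
    stationary[is.na(stationary)] <- FALSE
  }
  list(cluster = km$cluster, centers = km$centers, sizes = km$size,
       stationary = stationary)
}

#' Export window clips as coordinate CSV files
#'
#' One file per requested window, named `{well}_{start_frame}.csv` with
#' columns `frame, keypoint_index, y, x` (raw pixel coordinates).
#' Rendering the clips to video is an optional manual-review aid and is
#' not performed here.
#'
#' @param track a [pose_track()].
#' @param window_starts 1-based window start frames.
#' @param out_dir output directory (created if missing).
#' @param W window length.
#' @return invisibly, the written file paths.
#' @export
extract_clips <- function(track, window_starts, out_dir, W = 40) {
  N <- n_frames(track)
  if (any(window_starts < 1 | window_starts > N - W + 1))
    stop("window start out of range", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(window_starts, function(i) {
    co <- track$coords[i:(i + W - 1L), , , drop = FALSE]
    dt <- data.table::data.table(
      frame = rep(i:(i + W - 1L), each = 8L),
      keypoint_index = rep(1:8, W),
      y = as.vector(t(co[, , 1])),
      x = as.vector(t(co[, , 2])))
    p <- file.path(out_dir, sprintf("%s_%d.csv", track$well_id, i))
    data.table::fwrite(dt, p)
    p
  }, character(1))
  invisible(paths)
}

#' Stratified train/test split of a clip set
#'
#' Splits 90/10 by default, stratified by class so every class appears in
#' both subsets (each class's training share is within one clip of the
#' target fraction).
#'
#' @param clips a `clip_set`.
#' @param train_fraction fraction assigned to training (default 0.9).
#' @param seed RNG seed.
#' @return list with `train` and `test` clip sets.
#' @export
split_train_test <- function(clips, train_fraction = 0.9, seed = 2023) {
  labs <- clips$labels
  if (any(table(labs[!is.na(labs)]) == 1))
    stop("need >= 2 clips per represented class to split", call. = FALSE)
  set.seed(seed)
  tr <- logical(length(labs))
  for (cl in levels(labs)) {
    idx <- which(labs == cl)
    n <- length(idx)
    if (n == 0) next
    n_tr <- min(max(round(train_fraction * n), 1L), n - 1L)
    tr[sample(idx, n_tr)] <- TRUE
  }
  subset_clips <- function(keep) {
    out <- clips
    out$coords <- clips$coords[keep, , , , drop = FALSE]
    out$labels <- clips$labels[keep]
    out
  }
  list(train = subset_clips(tr), test = subset_clips(!tr))
}

#' Train the motor-call classifier
#'
#' Fits, on the training clips only: the coordinate normalizer
#' ([fit_normalizer()] on the aligned clips), a PCA retaining 95 percent
#' of the training variance (exact SVD, no whitening), and a random
#' forest on the PCA scores. Everything needed for inference is stored in
#' the returned bundle.
#'
#' @param train a training `clip_set` covering every class of its plate
#'   format.
#' @param pca_variance retained variance fraction (default 0.95).
#' @param ntree forest size (default 100).
#' @param seed RNG seed for the forest (default 2023; also recorded as
#'   the PCA random state for provenance, though the exact SVD is
#'   deterministic).
#' @return object of class `model_bundle`.
#' @export
train_behavior_model <- function(train, pca_variance = 0.95, ntree = 100,
                                 seed = 2023) {
  cs <- class_set(train$plate_format)
  missing_cl <- setdiff(cs, as.character(unique(train$labels)))
  if (length(missing_cl))
    stop("class absent from training set: ",
         paste(missing_cl, collapse = ", "), call. = FALSE)
  # align, then fit the normalizer on the aligned training coordinates
  raw <- featurize_clips(train)
  normalizer <- fit_normalizer(as.vector(raw), plate_format = train$plate_format)
  X <- raw / normalizer$scale - normalizer$offset
  if (nrow(X) < 2) stop("PCA needs at least 2 training clips", call. = FALSE)
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  expl <- pca$sdev^2 / sum(pca$sdev^2)
  ncomp <- which(cumsum(expl) >= pca_variance)[1]
  rotation <- pca$rotation[, seq_len(ncomp), drop = FALSE]
  scores <- sweep(X, 2, pca$center) %*% rotation
  y <- factor(train$labels, levels = cs)
  set.seed(seed)
  # balanced bootstrap: class counts are deliberately unequal (rare
  # startle classes), so each tree samples every class equally
  forest <- randomForest::randomForest(
    x = scores, y = y, ntree = ntree, strata = y,
    sampsize = rep(min(table(y)), nlevels(y)))
  structure(list(
    plate_format = train$plate_format, class_set = cs,
    W = train$W, stride = 1L, flatten_order = "frame,keypoint,(y,x)",
    fps = train$fps, pixel_pitch_um = train$pixel_pitch_um,
    normalizer = normalizer,
    pca = list(center = pca$center, rotation = rotation, ncomp = ncomp,
               explained = sum(expl[seq_len(ncomp)]), variance_target = pca_variance,
               random_state = seed, whiten = FALSE),
    forest = forest,
    meta = list(ntree = ntree, forest_seed = seed,
                class_counts = as.list(table(y)))),
    class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> %s: %d classes, W=%d, PCA %d comps (%.1f%% var), %d trees\n",
              x$plate_format, length(x$class_set), x$W, x$pca$ncomp,
              100 * x$pca$explained, x$meta$ntree))
  invisible(x)
}

# feature matrix -> PCA scores under a bundle
.bundle_scores <- function(bundle, features) {
  features <- as.matrix(features)
  if (ncol(features) != bundle$W * 16L)
    stop("feature length ", ncol(features), " does not match bundle W = ",
         bundle$W, " (expected ", bundle$W * 16L, ")", call. = FALSE)
  sweep(features, 2, bundle$pca$center) %*% bundle$pca$rotation
}

#' Predict per-window motor calls
#'
#' @param bundle a fitted `model_bundle`.
#' @param features n x W*16 matrix of *normalized* flattened windows
#'   (e.g. from [featurize_track()] with the bundle's normalizer, or
#'   [featurize_clips()]).
#' @return factor of calls over the bundle's class set.
#' @export
predict_calls <- function(bundle, features) {
  scores <- .bundle_scores(bundle, features)
  stats::predict(bundle$forest, scores, type = "response")
}

#' Classify a pose track into window calls
#'
#' Runs the full inference path -- windowing, egocentric alignment,
#' normalization with the bundle's stored constants, PCA projection,
#' forest prediction -- and returns one call per stride-1 window.
#'
#' @param bundle a `model_bundle`.
#' @param track a [pose_track()].
#' @return data.frame with `well`, `acquisition`, `start_frame`, `call`.
#' @export
classify_track <- function(bundle, track) {
  ft <- featurize_track(track, W = bundle$W, stride = bundle$stride,
                        normalizer = bundle$normalizer)
  calls <- predict_calls(bundle, ft$features)
  data.frame(well = track$well_id, acquisition = track$acquisition_id,
             start_frame = ft$start_frames, call = calls)
}

#' Evaluate a model on held-out clips
#'
#' @param bundle a `model_bundle`.
#' @param test a `clip_set` disjoint from the training set.
#' @return object of class `eval_report`: row-normalized confusion matrix
#'   (true x predicted), per-class precision/recall/F1, and overall
#'   micro-, macro- and support-weighted F1.
#' @export
evaluate_model <- function(bundle, test) {
  pred <- predict_calls(bundle, featurize_clips(test, bundle$normalizer))
  truth <- factor(test$labels, levels = bundle$class_set)
  eval_calls(truth, pred, bundle$class_set)
}

#' @rdname evaluate_model
#' @param truth,pred factors of true and predicted calls.
#' @param classes class label order.
#' @export
eval_calls <- function(truth, pred, classes = levels(factor(truth))) {
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  cm <- table(true = truth, predicted = pred)
  rs <- rowSums(cm)
  cm_prop <- sweep(cm, 1, ifelse(rs == 0, 1, rs), `/`)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) == 0, NA_real_, tp / colSums(cm))
  rec <- ifelse(rs == 0, NA_real_, tp / rs)
  f1 <- ifelse(is.na(prec) | is.na(rec) | (prec + rec) == 0, 0,
               2 * prec * rec / (prec + rec))
  present <- rs > 0
  support <- rs[present]
  structure(list(
    confusion = unclass(cm), confusion_prop = unclass(cm_prop),
    per_class = data.frame(class = classes, precision = as.vector(prec),
                           recall = as.vector(rec), f1 = as.vector(f1),
                           support = as.vector(rs)),
    f1_micro = sum(tp) / sum(cm),
    f1_macro = mean(f1[present]),
    f1_weighted = sum(f1[present] * support) / sum(support)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(round(x$confusion_prop, 3))
  cat(sprintf("F1 micro %.3f | macro %.3f | weighted %.3f\n",
              x$f1_micro, x$f1_macro, x$f1_weighted))
  invisible(x)
}

#' 2-D UMAP embedding of behavior windows (visualization only)
#'
#' @param features n x p feature matrix (n >= 10).
#' @param seed RNG seed; embeddings are reproducible for a fixed seed.
#' @param n_neighbors UMAP neighborhood size (capped at n - 1).
#' @return n x 2 matrix of embedding coordinates.
#' @export
umap_embed <- function(features, seed = 2023, n_neighbors = 15) {
  features <- as.matrix(features)
  if (nrow(features) < 10) stop("need >= 10 samples to embed", call. = FALSE)
  set.seed(seed)
  emb <- uwot::umap(features, n_neighbors = min(n_neighbors, nrow(features) - 1),
                    n_threads = 1, n_sgd_threads = 0)
  colnames(emb) <- c("umap1", "umap2")
  emb
}
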