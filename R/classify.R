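# Step I of the combined pipeline: a random-forest pixel classifier over the
# four texture classes (border, gap, big_fibre, small_fibre), trained on
# sparse brush annotations, and the derivation of the border mask and the
# initial clusters from its predictions.

#' Annotation maps
#'
#' An annotation map is an integer matrix with 0 = unlabeled and classes
#' 1 = border, 2 = gap, 3 = big_fibre, 4 = small_fibre (the indexed-PNG
#' convention). `annotation_map()` validates such a matrix.
#'
#' @param ann integer matrix with values in 0..4.
#' @return the validated matrix.
#' @export
annotation_map <- function(ann) {
  assert_labels(ann, "annotation map")
  if (max(ann) > 4) stop_fs("annotation values must be in 0..4")
  ann
}

#' Train the random-forest pixel classifier
#'
#' Fits a 100-tree random forest on the feature vectors of the annotated
#' pixels only. At least two distinct classes must be annotated. The fit is
#' deterministic for a given seed (single-threaded).
#'
#' @param stack feature array from [compute_features()].
#' @param ann annotation map (see [annotation_map()]), same H x W.
#' @param seed integer RNG seed stored with the model.
#' @param cfg the [feature_config()] used to build `stack`; stored so that
#'   prediction can verify channel compatibility.
#' @param num_trees forest size.
#' @return object of class `fs_classifier`.
#' @export
train_classifier <- function(stack, ann, seed = 1L, cfg = feature_config(),
                             num_trees = 100L) {
  ann <- annotation_map(ann)
  if (!identical(dim(stack)[1:2], dim(ann))) {
    stop_fs("feature stack and annotation map must share dimensions")
  }
  if (dim(stack)[3] != n_feature_channels(cfg)) {
    stop_fs("feature stack has ", dim(stack)[3], " channels but config expects ",
            n_feature_channels(cfg))
  }
  labelled <- which(ann > 0)
  classes_present <- sort(unique(ann[labelled]))
  if (length(classes_present) < 2L) {
    stop_fs("training needs annotations in at least 2 distinct classes; ",
            "got ", length(classes_present),
            " (a single class gives the forest nothing to separate)")
  }
  df <- stack_to_frame(stack, labelled)
  df$.class <- factor(FIBRESEG_CLASSES[ann[labelled]], levels = FIBRESEG_CLASSES)
  df$.class <- droplevels(df$.class)
  forest <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = num_trees, probability = TRUE, min.node.size = 1L,
    seed = seed, num.threads = 1L
  )
  structure(list(
    forest = forest,
    feature_config = cfg,
    classes = levels(df$.class),
    seed = as.integer(seed),
    num_trees = as.integer(num_trees)
  ), class = "fs_classifier")
}

#' Predict a class map
#'
#' Assigns every pixel the majority-vote class of the forest. Ties are broken
#' by the fixed class order border, gap, big_fibre, small_fibre.
#'
#' @param clf an `fs_classifier`.
#' @param stack feature array computed with the classifier's feature config.
#' @return integer matrix of class codes 1..4 (see [annotation_map()]).
#' @export
predict_classes <- function(clf, stack) {
  stopifnot(inherits(clf, "fs_classifier"))
  if (dim(stack)[3] != n_feature_channels(clf$feature_config)) {
    stop_fs("feature stack has ", dim(stack)[3],
            " channels but the classifier was trained with ",
            n_feature_channels(clf$feature_config))
  }
  df <- stack_to_frame(stack)
  prob <- predict(clf$forest, df, num.threads = 1L)$predictions
  # order columns by the canonical class order, then first-max tie-break
  ord <- match(clf$classes, colnames(prob))
  prob <- prob[, ord, drop = FALSE]
  pick <- max.col(prob, ties.method = "first")
  codes <- match(clf$classes, FIBRESEG_CLASSES)[pick]
  matrix(as.integer(codes), dim(stack)[1], dim(stack)[2])
}

#' Border mask from a class map
#'
#' @param class_map integer matrix of class codes (1 = border).
#' @return logical matrix, TRUE where the class is border.
#' @export
extract_border_mask <- function(class_map) {
  assert_labels(class_map, "class map")
  class_map == 1L
}

#' Initial clusters from a border mask
#'
#' Clusters are the smallest regions fully encapsulated by border pixels:
#' 4-connected components of the non-border pixels, with components that
#' touch the image boundary assigned label 0 (not encapsulated). Labels are
#' 1..K in raster-scan order. The complementary border set is implicitly
#' 8-connected, which makes a one-pixel border watertight.
#'
#' @param border logical border mask.
#' @return integer label matrix.
#' @export
initial_clusters <- function(border) {
  assert_mask(border, "border mask")
  lab <- label_components(!border, connectivity = 4L)
  drop_boundary_components(lab)
}

#' Save / load a pixel classifier
#'
#' The archive stores the forest, feature configuration, class list and seed;
#' a round trip reproduces predictions exactly.
#'
#' @param clf an `fs_classifier`.
#' @param path file path.
#' @return `load_classifier()` returns the classifier.
#' @export
save_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "fs_classifier"))
  saveRDS(clf, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  clf <- readRDS(path)
  if (!inherits(clf, "fs_classifier")) stop_fs("not a classifier archive: ", path)
  clf
}
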