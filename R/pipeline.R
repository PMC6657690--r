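# End-to-end orchestration: the combined pipeline (classify -> separate ->
# reconstruct), the SL-only arm (initial clusters reconstructed without
# watershed), the CV-only reference pipeline, and the three-way comparison.

#' Run configuration
#'
#' Aggregates every stage's configuration with the package defaults
#' (intensity threshold off; watershed tau = 0.3; GAC alpha = 2000,
#' sigma = 2, nu = +1, mu = 3, theta = 0.3; ridge sigma* = 0.7,
#' alpha_r = 0.5, beta_r = 0.03; 11x11 closing / 3x3 double dilation /
#' 8x8 elliptical erosion kernels with the 5000 / 500 px^2 size rules).
#'
#' @param preprocess a [preprocess_config()].
#' @param features a [feature_config()].
#' @param separation a [separation_config()].
#' @param gac a [gac_config()].
#' @param ridge a [ridge_config()].
#' @param erosion an [erosion_config()].
#' @return a list of class `fs_run_config`.
#' @export
run_config <- function(preprocess = preprocess_config(),
                       features = feature_config(),
                       separation = separation_config(),
                       gac = gac_config(),
                       ridge = ridge_config(),
                       erosion = erosion_config()) {
  structure(list(preprocess = preprocess, features = features,
                 separation = separation, gac = gac, ridge = ridge,
                 erosion = erosion),
            class = "fs_run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg a [run_config()].
#' @return `read_run_config()` returns an `fs_run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "fs_run_config"))
  plain <- lapply(cfg, function(part) {
    lapply(unclass(part), function(v) if (is.matrix(v)) NULL else v)
  })
  # kernels are rebuilt from defaults on read; only scalars are serialised
  plain$erosion <- plain$erosion[!vapply(plain$erosion, is.null, logical(1))]
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    preprocess = do.call(preprocess_config, y$preprocess %||% list()),
    features = do.call(feature_config, y$features %||% list()),
    separation = do.call(separation_config, y$separation %||% list()),
    gac = do.call(gac_config, y$gac %||% list()),
    ridge = do.call(ridge_config, y$ridge %||% list()),
    erosion = do.call(erosion_config,
                      y$erosion[setdiff(names(y$erosion),
                                        c("closing_kernel", "dilation_kernel",
                                          "erosion_kernel"))] %||% list())
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the combined pipeline on one image
#'
#' Preprocess (manual intensity threshold), classify pixels, extract the
#' border mask, separate clusters by distance-transform watershed, and
#' reconstruct each final cluster with the GAC. Deterministic given the
#' model and configuration.
#'
#' @param img intensity image matrix (or a path readable by
#'   [load_grayscale()]).
#' @param classifier an `fs_classifier` from [train_classifier()].
#' @param cfg a [run_config()].
#' @return list with `fibres`, `labels`, `table`, `class_map`, `border`,
#'   `separation` (the [separate_clusters()] intermediates) and `stages`
#'   (timings in seconds).
#' @export
run_slcv <- function(img, classifier, cfg = run_config()) {
  if (is.character(img)) img <- load_grayscale(img)
  if (!inherits(classifier, "fs_classifier")) {
    stop_fs("no trained model supplied; train one with train_classifier() ",
            "or load one with load_classifier()")
  }
  t0 <- proc.time()[["elapsed"]]
  pre <- apply_intensity_threshold(img, cfg$preprocess)
  stack <- compute_features(pre, classifier$feature_config)
  cm <- predict_classes(classifier, stack)
  border <- extract_border_mask(cm)
  t1 <- proc.time()[["elapsed"]]
  sep <- separate_clusters(border, cfg$separation)
  t2 <- proc.time()[["elapsed"]]
  fibres <- reconstruct_all(sep$final, pre, cfg$gac)
  t3 <- proc.time()[["elapsed"]]
  list(fibres = fibres,
       labels = fibres_to_label_image(fibres, dim(img)),
       table = fibre_table(fibres),
       class_map = cm, border = border, separation = sep,
       stages = c(classify = t1 - t0, separate = t2 - t1,
                  reconstruct = t3 - t2))
}

# SL-only arm: initial clusters reconstructed directly, no watershed.
run_sl_only <- function(img, classifier, cfg = run_config()) {
  pre <- apply_intensity_threshold(img, cfg$preprocess)
  stack <- compute_features(pre, classifier$feature_config)
  cm <- predict_classes(classifier, stack)
  border <- fill_small_holes(extract_border_mask(cm), cfg$separation)
  clusters <- initial_clusters(border)
  fibres <- reconstruct_all(clusters, pre, cfg$gac)
  list(fibres = fibres, labels = fibres_to_label_image(fibres, dim(img)))
}

#' Train a pixel classifier from synthetic samples
#'
#' Builds sparse annotations from the samples' groundtruth and fits one
#' classifier on the pooled annotated pixels (training on a small number of
#' images mirrors how the sparse-brush workflow is used in practice).
#'
#' @param samples list of `fs_synthetic_sample` to train on.
#' @param cfg a [run_config()].
#' @param strokes_per_class dabs per class per sample.
#' @param seed RNG seed for stroke placement and the forest.
#' @return an `fs_classifier`.
#' @export
train_on_samples <- function(samples, cfg = run_config(),
                             strokes_per_class = 12L, seed = 1L) {
  stacks <- list(); anns <- list()
  for (i in seq_along(samples)) {
    pre <- apply_intensity_threshold(samples[[i]]$image, cfg$preprocess)
    stacks[[i]] <- compute_features(pre, cfg$features)
    anns[[i]] <- annotation_from_groundtruth(samples[[i]], strokes_per_class,
                                             seed = seed + i)
  }
  # pool by stacking images vertically (annotation positions are per-image)
  H <- vapply(stacks, function(s) dim(s)[1], integer(1))
  W <- vapply(stacks, function(s) dim(s)[2], integer(1))
  if (length(unique(W)) != 1L) stop_fs("training samples must share width")
  C <- dim(stacks[[1]])[3]
  big <- array(0, dim = c(sum(H), W[1], C))
  big_ann <- matrix(0L, sum(H), W[1])
  at <- 0L
  for (i in seq_along(stacks)) {
    rows <- at + seq_len(H[i])
    big[rows, , ] <- stacks[[i]]
    big_ann[rows, ] <- anns[[i]]
    at <- at + H[i]
  }
  dimnames(big) <- dimnames(stacks[[1]])
  train_classifier(big, big_ann, seed = seed, cfg = cfg$features)
}

#' Compare the combined, SL-only and CV-only pipelines
#'
#' Runs all three arms on every sample and evaluates them against the
#' groundtruth with [evaluate_pipelines()]. The SL-only arm reconstructs
#' the initial clusters without watershed separation; the CV-only arm is
#' the reference pipeline.
#'
#' @param samples list of `fs_synthetic_sample` (or paired lists of images
#'   and groundtruths via `images` / `groundtruths`).
#' @param classifier an `fs_classifier` applied to every image.
#' @param cfg a [run_config()].
#' @param B bootstrap iterations.
#' @param seed bootstrap seed.
#' @param arms subset of `c("slcv", "sl_only", "cv_only")`.
#' @return an `fs_report` (see [evaluate_pipelines()]) with an extra
#'   `manifest` entry (configuration fingerprint and seeds).
#' @export
run_compare <- function(samples, classifier, cfg = run_config(), B = 1e5,
                        seed = 1L, arms = c("slcv", "sl_only", "cv_only")) {
  images <- lapply(samples, function(s) {
    apply_intensity_threshold(s$image, cfg$preprocess)
  })
  groundtruths <- lapply(samples, `[[`, "groundtruth")
  outputs <- list()
  if ("slcv" %in% arms) {
    outputs$slcv <- lapply(seq_along(samples), function(i) {
      run_slcv(samples[[i]]$image, classifier, cfg)$labels
    })
  }
  if ("sl_only" %in% arms) {
    outputs$sl_only <- lapply(seq_along(samples), function(i) {
      run_sl_only(samples[[i]]$image, classifier, cfg)$labels
    })
  }
  if ("cv_only" %in% arms) {
    outputs$cv_only <- lapply(seq_along(samples), function(i) {
      run_reference_pipeline(images[[i]], cfg$ridge, cfg$erosion,
                             cfg$gac)$labels
    })
  }
  report <- evaluate_pipelines(images, groundtruths, outputs,
                               ridge_cfg = cfg$ridge, B = B, seed = seed)
  report$manifest <- run_manifest(cfg, seed = seed, B = B,
                                  n_images = length(samples))
  report
}

# Reproducibility fingerprint: config hash, seeds, versions.
run_manifest <- function(cfg, seed, B, n_images) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(lapply(unclass(cfg), unclass), tmp, version = 2L)
  list(config_md5 = unname(tools::md5sum(tmp)),
       seed = as.integer(seed), B = as.integer(B),
       n_images = as.integer(n_images),
       package_version = as.character(utils::packageVersion("fibreseg")),
       r_version = as.character(getRversion()))
}

#' Write an evaluation report to JSON
#'
#' @param report an `fs_report`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "fs_report"))
  out <- list(
    sensitivity_by_size = report$sensitivity_by_size,
    bootstrap = report$bootstrap,
    dsc_summary = report$dsc_summary,
    kl = report$kl,
    n_reference_clusters = report$n_reference_clusters,
    seed = report$seed, B = report$B,
    manifest = report$manifest
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
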