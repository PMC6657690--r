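# The purely computer-vision reference pipeline: single-scale Hessian ridge
# likelihood -> Otsu binarisation -> morphological closing / dilation /
# inversion to extract clusters -> iterative erosion to sub-threshold size ->
# GAC reconstruction (shared with the combined pipeline).

#' Ridge detection configuration
#'
#' Single-scale ridge likelihood at scale `sigma_star`. `alpha_r` weights
#' the blob-vs-line ratio term and `beta_r` the edge-strength term in the
#' likelihood (distinct from the GAC's `alpha`).
#'
#' @param sigma_star Gaussian scale of the ridge filter, px.
#' @param alpha_r ratio-term scale.
#' @param beta_r strength-term scale.
#' @return a list of class `fs_ridge_config`.
#' @export
ridge_config <- function(sigma_star = 0.7, alpha_r = 0.5, beta_r = 0.03) {
  if (sigma_star <= 0) stop_fs("sigma_star must be > 0")
  if (alpha_r <= 0 || beta_r <= 0) stop_fs("alpha_r and beta_r must be > 0")
  structure(list(sigma_star = sigma_star, alpha_r = alpha_r, beta_r = beta_r),
            class = "fs_ridge_config")
}

#' Erosion / cluster-extraction configuration
#'
#' Kernels and size thresholds of the reference pipeline's second step:
#' closing with an 11x11 rectangle, two dilations with a 3x3 rectangle,
#' inversion and contour detection; then iterative erosion of each cluster
#' with an 8x8 elliptical kernel (anchor fixed at (4, 4)) until its area is
#' below `size_threshold` px^2, and removal of pieces smaller than
#' `min_cluster_size` px^2.
#'
#' @param size_threshold erosion stop size, px^2.
#' @param min_cluster_size artefact-removal floor, px^2.
#' @param closing_kernel,dilation_kernel,erosion_kernel structuring
#'   elements.
#' @param dilation_iterations number of dilation repetitions.
#' @return a list of class `fs_erosion_config`.
#' @export
erosion_config <- function(size_threshold = 5000, min_cluster_size = 500,
                           closing_kernel = se_box(11, 11),
                           dilation_kernel = se_box(3, 3),
                           dilation_iterations = 2L,
                           erosion_kernel = se_ellipse(8, 8)) {
  if (!(size_threshold > min_cluster_size && min_cluster_size > 0)) {
    stop_fs("need size_threshold > min_cluster_size > 0")
  }
  structure(list(size_threshold = size_threshold,
                 min_cluster_size = min_cluster_size,
                 closing_kernel = closing_kernel,
                 dilation_kernel = dilation_kernel,
                 dilation_iterations = as.integer(dilation_iterations),
                 erosion_kernel = erosion_kernel),
            class = "fs_erosion_config")
}

#' Hessian ridge likelihood
#'
#' Smooths the [0, 1]-normalised image at scale `sigma_star`, forms the
#' Hessian, orders its eigenvalues by magnitude |lambda1| >= |lambda2| and
#' scores each pixel with
#' `r = exp(-R_B / alpha_r^2) * (1 - exp(-S^2 / beta_r^2))` where
#' `R_B = |lambda2 / lambda1|` and `S = lambda1^2 + lambda2^2`; `r = 0`
#' wherever `lambda1 > 0` (bright-on-dark ridges only) or the image is flat
#' (`lambda1 = 0`, forced by S = 0 and avoiding the 0/0 in R_B).
#'
#' @param img numeric matrix in [0, 255].
#' @param cfg a [ridge_config()].
#' @return numeric matrix of likelihoods in [0, 1).
#' @export
ridge_likelihood <- function(img, cfg = ridge_config()) {
  assert_image(img)
  stopifnot(inherits(cfg, "fs_ridge_config"))
  sm <- gaussian_smooth(normalize01(img), cfg$sigma_star)
  ev <- hessian_eigen(hessian2d(sm))
  swap <- abs(ev$lmin) > abs(ev$lmax)
  l1 <- ifelse(swap, ev$lmin, ev$lmax)
  l2 <- ifelse(swap, ev$lmax, ev$lmin)
  S <- l1^2 + l2^2
  rb <- ifelse(l1 == 0, 0, abs(l2 / l1))
  r <- exp(-rb / cfg$alpha_r^2) * (1 - exp(-S^2 / cfg$beta_r^2))
  r[l1 > 0] <- 0
  r[l1 == 0] <- 0
  # the strength factor saturates to 1 in floating point on very strong
  # ridges; keep the documented half-open range
  r <- pmin(r, 1 - .Machine$double.eps)
  matrix(r, nrow(img), ncol(img))
}

#' Otsu binarisation of a ridge map
#'
#' Rescales the map linearly to [0, 255], finds the 256-bin Otsu threshold
#' (maximising between-class variance) and returns the above-threshold mask.
#'
#' @param r numeric matrix (e.g. from [ridge_likelihood()]).
#' @return logical mask.
#' @export
otsu_binarize <- function(r) {
  if (!is.matrix(r) || !is.numeric(r)) stop_fs("r must be a numeric matrix")
  lo <- min(r); hi <- max(r)
  if (hi == lo) {
    warning("constant map: Otsu threshold undefined, returning all-false mask")
    return(matrix(FALSE, nrow(r), ncol(r)))
  }
  v <- round((r - lo) / (hi - lo) * 255)
  p <- tabulate(v + 1L, nbins = 256L) / length(v)
  w0 <- cumsum(p)
  m0 <- cumsum(p * (0:255))
  mt <- m0[256]
  # between-class variance for every cut t (class 0: value <= t)
  bc <- ifelse(w0 > 0 & w0 < 1,
               (mt * w0 - m0)^2 / (w0 * (1 - w0)), -Inf)
  t_star <- which.max(bc[1:255]) - 1L # first maximiser, cut below 255
  v > t_star
}

#' Extract clusters by closing, dilation and inversion
#'
#' Morphologically closes the binary border map to seal very small holes,
#' dilates it, inverts, and labels the 4-connected components; components
#' touching the image boundary are background (label 0).
#'
#' @param border logical border mask (e.g. Otsu-binarised ridges).
#' @param cfg an [erosion_config()].
#' @return integer label matrix.
#' @export
extract_clusters_closing <- function(border, cfg = erosion_config()) {
  assert_mask(border, "border mask")
  b <- binary_close(border, cfg$closing_kernel)
  b <- binary_dilate(b, cfg$dilation_kernel, iterations = cfg$dilation_iterations)
  lab <- label_components(!b, connectivity = 4L)
  drop_boundary_components(lab)
}

#' Iteratively erode clusters below a size threshold
#'
#' Each cluster is independently eroded with the elliptical kernel until its
#' area drops below `size_threshold`. Erosion may split a cluster; all
#' resulting pieces are kept and processed independently. Pieces smaller
#' than `min_cluster_size` are removed at the end and the survivors are
#' relabelled 1..K.
#'
#' @param clusters integer label matrix.
#' @param cfg an [erosion_config()].
#' @return integer label matrix of eroded pieces.
#' @export
iterative_erosion <- function(clusters, cfg = erosion_config()) {
  assert_labels(clusters, "clusters")
  H <- nrow(clusters); W <- ncol(clusters)
  out <- matrix(FALSE, H, W)
  pieces <- list()
  ids <- setdiff(sort(unique(as.vector(clusters))), 0L)
  queue <- lapply(ids, function(id) clusters == id)
  while (length(queue)) {
    m <- queue[[1]]; queue <- queue[-1]
    area <- sum(m)
    if (area == 0L) next
    if (area < cfg$size_threshold) {
      pieces[[length(pieces) + 1L]] <- m
      next
    }
    e <- binary_erode(m, cfg$erosion_kernel)
    comp <- label_components(e, connectivity = 4L)
    k <- max(comp)
    if (k == 0L) next # eroded away entirely
    if (k == 1L) {
      queue <- c(list(e), queue)
    } else {
      queue <- c(lapply(seq_len(k), function(i) comp == i), queue)
    }
  }
  pieces <- Filter(function(m) sum(m) >= cfg$min_cluster_size, pieces)
  lab <- matrix(0L, H, W)
  for (i in seq_along(pieces)) lab[pieces[[i]]] <- i
  relabel_raster(lab)
}

#' Run the reference pipeline end to end
#'
#' Ridge likelihood, Otsu binarisation, cluster extraction, iterative
#' erosion, then GAC reconstruction of each piece (boundary-touching pieces
#' excluded) on the same image.
#'
#' @param img preprocessed intensity image.
#' @param ridge_cfg a [ridge_config()].
#' @param erosion_cfg an [erosion_config()].
#' @param gac_cfg a [gac_config()].
#' @return list with `fibres` (as [reconstruct_all()]), `labels` (final
#'   fibre label image), `ridges`, `borders`, `clusters`, `seeds`.
#' @export
run_reference_pipeline <- function(img, ridge_cfg = ridge_config(),
                                   erosion_cfg = erosion_config(),
                                   gac_cfg = gac_config()) {
  assert_image(img)
  r <- ridge_likelihood(img, ridge_cfg)
  if (min(r) == max(r)) {
    return(list(fibres = list(),
                labels = matrix(0L, nrow(img), ncol(img)),
                ridges = r, borders = matrix(FALSE, nrow(img), ncol(img)),
                clusters = matrix(0L, nrow(img), ncol(img)),
                seeds = matrix(0L, nrow(img), ncol(img))))
  }
  borders <- otsu_binarize(r)
  clusters <- extract_clusters_closing(borders, erosion_cfg)
  seeds <- iterative_erosion(clusters, erosion_cfg)
  fibres <- reconstruct_all(seeds, img, gac_cfg)
  list(fibres = fibres,
       labels = fibres_to_label_image(fibres, dim(img)),
       ridges = r, borders = borders, clusters = clusters, seeds = seeds)
}
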