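# Step III: morphological geodesic active contour (GAC) reconstruction.
# Each final cluster seeds a contour that inflates (balloon force), is pulled
# onto intensity edges by the attraction field g(I), and is curvature-
# smoothed, until the mask stabilises. The PDE terms are solved with the
# morphological operators (dilation/erosion, sup-inf/inf-sup) rather than
# numerical integration.

#' GAC configuration
#'
#' `alpha` and `sigma` shape the attraction field
#' `g(I) = 1 / sqrt(1 + alpha * |grad(G_sigma (x) I)|)`: larger `alpha`
#' sharpens the stopping behaviour at edges, `sigma` sets the edge scale in
#' px. `nu` is the balloon sign (+1 inflate, -1 deflate, 0 off), `mu` the
#' number of curvature-smoothing passes per iteration, and `theta` the gate
#' on g below which the balloon is not applied (so the contour freezes on
#' strong edges).
#'
#' @param alpha attraction sharpness (>= 0).
#' @param sigma Gaussian scale of the attraction field, px (> 0).
#' @param nu balloon sign: -1, 0 or +1.
#' @param mu smoothing repetitions per iteration (>= 0).
#' @param theta balloon gating threshold on g, in [0, 1].
#' @param max_iterations iteration cap.
#' @param convergence_window consecutive unchanged iterations required to
#'   declare convergence (mask compared against the two previous states, so
#'   the alternating smoother's 2-cycles also count as converged).
#' @return a list of class `fs_gac_config`.
#' @export
gac_config <- function(alpha = 2000, sigma = 2, nu = 1L, mu = 3L, theta = 0.3,
                       max_iterations = 500L, convergence_window = 5L) {
  if (alpha < 0) stop_fs("alpha must be >= 0")
  if (sigma <= 0) stop_fs("sigma must be > 0")
  if (!nu %in% c(-1L, 0L, 1L)) stop_fs("nu must be -1, 0 or +1")
  if (mu < 0) stop_fs("mu must be >= 0")
  assert_scalar_in(theta, 0, 1, "theta")
  structure(list(alpha = alpha, sigma = sigma, nu = as.integer(nu),
                 mu = as.integer(mu), theta = theta,
                 max_iterations = as.integer(max_iterations),
                 convergence_window = as.integer(convergence_window)),
            class = "fs_gac_config")
}

#' Edge attraction field
#'
#' Computes `g(I) = 1 / sqrt(1 + alpha * |grad(G_sigma (x) I)|)` on the
#' [0, 1]-normalised image: g is 1 on flat regions and approaches 0 at
#' strong intensity edges, which is where the contour is meant to stop.
#'
#' @param img numeric matrix in [0, 255].
#' @param cfg a [gac_config()].
#' @return numeric matrix with values in (0, 1].
#' @export
attraction_field <- function(img, cfg = gac_config()) {
  assert_image(img)
  stopifnot(inherits(cfg, "fs_gac_config"))
  sm <- gaussian_smooth(normalize01(img), cfg$sigma)
  gr <- gradient2d(sm)
  1 / sqrt(1 + cfg$alpha * sqrt(gr$dr^2 + gr$dc^2))
}

#' Evolve a morphological GAC from a seed mask
#'
#' Runs the morphological solver: per iteration a balloon
#' dilation/erosion gated by `g > theta`, an attraction update flipping
#' pixels where `grad(g) . grad(u)` is decisive, and `mu` alternating
#' sup-inf / inf-sup curvature passes. Stops when the mask is unchanged
#' (up to the smoother's alternation) for `convergence_window` consecutive
#' iterations, or at `max_iterations`.
#'
#' @param seed logical seed mask (nonempty).
#' @param g attraction field from [attraction_field()], same size.
#' @param cfg a [gac_config()].
#' @return logical mask of the evolved contour interior.
#' @export
gac_evolve <- function(seed, g, cfg = gac_config()) {
  assert_mask(seed, "seed")
  if (!any(seed)) stop_fs("seed mask is empty")
  assert_same_dim(seed, g, "seed and attraction field")
  res <- .gac_evolve_cpp(matrix(as.integer(seed), nrow(seed)), g,
                         cfg$nu, cfg$theta, cfg$mu,
                         cfg$max_iterations, cfg$convergence_window)
  out <- res$mask == 1L
  attr(out, "iterations") <- res$iterations
  out
}

#' Measure a fibre mask
#'
#' Area is the pixel count; the feret diameter is the maximum pairwise
#' distance between pixel centres on the mask's convex hull; the perimeter
#' is the length of the traced outer contour (diagonal steps count sqrt(2));
#' the centroid is the mean pixel coordinate.
#'
#' @param mask logical fibre mask (nonempty).
#' @param fibre_id id recorded in the output row.
#' @return one-row tibble: fibre_id, area, feret, centroid_row,
#'   centroid_col, perimeter.
#' @export
measure_fibre <- function(mask, fibre_id = 1L) {
  assert_mask(mask, "fibre mask")
  px <- which(mask, arr.ind = TRUE)
  if (nrow(px) == 0L) stop_fs("fibre mask is empty")
  area <- nrow(px)
  centroid <- colMeans(px)
  feret <- 0
  if (area > 1L) {
    hull <- px[grDevices::chull(px[, 1], px[, 2]), , drop = FALSE]
    dmat <- as.matrix(stats::dist(hull))
    feret <- max(dmat)
  }
  perimeter <- if (area == 1L) 0 else {
    oc <- EBImage::ocontour(EBImage::as.Image(matrix(as.numeric(mask), nrow(mask))))[[1]]
    if (nrow(oc) < 2L) 0 else {
      steps <- sqrt(rowSums((oc - oc[c(2:nrow(oc), 1L), , drop = FALSE])^2))
      sum(steps)
    }
  }
  tibble::tibble(
    fibre_id = as.integer(fibre_id), area = as.numeric(area),
    feret = feret, centroid_row = centroid[[1]], centroid_col = centroid[[2]],
    perimeter = perimeter
  )
}

# Crop window around a seed with a growth margin, clamped to the image.
crop_window <- function(mask, margin) {
  px <- which(mask, arr.ind = TRUE)
  r0 <- max(1L, min(px[, 1]) - margin); r1 <- min(nrow(mask), max(px[, 1]) + margin)
  c0 <- max(1L, min(px[, 2]) - margin); c1 <- min(ncol(mask), max(px[, 2]) + margin)
  list(rows = r0:r1, cols = c0:c1)
}

#' Reconstruct all fibres from final clusters
#'
#' Drops clusters touching the image boundary (their fibres are incomplete),
#' computes the attraction field once on the supplied (preprocessed) image,
#' and evolves each remaining cluster independently with [gac_evolve()].
#' Each contour is evolved on a window around its seed (`grow_margin` px of
#' slack on every side) for speed; results are independent of the order of
#' clusters. Overlaps between independently evolved fibres are permitted and
#' retained; `resolve_overlaps = TRUE` optionally reassigns contested pixels
#' to the fibre with the nearer seed.
#'
#' @param final_clusters label matrix from [watershed_separation()].
#' @param img preprocessed intensity image.
#' @param cfg a [gac_config()].
#' @param grow_margin evolution window slack in px.
#' @param resolve_overlaps reassign contested pixels to the nearest seed.
#' @return list of fibres; each has `fibre_id`, `mask` (full-size logical),
#'   `source_cluster_id`, and `measure` (tibble row from [measure_fibre()]).
#' @export
reconstruct_all <- function(final_clusters, img, cfg = gac_config(),
                            grow_margin = 40L, resolve_overlaps = FALSE) {
  assert_labels(final_clusters, "final clusters")
  assert_image(img)
  assert_same_dim(final_clusters, img, "clusters and image")
  g <- attraction_field(img, cfg)
  lab <- drop_boundary_components(final_clusters)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  fibres <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    seed <- lab == ids[i]
    win <- crop_window(seed, grow_margin)
    sub <- gac_evolve(seed[win$rows, win$cols, drop = FALSE],
                      g[win$rows, win$cols, drop = FALSE], cfg)
    mask <- matrix(FALSE, nrow(img), ncol(img))
    mask[win$rows, win$cols] <- sub
    # keep only the component containing the seed (the attraction term can
    # nucleate detached specks on distant edges)
    comp <- label_components(mask, 4L)
    seed_ids <- setdiff(unique(comp[seed]), 0L)
    mask <- comp %in% seed_ids & comp > 0L
    mask <- matrix(mask, nrow(img), ncol(img))
    if (!any(mask)) {
      # a very small seed can be annihilated by the curvature smoothing;
      # fall back to the unevolved cluster rather than losing the fibre
      mask <- seed
    }
    fibres[[i]] <- list(fibre_id = i, mask = mask,
                        source_cluster_id = ids[i],
                        measure = measure_fibre(mask, i))
  }
  if (resolve_overlaps && length(fibres) > 1L) {
    fibres <- resolve_fibre_overlaps(fibres, lab)
  }
  fibres
}

# Reassign pixels claimed by several fibres to the fibre with nearest seed.
resolve_fibre_overlaps <- function(fibres, seed_lab) {
  count <- Reduce(`+`, lapply(fibres, function(f) f$mask * 1L))
  contested <- which(count > 1L, arr.ind = TRUE)
  if (nrow(contested) == 0L) return(fibres)
  seed_px <- lapply(fibres, function(f) {
    which(seed_lab == f$source_cluster_id, arr.ind = TRUE)
  })
  for (k in seq_len(nrow(contested))) {
    p <- contested[k, ]
    owners <- which(vapply(fibres, function(f) f$mask[p[1], p[2]], logical(1)))
    d <- vapply(owners, function(o) {
      min((seed_px[[o]][, 1] - p[1])^2 + (seed_px[[o]][, 2] - p[2])^2)
    }, numeric(1))
    keep <- owners[which.min(d)]
    for (o in setdiff(owners, keep)) fibres[[o]]$mask[p[1], p[2]] <- FALSE
  }
  for (i in seq_along(fibres)) {
    fibres[[i]]$measure <- measure_fibre(fibres[[i]]$mask, fibres[[i]]$fibre_id)
  }
  fibres
}

#' Fibre table and label image from reconstructed fibres
#'
#' @param fibres list from [reconstruct_all()].
#' @return `fibre_table()` a tibble (one row per fibre);
#'   `fibres_to_label_image()` an integer label matrix (fibres painted in id
#'   order, later ids win contested pixels).
#' @export
fibre_table <- function(fibres) {
  if (length(fibres) == 0L) {
    return(tibble::tibble(fibre_id = integer(), area = numeric(),
                          feret = numeric(), centroid_row = numeric(),
                          centroid_col = numeric(), perimeter = numeric()))
  }
  dplyr::bind_rows(lapply(fibres, `[[`, "measure"))
}

#' @rdname fibre_table
#' @param dim_hw image dimensions c(H, W); defaults to the first mask's.
#' @export
fibres_to_label_image <- function(fibres, dim_hw = NULL) {
  if (length(fibres) == 0L) {
    if (is.null(dim_hw)) stop_fs("dim_hw required when no fibres are present")
    return(matrix(0L, dim_hw[1], dim_hw[2]))
  }
  if (is.null(dim_hw)) dim_hw <- dim(fibres[[1]]$mask)
  out <- matrix(0L, dim_hw[1], dim_hw[2])
  for (f in fibres) out[f$mask] <- f$fibre_id
  out
}
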