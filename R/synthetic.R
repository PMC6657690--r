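# Deterministic generator of synthetic fluorescence-style muscle
# cross-sections with groundtruth. A seeded point process with one Lloyd
# relaxation pass gives a Voronoi mosaic of convex-ish, size-varied cells;
# walls are rendered as bright bands along cell bisectors. Cells touching
# the image edge become dark interstitial gap regions (so the fibre bundle
# is enclosed by its stained boundary, as in real sections), optionally
# joined by interior gap cells, and the challenge classes of real stained
# sections are injected on top: per-wall border holes, intra-fibre speckle
# (uniform or clustered), noisy gaps and a stitching brightness step. The
# wall registry records every fibre-fibre wall and whether a hole was
# punched into it, so expected separation behaviour is exactly known.

#' Synthetic cross-section configuration
#'
#' @param height,width image size in px.
#' @param n_fibres target number of Voronoi cells (fibres + gap regions).
#' @param border_width wall thickness in px.
#' @param border_intensity wall staining intensity in [0, 255].
#' @param border_hole_rate probability that a fibre-fibre wall receives a
#'   hole (a gap of length about `2 * (border_width + 4)` px, long enough
#'   that neither one border dilation nor a moderate morphological closing
#'   can reseal it).
#' @param fibre_intensity_range c(low, high) of per-fibre base intensity.
#' @param speckle_sd intra-fibre noise SD in intensity units.
#' @param speckle_clumping `"uniform"` (i.i.d. Gaussian) or `"clustered"`
#'   (low-frequency blobs of bright speckle, emulating vesicle-like spots).
#' @param gap_fraction fraction of the mosaic area turned into additional
#'   interior gap regions (cells touching the image edge are always gap, so
#'   the bundle is enclosed).
#' @param gap_noise_sd intensity SD of gap staining noise.
#' @param stitch_step intensity offset added right of a vertical seam at the
#'   image midline (0 = off).
#' @param seed integer RNG seed; every sample is a pure function of its
#'   config.
#' @return a list of class `fs_synthetic_config`.
#' @export
synthetic_config <- function(height = 320L, width = 320L, n_fibres = 40L,
                             border_width = 1.5, border_intensity = 230,
                             border_hole_rate = 0,
                             fibre_intensity_range = c(60, 130),
                             speckle_sd = 0,
                             speckle_clumping = c("uniform", "clustered"),
                             gap_fraction = 0.04, gap_noise_sd = 0,
                             stitch_step = 0, seed = 1L) {
  speckle_clumping <- match.arg(speckle_clumping)
  assert_scalar_in(border_intensity, 0, 255, "border_intensity")
  assert_scalar_in(border_hole_rate, 0, 1, "border_hole_rate")
  if (n_fibres < 1) stop_fs("n_fibres must be >= 1")
  if (any(fibre_intensity_range < 0) || any(fibre_intensity_range > 255)) {
    stop_fs("fibre_intensity_range must lie in [0, 255]")
  }
  if (height * width < 100 * n_fibres) {
    stop_fs("infeasible geometry: fewer than 100 px per fibre")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_fibres = as.integer(n_fibres), border_width = border_width,
                 border_intensity = border_intensity,
                 border_hole_rate = border_hole_rate,
                 fibre_intensity_range = fibre_intensity_range,
                 speckle_sd = speckle_sd, speckle_clumping = speckle_clumping,
                 gap_fraction = gap_fraction, gap_noise_sd = gap_noise_sd,
                 stitch_step = stitch_step, seed = as.integer(seed)),
            class = "fs_synthetic_config")
}

# Nearest and second-nearest Voronoi site per pixel (squared distances).
voronoi_fields <- function(sr, sc, H, W) {
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  d1 <- matrix(Inf, H, W); d2 <- matrix(Inf, H, W)
  l1 <- matrix(0L, H, W); l2 <- matrix(0L, H, W)
  for (k in seq_along(sr)) {
    dk <- (rr - sr[k])^2 + (cc - sc[k])^2
    upd2 <- dk < d2 & dk >= d1
    d2[upd2] <- dk[upd2]; l2[upd2] <- k
    upd1 <- dk < d1
    d2[upd1] <- d1[upd1]; l2[upd1] <- l1[upd1]
    d1[upd1] <- dk[upd1]; l1[upd1] <- k
  }
  list(d1 = d1, d2 = d2, l1 = l1, l2 = l2)
}

#' Generate one synthetic cross-section with groundtruth
#'
#' @param cfg a [synthetic_config()].
#' @return list of class `fs_synthetic_sample`: `image` (8-bit matrix),
#'   `groundtruth` (label matrix; walls and gaps are 0), `wall_registry`
#'   (tibble cell_id_a, cell_id_b, hole_applied for every fibre-fibre
#'   wall), `boundary_cells` (labels touching the image edge), plus the
#'   internal `wall_mask` and `gap_mask` used for annotation sampling, and
#'   the `config`.
#' @export
generate_cross_section <- function(cfg) {
  stopifnot(inherits(cfg, "fs_synthetic_config"))
  H <- cfg$height; W <- cfg$width; n <- cfg$n_fibres
  with_local_seed(cfg$seed, {
    sr <- runif(n, 1, H); sc <- runif(n, 1, W)
    # one Lloyd relaxation pass: move each site to its cell centroid
    vf <- voronoi_fields(sr, sc, H, W)
    for (k in seq_len(n)) {
      px <- which(vf$l1 == k, arr.ind = TRUE)
      if (nrow(px) > 0L) {
        sr[k] <- mean(px[, 1]); sc[k] <- mean(px[, 2])
      }
    }
    vf <- voronoi_fields(sr, sc, H, W)
    # constant-width walls: perpendicular distance of the pixel to the
    # bisector of its two nearest sites, |d1^2 - d2^2| / (2 |s_i - s_j|)
    site_dist <- sqrt((sr[vf$l1] - sr[vf$l2])^2 + (sc[vf$l1] - sc[vf$l2])^2)
    perp <- abs(vf$d1 - vf$d2) / (2 * pmax(site_dist, 1e-9))
    wall <- matrix(perp < cfg$border_width / 2, H, W)
    pair_a <- pmin(vf$l1, vf$l2); pair_b <- pmax(vf$l1, vf$l2)

    # interstitial gaps: every cell on the image edge (so the bundle is
    # enclosed by its stained boundary), plus random interior cells up to
    # gap_fraction of the area
    edge_cells <- unique(c(vf$l1[1, ], vf$l1[H, ], vf$l1[, 1], vf$l1[, W]))
    cell_area <- tabulate(vf$l1, nbins = n)
    gap_cells <- edge_cells
    if (cfg$gap_fraction > 0) {
      inner <- setdiff(seq_len(n), edge_cells)
      ord <- if (length(inner) > 1L) sample(inner) else inner
      cum <- cumsum(cell_area[ord])
      gap_cells <- c(gap_cells,
                     ord[seq_len(sum(cum <= cfg$gap_fraction * H * W))])
    }
    is_gap_cell <- seq_len(n) %in% gap_cells
    gap_mask <- matrix(is_gap_cell[vf$l1], H, W)
    # no membranes inside the interstitial space
    wall[wall & is_gap_cell[pair_a] & is_gap_cell[pair_b]] <- FALSE

    # fibre-fibre walls and hole injection
    fib_wall <- wall & !is_gap_cell[pair_a] & !is_gap_cell[pair_b]
    keys <- paste(pair_a[fib_wall], pair_b[fib_wall])
    wall_pairs <- unique(keys)
    hole_r <- ceiling(cfg$border_width + 4) # hole length ~ 2*r, beyond closing reach
    registry <- list()
    for (wp in wall_pairs) {
      ab <- as.integer(strsplit(wp, " ")[[1]])
      hole <- runif(1) < cfg$border_hole_rate
      if (hole) {
        idx <- which(fib_wall & pair_a == ab[1] & pair_b == ab[2])
        centre <- idx[sample.int(length(idx), 1L)]
        cr <- (centre - 1L) %% H + 1L; ccol <- (centre - 1L) %/% H + 1L
        px <- which(wall, arr.ind = TRUE)
        near <- pmax(abs(px[, 1] - cr), abs(px[, 2] - ccol)) <= hole_r
        onpair <- pair_a[wall][near] == ab[1] & pair_b[wall][near] == ab[2]
        kill <- px[near, , drop = FALSE][onpair, , drop = FALSE]
        wall[kill] <- FALSE
      }
      registry[[length(registry) + 1L]] <-
        data.frame(site_a = ab[1], site_b = ab[2], hole_applied = hole)
    }
    registry <- if (length(registry)) do.call(rbind, registry) else {
      data.frame(site_a = integer(), site_b = integer(),
                 hole_applied = logical())
    }

    # groundtruth: fibre pixels (not wall, not gap), relabelled 1..K in
    # raster order
    gt0 <- vf$l1
    gt0[wall | gap_mask] <- 0L
    gt <- relabel_raster(gt0)
    site_to_label <- integer(n)
    for (k in setdiff(unique(as.vector(gt0)), 0L)) {
      site_to_label[k] <- gt[which(gt0 == k)[1]]
    }
    registry$cell_id_a <- site_to_label[registry$site_a]
    registry$cell_id_b <- site_to_label[registry$site_b]
    # drop walls of cells that were swallowed entirely by wall rendering
    registry <- registry[registry$cell_id_a > 0L & registry$cell_id_b > 0L, ,
                         drop = FALSE]
    registry <- tibble::as_tibble(
      registry[, c("cell_id_a", "cell_id_b", "hole_applied")]
    )
    boundary_cells <- setdiff(unique(c(gt[1, ], gt[H, ], gt[, 1], gt[, W])), 0L)

    # render
    img <- matrix(0, H, W)
    base <- runif(n, cfg$fibre_intensity_range[1], cfg$fibre_intensity_range[2])
    fibre_px <- !wall & !gap_mask
    img[fibre_px] <- base[vf$l1[fibre_px]]
    img[gap_mask] <- 8
    img[wall] <- cfg$border_intensity
    if (cfg$speckle_sd > 0) {
      if (cfg$speckle_clumping == "uniform") {
        img[fibre_px] <- img[fibre_px] +
          rnorm(sum(fibre_px), 0, cfg$speckle_sd)
      } else {
        field <- gaussian_smooth(matrix(rnorm(H * W), H, W), 3)
        blobs <- field > stats::quantile(field, 0.88)
        img[fibre_px] <- img[fibre_px] +
          rnorm(sum(fibre_px), 0, cfg$speckle_sd / 2)
        bump <- fibre_px & blobs
        img[bump] <- img[bump] + 4 * cfg$speckle_sd
      }
    }
    if (cfg$gap_noise_sd > 0 && any(gap_mask)) {
      img[gap_mask] <- img[gap_mask] +
        abs(rnorm(sum(gap_mask), 0, cfg$gap_noise_sd))
    }
    if (cfg$stitch_step != 0) {
      seam <- floor(W / 2) + 1L
      img[, seam:W] <- img[, seam:W] + cfg$stitch_step
    }
    img <- round(pmin(pmax(img, 0), 255))
    structure(list(image = img, groundtruth = gt, wall_registry = registry,
                   boundary_cells = boundary_cells, wall_mask = wall,
                   gap_mask = gap_mask, config = cfg),
              class = "fs_synthetic_sample")
  })
}

#' Generate a benchmark suite of synthetic samples
#'
#' The presets fix the study conditions: `"clean"` renders noise-free,
#' hole-free mosaics; `"moderate"` injects border holes (rate 0.22),
#' uniform intra-fibre speckle and gap noise; `"hard"` raises the hole rate,
#' switches to clustered speckle, and adds a stitching seam.
#'
#' @param set_size number of samples.
#' @param preset `"clean"`, `"moderate"` or `"hard"`.
#' @param seed master seed; sample i uses `seed + 7919 * i`.
#' @return list of `fs_synthetic_sample`.
#' @export
generate_benchmark <- function(set_size, preset = c("clean", "moderate", "hard"),
                               seed = 1L) {
  preset <- match.arg(preset)
  lapply(seq_len(set_size), function(i) {
    s <- as.integer(seed + 7919L * i)
    cfg <- switch(preset,
      clean = synthetic_config(seed = s),
      moderate = synthetic_config(border_hole_rate = 0.12, speckle_sd = 8,
                                  gap_noise_sd = 6, seed = s),
      hard = synthetic_config(border_hole_rate = 0.2, speckle_sd = 10,
                              speckle_clumping = "clustered",
                              gap_noise_sd = 10, stitch_step = 30, seed = s)
    )
    generate_cross_section(cfg)
  })
}

#' Sparse annotations from a synthetic sample's groundtruth
#'
#' Emulates sparse brush training: for each class a few small dabs are
#' sampled from the regions the class describes — walls for `border`, gap
#' pixels for `gap`, interiors of above-median-area cells for `big_fibre`
#' and below-median cells for `small_fibre`. A class with no eligible
#' region is omitted with a warning.
#'
#' @param sample an `fs_synthetic_sample`.
#' @param strokes_per_class dabs per class (0 gives an unlabeled map).
#' @param seed RNG seed.
#' @param dab_radius Chebyshev radius of each dab, px.
#' @return integer annotation map (see [annotation_map()]).
#' @export
annotation_from_groundtruth <- function(sample, strokes_per_class = 5L,
                                        seed = 1L, dab_radius = 2L) {
  stopifnot(inherits(sample, "fs_synthetic_sample"))
  H <- nrow(sample$image); W <- ncol(sample$image)
  ann <- matrix(0L, H, W)
  if (strokes_per_class == 0L) return(ann)
  gt <- sample$groundtruth
  # interior pixels: off the walls by one pixel
  interior <- gt > 0L & !binary_dilate(sample$wall_mask, se_box(3, 3))
  areas <- table(gt[gt > 0L])
  med <- stats::median(as.numeric(areas))
  big_ids <- as.integer(names(areas)[as.numeric(areas) >= med])
  eligible <- list(
    border = which(sample$wall_mask),
    gap = which(sample$gap_mask & !binary_dilate(sample$wall_mask, se_box(3, 3))),
    big_fibre = which(interior & matrix(gt %in% big_ids, H, W)),
    small_fibre = which(interior & !matrix(gt %in% big_ids, H, W) & gt > 0L)
  )
  with_local_seed(seed, {
    for (ci in seq_along(FIBRESEG_CLASSES)) {
      el <- eligible[[FIBRESEG_CLASSES[ci]]]
      if (length(el) == 0L) {
        warning("no eligible region for class '", FIBRESEG_CLASSES[ci],
                "'; omitted")
        next
      }
      anchors <- el[sample.int(length(el), min(strokes_per_class, length(el)))]
      for (a in anchors) {
        ar <- (a - 1L) %% H + 1L; ac <- (a - 1L) %/% H + 1L
        rows <- max(1L, ar - dab_radius):min(H, ar + dab_radius)
        cols <- max(1L, ac - dab_radius):min(W, ac + dab_radius)
        block <- matrix(FALSE, H, W)
        block[rows, cols] <- TRUE
        hit <- which(block)
        hit <- intersect(hit, el)
        ann[hit] <- ci
      }
    }
  })
  ann
}
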