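# Error-analysis framework: reference clusters (groups of touching
# groundtruth cells enclosed by a detected border), separation sensitivity
# from a per-cluster contingency table, paired bootstrap comparison of
# pipelines, Dice similarity of reconstructed areas, and Kullback-Leibler
# divergence between fibre-area distributions.

#' Reference clusters from an image and its groundtruth
#'
#' Applies a neutral gradient analysis (ridge likelihood, Otsu
#' binarisation, one 3x3 dilation) to the image to obtain border pixels,
#' takes the encapsulated components (as in [initial_clusters()]) and counts
#' for each component the groundtruth cells whose plurality of pixel mass
#' lies inside it. Only clusters containing more than one groundtruth cell
#' are kept: these are the genuinely hard separation cases, indexed by their
#' size n.
#'
#' @param img intensity image.
#' @param groundtruth label matrix of manually delineated cells.
#' @param ridge_cfg a [ridge_config()].
#' @return list of reference clusters; each has `cluster_id`,
#'   `member_cell_ids`, `n` and `region` (logical mask).
#' @export
reference_clusters <- function(img, groundtruth, ridge_cfg = ridge_config()) {
  assert_image(img)
  assert_labels(groundtruth, "groundtruth")
  assert_same_dim(img, groundtruth, "image and groundtruth")
  r <- ridge_likelihood(img, ridge_cfg)
  if (min(r) == max(r)) return(list())
  border <- binary_dilate(otsu_binarize(r), se_box(3, 3), iterations = 1L)
  clusters <- initial_clusters(border)
  cell_ids <- setdiff(sort(unique(as.vector(groundtruth))), 0L)
  if (length(cell_ids) == 0L || !any(clusters > 0L)) return(list())
  # plurality assignment of each groundtruth cell to a cluster (or 0)
  assigned <- vapply(cell_ids, function(cid) {
    tab <- table(clusters[groundtruth == cid])
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
  out <- list()
  for (cl in setdiff(sort(unique(assigned)), 0L)) {
    members <- cell_ids[assigned == cl]
    if (length(members) <= 1L) next
    out[[length(out) + 1L]] <- list(
      cluster_id = cl,
      member_cell_ids = members,
      n = length(members),
      region = clusters == cl
    )
  }
  out
}

#' Group reference clusters by size and drop sparse sizes
#'
#' @param clusters list of reference clusters (possibly pooled over images).
#' @param min_samples smallest group size retained.
#' @return named list mapping size n to the list of clusters of that size.
#' @export
group_and_filter <- function(clusters, min_samples = 5L) {
  sizes <- vapply(clusters, `[[`, integer(1), "n")
  out <- list()
  for (n in sort(unique(sizes))) {
    grp <- clusters[sizes == n]
    if (length(grp) >= min_samples) out[[as.character(n)]] <- grp
  }
  out
}

#' Match detected fibres to groundtruth cells
#'
#' Greedy one-to-one matching by descending pairwise Dice; a pair is
#' accepted only if its Dice is at least `min_dice` (default 0.5, which
#' guarantees a unique majority-overlap partner).
#'
#' @param detected,groundtruth label matrices of equal size.
#' @param min_dice acceptance threshold.
#' @return list with `pairs` (tibble: detected_id, groundtruth_id, dice),
#'   `unmatched_detected`, `unmatched_groundtruth`.
#' @export
match_detections <- function(detected, groundtruth, min_dice = 0.5) {
  assert_labels(detected, "detected")
  assert_labels(groundtruth, "groundtruth")
  assert_same_dim(detected, groundtruth)
  det_ids <- setdiff(sort(unique(as.vector(detected))), 0L)
  gt_ids <- setdiff(sort(unique(as.vector(groundtruth))), 0L)
  if (length(det_ids) == 0L || length(gt_ids) == 0L) {
    return(list(pairs = tibble::tibble(detected_id = integer(),
                                       groundtruth_id = integer(),
                                       dice = numeric()),
                unmatched_detected = det_ids, unmatched_groundtruth = gt_ids))
  }
  det_sz <- table(factor(detected[detected > 0L], levels = det_ids))
  gt_sz <- table(factor(groundtruth[groundtruth > 0L], levels = gt_ids))
  both <- detected > 0L & groundtruth > 0L
  ov <- table(factor(detected[both], levels = det_ids),
              factor(groundtruth[both], levels = gt_ids))
  dice_mat <- 2 * ov / outer(as.numeric(det_sz), as.numeric(gt_sz), `+`)
  cand <- which(dice_mat >= min_dice, arr.ind = TRUE)
  if (nrow(cand) > 0L) {
    # descending dice; deterministic tie-break by (detected, groundtruth) id
    ordn <- order(-dice_mat[cand], cand[, 1], cand[, 2])
    cand <- cand[ordn, , drop = FALSE]
  }
  used_d <- logical(length(det_ids)); used_g <- logical(length(gt_ids))
  pr <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_d[i] || used_g[j]) next
    used_d[i] <- TRUE; used_g[j] <- TRUE
    pr[[length(pr) + 1L]] <- tibble::tibble(
      detected_id = det_ids[i], groundtruth_id = gt_ids[j],
      dice = dice_mat[i, j]
    )
  }
  pairs <- if (length(pr)) dplyr::bind_rows(pr) else {
    tibble::tibble(detected_id = integer(), groundtruth_id = integer(),
                   dice = numeric())
  }
  list(pairs = pairs,
       unmatched_detected = det_ids[!used_d],
       unmatched_groundtruth = gt_ids[!used_g])
}

#' Contingency table of a reference cluster
#'
#' `a` counts the member cells with an accepted one-to-one match (true
#' positives), `d = n - a` the member cells missed or not separated (false
#' negatives), and `b` the detections intersecting the cluster region that
#' contain more than one member cell (each covering at least
#' `multi_frac` of the detection's area).
#'
#' @param rc one reference cluster from [reference_clusters()].
#' @param match a [match_detections()] result for the whole image.
#' @param detected,groundtruth the label matrices used for `match`.
#' @param multi_frac per-cell coverage fraction for counting `b`.
#' @return list of class `fs_contingency`: n, a, b, d.
#' @export
contingency <- function(rc, match, detected, groundtruth, multi_frac = 0.1) {
  a <- sum(match$pairs$groundtruth_id %in% rc$member_cell_ids)
  det_in <- setdiff(unique(detected[rc$region]), 0L)
  b <- 0L
  for (id in det_in) {
    det_mask <- detected == id
    det_area <- sum(det_mask)
    covered <- vapply(rc$member_cell_ids, function(cid) {
      sum(det_mask & groundtruth == cid) >= multi_frac * det_area
    }, logical(1))
    if (sum(covered) >= 2L) b <- b + 1L
  }
  contingency_table(n = rc$n, a = a, b = b)
}

#' Build a contingency table directly
#'
#' @param n reference-cluster size (number of member groundtruth cells).
#' @param a true positives (0 <= a <= n).
#' @param b false positives (detections spanning several member cells).
#' @return list of class `fs_contingency` with d = n - a.
#' @export
contingency_table <- function(n, a, b = 0L) {
  if (n < 1) stop_fs("n must be >= 1")
  if (a < 0 || a > n) stop_fs("need 0 <= a <= n")
  structure(list(n = as.integer(n), a = as.integer(a), b = as.integer(b),
                 d = as.integer(n - a)),
            class = "fs_contingency")
}

#' Separation sensitivity
#'
#' `sensitivity = a / (a + d)`: the fraction of cells within a reference
#' cluster that were separated correctly.
#'
#' @param tab an `fs_contingency` from [contingency()] / [contingency_table()].
#' @return numeric in [0, 1].
#' @export
sensitivity <- function(tab) {
  stopifnot(inherits(tab, "fs_contingency"))
  if (tab$a + tab$d < 1) stop_fs("sensitivity undefined for empty cluster")
  tab$a / (tab$a + tab$d)
}

#' Paired bootstrap comparison of two pipelines
#'
#' Tests H0: "the mean of `values_pl2` is >= the mean of `values_pl1`" by
#' resampling the paired observations with replacement `B` times and
#' recording the fraction of resamples in which H0 holds. A small p-value
#' supports pl1 being better than pl2.
#'
#' @param values_pl1,values_pl2 paired numeric vectors (same reference
#'   clusters, two pipelines).
#' @param B bootstrap iterations.
#' @param seed RNG seed.
#' @param keep_means retain per-iteration means in the result.
#' @return list of class `fs_bootstrap`: p_value, B, seed, and optionally
#'   `means` (B x 2).
#' @export
bootstrap_compare <- function(values_pl1, values_pl2, B = 1e5, seed = 1L,
                              keep_means = FALSE) {
  if (length(values_pl1) == 0L) stop_fs("empty input")
  if (length(values_pl1) != length(values_pl2)) {
    stop_fs("paired inputs must have equal length")
  }
  n <- length(values_pl1)
  h0 <- logical(B)
  means <- if (keep_means) matrix(NA_real_, B, 2) else NULL
  with_local_seed(seed, {
    for (i in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      m1 <- mean(values_pl1[idx]); m2 <- mean(values_pl2[idx])
      h0[i] <- m2 >= m1
      if (keep_means) means[i, ] <- c(m1, m2)
    }
  })
  structure(list(p_value = mean(h0), B = as.integer(B),
                 seed = as.integer(seed), means = means),
            class = "fs_bootstrap")
}

#' Dice similarity coefficient
#'
#' `DSC = 2 |X intersect Y| / (|X| + |Y|)`: 1 for identical areas, 0 for
#' disjoint ones.
#'
#' @param X,Y logical masks of equal size, not both empty.
#' @return numeric in [0, 1].
#' @export
dice <- function(X, Y) {
  assert_mask(X, "X"); assert_mask(Y, "Y")
  assert_same_dim(X, Y)
  sx <- sum(X); sy <- sum(Y)
  if (sx + sy == 0L) stop_fs("Dice undefined for two empty masks")
  2 * sum(X & Y) / (sx + sy)
}

#' Kullback-Leibler divergence between area distributions
#'
#' Histograms both area samples on shared bins of width `bin_size` from 0 to
#' their joint maximum, normalises to probabilities and evaluates
#' `D_KL(P || Q) = sum P log(P / Q)` (natural log). Terms with P = 0
#' contribute 0; bins with Q = 0 but P > 0 are handled by adding
#' epsilon = 1e-12 to every Q bin and renormalising.
#'
#' @param areas_P,areas_Q nonempty numeric vectors of areas (px^2).
#' @param bin_size histogram bin width (px^2).
#' @return nonnegative numeric.
#' @export
kl_area_divergence <- function(areas_P, areas_Q, bin_size) {
  if (length(areas_P) == 0L || length(areas_Q) == 0L) stop_fs("empty input")
  if (bin_size <= 0) stop_fs("bin_size must be > 0")
  top <- max(areas_P, areas_Q)
  breaks <- seq(0, bin_size * (floor(top / bin_size) + 1L), by = bin_size)
  p <- tabulate(findInterval(areas_P, breaks, left.open = TRUE,
                             rightmost.closed = TRUE),
                nbins = length(breaks) - 1L)
  q <- tabulate(findInterval(areas_Q, breaks, left.open = TRUE,
                             rightmost.closed = TRUE),
                nbins = length(breaks) - 1L)
  P <- p / sum(p)
  Q <- q / sum(q)
  Q <- (Q + 1e-12) / sum(Q + 1e-12)
  keep <- P > 0
  sum(P[keep] * log(P[keep] / Q[keep]))
}

#' Kernel density estimate of a binned area distribution
#'
#' Histograms the areas with bin width `bin_size`, then smooths the bin
#' masses with a Gaussian kernel whose bandwidth is `bandwidth_factor`
#' times the sample standard deviation. The returned curve integrates to 1.
#'
#' @param areas numeric vector of areas (px^2), more than one distinct value.
#' @param bin_size histogram bin width (px^2).
#' @param bandwidth_factor bandwidth as a fraction of the sample SD.
#' @param n_grid number of curve points.
#' @return tibble with columns `area`, `density`.
#' @export
area_density <- function(areas, bin_size = 800, bandwidth_factor = 0.2,
                         n_grid = 512L) {
  if (length(areas) == 0L) stop_fs("empty input")
  s <- sd(areas)
  if (!is.finite(s) || s == 0) {
    stop_fs("degenerate bandwidth: need more than one distinct area value")
  }
  bw <- bandwidth_factor * s
  breaks <- seq(0, bin_size * (floor(max(areas) / bin_size) + 1L), by = bin_size)
  counts <- tabulate(findInterval(areas, breaks, left.open = TRUE,
                                  rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  mass <- counts / sum(counts)
  centers <- breaks[-1] - bin_size / 2
  grid <- seq(min(centers) - 4 * bw, max(centers) + 4 * bw, length.out = n_grid)
  dens <- vapply(grid, function(x) sum(mass * dnorm(x, centers, bw)), numeric(1))
  tibble::tibble(area = grid, density = dens)
}

# Per-cluster sensitivities of one method on one image.
cluster_sensitivities <- function(rcs, detected, groundtruth) {
  if (length(rcs) == 0L) return(tibble::tibble(cluster_id = integer(),
                                               n = integer(), a = integer(),
                                               b = integer(),
                                               sensitivity = numeric()))
  m <- match_detections(detected, groundtruth)
  rows <- lapply(rcs, function(rc) {
    tab <- contingency(rc, m, detected, groundtruth)
    tibble::tibble(cluster_id = rc$cluster_id, n = rc$n, a = tab$a, b = tab$b,
                   sensitivity = sensitivity(tab))
  })
  dplyr::bind_rows(rows)
}

#' Evaluate pipelines against groundtruth
#'
#' For every image, derives the reference clusters and scores every method's
#' label image: per-cluster separation sensitivity, pairwise paired
#' bootstrap p-values per cluster size (sizes with fewer than `min_samples`
#' clusters are dropped) and pooled over retained sizes, Dice similarity
#' restricted to cells correctly separated by all compared methods, and KL
#' divergence of the reconstructed-area distribution from the groundtruth
#' areas over a ladder of bin sizes.
#'
#' @param images list of intensity images.
#' @param groundtruths list of groundtruth label matrices.
#' @param pipeline_outputs named list (one entry per method) of lists of
#'   label matrices aligned with `images`.
#' @param ridge_cfg a [ridge_config()] for the reference-cluster borders.
#' @param B bootstrap iterations.
#' @param seed bootstrap RNG seed.
#' @param min_samples per-size sample floor.
#' @param kl_bin_sizes histogram bin-size ladder for the KL curves.
#' @return list of class `fs_report`: `sensitivities` (tibble),
#'   `sensitivity_by_size`, `bootstrap` (tibble of pairwise tests),
#'   `dsc` (tibble), `dsc_summary`, `kl` (tibble), `n_reference_clusters`,
#'   `seed`, `B`.
#' @export
evaluate_pipelines <- function(images, groundtruths, pipeline_outputs,
                               ridge_cfg = ridge_config(), B = 1e5, seed = 1L,
                               min_samples = 5L,
                               kl_bin_sizes = c(50, 100, 200, 500, 1e3, 2e3,
                                                5e3, 1e4, 2e4)) {
  stopifnot(length(images) == length(groundtruths))
  methods <- names(pipeline_outputs)
  if (is.null(methods) || any(methods == "")) {
    stop_fs("pipeline_outputs must be a named list of per-method outputs")
  }
  for (m in methods) {
    stopifnot(length(pipeline_outputs[[m]]) == length(images))
  }
  sens_rows <- list()
  match_cache <- list()
  for (i in seq_along(images)) {
    rcs <- reference_clusters(images[[i]], groundtruths[[i]], ridge_cfg)
    for (m in methods) {
      tabs <- cluster_sensitivities(rcs, pipeline_outputs[[m]][[i]],
                                    groundtruths[[i]])
      if (nrow(tabs)) {
        tabs$image <- i
        tabs$method <- m
        sens_rows[[length(sens_rows) + 1L]] <- tabs
      }
      match_cache[[paste(i, m)]] <-
        match_detections(pipeline_outputs[[m]][[i]], groundtruths[[i]])
    }
  }
  sens <- if (length(sens_rows)) dplyr::bind_rows(sens_rows) else {
    tibble::tibble(cluster_id = integer(), n = integer(), a = integer(),
                   b = integer(), sensitivity = numeric(), image = integer(),
                   method = character())
  }
  # retained sizes: at least min_samples clusters of that size
  size_counts <- sens |>
    dplyr::filter(.data$method == methods[[1]]) |>
    dplyr::count(.data$n, name = "nn")
  kept_sizes <- size_counts$n[size_counts$nn >= min_samples]
  by_size <- sens |>
    dplyr::filter(.data$n %in% kept_sizes) |>
    dplyr::group_by(.data$method, .data$n) |>
    dplyr::summarise(mean_sensitivity = mean(.data$sensitivity),
                     n_clusters = dplyr::n(), .groups = "drop")
  # pairwise paired bootstrap per size and pooled
  boot_rows <- list()
  if (length(methods) >= 2L && nrow(sens) > 0L) {
    key <- sens |>
      dplyr::filter(.data$n %in% kept_sizes) |>
      dplyr::arrange(.data$image, .data$cluster_id)
    for (i1 in seq_along(methods)) {
      for (i2 in seq_along(methods)) {
        if (i1 == i2) next
        m1 <- methods[i1]; m2 <- methods[i2]
        v1all <- key$sensitivity[key$method == m1]
        v2all <- key$sensitivity[key$method == m2]
        nall <- key$n[key$method == m1]
        for (sz in c(as.list(sort(unique(nall))), list("pooled"))) {
          pick <- if (identical(sz, "pooled")) rep(TRUE, length(nall))
                  else nall == sz
          if (!any(pick)) next
          bt <- bootstrap_compare(v1all[pick], v2all[pick], B = B, seed = seed)
          boot_rows[[length(boot_rows) + 1L]] <- tibble::tibble(
            pl1 = m1, pl2 = m2,
            size = if (identical(sz, "pooled")) "pooled" else as.character(sz),
            n_samples = sum(pick), p_value = bt$p_value
          )
        }
      }
    }
  }
  boot <- if (length(boot_rows)) dplyr::bind_rows(boot_rows) else {
    tibble::tibble(pl1 = character(), pl2 = character(), size = character(),
                   n_samples = integer(), p_value = numeric())
  }
  # DSC restricted to cells correctly separated by all methods
  dsc_rows <- list()
  for (i in seq_along(images)) {
    gt <- groundtruths[[i]]
    gt_ids <- setdiff(sort(unique(as.vector(gt))), 0L)
    if (length(gt_ids) == 0L) next
    matched_by <- lapply(methods, function(m) {
      match_cache[[paste(i, m)]]$pairs
    })
    common <- Reduce(intersect, lapply(matched_by, `[[`, "groundtruth_id"))
    for (cid in common) {
      cell <- gt == cid
      for (k in seq_along(methods)) {
        pairs <- matched_by[[k]]
        det_id <- pairs$detected_id[pairs$groundtruth_id == cid]
        det <- pipeline_outputs[[methods[k]]][[i]] == det_id
        dsc_rows[[length(dsc_rows) + 1L]] <- tibble::tibble(
          image = i, groundtruth_id = cid, method = methods[k],
          dsc = dice(det, cell)
        )
      }
    }
  }
  dsc <- if (length(dsc_rows)) dplyr::bind_rows(dsc_rows) else {
    tibble::tibble(image = integer(), groundtruth_id = integer(),
                   method = character(), dsc = numeric())
  }
  dsc_summary <- dsc |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mean_dsc = mean(.data$dsc), n_cells = dplyr::n(),
                     .groups = "drop")
  # KL curves: groundtruth areas vs reconstructed areas, pooled over images
  gt_areas <- unlist(lapply(groundtruths, function(gt) {
    as.numeric(table(gt[gt > 0L]))
  }))
  kl_rows <- list()
  for (m in methods) {
    det_areas <- unlist(lapply(pipeline_outputs[[m]], function(lb) {
      as.numeric(table(lb[lb > 0L]))
    }))
    if (length(det_areas) == 0L || length(gt_areas) == 0L) next
    for (h in kl_bin_sizes) {
      kl_rows[[length(kl_rows) + 1L]] <- tibble::tibble(
        method = m, bin_size = h,
        kl = kl_area_divergence(gt_areas, det_areas, h)
      )
    }
  }
  kl <- if (length(kl_rows)) dplyr::bind_rows(kl_rows) else {
    tibble::tibble(method = character(), bin_size = numeric(), kl = numeric())
  }
  structure(list(
    sensitivities = sens, sensitivity_by_size = by_size, bootstrap = boot,
    dsc = dsc, dsc_summary = dsc_summary, kl = kl,
    n_reference_clusters = nrow(sens) / max(1L, length(methods)),
    seed = as.integer(seed), B = as.integer(B)
  ), class = "fs_report")
}
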