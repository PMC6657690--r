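test_that("ridge likelihood is zero on flat images and dark lines", {
  expect_true(all(ridge_likelihood(matrix(50, 20, 20)) == 0))
  # dark 2-px line on bright background: lambda1 > 0 on the line centre
  img <- matrix(200, 21, 21)
  img[10:11, ] <- 20
  r <- ridge_likelihood(img)
  expect_true(all(r[10:11, 5:15] == 0))
})

test_that("ridge likelihood matches a brute-force hessian oracle", {
  img <- matrix(0, 25, 25)
  img[12:13, ] <- 255 # bright 2-px horizontal line
  cfg <- ridge_config(sigma_star = 0.7)
  r <- ridge_likelihood(img, cfg)
  # oracle: dense gaussian smoothing, finite-difference hessian, explicit
  # 2x2 eigendecomposition, magnitude ordering, likelihood formula
  sm <- brute_gaussian(img / 255, 0.7)
  H <- nrow(img); W <- ncol(img)
  pad <- function(i, n) pmin(pmax(i, 1L), n)
  oracle <- matrix(0, H, W)
  for (a in 1:H) {
    for (b in 1:W) {
      ap <- pad(a + 1, H); am <- pad(a - 1, H)
      bp <- pad(b + 1, W); bm <- pad(b - 1, W)
      drr <- sm[ap, b] - 2 * sm[a, b] + sm[am, b]
      dcc <- sm[a, bp] - 2 * sm[a, b] + sm[a, bm]
      drc <- (sm[ap, bp] - sm[ap, bm] - sm[am, bp] + sm[am, bm]) / 4
      ev <- eigen(matrix(c(drr, drc, drc, dcc), 2, 2), symmetric = TRUE)$values
      l1 <- ev[which.max(abs(ev))]; l2 <- ev[which.min(abs(ev))]
      if (l1 > 0 || l1 == 0) next
      S <- l1^2 + l2^2
      oracle[a, b] <- exp(-abs(l2 / l1) / 0.5^2) * (1 - exp(-S^2 / 0.03^2))
    }
  }
  expect_lt(max(abs(r - oracle)), 1e-6)
  # the maximum response lies on the line
  expect_true(all(which(r == max(r), arr.ind = TRUE)[, 1] %in% 12:13))
  # bounds: r in [0, 1), zero wherever lambda1 > 0 or the image is flat
  expect_true(all(r >= 0 & r < 1))
})

test_that("otsu binarisation matches exhaustive between-class variance", {
  x <- matrix(c(rep(0, 900), rep(0.9, 100)), 25, 40)
  mask <- otsu_binarize(x)
  expect_equal(sum(mask), 100L)
  expect_true(all(mask[x == 0.9]))
  # cut point equals the brute-force maximiser over all 256 cut values
  set.seed(8)
  y <- matrix(runif(400)^2, 20, 20)
  m2 <- otsu_binarize(y)
  t_star <- brute_otsu(y)
  ys <- round((y - min(y)) / (max(y) - min(y)) * 255)
  expect_identical(m2, ys > t_star)
  # independent cross-check: EBImage's otsu lands within a bin or two
  # (its returned threshold uses a different bin-edge convention)
  eb <- EBImage::otsu(EBImage::as.Image((y - min(y)) / (max(y) - min(y))),
                      range = c(0, 1), levels = 256)
  expect_lt(abs(eb * 255 - t_star), 3)
  expect_warning(out <- otsu_binarize(matrix(0, 5, 5)), "constant")
  expect_false(any(out))
})

test_that("closing-dilation-inversion extraction seals wall holes", {
  # closed ring with a 5-px hole in its wall -> hole sealed, 1 cluster
  ring <- ring_mask(41, 41, 21, 21, 14, 2)
  holey <- ring
  holey[20:24, which(ring[22, ])[1]] <- FALSE # carve a small hole
  lab <- extract_clusters_closing(holey, erosion_config())
  expect_equal(max(lab), 1L)
  # all-false border: everything joins the boundary -> zero clusters
  expect_equal(max(extract_clusters_closing(matrix(FALSE, 30, 30),
                                            erosion_config())), 0L)
  # clusters are strictly smaller than the encapsulated interior because of
  # the double dilation
  plain <- initial_clusters(ring)
  expect_lt(sum(lab > 0L), sum(plain > 0L))
})

test_that("iterative erosion obeys the size rules and can split", {
  cfg <- erosion_config(size_threshold = 5000, min_cluster_size = 500)
  # area below the threshold -> untouched
  small_disc <- matrix(0L, 80, 80)
  small_disc[disc_mask(80, 80, 40, 40, 35)] <- 1L # area ~ 3848 < 5000
  out <- iterative_erosion(small_disc, cfg)
  expect_identical(out, small_disc)

  # big disc erodes to a single piece in [500, 5000)
  big <- matrix(0L, 180, 180)
  big[disc_mask(180, 180, 90, 90, 80)] <- 1L # ~ 20100 px
  out <- iterative_erosion(big, cfg)
  expect_equal(max(out), 1L)
  expect_lt(sum(out > 0L), 5000)
  expect_gte(sum(out > 0L), 500)

  # dumbbell of ~12000 px splits into 2 pieces at the neck
  db <- matrix(0L, 150, 260)
  db[dumbbell_mask(150, 260, r = 44, neck_halfwidth = 3,
                   c1 = c(75, 60), c2 = c(75, 200))] <- 1L
  out <- iterative_erosion(db, cfg)
  expect_equal(max(out), 2L)
  # pieces never grow and never merge
  expect_true(all(db[out > 0L] == 1L))
})

test_that("reference pipeline runs end to end on a synthetic mosaic", {
  sm <- generate_cross_section(synthetic_config(seed = 31))
  pre <- apply_intensity_threshold(sm$image, preprocess_config(30))
  res <- run_reference_pipeline(pre)
  gt_ids <- setdiff(unique(as.vector(sm$groundtruth)), 0L)
  # clean borders: one fibre per interior groundtruth cell, all matched
  m <- match_detections(res$labels, sm$groundtruth)
  expect_gte(nrow(m$pairs), length(gt_ids) - 1L)
  # blank image: no fibres
  blank <- run_reference_pipeline(matrix(0, 40, 40))
  expect_length(blank$fibres, 0L)
})

test_that("holed walls between small fibres defeat erosion-based separation
           but not the watershed", {
  # every wall holed in the default small-fibre mosaic: merged pairs stay
  # below the erosion size threshold, so erosion cannot split them
  sm <- generate_cross_section(synthetic_config(border_hole_rate = 1, seed = 5))
  pre <- apply_intensity_threshold(sm$image, preprocess_config(30))
  res <- run_reference_pipeline(pre)
  m_cv <- match_detections(res$labels, sm$groundtruth)
  n_gt <- length(setdiff(unique(as.vector(sm$groundtruth)), 0L))
  expect_lt(nrow(m_cv$pairs), n_gt)
  # the watershed separation on the true walls recovers more cells from the
  # same holes
  sep <- separate_clusters(sm$wall_mask, separation_config())
  fib <- reconstruct_all(sep$final, pre)
  m_ws <- match_detections(fibres_to_label_image(fib, dim(pre)),
                           sm$groundtruth)
  expect_gt(nrow(m_ws$pairs), nrow(m_cv$pairs))
})
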