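test_that("hole filling is the configured number of 3x3 dilations", {
  # 1-px gap in a straight border line closes after one iteration
  b <- matrix(FALSE, 7, 7)
  b[4, c(1:3, 5:7)] <- TRUE
  out <- fill_small_holes(b, separation_config(dilation_iterations = 1L))
  expect_true(all(out[4, ])) # the line is continuous again
  # oracle: one shift-dilation with the full 3x3 square
  expect_identical(out, binary_dilate(b, se_box(3, 3)))
  # zero iterations is the identity; empty mask stays empty
  expect_identical(fill_small_holes(b, separation_config(dilation_iterations = 0L)), b)
  empty <- matrix(FALSE, 5, 5)
  expect_identical(fill_small_holes(empty, separation_config()), empty)
})

test_that("distance transform is the exact euclidean distance to the border", {
  ring <- ring_mask(25, 25, 13, 13, 10)
  cl <- initial_clusters(ring)
  d <- distance_transform(ring, cl)
  # 4-neighbour of a border pixel has distance 1, diagonal sqrt(2)
  inside <- cl == 1L
  expect_equal(sort(unique(round(d[inside & d <= sqrt(2)], 6))),
               round(c(1, sqrt(2)), 6))
  # oracle: brute-force all-pairs distances on the full fixture
  oracle <- brute_distance(inside, ring)
  expect_lt(max(abs(d[inside] - oracle[inside])), 1e-9)
  # max within 0.5 px of the ring radius
  expect_lt(abs(max(d) - 10), 0.5)
  # zero on border and outside the clusters
  expect_true(all(d[ring] == 0))
  expect_true(all(d[cl == 0L] == 0))
})

dumbbell_fixture <- function() {
  shape <- dumbbell_mask(H = 60, W = 90, r = 10, neck_halfwidth = 2)
  es <- enclosed_shape(shape)
  cl <- initial_clusters(es$border)
  d <- distance_transform(es$border, cl)
  list(border = es$border, clusters = cl, dist = d)
}

test_that("marker thresholding splits the dumbbell but not a disc", {
  # single disc: unimodal distance map -> exactly one marker at tau = 0.3
  es <- enclosed_shape(disc_mask(30, 30, 15, 15, 10))
  cl <- initial_clusters(es$border)
  d <- distance_transform(es$border, cl)
  mk <- threshold_distance(d, cl, separation_config(tau = 0.3))
  expect_equal(max(mk), 1L)

  # dumbbell: neck distance < 0.3 * disc max -> exactly two markers
  fx <- dumbbell_fixture()
  mk <- threshold_distance(fx$dist, fx$clusters, separation_config(tau = 0.3))
  expect_equal(max(mk), 2L)

  # tau = 0 keeps the entire interiors
  mk0 <- threshold_distance(fx$dist, fx$clusters, separation_config(tau = 0))
  expect_equal(sum(mk0 > 0), sum(fx$clusters > 0))
})

test_that("raising tau refines markers (each component nests in a coarser one)", {
  fx <- dumbbell_fixture()
  taus <- c(0.1, 0.3, 0.5, 0.8)
  marks <- lapply(taus, function(t) {
    threshold_distance(fx$dist, fx$clusters, separation_config(tau = t))
  })
  for (k in seq_len(length(taus) - 1L)) {
    fine <- marks[[k + 1L]]; coarse <- marks[[k]]
    for (id in setdiff(unique(as.vector(fine)), 0L)) {
      under <- coarse[fine == id]
      expect_true(all(under > 0L)) # subset of surviving coarse pixels
      expect_equal(length(unique(under)), 1L) # within a single component
    }
  }
})

test_that("watershed splits the dumbbell at the neck like nearest-marker", {
  fx <- dumbbell_fixture()
  mk <- threshold_distance(fx$dist, fx$clusters, separation_config(tau = 0.3))
  ws <- watershed_separation(fx$dist, mk, fx$border)
  expect_equal(length(setdiff(unique(as.vector(ws)), 0L)), 2L)
  # final clusters stay inside the initial cluster and never merge
  expect_true(all(fx$clusters[ws > 0L] == 1L))
  # brute-force nearest-marker partition: neither basin crosses the neck
  # midline by more than 1 px
  px <- which(ws > 0L, arr.ind = TRUE)
  mid <- 45 # symmetric fixture: discs at columns 25 and 65
  lab_left <- ws[which(ws > 0L)[which.min(px[, 2])]]
  left_cols <- px[ws[ws > 0L] == lab_left, 2]
  right_cols <- px[ws[ws > 0L] != lab_left, 2]
  expect_lte(max(left_cols), mid + 1)
  expect_gte(min(right_cols), mid - 1)
})

test_that("watershed with full-interior markers reproduces the clusters", {
  fx <- dumbbell_fixture()
  mk0 <- threshold_distance(fx$dist, fx$clusters, separation_config(tau = 0))
  ws <- watershed_separation(fx$dist, mk0, fx$border)
  expect_equal(ws > 0L, fx$clusters > 0L)
  # empty markers warn and return all zero
  expect_warning(
    out <- watershed_separation(fx$dist, matrix(0L, 60, 90), fx$border),
    "empty"
  )
  expect_true(all(out == 0L))
})

test_that("separation never merges and marker counts carry through", {
  g <- grid_border(3, cell = 14)
  # punch a hole in one interior wall so two cells merge into one cluster
  b <- g
  b[16, 18:26] <- FALSE
  sep <- separate_clusters(b, separation_config(tau = 0.3,
                                                dilation_iterations = 0L))
  # each final cluster lies inside exactly one initial cluster
  for (id in setdiff(unique(as.vector(sep$final)), 0L)) {
    expect_equal(length(unique(sep$initial[sep$final == id])), 1L)
  }
  # markers per initial cluster equal final clusters per initial cluster
  for (ic in setdiff(unique(as.vector(sep$initial)), 0L)) {
    n_mark <- length(setdiff(unique(sep$markers[sep$initial == ic]), 0L))
    n_fin <- length(setdiff(unique(sep$final[sep$initial == ic]), 0L))
    expect_equal(n_fin, n_mark)
  }
})
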