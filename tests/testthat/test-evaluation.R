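test_that("sensitivity is a/(a+d) with the published worked values", {
  expect_equal(round(sensitivity(contingency_table(n = 6, a = 4)), 2), 0.67)
  expect_equal(sensitivity(contingency_table(n = 5, a = 2)), 0.4)
  expect_equal(sensitivity(contingency_table(n = 3, a = 3)), 1.0)
  # bounds and the d = 0 equivalence
  for (n in 1:6) for (a in 0:n) {
    s <- sensitivity(contingency_table(n, a))
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s == 1, a == n)
  }
  expect_error(contingency_table(n = 4, a = 5), "a <= n")
})

test_that("contingency tables conserve a + d = n", {
  for (n in 1:6) for (a in 0:n) {
    tab <- contingency_table(n, a)
    expect_equal(tab$a + tab$d, tab$n)
  }
})

test_that("dice matches hand-counted overlaps and is a bounded metric", {
  X <- matrix(FALSE, 4, 4); Y <- matrix(FALSE, 4, 4)
  X[1, 1:4] <- TRUE; Y[1, 3:4] <- TRUE; Y[2, 1:2] <- TRUE
  expect_equal(dice(X, Y), 0.5) # |X|=|Y|=4, overlap 2
  expect_equal(dice(X, X), 1)
  Z <- matrix(FALSE, 4, 4); Z[4, 4] <- TRUE
  expect_equal(dice(X, Z), 0)
  expect_equal(dice(X, Y), dice(Y, X))
  expect_error(dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), "empty")
  # dice = 1 iff X = Y
  set.seed(11)
  for (i in 1:20) {
    A <- matrix(runif(36) > 0.5, 6, 6)
    B <- matrix(runif(36) > 0.5, 6, 6)
    if (sum(A) + sum(B) == 0) next
    expect_equal(dice(A, B) == 1, identical(A, B))
  }
})

test_that("greedy matching is one-to-one with the 0.5 dice gate", {
  gt <- matrix(0L, 10, 10)
  gt[2:5, 2:5] <- 1L; gt[7:9, 7:9] <- 2L
  # identity: perfect matching with dice 1
  m <- match_detections(gt, gt)
  expect_equal(nrow(m$pairs), 2L)
  expect_true(all(m$pairs$dice == 1))
  # empty detections: everything unmatched
  m0 <- match_detections(matrix(0L, 10, 10), gt)
  expect_equal(nrow(m0$pairs), 0L)
  expect_equal(m0$unmatched_groundtruth, c(1L, 2L))
  # one detection covering two equal cells entirely: dice 2/3 with each,
  # counted once for the tie-ordered first cell
  gt2 <- matrix(0L, 6, 8)
  gt2[2:5, 2:3] <- 1L; gt2[2:5, 6:7] <- 2L
  det <- matrix(0L, 6, 8)
  det[2:5, 2:7] <- 1L
  dd <- 2 * 8 / (24 + 8)
  m2 <- match_detections(det, gt2)
  expect_equal(nrow(m2$pairs), 1L)
  expect_equal(m2$pairs$groundtruth_id, 1L)
  expect_equal(m2$pairs$dice, dd)
  expect_equal(m2$unmatched_groundtruth, 2L)
})

test_that("contingency counts multi-cell detections as false positives", {
  gt <- matrix(0L, 8, 12)
  gt[2:7, 2:5] <- 1L; gt[2:7, 8:11] <- 2L
  rc <- list(cluster_id = 1L, member_cell_ids = c(1L, 2L), n = 2L,
             region = matrix(TRUE, 8, 12))
  # one detection spanning the whole cluster: a = 1 (greedy match to one
  # cell at dice 2/3), b = 1
  det <- matrix(0L, 8, 12)
  det[2:7, 2:11] <- 1L
  m <- match_detections(det, gt)
  tab <- contingency(rc, m, det, gt)
  expect_equal(tab$b, 1L)
  # perfect separation: a = 2, b = 0, d = 0
  mp <- match_detections(gt, gt)
  tabp <- contingency(rc, mp, gt, gt)
  expect_equal(c(tabp$a, tabp$b, tabp$d), c(2L, 0L, 0L))
})

test_that("bootstrap p-values hit the exact endpoints", {
  x <- c(0.5, 0.7, 0.9, 0.4)
  expect_equal(bootstrap_compare(x, x, B = 500, seed = 1)$p_value, 1)
  expect_equal(bootstrap_compare(x, x + 0.1, B = 500, seed = 1)$p_value, 1)
  expect_equal(bootstrap_compare(x + 0.1, x, B = 500, seed = 1)$p_value, 0)
  expect_equal(bootstrap_compare(rep(1, 5), rep(0, 5), B = 200, seed = 2)$p_value, 0)
  # determinism under the seed
  y <- c(0.2, 0.9, 0.1, 0.8)
  b1 <- bootstrap_compare(x, y, B = 1000, seed = 9)
  b2 <- bootstrap_compare(x, y, B = 1000, seed = 9)
  expect_equal(b1$p_value, b2$p_value)
  expect_error(bootstrap_compare(numeric(0), numeric(0)), "empty")
})

test_that("bootstrap agrees with exhaustive enumeration at n = 3", {
  v1 <- c(1, 0, 0.5); v2 <- c(0.5, 0.5, 0.5)
  # enumerate all 27 equally likely index triples
  idx <- expand.grid(1:3, 1:3, 1:3)
  h0 <- apply(idx, 1, function(i) {
    mean(v2[as.integer(i)]) >= mean(v1[as.integer(i)])
  })
  exact <- mean(h0)
  B <- 1e4
  bt <- bootstrap_compare(v1, v2, B = B, seed = 4)
  se <- sqrt(exact * (1 - exact) / B)
  expect_lt(abs(bt$p_value - exact), 3 * se)
})

test_that("KL divergence follows the closed form and Gibbs' inequality", {
  # P counts (2,2), Q counts (3,1) over 2 bins of width 10
  P <- c(5, 5, 15, 15); Q <- c(5, 5, 5, 15)
  expect_equal(kl_area_divergence(P, Q, 10),
               0.5 * log(0.5 / 0.75) + 0.5 * log(0.5 / 0.25),
               tolerance = 1e-9) # epsilon smoothing of Q perturbs at ~1e-12
  # identical sequences: zero for every printed bin size
  areas <- c(120, 400, 950, 3000, 7000, 15000)
  for (h in c(50, 100, 200, 500, 1e3, 2e3, 5e3, 1e4, 2e4)) {
    expect_equal(kl_area_divergence(areas, areas, h), 0)
  }
  # nonnegativity on random paired sequences
  set.seed(13)
  for (i in 1:100) {
    a <- runif(30, 0, 2e4); b <- runif(30, 0, 2e4)
    expect_gte(kl_area_divergence(a, b, 1000), 0)
  }
  expect_error(kl_area_divergence(numeric(0), 1:3, 100), "empty")
})

test_that("area density integrates to one and mirrors symmetric input", {
  set.seed(7)
  areas <- c(rnorm(300, 4000, 300), rnorm(300, 12000, 300))
  d <- area_density(areas, bin_size = 800, bandwidth_factor = 0.2)
  integral <- sum(diff(d$area) * (head(d$density, -1) + d$density[-1]) / 2)
  expect_lt(abs(integral - 1), 1e-3)
  # symmetric bimodal histogram -> curve symmetric about the midpoint
  # (spikes in the first and last occupied bin so the curve grid itself is
  # symmetric about their midpoint)
  sym <- c(rep(400, 100), rep(8400, 100))
  ds <- area_density(sym, bin_size = 800, bandwidth_factor = 0.05)
  mid <- 4400 # midpoint of the two occupied bin centres
  left <- ds$density[ds$area < mid]
  right <- rev(ds$density[ds$area > mid])
  k <- min(length(left), length(right))
  expect_lt(max(abs(tail(left, k) - tail(right, k))), 1e-6)
  expect_error(area_density(rep(5, 10)), "degenerate")
})

test_that("group_and_filter drops sparse sizes", {
  mk <- function(n) list(cluster_id = 1L, member_cell_ids = seq_len(n),
                         n = as.integer(n), region = NULL)
  cls <- c(replicate(4, mk(2), simplify = FALSE))
  expect_length(group_and_filter(cls), 0L)
  cls <- c(replicate(5, mk(2), simplify = FALSE),
           replicate(3, mk(3), simplify = FALSE))
  out <- group_and_filter(cls)
  expect_equal(names(out), "2")
  expect_length(out[["2"]], 5L)
  counts <- c(`2` = 150, `3` = 58, `4` = 31, `5` = 8, `6` = 15)
  cls <- unlist(lapply(names(counts), function(nm) {
    replicate(counts[[nm]], mk(as.integer(nm)), simplify = FALSE)
  }), recursive = FALSE)
  expect_equal(names(group_and_filter(cls)), c("2", "3", "4", "5", "6"))
})

test_that("reference clusters reflect injected wall holes", {
  # crisp walls -> no reference cluster survives the n > 1 filter
  clean <- generate_cross_section(synthetic_config(seed = 41))
  pre <- apply_intensity_threshold(clean$image, preprocess_config(30))
  expect_length(reference_clusters(pre, clean$groundtruth), 0L)
  # every wall holed in a small mosaic -> merged clusters appear and every
  # registered hole pair sits in the same reference cluster
  holey <- generate_cross_section(synthetic_config(border_hole_rate = 1,
                                                   n_fibres = 12, seed = 5))
  preh <- apply_intensity_threshold(holey$image, preprocess_config(30))
  rcs <- reference_clusters(preh, holey$groundtruth)
  expect_gte(length(rcs), 1L)
  sizes <- vapply(rcs, `[[`, integer(1), "n")
  expect_true(all(sizes >= 2L))
  members <- lapply(rcs, `[[`, "member_cell_ids")
  reg <- holey$wall_registry[holey$wall_registry$hole_applied, ]
  in_same <- function(a, b) {
    any(vapply(members, function(m) a %in% m && b %in% m, logical(1)))
  }
  ok <- mapply(in_same, reg$cell_id_a, reg$cell_id_b)
  expect_gte(mean(ok), 0.8) # holes drive the merges
})

test_that("evaluating a method against itself gives p = 1 everywhere", {
  sm <- generate_cross_section(synthetic_config(border_hole_rate = 1,
                                                n_fibres = 12, seed = 5))
  pre <- apply_intensity_threshold(sm$image, preprocess_config(30))
  sep <- separate_clusters(sm$wall_mask)
  lab <- sep$final
  rep <- evaluate_pipelines(list(pre), list(sm$groundtruth),
                            list(a = list(lab), b = list(lab)),
                            B = 200, seed = 3, min_samples = 1L)
  expect_true(all(rep$bootstrap$p_value == 1))
  # restriction rule: both methods share the same matched cells, so the
  # DSC table contains each matched cell exactly twice
  expect_equal(sum(rep$dsc$method == "a"), sum(rep$dsc$method == "b"))
})
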