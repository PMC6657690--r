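# Geometric fixtures built in code: discs, rings, dumbbells, drawn grids.

# Filled disc mask.
disc_mask <- function(H, W, cr, cc, r) {
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  (rows - cr)^2 + (cols - cc)^2 <= r^2
}

# One-pixel-thick ring (annulus between radii r and r+1).
ring_mask <- function(H, W, cr, cc, r, thickness = 1) {
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  d2 <- (rows - cr)^2 + (cols - cc)^2
  d2 >= r^2 & d2 < (r + thickness)^2
}

# Two discs of radius r joined by a neck of the given half-width.
dumbbell_mask <- function(H = 60, W = 90, r = 10, neck_halfwidth = 2,
                          c1 = c(30, 25), c2 = c(30, 65)) {
  m <- disc_mask(H, W, c1[1], c1[2], r) | disc_mask(H, W, c2[1], c2[2], r)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  neck <- abs(rows - c1[1]) <= neck_halfwidth &
    cols >= c1[2] & cols <= c2[2]
  m | neck
}

# Border mask enclosing a dumbbell: border = boundary band around the shape.
# Returns list(border, interior).
enclosed_shape <- function(shape) {
  grown <- binary_dilate(shape, se_box(3, 3))
  list(border = grown & !shape, interior = shape)
}

# A drawn k x k grid of square cells: border lines on the grid, outer frame
# closed. Returns the border mask.
grid_border <- function(k = 3, cell = 12, lw = 1) {
  n <- k * cell + (k + 1) * lw
  b <- matrix(FALSE, n, n)
  at <- 1L
  for (i in 0:k) {
    pos <- i * (cell + lw) + seq_len(lw)
    b[pos, ] <- TRUE
    b[, pos] <- TRUE
  }
  b
}

# Tiny two-class training image: bright cross on dark background.
cross_image <- function(n = 16, value = 255) {
  img <- matrix(0, n, n)
  mid <- (n %/% 2)
  img[mid + (0:1), ] <- value
  img[, mid + (0:1)] <- value
  img
}

# Dense brute-force convolution with a sampled 2-D Gaussian kernel and
# reflective boundaries: independent oracle for the separable filter.
brute_gaussian <- function(m, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k1 <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  H <- nrow(m); W <- ncol(m)
  reflect <- function(i, n) {
    i <- ifelse(i < 1L, 1L - i, i)
    i <- ifelse(i > n, 2L * n + 1L - i, i)
    pmin(pmax(i, 1L), n)
  }
  out <- matrix(0, H, W)
  for (a in seq_len(H)) {
    for (b in seq_len(W)) {
      acc <- 0
      for (dr in -r:r) {
        for (dc in -r:r) {
          acc <- acc + k2[dr + r + 1L, dc + r + 1L] *
            m[reflect(a + dr, H), reflect(b + dc, W)]
        }
      }
      out[a, b] <- acc
    }
  }
  out
}

# Brute-force exact Euclidean distance from each TRUE pixel of `from` to the
# nearest TRUE pixel of `to`.
brute_distance <- function(from, to) {
  tpx <- which(to, arr.ind = TRUE)
  out <- matrix(0, nrow(from), ncol(from))
  for (p in which(from)) {
    pr <- (p - 1L) %% nrow(from) + 1L
    pc <- (p - 1L) %/% nrow(from) + 1L
    out[p] <- sqrt(min((tpx[, 1] - pr)^2 + (tpx[, 2] - pc)^2))
  }
  out
}

# Brute-force Otsu cut point: scan all 256 cut values for the maximum
# between-class variance on the rescaled 8-bit histogram; returns the
# integer cut t* (mask = value > t*).
brute_otsu <- function(x) {
  v <- round((x - min(x)) / (max(x) - min(x)) * 255)
  best <- -Inf; best_t <- 0L
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bc <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bc > best) { best <- bc; best_t <- t }
  }
  best_t
}

# Small deterministic random image.
random_image <- function(H, W, seed = 1) {
  set.seed(seed)
  matrix(sample(0:255, H * W, replace = TRUE), H, W)
}
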