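# Internal validation and small numeric helpers.

stop_fs <- function(...) stop(..., call. = FALSE)

assert_image <- function(img, name = "image") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop_fs(name, " must be a numeric matrix")
  }
  if (nrow(img) < 1L || ncol(img) < 1L) {
    stop_fs(name, " must have at least one row and one column")
  }
  if (anyNA(img)) stop_fs(name, " contains NA values")
  if (min(img) < 0 || max(img) > 255) {
    stop_fs(name, " must hold 8-bit intensities in [0, 255]")
  }
  invisible(img)
}

assert_mask <- function(mask, name = "mask") {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop_fs(name, " must be a logical matrix")
  }
  if (anyNA(mask)) stop_fs(name, " contains NA values")
  invisible(mask)
}

assert_labels <- function(lab, name = "labels") {
  if (!is.matrix(lab) || !is.numeric(lab)) {
    stop_fs(name, " must be an integer matrix")
  }
  if (anyNA(lab) || any(lab < 0) || any(lab != round(lab))) {
    stop_fs(name, " must hold nonnegative integer labels")
  }
  invisible(lab)
}

assert_same_dim <- function(a, b, what = "inputs") {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop_fs(what, " must share dimensions (",
            paste(dim(a)[1:2], collapse = "x"), " vs ",
            paste(dim(b)[1:2], collapse = "x"), ")")
  }
  invisible(TRUE)
}

assert_scalar_in <- function(x, lo, hi, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop_fs(name, " must be a single value in [", lo, ", ", hi, "]")
  }
  invisible(x)
}

# Scale 8-bit intensities to [0, 1] for filtering.
normalize01 <- function(img) img / 255

# Reflect-pad a matrix by r pixels on every side (symmetric, edge included).
pad_reflect <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  # symmetric reflection (edge pixel included); clamp when r exceeds the image
  ridx <- pmin(pmax(c(rev(seq_len(r)), seq_len(H), 2L * H + 1L - (H + seq_len(r))), 1L), H)
  cidx <- pmin(pmax(c(rev(seq_len(r)), seq_len(W), 2L * W + 1L - (W + seq_len(r))), 1L), W)
  m[ridx, cidx, drop = FALSE]
}

# Separable convolution with a symmetric 1-D kernel along rows then columns,
# reflective boundary handling. kernel has odd length 2r+1.
conv_sep <- function(m, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(m * kernel)
  H <- nrow(m); W <- ncol(m)
  p <- pad_reflect(m, r)
  # vertical pass
  acc <- matrix(0, H, ncol(p))
  for (k in seq_along(kernel)) {
    acc <- acc + kernel[k] * p[(k - 1L) + seq_len(H), , drop = FALSE]
  }
  # horizontal pass
  out <- matrix(0, H, W)
  for (k in seq_along(kernel)) {
    out <- out + kernel[k] * acc[, (k - 1L) + seq_len(W), drop = FALSE]
  }
  out
}

# Sampled, normalised Gaussian kernel; radius covers 4 sigma.
gaussian_kernel <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0) {
    stop_fs("sigma must be a single positive value")
  }
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_smooth <- function(m, sigma) conv_sep(m, gaussian_kernel(sigma))

# Central-difference first derivatives with reflective boundaries.
# Returns list(dr, dc): derivative along rows (vertical) and columns.
gradient2d <- function(m) {
  p <- pad_reflect(m, 1L)
  H <- nrow(m); W <- ncol(m)
  list(
    dr = (p[3:(H + 2), 2:(W + 1), drop = FALSE] -
            p[1:H, 2:(W + 1), drop = FALSE]) / 2,
    dc = (p[2:(H + 1), 3:(W + 2), drop = FALSE] -
            p[2:(H + 1), 1:W, drop = FALSE]) / 2
  )
}

# Hessian entries by central second differences of a (smoothed) image.
hessian2d <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- pad_reflect(m, 1L)
  ctr <- p[2:(H + 1), 2:(W + 1), drop = FALSE]
  drr <- p[3:(H + 2), 2:(W + 1), drop = FALSE] - 2 * ctr +
    p[1:H, 2:(W + 1), drop = FALSE]
  dcc <- p[2:(H + 1), 3:(W + 2), drop = FALSE] - 2 * ctr +
    p[2:(H + 1), 1:W, drop = FALSE]
  drc <- (p[3:(H + 2), 3:(W + 2), drop = FALSE] -
            p[3:(H + 2), 1:W, drop = FALSE] -
            p[1:H, 3:(W + 2), drop = FALSE] +
            p[1:H, 1:W, drop = FALSE]) / 4
  list(drr = drr, dcc = dcc, drc = drc)
}

# Eigenvalues of the symmetric 2x2 Hessian per pixel.
# Returns list(lmax, lmin) with lmax >= lmin (signed ordering).
hessian_eigen <- function(h) {
  tr <- (h$drr + h$dcc) / 2
  disc <- sqrt(((h$drr - h$dcc) / 2)^2 + h$drc^2)
  list(lmax = tr + disc, lmin = tr - disc)
}

# Run a block of code under a local RNG state so callers' streams are intact.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
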