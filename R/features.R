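# Per-pixel feature stack for the pixel classifier: Gaussian-smoothed
# intensities at several scales plus the eigenvalue pair of the Hessian of
# Gaussian at several texture scales. Intensities are normalised to [0, 1]
# before filtering; boundaries are handled by reflection.

#' Feature configuration
#'
#' The defaults are the scale sets used for fluorescence-stained muscle
#' cross-sections: Gaussian smoothing at sigma = 0.3, 0.7, 1.0, 1.6, 3.5 px
#' and Hessian-of-Gaussian eigenvalues at sigma = 1.6, 3.5, 5.0, 10.0 px,
#' giving 5 + 2*4 = 13 channels.
#'
#' @param sigma_intensity positive smoothing scales (px).
#' @param sigma_texture positive Hessian scales (px).
#' @return a list of class `fs_feature_config`.
#' @export
feature_config <- function(sigma_intensity = c(0.3, 0.7, 1.0, 1.6, 3.5),
                           sigma_texture = c(1.6, 3.5, 5.0, 10.0)) {
  if (any(sigma_intensity <= 0) || any(sigma_texture <= 0)) {
    stop_fs("all feature scales must be > 0")
  }
  structure(list(sigma_intensity = sort(sigma_intensity),
                 sigma_texture = sort(sigma_texture)),
            class = "fs_feature_config")
}

n_feature_channels <- function(cfg) {
  length(cfg$sigma_intensity) + 2L * length(cfg$sigma_texture)
}

#' Compute the per-pixel feature stack
#'
#' Channels are, in order: the smoothed intensity at each
#' `sigma_intensity`, then for each `sigma_texture` the pair
#' (lambda_max, lambda_min) of Hessian-of-Gaussian eigenvalues (signed
#' ordering, lambda_max >= lambda_min). On a constant image all eigenvalue
#' channels are exactly zero.
#'
#' @param img numeric matrix in [0, 255].
#' @param cfg a [feature_config()].
#' @return numeric array H x W x C with named channels.
#' @export
compute_features <- function(img, cfg = feature_config()) {
  assert_image(img)
  stopifnot(inherits(cfg, "fs_feature_config"))
  x <- normalize01(img)
  C <- n_feature_channels(cfg)
  out <- array(0, dim = c(nrow(x), ncol(x), C))
  nm <- character(C)
  i <- 0L
  for (s in cfg$sigma_intensity) {
    i <- i + 1L
    out[, , i] <- gaussian_smooth(x, s)
    nm[i] <- sprintf("gauss_%g", s)
  }
  for (s in cfg$sigma_texture) {
    sm <- gaussian_smooth(x, s)
    ev <- hessian_eigen(hessian2d(sm))
    out[, , i + 1L] <- ev$lmax
    out[, , i + 2L] <- ev$lmin
    nm[i + 1L] <- sprintf("hess_max_%g", s)
    nm[i + 2L] <- sprintf("hess_min_%g", s)
    i <- i + 2L
  }
  dimnames(out) <- list(NULL, NULL, nm)
  out
}

stack_to_frame <- function(stack, pixels = NULL) {
  C <- dim(stack)[3]
  m <- matrix(stack, ncol = C)
  colnames(m) <- dimnames(stack)[[3]]
  if (!is.null(pixels)) m <- m[pixels, , drop = FALSE]
  as.data.frame(m)
}
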