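# Binary morphology on logical matrices with explicit structuring elements.
# Kernels are logical matrices with an anchor (1-based row/col inside the
# kernel); even-sized kernels therefore have a well-defined, documented
# placement. Out-of-image pixels count as background.

#' Structuring elements
#'
#' `se_box()` builds a filled rectangular kernel, `se_ellipse()` a filled
#' ellipse inscribed in the given bounding box (matching the common
#' computer-vision elliptical element). The anchor defaults to
#' `ceiling(size / 2)`, which for the 8x8 ellipse used by the iterative
#' erosion step places it at (4, 4).
#'
#' @param nr,nc kernel height and width in pixels.
#' @param anchor integer vector (row, col) of the anchor, 1-based.
#' @return a logical matrix with an `anchor` attribute.
#' @examples
#' se_box(3, 3)
#' sum(se_ellipse(8, 8))
#' @export
se_box <- function(nr, nc = nr, anchor = ceiling(c(nr, nc) / 2)) {
  k <- matrix(TRUE, nr, nc)
  attr(k, "anchor") <- as.integer(anchor)
  k
}

#' @rdname se_box
#' @export
se_ellipse <- function(nr, nc = nr, anchor = ceiling(c(nr, nc) / 2)) {
  # inscribed ellipse with semi-axes (nr-1)/2, (nc-1)/2 about the box centre
  rc <- (nr - 1) / 2; cc <- (nc - 1) / 2
  r0 <- (nr + 1) / 2; c0 <- (nc + 1) / 2
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  k <- ((rows - r0) / max(rc, 0.5))^2 + ((cols - c0) / max(cc, 0.5))^2 <= 1 + 1e-9
  attr(k, "anchor") <- as.integer(anchor)
  k
}

kernel_offsets <- function(kernel) {
  anchor <- attr(kernel, "anchor")
  if (is.null(anchor)) anchor <- ceiling(dim(kernel) / 2)
  w <- which(kernel, arr.ind = TRUE)
  cbind(w[, 1] - anchor[1], w[, 2] - anchor[2])
}

shift_mask <- function(mask, dr, dc, fill = FALSE) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(fill, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  if (length(rs) < 1 || length(cs) < 1) return(out)
  out[rs, cs] <- mask[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Binary dilation and erosion
#'
#' Plain set-morphology on logical masks. Pixels outside the image are
#' treated as background, so dilation cannot grow in from the outside and
#' erosion removes foreground touching the image edge if the kernel
#' overhangs it.
#'
#' @param mask logical matrix.
#' @param kernel structuring element from [se_box()] or [se_ellipse()].
#' @param iterations number of repeated applications.
#' @return logical matrix of the same size.
#' @export
binary_dilate <- function(mask, kernel = se_box(3, 3), iterations = 1L) {
  assert_mask(mask)
  off <- kernel_offsets(kernel)
  for (i in seq_len(iterations)) {
    out <- matrix(FALSE, nrow(mask), ncol(mask))
    for (j in seq_len(nrow(off))) {
      out <- out | shift_mask(mask, off[j, 1], off[j, 2], fill = FALSE)
    }
    mask <- out
  }
  mask
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(mask, kernel = se_box(3, 3), iterations = 1L) {
  assert_mask(mask)
  off <- kernel_offsets(kernel)
  for (i in seq_len(iterations)) {
    out <- matrix(TRUE, nrow(mask), ncol(mask))
    for (j in seq_len(nrow(off))) {
      # reflected offsets so that erode is the dual of dilate for any anchor
      out <- out & shift_mask(mask, -off[j, 1], -off[j, 2], fill = FALSE)
    }
    mask <- out
  }
  mask
}

#' @rdname binary_dilate
#' @export
binary_close <- function(mask, kernel = se_box(3, 3)) {
  binary_erode(binary_dilate(mask, kernel), kernel)
}

#' Connected-component labelling
#'
#' Labels connected foreground components 1..K in raster-scan order of each
#' component's first pixel (reading the image row by row).
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels; background is 0.
#' @export
label_components <- function(mask, connectivity = 4L) {
  assert_mask(mask)
  if (!connectivity %in% c(4L, 8L)) stop_fs("connectivity must be 4 or 8")
  .cc_label_cpp(mask, as.integer(connectivity))
}

# Set boundary-touching components to 0 and relabel the rest 1..K in
# raster-scan order of first pixel.
drop_boundary_components <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  touching <- unique(c(lab[1, ], lab[H, ], lab[, 1], lab[, W]))
  touching <- touching[touching > 0]
  if (length(touching)) lab[lab %in% touching] <- 0L
  relabel_raster(lab)
}

# Relabel positive labels 1..K by raster order of each label's first pixel.
relabel_raster <- function(lab) {
  if (!any(lab > 0)) return(matrix(0L, nrow(lab), ncol(lab)))
  tl <- t(lab) # row-major traversal
  first <- !duplicated(as.vector(tl)) & as.vector(tl) > 0
  order_ids <- as.vector(tl)[first]
  map <- integer(max(lab))
  map[order_ids] <- seq_along(order_ids)
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  matrix(as.integer(out), nrow(lab), ncol(lab))
}
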