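# Step II: separate initial clusters into single-cell clusters. Small border
# holes are first closed by dilation; the cluster interiors are then
# distance-transformed, thresholded at a fraction tau of the (per-cluster)
# maximum to obtain markers, and flooded by marker-based watershed.

#' Separation configuration
#'
#' `tau` is the relative distance threshold: pixels of the distance map
#' below `tau * max` are removed, and the surviving components seed the
#' watershed. Larger values split clusters more readily. With
#' `threshold_scope = "per_cluster"` (default) the maximum is taken within
#' each initial cluster, so small fibres keep their markers in the presence
#' of large ones; `"global"` applies one image-wide maximum.
#'
#' @param tau relative threshold in [0, 1] (a typical working value is 0.3).
#' @param dilation_iterations border-dilation repetitions for hole filling.
#' @param threshold_scope `"per_cluster"` or `"global"`.
#' @return a list of class `fs_separation_config`.
#' @export
separation_config <- function(tau = 0.3, dilation_iterations = 1L,
                              threshold_scope = c("per_cluster", "global")) {
  assert_scalar_in(tau, 0, 1, "tau")
  threshold_scope <- match.arg(threshold_scope)
  if (dilation_iterations < 0) stop_fs("dilation_iterations must be >= 0")
  structure(list(tau = tau,
                 dilation_iterations = as.integer(dilation_iterations),
                 threshold_scope = threshold_scope),
            class = "fs_separation_config")
}

#' Fill small border holes by dilation
#'
#' @param border logical border mask.
#' @param cfg a [separation_config()]; its `dilation_iterations` 3x3-square
#'   dilations are applied.
#' @return dilated border mask.
#' @export
fill_small_holes <- function(border, cfg = separation_config()) {
  assert_mask(border, "border mask")
  if (cfg$dilation_iterations == 0L) return(border)
  binary_dilate(border, se_box(3, 3), iterations = cfg$dilation_iterations)
}

#' Distance transform of cluster interiors
#'
#' Exact Euclidean distance of every labelled cluster pixel to the nearest
#' border pixel; 0 on border pixels and outside the clusters.
#'
#' @param border logical border mask.
#' @param clusters label matrix from [initial_clusters()] on this border.
#' @return numeric distance matrix.
#' @export
distance_transform <- function(border, clusters) {
  assert_mask(border, "border mask")
  assert_labels(clusters, "clusters")
  assert_same_dim(border, clusters)
  if (!any(border)) return(matrix(0, nrow(border), ncol(border)))
  d <- EBImage::distmap(matrix(as.numeric(!border), nrow(border)), "euclidean")
  d <- matrix(as.numeric(d), nrow(border))
  d[clusters == 0L] <- 0
  d
}

#' Threshold the distance map into markers
#'
#' Keeps distance values `>= tau * max`, where the maximum is per initial
#' cluster (default) or global, and labels the surviving 8-connected
#' components as markers.
#'
#' @param dist distance map from [distance_transform()].
#' @param clusters initial cluster labels.
#' @param cfg a [separation_config()].
#' @return integer marker label matrix.
#' @export
threshold_distance <- function(dist, clusters, cfg = separation_config()) {
  assert_labels(clusters, "clusters")
  assert_same_dim(dist, clusters)
  keep <- matrix(FALSE, nrow(dist), ncol(dist))
  inside <- clusters > 0L
  if (any(inside)) {
    if (cfg$threshold_scope == "global") {
      mx <- max(dist[inside])
      keep <- inside & dist >= cfg$tau * mx
    } else {
      mx_by <- tapply(dist[inside], clusters[inside], max)
      thr <- matrix(0, nrow(dist), ncol(dist))
      thr[inside] <- cfg$tau * mx_by[as.character(clusters[inside])]
      keep <- inside & dist >= thr
    }
  }
  label_components(keep, connectivity = 8L)
}

#' Marker-based watershed separation
#'
#' Floods the negated distance map outward from the markers, restricted to
#' non-border cluster pixels. Flooding stops where a front meets a border
#' pixel or another front; pixels where two basins meet (the watershed
#' ridge) are left at label 0, so final clusters never touch.
#'
#' @param dist distance map.
#' @param markers marker labels from [threshold_distance()].
#' @param border logical border mask.
#' @return integer label matrix of final clusters.
#' @export
watershed_separation <- function(dist, markers, border) {
  assert_labels(markers, "markers")
  assert_mask(border, "border mask")
  assert_same_dim(dist, markers)
  assert_same_dim(dist, border)
  if (!any(markers > 0L)) {
    warning("empty marker image: returning all-zero labels")
    return(matrix(0L, nrow(dist), ncol(dist)))
  }
  allowed <- !border & dist > 0
  .marker_watershed_cpp(dist, matrix(as.integer(markers), nrow(markers)),
                        allowed)
}

#' Run the full separation step
#'
#' Convenience wrapper: hole-filling dilation, initial clusters, distance
#' transform, marker thresholding, watershed.
#'
#' @param border border mask from step I.
#' @param cfg a [separation_config()].
#' @return list with elements `border` (dilated), `initial` (initial
#'   clusters), `dist`, `markers`, `final` (separated cluster labels).
#' @export
separate_clusters <- function(border, cfg = separation_config()) {
  border2 <- fill_small_holes(border, cfg)
  initial <- initial_clusters(border2)
  d <- distance_transform(border2, initial)
  markers <- threshold_distance(d, initial, cfg)
  final <- if (any(markers > 0L)) {
    watershed_separation(d, markers, border2)
  } else {
    matrix(0L, nrow(border2), ncol(border2))
  }
  list(border = border2, initial = initial, dist = d, markers = markers,
       final = final)
}
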