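#' Classify a binary habitat raster into matrix, edge and core
#'
#' Core is habitat eroded `edge_depth_px` times with a 3x3 (8-connected)
#' structuring element, i.e. habitat pixels whose full Chebyshev neighbourhood
#' of radius `edge_depth_px` is habitat; edge is the remaining habitat swath;
#' matrix is non-habitat. With 10 m pixels the default depth of 10 pixels gives
#' the conventional 100 m edge swath. NoData propagates, and unknown
#' (NoData) neighbours never count as habitat, so pixels bordering NoData are
#' classed edge rather than core.
#'
#' @param habitat a [habitat_raster].
#' @param edge_depth_px edge depth in pixels (positive integer, default 10).
#' @return an `fh_raster` of class `mac_map` with integer codes 0 = matrix,
#'   1 = edge, 2 = core (and `NA` NoData).
#' @examples
#' r <- habitat_raster(matrix(1, 5, 5))
#' table(as.matrix(classify_mac(r, edge_depth_px = 1)))
#' @export
classify_mac <- function(habitat, edge_depth_px = 10) {
  if (!inherits(habitat, "habitat_raster")) {
    stop("`habitat` must be a habitat_raster (binary 0/1/NA grid)")
  }
  if (length(edge_depth_px) != 1L || edge_depth_px < 1 ||
      edge_depth_px != round(edge_depth_px)) {
    stop("`edge_depth_px` must be a positive integer")
  }
  g <- habitat$grid
  core <- erode_box(g == 1, as.integer(edge_depth_px))
  out <- matrix(0L, nrow(g), ncol(g))
  out[g == 1] <- 1L
  out[core & g == 1] <- 2L
  out[is.na(g)] <- NA_integer_
  r <- fh_raster(out, res = habitat$res, origin = habitat$origin,
                 crs = habitat$crs, layer = "mac",
                 units = "0=matrix,1=edge,2=core", epoch = habitat$epoch,
                 class = "mac_map")
  attr(r, "edge_depth_px") <- as.integer(edge_depth_px)
  r
}

#' Signed Euclidean distance to the habitat boundary
#'
#' Every pixel gets the Euclidean distance (metres, pixel centre to pixel
#' centre) to the nearest pixel of the opposite class: negative inside habitat
#' (interior distances), positive in the matrix. NoData pixels are excluded
#' from both the source and target sets and stay NoData.
#'
#' @param habitat a [habitat_raster] containing at least one pixel of each
#'   class.
#' @return an `fh_raster` of class `signed_distance_raster` (metres).
#' @examples
#' r <- habitat_raster(rbind(c(0, 1), c(0, 1)))
#' as.matrix(signed_edge_distance(r))
#' @export
signed_edge_distance <- function(habitat) {
  if (!inherits(habitat, "habitat_raster")) {
    stop("`habitat` must be a habitat_raster")
  }
  g <- habitat$grid
  if (!any(g == 1, na.rm = TRUE) || !any(g == 0, na.rm = TRUE)) {
    stop("edge undefined: raster must contain both habitat and matrix pixels")
  }
  d_to_matrix <- dist_to_set_px(g == 0)   # defined on habitat pixels
  d_to_habitat <- dist_to_set_px(g == 1)  # defined on matrix pixels
  d <- ifelse(g == 1, -d_to_matrix, d_to_habitat) * habitat$res
  d[is.na(g)] <- NA_real_
  fh_raster(d, res = habitat$res, origin = habitat$origin, crs = habitat$crs,
            layer = "signed_edge_distance", units = "m", epoch = habitat$epoch,
            class = "signed_distance_raster")
}

#' Extract the extended-forest-edge (EFE) functional habitat band
#'
#' The functional habitat is the band of pixels whose signed edge distance
#' falls in a closed interval around the forest boundary. The default
#' interval, -86 m (interior) to +11 m (exterior), is the interquartile range
#' of the distances from woodland-specialist butterfly occurrence records to
#' the forest edge; see [interquartile_interval()] for recomputing such a band
#' from occurrence data.
#'
#' @param habitat a [habitat_raster].
#' @param interval numeric length-2, `c(d_lo, d_hi)` in metres with
#'   `d_lo <= d_hi`; negative = interior.
#' @param distances optionally a precomputed [signed_edge_distance()] raster
#'   for `habitat` (saves recomputation).
#' @return an `fh_raster` of class `efe_map`: 1 = functional habitat, 0
#'   elsewhere, `NA` NoData; the interval is kept in attribute `"interval"`.
#' @export
extract_efe <- function(habitat, interval = c(-86, 11), distances = NULL) {
  if (length(interval) != 2L || any(!is.finite(interval) & !is.infinite(interval))) {
    stop("`interval` must be two numbers c(d_lo, d_hi)")
  }
  if (interval[1] > interval[2]) stop("inverted interval: d_lo must be <= d_hi")
  if (is.null(distances)) {
    distances <- signed_edge_distance(habitat)
  } else {
    stop_if_misaligned(habitat, distances)
  }
  d <- distances$grid
  m <- ifelse(d >= interval[1] & d <= interval[2], 1L, 0L)
  m[is.na(d)] <- NA_integer_
  r <- fh_raster(m, res = habitat$res, origin = habitat$origin,
                 crs = habitat$crs, layer = "efe", units = "binary",
                 epoch = habitat$epoch, class = "efe_map")
  attr(r, "interval") <- as.numeric(interval)
  r
}
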