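#' Gap-crossing functional-connectivity map
#'
#' Patches (8-connected components) of the functional-habitat band whose
#' mutual Euclidean gap does not exceed the crossing-capability distance are
#' merged into functional clusters, and every functional-habitat pixel is
#' assigned the total functional-habitat area (hectares) of its cluster: the
#' habitat a disperser sitting on that pixel can reach by crossing matrix gaps
#' up to `crossing_dist` metres wide.
#'
#' Gap bridging is realised morphologically: pixels within `crossing_dist / 2`
#' (exact Euclidean distance) of the band are joined to it and 8-connected
#' components of this dilation define the clusters — the standard
#' disc-dilation realisation of "gaps no wider than the threshold are
#' bridged". Near-threshold gaps (within about one pixel diagonal of
#' `crossing_dist`) may fall on either side of the merge, an unavoidable
#' consequence of pixel-centre discretisation.
#'
#' @param efe an `efe_map` from [extract_efe()] (or any binary `fh_raster`).
#' @param crossing_dist maximum matrix gap an individual crosses, metres
#'   (default 500). `0` keeps every patch on its own.
#' @return an `fh_raster` of class `fc_map` (hectares). Attributes
#'   `"patch_labels"` (integer matrix of 8-connected patches) and
#'   `"patch_cluster"` (cluster id per patch) expose the partition.
#' @examples
#' efe <- habitat_raster(matrix(c(1, 1, 0, 0, 0, 0), 1))  # a 2-pixel patch
#' efe$layer <- "efe"
#' as.matrix(functional_connectivity(efe, crossing_dist = 0))
#' @export
functional_connectivity <- function(efe, crossing_dist = 500) {
  if (!inherits(efe, "fh_raster")) stop("`efe` must be an fh_raster")
  if (length(crossing_dist) != 1L || is.na(crossing_dist) || crossing_dist < 0) {
    stop("`crossing_dist` must be a single non-negative number (metres)")
  }
  if (crossing_dist > 0 && (crossing_dist / efe$res) %% 1 != 0) {
    warning("crossing_dist is not a multiple of the resolution; ",
            "gap decisions near the threshold are discretisation-limited")
  }
  g <- efe$grid
  mask <- !is.na(g) & g == 1
  out <- matrix(0, nrow(g), ncol(g))
  out[is.na(g)] <- NA_real_
  mk <- function(values_map) {
    r <- fh_raster(values_map, res = efe$res, origin = efe$origin,
                   crs = efe$crs, layer = "fc", units = "ha",
                   epoch = efe$epoch, class = "fc_map")
    attr(r, "crossing_dist") <- crossing_dist
    r
  }
  if (!any(mask)) {
    warning("empty functional-habitat raster: returning all-zero map")
    r <- mk(out)
    attr(r, "patch_labels") <- matrix(0L, nrow(g), ncol(g))
    attr(r, "patch_cluster") <- integer(0)
    return(r)
  }
  patches <- label_components(mask, connectivity = 8)
  if (crossing_dist == 0) {
    dil_lab <- patches
  } else {
    # exact Euclidean disc dilation of radius crossing_dist/2, as a distance
    # threshold (eps guards grid-exact radii against FP noise)
    d_px <- dist_to_set_px(mask)
    radius_px <- crossing_dist / 2 / efe$res
    dilated <- d_px <= radius_px + 1e-9
    dil_lab <- label_components(dilated, connectivity = 8)
  }
  n_patch <- max(patches, na.rm = TRUE)
  in_patch <- !is.na(patches) & patches > 0
  # cluster of each patch = label of its pixels in the dilation
  patch_cluster <- integer(n_patch)
  patch_cluster[patches[in_patch]] <- dil_lab[in_patch]
  patch_cluster <- match(patch_cluster, sort(unique(patch_cluster)))
  patch_px <- tabulate(patches[in_patch], nbins = n_patch)
  cluster_area <- tapply(patch_px, patch_cluster, sum) * pixel_area_ha(efe)
  out[in_patch] <- as.numeric(cluster_area[as.character(patch_cluster[patches[in_patch]])])
  out[is.na(g)] <- NA_real_
  r <- mk(out)
  attr(r, "patch_labels") <- patches
  attr(r, "patch_cluster") <- patch_cluster
  r
}

#' Temporal mean and coefficient of variation across epochs
#'
#' Per-pixel mean and CV (sample SD with the n-1 denominator, divided by the
#' mean) of two or more aligned connectivity maps. The CV is NoData wherever
#' the mean is zero, and any pixel that is NoData in one epoch is NoData in
#' both summaries.
#'
#' @param stack list of >= 2 aligned `fc_map` rasters (one per epoch).
#' @return list of class `temporal_summary` with `mean` and `cv` rasters and
#'   `n_epochs`.
#' @export
temporal_summary <- function(stack) {
  if (!is.list(stack) || length(stack) < 2L) {
    stop("`stack` must be a list of at least two aligned rasters")
  }
  for (i in seq_along(stack)[-1]) stop_if_misaligned(stack[[1]], stack[[i]])
  arr <- simplify2array(lapply(stack, function(r) r$grid))
  mu <- apply(arr, c(1, 2), mean)          # NA propagates
  sdv <- apply(arr, c(1, 2), stats::sd)
  cv <- sdv / mu
  cv[!is.na(mu) & mu == 0] <- NA_real_
  tmpl <- stack[[1]]
  structure(list(
    mean = fh_raster(mu, res = tmpl$res, origin = tmpl$origin, crs = tmpl$crs,
                     layer = "fc_temporal_mean", units = "ha"),
    cv = fh_raster(cv, res = tmpl$res, origin = tmpl$origin, crs = tmpl$crs,
                   layer = "fc_temporal_cv", units = ""),
    n_epochs = length(stack)
  ), class = "temporal_summary")
}

#' @method print temporal_summary
#' @export
print.temporal_summary <- function(x, ...) {
  cat(sprintf("<temporal_summary> over %d epochs\n", x$n_epochs))
  print(x$mean)
  print(x$cv)
  invisible(x)
}
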