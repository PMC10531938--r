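# Internal raster morphology helpers.
#
# Erosion and the exact Euclidean distance transform are delegated to EBImage
# (centre-to-centre pixel distances). Connected-component labelling is done on
# the pixel-adjacency graph with igraph because 8-connectivity is required and
# labels must be deterministic (components are renumbered in row-major order of
# their first pixel).

# Distance (in pixels) from every pixel to the nearest pixel where target is
# TRUE. NA cells in `target` are never treated as targets.
dist_to_set_px <- function(target) {
  fg <- ifelse(is.na(target) | !target, 1, 0)
  if (all(fg == 1)) stop("distance undefined: target set is empty")
  as.matrix(EBImage::distmap(fg, metric = "euclidean"))
}

# Binary erosion with a (2k+1) x (2k+1) box (= k iterations of 3x3, 8-connected
# structuring element). NA cells count as background, so erosion never claims a
# core pixel whose neighbourhood is unknown; the grid is zero-padded so that
# the outside world counts as background too (EBImage clamps at the border).
erode_box <- function(mask, k) {
  m <- ifelse(is.na(mask) | !mask, 0, 1)
  nr <- nrow(m)
  nc <- ncol(m)
  pad <- matrix(0, nr + 2L * k, nc + 2L * k)
  pad[(k + 1L):(k + nr), (k + 1L):(k + nc)] <- m
  er <- as.matrix(EBImage::erode(pad, EBImage::makeBrush(2L * k + 1L, shape = "box")))
  er[(k + 1L):(k + nr), (k + 1L):(k + nc)] == 1
}

# Label connected components of a logical mask. Returns an integer matrix with
# 0 outside the mask, NA where mask is NA, and labels 1..n inside; labels are
# ordered by the smallest row-major pixel index of each component.
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(mask)
  nc <- ncol(mask)
  m <- !is.na(mask) & mask
  idx <- which(m)                      # column-major pixel indices
  lab <- matrix(0L, nr, nc)
  lab[is.na(mask)] <- NA_integer_
  if (!length(idx)) return(lab)

  # edges to neighbours in 4 of the 8 directions (the other 4 are mirrors)
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  from <- integer(0)
  to <- integer(0)
  for (s in shifts) {
    r2 <- row + s[1]
    c2 <- col + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- m[j]
    from <- c(from, idx[ok][keep])
    to <- c(to, j[keep])
  }
  # vertices = mask pixels, numbered 1..length(idx)
  if (length(from)) {
    vid <- integer(nr * nc)
    vid[idx] <- seq_along(idx)
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    g <- igraph::add_edges(g, rbind(vid[from], vid[to]))
    comp <- igraph::components(g)$membership
  } else {
    comp <- seq_along(idx)
  }
  # renumber deterministically: order components by first (row-major) pixel
  rowmajor <- (row - 1L) * nc + col
  first <- tapply(rowmajor, comp, min)
  renum <- integer(length(first))
  renum[order(first)] <- seq_along(first)
  lab[idx] <- renum[comp]
  lab
}
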