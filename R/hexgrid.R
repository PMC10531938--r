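#' Hexagonal tessellation of a projected plane
#'
#' Flat-top hexagons indexed by axial coordinates `(q, r)`. `spacing` is the
#' distance across flats (= the centre-to-centre distance of neighbouring
#' cells), so a "5 km hexagonal grid" means `spacing = 5000`. Points are
#' assigned to cells by exact axial (cube) rounding, which maps every point to
#' the cell whose centre is nearest; points equidistant from two centres
#' resolve by the rounding of the largest fractional component, a fixed
#' deterministic rule.
#'
#' @param spacing distance across flats in metres (default 5000).
#' @param origin numeric length-2; grid origin (a cell centre sits here).
#' @param crs CRS tag; must match the point sets and rasters the grid is
#'   combined with.
#' @return object of class `hex_grid`.
#' @export
hex_grid <- function(spacing = 5000, origin = c(0, 0), crs = "local-metric") {
  stopifnot(is.numeric(spacing), length(spacing) == 1L, spacing > 0)
  structure(list(spacing = spacing, size = spacing / sqrt(3),
                 origin = as.numeric(origin[1:2]), crs = as.character(crs)),
            class = "hex_grid")
}

#' @method print hex_grid
#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("<hex_grid> flat-top, %g m across flats, origin (%g, %g), crs %s\n",
              x$spacing, x$origin[1], x$origin[2], x$crs))
  invisible(x)
}

# Axial cell index of each point; returns data.frame(q, r, cell).
hex_cell_of <- function(grid, x, y) {
  px <- (x - grid$origin[1]) / grid$size
  py <- (y - grid$origin[2]) / grid$size
  qf <- 2 / 3 * px
  rf <- -1 / 3 * px + sqrt(3) / 3 * py
  # cube rounding
  xf <- qf
  zf <- rf
  yf <- -xf - zf
  rx <- round(xf)
  ry <- round(yf)
  rz <- round(zf)
  dx <- abs(rx - xf)
  dy <- abs(ry - yf)
  dz <- abs(rz - zf)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  data.frame(q = as.integer(rx), r = as.integer(rz),
             cell = sprintf("%d:%d", as.integer(rx), as.integer(rz)))
}

# Centre coordinates of axial cells.
hex_center <- function(grid, q, r) {
  cbind(x = grid$origin[1] + grid$size * 1.5 * q,
        y = grid$origin[2] + grid$size * sqrt(3) * (r + q / 2))
}

#' Aggregate point occurrences on a hexagonal grid
#'
#' Each record is assigned to exactly one cell; per cell the function reports
#' the number of observations, the number of distinct years with at least one
#' observation and the number of distinct calendar decades (1970-1979, ...)
#' with at least one observation. Records whose date cannot be parsed to a
#' year are rejected (their count is reported in attribute `"n_rejected"`).
#'
#' @param occ data.frame with columns `x`, `y` (metres) and `date` (a `Date`,
#'   a "YYYY-..." string, or a numeric year); optional attribute `"crs"`.
#' @param grid a [hex_grid].
#' @return data.frame of class `hex_cell_summary`: one row per occupied cell
#'   with `cell`, `q`, `r`, `center_x`, `center_y`, `n_obs`, `n_years`,
#'   `n_decades`.
#' @export
hex_aggregate_occurrences <- function(occ, grid) {
  stopifnot(inherits(grid, "hex_grid"), all(c("x", "y", "date") %in% names(occ)))
  occ_crs <- attr(occ, "crs")
  if (!is.null(occ_crs) && !identical(occ_crs, grid$crs)) {
    stop("CRS mismatch between occurrences (", occ_crs, ") and grid (",
         grid$crs, ")")
  }
  if (!all(is.finite(occ$x)) || !all(is.finite(occ$y))) {
    stop("occurrence coordinates must be finite")
  }
  year <- parse_year(occ$date)
  keep <- !is.na(year)
  n_rejected <- sum(!keep)
  if (n_rejected > 0) {
    message(n_rejected, " record(s) with unparseable dates rejected")
  }
  occ <- occ[keep, , drop = FALSE]
  year <- year[keep]
  cells <- hex_cell_of(grid, occ$x, occ$y)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(occ)), cells$cell), function(i) {
    data.frame(cell = cells$cell[i[1]], q = cells$q[i[1]], r = cells$r[i[1]],
               n_obs = length(i),
               n_years = length(unique(year[i])),
               n_decades = length(unique(year[i] %/% 10L)))
  }))
  rownames(agg) <- NULL
  ctr <- hex_center(grid, agg$q, agg$r)
  agg$center_x <- ctr[, "x"]
  agg$center_y <- ctr[, "y"]
  agg <- agg[order(agg$q, agg$r), c("cell", "q", "r", "center_x", "center_y",
                                    "n_obs", "n_years", "n_decades")]
  rownames(agg) <- NULL
  attr(agg, "n_rejected") <- n_rejected
  attr(agg, "spacing") <- grid$spacing
  class(agg) <- c("hex_cell_summary", "data.frame")
  agg
}

parse_year <- function(date) {
  if (inherits(date, "Date")) {
    return(as.integer(format(date, "%Y")))
  }
  if (is.numeric(date)) {
    y <- as.integer(date)
    y[y < 1 | y > 9999] <- NA_integer_
    return(y)
  }
  y <- suppressWarnings(as.integer(sub("^\\s*(\\d{4}).*$", "\\1",
                                       as.character(date))))
  y
}

#' Per-cell mean of a raster on a hexagonal grid
#'
#' Assigns every non-NoData pixel centre to its hexagonal cell and averages
#' the pixel values, e.g. to summarise a functional-connectivity map over the
#' cells used for occurrence aggregation and site selection.
#'
#' @param x an `fh_raster`.
#' @param grid a [hex_grid] with the same CRS tag.
#' @param fun summary function (default `mean`).
#' @return data.frame with `cell`, `q`, `r` and `value`.
#' @export
hex_aggregate_raster <- function(x, grid, fun = mean) {
  stopifnot(inherits(x, "fh_raster"), inherits(grid, "hex_grid"))
  if (!identical(x$crs, grid$crs)) stop("CRS mismatch between raster and grid")
  idx <- which(!is.na(x$grid))
  row <- ((idx - 1L) %% nrow(x$grid)) + 1L
  col <- ((idx - 1L) %/% nrow(x$grid)) + 1L
  xy <- raster_xy(x, row, col)
  cells <- hex_cell_of(grid, xy[, "x"], xy[, "y"])
  v <- tapply(x$grid[idx], cells$cell, fun)
  qr <- do.call(rbind, strsplit(names(v), ":"))
  out <- data.frame(cell = names(v), q = as.integer(qr[, 1]),
                    r = as.integer(qr[, 2]), value = as.numeric(v))
  out <- out[order(out$q, out$r), ]
  rownames(out) <- NULL
  out
}

#' Rank candidate sampling cells and pick connectivity extremes
#'
#' Cells are sorted lexicographically by occurrence abundance, then number of
#' decades, then number of years with observations (all descending, ties by
#' cell id); among the `top_k` best-ranked cells the cells with the lowest and
#' highest mean functional connectivity are returned as the fragmented-
#' and homogeneous-woodland sampling candidates.
#'
#' @param cells a data.frame with `cell`, `n_obs`, `n_years`, `n_decades` and
#'   `fc_mean` columns (e.g. a [hex_aggregate_occurrences()] result merged
#'   with [hex_aggregate_raster()]).
#' @param top_k how many top-ranked cells to screen (default 5).
#' @return list of class `cell_ranking`: `lowest` and `highest` (single-row
#'   data.frames) and `top` (the screened cells in rank order).
#' @export
rank_sampling_cells <- function(cells, top_k = 5) {
  need <- c("cell", "n_obs", "n_years", "n_decades", "fc_mean")
  if (!all(need %in% names(cells))) {
    stop("`cells` must have columns: ", paste(need, collapse = ", "))
  }
  if (top_k < 2) stop("`top_k` must be at least 2")
  ord <- order(-cells$n_obs, -cells$n_decades, -cells$n_years, cells$cell)
  top <- cells[ord[seq_len(min(top_k, nrow(cells)))], , drop = FALSE]
  rownames(top) <- NULL
  # ties on fc_mean resolve to the smallest cell id
  by_fc <- top[order(top$fc_mean, top$cell), , drop = FALSE]
  lowest <- by_fc[1, , drop = FALSE]
  highest <- by_fc[nrow(by_fc), , drop = FALSE]
  if (isTRUE(all.equal(lowest$fc_mean, highest$fc_mean))) {
    warning("all screened cells have equal mean connectivity; ",
            "lowest and highest coincide")
  }
  structure(list(lowest = lowest, highest = highest, top = top),
            class = "cell_ranking")
}

#' @method print cell_ranking
#' @export
print.cell_ranking <- function(x, ...) {
  cat("<cell_ranking>\n lowest-FC cell: ", x$lowest$cell,
      sprintf(" (fc_mean = %g)\n", x$lowest$fc_mean))
  cat(" highest-FC cell:", x$highest$cell,
      sprintf(" (fc_mean = %g)\n", x$highest$fc_mean))
  cat(" screened", nrow(x$top), "cells\n")
  invisible(x)
}

#' Random survey points inside functional habitat with a minimum spacing
#'
#' Draws `n` points uniformly over the functional-habitat pixels of `region`
#' (uniform position within a uniformly chosen habitat pixel) by rejection
#' sampling, enforcing a minimum pairwise distance to avoid spatial
#' pseudo-replication. Reproducible for a fixed `seed`.
#'
#' @param region a binary `fh_raster` (e.g. an `efe_map`, possibly masked to
#'   one sampling cell).
#' @param n number of points (default 10).
#' @param min_dist minimum pairwise distance in metres (default 200).
#' @param seed optional integer seed.
#' @param max_iter rejection attempts before giving up (default `1000 * n`).
#' @return data.frame with `x`, `y`; attribute `"crs"` carries the region CRS.
#' @export
random_survey_points <- function(region, n = 10, min_dist = 200, seed = NULL,
                                 max_iter = 1000 * n) {
  stopifnot(inherits(region, "fh_raster"), n >= 1)
  cand <- which(!is.na(region$grid) & region$grid == 1)
  if (!length(cand)) stop("`region` contains no habitat pixels")
  if (!is.null(seed)) set.seed(seed)
  nr <- nrow(region$grid)
  pts <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(pts) < n && tries < max_iter) {
    tries <- tries + 1L
    i <- cand[sample.int(length(cand), 1L)]
    row <- ((i - 1L) %% nr) + 1L
    col <- ((i - 1L) %/% nr) + 1L
    ctr <- raster_xy(region, row, col)
    p <- ctr[1, ] + stats::runif(2, -0.5, 0.5) * region$res
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= min_dist) {
      pts <- rbind(pts, p)
    }
  }
  if (nrow(pts) < n) {
    stop("could not place ", n, " points at min_dist = ", min_dist,
         " m; achieved ", nrow(pts), " after ", max_iter, " attempts")
  }
  out <- data.frame(x = pts[, 1], y = pts[, 2])
  attr(out, "crs") <- region$crs
  out
}
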