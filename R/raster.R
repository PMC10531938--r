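#' Raster containers for habitat and connectivity analysis
#'
#' `funhab` rasters are light S3 wrappers around a numeric or integer matrix
#' plus the georeferencing needed for metric analysis: pixel size in metres,
#' the coordinate of the lower-left corner, and a free-text CRS tag. Row 1 of
#' the matrix is the northernmost row (image convention); pixel centres are at
#' `x = xll + (col - 0.5) * res`, `y = yll + (nrow - row + 0.5) * res`.
#' `NA` encodes NoData and propagates through every operation.
#'
#' @param grid matrix; for `habitat_raster()` values must be 0 (matrix),
#'   1 (habitat) or `NA` (NoData).
#' @param res pixel side length in metres (default 10).
#' @param origin numeric length-2, x/y of the lower-left corner in metres.
#' @param crs free-text tag for the projected CRS; rasters and point sets are
#'   only combined when their tags match.
#' @param epoch free-text epoch label (e.g. "1775", "2018").
#' @return an object of class `c("habitat_raster", "fh_raster")`.
#' @examples
#' r <- habitat_raster(matrix(c(0, 1, 1, 1), 2, 2))
#' r
#' @export
habitat_raster <- function(grid, res = 10, origin = c(0, 0), crs = "local-metric",
                           epoch = "") {
  grid <- as.matrix(grid)
  bad <- !(grid %in% c(0, 1)) & !is.na(grid)
  if (any(bad)) {
    stop("habitat raster values must be 0, 1 or NA; found: ",
         paste(utils::head(unique(grid[bad]), 5), collapse = ", "))
  }
  storage.mode(grid) <- "integer"
  fh_raster(grid, res = res, origin = origin, crs = crs,
            layer = "habitat", units = "binary", epoch = epoch,
            class = "habitat_raster")
}

# Internal generic constructor shared by all raster layers.
fh_raster <- function(grid, res, origin = c(0, 0), crs = "local-metric",
                      layer = "values", units = "", epoch = "", class = NULL) {
  if (!is.matrix(grid)) stop("`grid` must be a matrix")
  if (!is.numeric(res) || length(res) != 1L || res <= 0) {
    stop("`res` must be a single positive number (metres)")
  }
  structure(
    list(grid = grid, res = res, origin = as.numeric(origin[1:2]),
         crs = as.character(crs), layer = layer, units = units,
         epoch = as.character(epoch)),
    class = c(class, "fh_raster")
  )
}

#' @method print fh_raster
#' @export
print.fh_raster <- function(x, ...) {
  cat(sprintf("<%s> %d x %d pixels, %g m resolution [%s]\n",
              paste(class(x)[1], collapse = ""), nrow(x$grid), ncol(x$grid),
              x$res, x$layer))
  cat(sprintf("  origin: (%g, %g)  crs: %s%s\n", x$origin[1], x$origin[2],
              x$crs, if (nzchar(x$epoch)) paste0("  epoch: ", x$epoch) else ""))
  v <- x$grid[!is.na(x$grid)]
  if (length(v)) {
    cat(sprintf("  values: min %g, max %g, NoData pixels: %d\n",
                min(v), max(v), sum(is.na(x$grid))))
  } else {
    cat("  values: all NoData\n")
  }
  invisible(x)
}

#' @export
plot.fh_raster <- function(x, main = x$layer, ...) {
  nr <- nrow(x$grid)
  nc <- ncol(x$grid)
  xs <- x$origin[1] + (seq_len(nc) - 0.5) * x$res
  ys <- x$origin[2] + (seq_len(nr) - 0.5) * x$res
  # image() wants x ascending and z[i, j] at (x[i], y[j]): transpose + flip rows
  z <- t(x$grid[nr:1, , drop = FALSE])
  graphics::image(xs, ys, z, asp = 1, xlab = "x (m)", ylab = "y (m)",
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}

#' @method as.matrix fh_raster
#' @export
as.matrix.fh_raster <- function(x, ...) x$grid

#' @export
dim.fh_raster <- function(x) dim(x$grid)

# Pixel area in hectares.
pixel_area_ha <- function(x) x$res^2 / 1e4

# TRUE when two rasters can be combined pixelwise.
rasters_aligned <- function(a, b) {
  identical(dim(a$grid), dim(b$grid)) &&
    isTRUE(all.equal(a$res, b$res)) &&
    isTRUE(all.equal(a$origin, b$origin)) &&
    identical(a$crs, b$crs)
}

stop_if_misaligned <- function(a, b) {
  if (!rasters_aligned(a, b)) {
    stop("rasters are not aligned (shape, resolution, origin and CRS must match)")
  }
  invisible(TRUE)
}

# Map point coordinates to (row, col); points outside the extent get NA.
raster_rowcol <- function(x, px, py) {
  col <- floor((px - x$origin[1]) / x$res) + 1L
  nr <- nrow(x$grid)
  row <- nr - floor((py - x$origin[2]) / x$res)
  out <- col < 1L | col > ncol(x$grid) | row < 1L | row > nr
  row[out] <- NA_integer_
  col[out] <- NA_integer_
  cbind(row = row, col = col)
}

# Centre coordinates of a (row, col) pixel.
raster_xy <- function(x, row, col) {
  cbind(x = x$origin[1] + (col - 0.5) * x$res,
        y = x$origin[2] + (nrow(x$grid) - row + 0.5) * x$res)
}

#' Read and write rasters as Esri ASCII grids
#'
#' Plain-text single-band raster exchange. The `.asc` header records shape,
#' lower-left corner and cell size; layer/units/CRS/epoch metadata travel in
#' `#`-prefixed comment lines appended after the data block (ignored by other
#' readers).
#'
#' @param x an `fh_raster`.
#' @param path file path.
#' @param nodata value used on disk for `NA` pixels (default -9999).
#' @return `write_ascii_grid()` returns `path` invisibly; `read_ascii_grid()`
#'   returns an `fh_raster` (a `habitat_raster` when the stored layer tag is
#'   "habitat").
#' @export
write_ascii_grid <- function(x, path, nodata = -9999) {
  stopifnot(inherits(x, "fh_raster"))
  g <- x$grid
  g[is.na(g)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(g)),
    sprintf("nrows %d", nrow(g)),
    sprintf("xllcorner %.10g", x$origin[1]),
    sprintf("yllcorner %.10g", x$origin[2]),
    sprintf("cellsize %.10g", x$res),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  utils::write.table(g, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("# layer=%s units=%s crs=%s epoch=%s",
                     x$layer, x$units, x$crs, x$epoch), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, " "), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  ncols <- as.integer(val("ncols"))
  nrows <- as.integer(val("nrows"))
  nodata <- val("NODATA_value")
  body <- lines[-(1:6)]
  meta_ln <- body[startsWith(body, "#")]
  body <- body[!startsWith(body, "#") & nzchar(trimws(body))]
  g <- matrix(scan(text = body, quiet = TRUE), nrow = nrows, ncol = ncols,
              byrow = TRUE)
  g[g == nodata] <- NA
  meta <- c(layer = "values", units = "", crs = "local-metric", epoch = "")
  if (length(meta_ln)) {
    kv <- regmatches(meta_ln[1], gregexpr("[a-z]+=[^ ]*", meta_ln[1]))[[1]]
    for (p in kv) {
      k <- sub("=.*", "", p)
      meta[k] <- sub("^[a-z]+=", "", p)
    }
  }
  if (identical(unname(meta["layer"]), "habitat")) {
    habitat_raster(g, res = val("cellsize"),
                   origin = c(val("xllcorner"), val("yllcorner")),
                   crs = meta[["crs"]], epoch = meta[["epoch"]])
  } else {
    fh_raster(g, res = val("cellsize"),
              origin = c(val("xllcorner"), val("yllcorner")),
              crs = meta[["crs"]], layer = meta[["layer"]],
              units = meta[["units"]], epoch = meta[["epoch"]])
  }
}
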