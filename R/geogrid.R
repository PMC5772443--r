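#' Define a regular analysis grid
#'
#' The analysis lattice is a regular grid of square cells in WGS84 decimal
#' degrees with a lower-left (south-west) origin. Rows count northward,
#' columns eastward; cells are half-open intervals
#' `[west, west + cell_size) x [south, south + cell_size)`, so every
#' in-bounds point belongs to exactly one cell and a point on a shared edge
#' belongs to the cell whose lower edge it sits on. All distances used
#' downstream are Euclidean in degree space; no great-circle correction is
#' applied.
#'
#' @param west,south Coordinates of the grid origin (lower-left corner),
#'   decimal degrees.
#' @param cell_size Cell edge length in decimal degrees (default 0.5).
#' @param n_cols,n_rows Grid dimensions (positive integers).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(-80, -20, 0.5, 60, 60)
#' point_to_cell(-79.9, -19.9, g)
#' @export
grid_spec <- function(west, south, cell_size = 0.5, n_cols, n_rows) {
  stopifnot(is.finite(west), is.finite(south),
            is.finite(cell_size), cell_size > 0,
            n_cols >= 1, n_rows >= 1)
  structure(list(west = west, south = south, cell_size = cell_size,
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d cols x %d rows, %.4g deg cells, origin (%g, %g)\n",
              x$n_cols, x$n_rows, x$cell_size, x$west, x$south))
  invisible(x)
}

#' Number of cells in a grid
#' @param grid A `grid_spec`.
#' @return Integer cell count.
#' @export
n_cells <- function(grid) grid$n_cols * grid$n_rows

#' Map points to grid cells
#'
#' Cell ids are 1-based, row-major from the south-west corner:
#' `id = (row - 1) * n_cols + col`. Points outside the grid rectangle map
#' to `NA`. Edges are half-open: a point exactly on the boundary between
#' two cells belongs to the cell whose lower (west/south) edge it lies on,
#' and the east/north outer edges are out of bounds.
#'
#' @param lon,lat Numeric vectors of coordinates, decimal degrees. Must be
#'   finite; records with missing coordinates should be filtered before
#'   gridding (see [validate_records()]).
#' @param grid A `grid_spec`.
#' @return Integer vector of cell ids (`NA` = out of bounds).
#' @export
point_to_cell <- function(lon, lat, grid) {
  if (length(lon) != length(lat)) stop("lon and lat lengths differ")
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("non-finite coordinates; filter missing coordinates first")
  col <- floor((lon - grid$west) / grid$cell_size) + 1
  row <- floor((lat - grid$south) / grid$cell_size) + 1
  ok <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  id <- ifelse(ok, (row - 1) * grid$n_cols + col, NA_integer_)
  as.integer(id)
}

#' Row/column index of cells
#' @param cell Integer vector of cell ids.
#' @param grid A `grid_spec`.
#' @return A data.frame with columns `row`, `col` (1-based).
#' @export
cell_rowcol <- function(cell, grid) {
  bad <- !is.na(cell) & (cell < 1 | cell > n_cells(grid))
  if (any(bad)) stop("cell id out of range")
  row <- (cell - 1L) %/% grid$n_cols + 1L
  col <- (cell - 1L) %% grid$n_cols + 1L
  data.frame(row = row, col = col)
}

#' Cell-center coordinates
#'
#' Midpoint of each cell; the inverse of [point_to_cell()] in the sense
#' that `point_to_cell(cell_center(c)) == c` for every in-bounds cell.
#'
#' @inheritParams cell_rowcol
#' @return A data.frame with columns `lon`, `lat`.
#' @export
cell_center <- function(cell, grid) {
  rc <- cell_rowcol(cell, grid)
  data.frame(lon = grid$west + (rc$col - 0.5) * grid$cell_size,
             lat = grid$south + (rc$row - 0.5) * grid$cell_size)
}

#' Construct a raster layer on a grid
#'
#' A raster layer stores one value per cell in cell-id order (row-major
#' from the south-west corner) plus a validity mask. Invalid cells (outside
#' the study region, or nodata in a file) carry `NA` values and are
#' excluded from all downstream statistics.
#'
#' @param grid A `grid_spec`.
#' @param values Numeric vector of length `n_cells(grid)` (recycled if
#'   scalar).
#' @param mask Logical vector of the same length; `FALSE` marks invalid
#'   cells. Defaults to all valid.
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(grid, values = NA_real_, mask = TRUE) {
  nc <- n_cells(grid)
  values <- rep_len(as.numeric(values), nc)
  mask <- rep_len(as.logical(mask), nc)
  values[!mask] <- NA_real_
  structure(list(grid = grid, values = values, mask = mask),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<raster_layer> %d x %d, %d valid cells, range [%g, %g]\n",
              x$grid$n_cols, x$grid$n_rows, sum(x$mask),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' Values of a raster layer as a matrix
#'
#' @param layer A `raster_layer`.
#' @return Matrix with `n_rows` rows and `n_cols` columns; row 1 is the
#'   southernmost row.
#' @export
raster_matrix <- function(layer) {
  matrix(layer$values, nrow = layer$grid$n_rows,
         ncol = layer$grid$n_cols, byrow = TRUE)
}

stopifnot_same_grid <- function(a, b) {
  ga <- a$grid; gb <- b$grid
  same <- isTRUE(all.equal(unclass(ga), unclass(gb), tolerance = 1e-9))
  if (!same) stop("raster layers are on different grids")
  invisible(TRUE)
}

#' Write a raster layer as an ESRI ASCII grid
#'
#' Plain-text single-band raster with the standard six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`); invalid cells are written as the nodata value (-9999).
#' Rows are written north to south per the format.
#'
#' @param layer A `raster_layer`.
#' @param path Output file path.
#' @param nodata Nodata sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path, nodata = -9999) {
  g <- layer$grid
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.10g", g$west),
           sprintf("yllcorner %.10g", g$south),
           sprintf("cellsize %.10g", g$cell_size),
           sprintf("NODATA_value %.10g", nodata))
  m <- raster_matrix(layer)
  m[is.na(m)] <- nodata
  rows <- apply(m[g$n_rows:1, , drop = FALSE], 1L, function(r)
    paste(formatC(r, format = "g", digits = 15), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path Path to an ESRI ASCII grid file.
#' @param grid Optional `grid_spec` the file must match; origin, cell size
#'   and dimensions are checked and a mismatch is an error naming the
#'   offending field.
#' @return A `raster_layer`; nodata cells become invalid in the mask.
#' @export
read_raster <- function(path, grid = NULL) {
  lines <- readLines(path)
  if (length(lines) < 7) stop("malformed raster: too few lines")
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed raster header at line ", i)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("malformed raster header: missing ", miss[1])
  g <- grid_spec(hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                 hdr$ncols, hdr$nrows)
  if (!is.null(grid)) {
    for (f in c("west", "south", "cell_size", "n_cols", "n_rows")) {
      if (!isTRUE(all.equal(g[[f]], grid[[f]], tolerance = 1e-9)))
        stop("raster does not match configured grid: field ", f)
    }
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  if (length(vals) != n_cells(g))
    stop("malformed raster: expected ", n_cells(g), " values, got ",
         length(vals))
  m <- matrix(vals, nrow = g$n_rows, ncol = g$n_cols, byrow = TRUE)
  m <- m[g$n_rows:1, , drop = FALSE]  # file is north-first; store south-first
  v <- as.numeric(t(m))
  is_nodata <- v == hdr$nodata_value
  raster_layer(g, ifelse(is_nodata, NA_real_, v), !is_nodata)
}

#' Region partition of a grid
#'
#' Wraps an integer-valued raster assigning every valid cell to one of a
#' small number of contiguous regions (six for the Amazonia-like study
#' system). Used by the outlier filter to decide whether a species is
#' narrowly or widely distributed.
#'
#' @param layer A `raster_layer` whose valid values are integer region
#'   labels starting at 1.
#' @return The layer, classed as `region_partition`.
#' @export
region_partition <- function(layer) {
  v <- layer$values[layer$mask]
  if (any(v != round(v)) || any(v < 1))
    stop("region labels must be positive integers")
  class(layer) <- c("region_partition", class(layer))
  layer
}

#' Region label of points
#' @param lon,lat Coordinates.
#' @param regions A `region_partition`.
#' @return Integer region labels (`NA` for out-of-grid or invalid cells).
#' @export
region_of <- function(lon, lat, regions) {
  cell <- point_to_cell(lon, lat, regions$grid)
  out <- rep(NA_integer_, length(cell))
  ok <- !is.na(cell)
  out[ok] <- as.integer(regions$values[cell[ok]])
  out
}
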