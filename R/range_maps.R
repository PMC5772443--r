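#' Convex hull with a dispersal buffer
#'
#' Estimates a species' extent of occurrence as the convex hull of its
#' cleaned occurrence points, expanded by a buffer (default 3 degrees,
#' the ~300 km dispersal limit also used by the abundance interpolation,
#' with degrees and km equated at the study latitude). Degenerate inputs
#' (one point, two points, collinear points) are handled: the buffered
#' region is then a disk or a capsule. The buffered outline returned for
#' plotting/serialisation is the Minkowski sum of the hull with a regular
#' 72-gon approximation of the disk; membership tests use exact distances
#' to the hull, not the approximation.
#'
#' @param lon,lat Occurrence coordinates (>= 1 point).
#' @param buffer_deg Buffer distance in degrees (default 3.0).
#' @return List of class `hull_buffer`: `points`, `hull` (matrix of hull
#'   vertices, in order), `buffer_deg`, `polygon` (approximate buffered
#'   outline).
#' @export
hull_buffer <- function(lon, lat, buffer_deg = 3.0) {
  stopifnot(length(lon) >= 1, length(lon) == length(lat), buffer_deg >= 0)
  pts <- cbind(lon = lon, lat = lat)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[h, , drop = FALSE]
  theta <- seq(0, 2 * pi, length.out = 73)[-73]
  disk <- cbind(buffer_deg * cos(theta), buffer_deg * sin(theta))
  mink <- do.call(rbind, lapply(seq_len(nrow(hull)), function(i)
    cbind(hull[i, 1] + disk[, 1], hull[i, 2] + disk[, 2])))
  hb <- grDevices::chull(mink[, 1], mink[, 2])
  poly <- mink[c(hb, hb[1]), , drop = FALSE]
  colnames(poly) <- c("lon", "lat")
  structure(list(points = pts, hull = hull, buffer_deg = buffer_deg,
                 polygon = poly), class = "hull_buffer")
}

# minimum distance from (lon, lat) points to the hull boundary/vertices;
# 0 for points inside the hull
dist_to_hull <- function(lon, lat, hb) {
  hull <- hb$hull
  n <- nrow(hull)
  if (n == 1) {
    return(sqrt((lon - hull[1, 1])^2 + (lat - hull[1, 2])^2))
  }
  d <- rep(Inf, length(lon))
  idx <- c(seq_len(n), 1L)
  for (i in seq_len(n)) {
    ax <- hull[idx[i], 1]; ay <- hull[idx[i], 2]
    bx <- hull[idx[i + 1], 1]; by <- hull[idx[i + 1], 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) rep(0, length(lon)) else
      pmin(1, pmax(0, ((lon - ax) * vx + (lat - ay) * vy) / L2))
    d <- pmin(d, sqrt((lon - (ax + t * vx))^2 + (lat - (ay + t * vy))^2))
  }
  if (n >= 3) {
    inside <- vapply(seq_along(lon), function(i)
      point_in_polygon(lon[i], lat[i], hull), logical(1))
    d[inside] <- 0
  }
  d
}

#' Test points against a buffered hull
#'
#' @param lon,lat Coordinates to test.
#' @param hb A `hull_buffer`.
#' @return Logical vector: inside the hull or within the buffer distance
#'   of it.
#' @export
in_hull_buffer <- function(lon, lat, hb) {
  dist_to_hull(lon, lat, hb) <= hb$buffer_deg + 1e-12
}

#' Clip a map to a buffered-hull range
#'
#' Cells whose centers fall outside the buffered polygon are set to 0.
#' Clipping is idempotent and can only shrink the presence area, which is
#' what makes the hull-clipped suitability map a conservative area-of-
#' occupancy estimate.
#'
#' @param layer A `raster_layer` (suitability or binary).
#' @param hb A `hull_buffer`.
#' @return The clipped `raster_layer`.
#' @export
clip_to_range <- function(layer, hb) {
  ctr <- cell_center(seq_len(n_cells(layer$grid)), layer$grid)
  outside <- !in_hull_buffer(ctr$lon, ctr$lat, hb)
  layer$values[outside & layer$mask] <- 0
  layer
}

#' Area of occupancy of a binary map
#'
#' @param bmap A binary `raster_layer`.
#' @return Count of 1-cells.
#' @export
area_of_occupancy <- function(bmap) {
  sum(bmap$values == 1, na.rm = TRUE)
}

#' Sensitivity (true positive rate) of a binary map
#'
#' Fraction of grid cells containing at least one reference point where
#' the map predicts presence. Cell-level: multiple points in one cell
#' count once; points outside the grid are ignored. Used both ways in the
#' model contrast: the interpolated-abundance map scored against
#' collection localities, and the suitability-derived map scored against
#' plot-presence localities.
#'
#' @param bmap A binary `raster_layer`.
#' @param lon,lat Reference presence coordinates.
#' @return Proportion in `[0, 1]`, or `NA` if no reference point maps to
#'   a grid cell.
#' @export
sensitivity <- function(bmap, lon, lat) {
  cell <- point_to_cell(lon, lat, bmap$grid)
  cells <- unique(cell[!is.na(cell)])
  if (length(cells) == 0) return(NA_real_)
  mean(bmap$values[cells] == 1, na.rm = TRUE)
}

#' Serialise a buffered hull as GeoJSON
#'
#' @param hb A `hull_buffer`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hull_geojson <- function(hb, path) {
  coords <- lapply(seq_len(nrow(hb$polygon)), function(i)
    c(hb$polygon[i, 1], hb$polygon[i, 2]))
  gj <- list(type = "Feature",
             properties = list(buffer_deg = hb$buffer_deg),
             geometry = list(type = "Polygon", coordinates = list(coords)))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
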