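#' Inverse-distance-weighting configuration
#'
#' Relative-abundance surfaces are interpolated from the nearest `k_max`
#' plots within `d_max` degrees of each cell center, with weights
#' `w_k = d_k^(-power)`. The defaults mirror the plot-interpolation
#' convention for Amazonian tree inventories: 150 neighbours, a 3-degree
#' (~300 km) dispersal limit, and square-root inverse-distance weights
#' (`power = 0.5`), read as inverse weighting since up-weighting distant
#' plots would contradict the interpolation's purpose. Distances are
#' Euclidean in degree space.
#'
#' @param k_max Maximum number of neighbour plots (default 150).
#' @param d_max Neighbourhood radius in degrees (default 3.0).
#' @param power Inverse-distance exponent p in `w = d^(-p)`
#'   (default 0.5).
#' @param eps Coincidence radius in degrees: plots closer than this to
#'   the query point short-circuit to their mean relative abundance
#'   (default 1e-9).
#' @return List of class `idw_config`.
#' @export
idw_config <- function(k_max = 150, d_max = 3.0, power = 0.5, eps = 1e-9) {
  stopifnot(k_max >= 1, d_max > 0, power > 0, eps >= 0)
  structure(list(k_max = as.integer(k_max), d_max = d_max, power = power,
                 eps = eps), class = "idw_config")
}

#' Relative abundance of a species in a plot
#'
#' `RA = n_i / N`: stems of the focal species over all stems in the plot.
#'
#' @param n_i Stem count of the focal species (0 <= n_i <= N).
#' @param N Total stems in the plot (>= 1).
#' @return Relative abundance in `[0, 1]`.
#' @export
plot_relative_abundance <- function(n_i, N) {
  if (any(N < 1)) stop("N must be >= 1")
  if (any(n_i < 0) || any(n_i > N)) stop("n_i must be in [0, N]")
  n_i / N
}

#' Interpolate relative abundance at one query point
#'
#' Neighbours are the plots within `d_max` degrees of the query point,
#' truncated to the `k_max` nearest; the estimate is the weighted mean
#' `sum(w_k RA_k) / sum(w_k)` with `w_k = d_k^(-power)`. No neighbour
#' within `d_max` predicts absence (0). Plots coincident with the query
#' point (distance < `eps`) short-circuit to their mean relative
#' abundance, making the interpolation exact at plot locations.
#'
#' @param lon,lat Query coordinates (degrees).
#' @param plot_lon,plot_lat,plot_ra Plot coordinates and relative
#'   abundances.
#' @param config An `idw_config`.
#' @return Scalar relative-abundance estimate.
#' @export
idw_predict_cell <- function(lon, lat, plot_lon, plot_lat, plot_ra,
                             config = idw_config()) {
  d <- sqrt((plot_lon - lon)^2 + (plot_lat - lat)^2)
  co <- d < config$eps
  if (any(co)) return(mean(plot_ra[co]))
  keep <- which(d <= config$d_max)
  if (length(keep) == 0) return(0)
  if (length(keep) > config$k_max)
    keep <- keep[order(d[keep])][seq_len(config$k_max)]
  w <- d[keep]^(-config$power)
  sum(w * plot_ra[keep]) / sum(w)
}

#' Interpolated relative-abundance surface
#'
#' Applies [idw_predict_cell()] from every valid forested cell center to
#' the plot table. Cells outside the forest mask (or outside the layer
#' mask) carry no value. An empty plot table yields an all-zero surface
#' with a warning.
#'
#' @param plots data.frame with `lon`, `lat` and either `ra` or the pair
#'   `n_i`/`N_total` columns for the focal species.
#' @param grid A `grid_spec`.
#' @param config An `idw_config`.
#' @param forest Optional binary forest `raster_layer`; non-forest cells
#'   are masked out.
#' @return List of class `abundance_surface`: `ra` (a `raster_layer`),
#'   `config`, `n_plots`.
#' @export
idw_surface <- function(plots, grid, config = idw_config(), forest = NULL) {
  if (is.null(plots$ra))
    plots$ra <- plot_relative_abundance(plots$n_i, plots$N_total)
  mask <- rep(TRUE, n_cells(grid))
  if (!is.null(forest)) mask <- forest$values == 1 & forest$mask
  vals <- rep(NA_real_, n_cells(grid))
  idx <- which(mask)
  if (nrow(plots) == 0) {
    warning("empty plot table: all-zero abundance surface")
    vals[idx] <- 0
  } else {
    ctr <- cell_center(idx, grid)
    for (i in seq_along(idx))
      vals[idx[i]] <- idw_predict_cell(ctr$lon[i], ctr$lat[i], plots$lon,
                                       plots$lat, plots$ra, config)
  }
  structure(list(ra = raster_layer(grid, vals, mask), config = config,
                 n_plots = nrow(plots)),
            class = "abundance_surface")
}

#' Binary range map from an abundance surface
#'
#' A cell is predicted present (1) iff its interpolated relative
#' abundance is strictly greater than 0 and the cell is forested;
#' naturally non-forested cells are excluded.
#'
#' @param surface An `abundance_surface`.
#' @param forest Optional binary forest `raster_layer`.
#' @return A binary `raster_layer` in `{0, 1}`.
#' @export
idw_binary_map <- function(surface, forest = NULL) {
  ra <- surface$ra
  v <- as.numeric(!is.na(ra$values) & ra$values > 0)
  if (!is.null(forest)) v[forest$values != 1] <- 0
  raster_layer(ra$grid, v, ra$mask | TRUE)
}
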