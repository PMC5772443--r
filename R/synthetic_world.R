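#' Configuration for the synthetic study system
#'
#' The generator emulates the moving parts of a large tropical-forest
#' study system at desk scale: smooth gridded environmental fields, tree
#' species with niche-plus-dispersal abundance surfaces, one-hectare plot
#' censuses drawn from the local relative abundances, and herbarium-style
#' collection records carrying spatial and collector bias plus injected
#' georeferencing errors. Every output is a deterministic function of
#' `seed`, and every corrupted record carries a ground-truth label, so each
#' pipeline stage has a known acceptance surface.
#'
#' @param seed Integer seed; fully determines all outputs.
#' @param grid A `grid_spec` (default 60 x 60 cells of 0.5 degrees).
#' @param n_env Number of environmental layers (default 6).
#' @param n_species Number of focal species (default 15).
#' @param n_plots Number of inventory plots (default 400).
#' @param stems_per_plot_mean Mean stems per plot (default 550, the
#'   average census size of a 1-ha Amazonian plot).
#' @param collections_per_species Target collection records per species
#'   before error injection (capped at the number of occupied cells).
#' @param collector_bias_exponent Exponent gamma in `(0, 1]` applied to
#'   relative abundance when sampling collections; gamma < 1
#'   over-represents low-abundance areas, mimicking collectors' bias
#'   (default 0.5).
#' @param ra_max Cell-maximum true relative abundance per species
#'   (default 0.05).
#' @param error_rates Named proportions (each < 0.5) of records receiving
#'   each injected error: `missing_coord`, `zero_coord`, `lat_eq_lon`,
#'   `capital_assign`, `centroid_assign`, `duplicate`, `misidentification`.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         grid = grid_spec(-80, -20, 0.5, 60, 60),
                         n_env = 6,
                         n_species = 15,
                         n_plots = 400,
                         stems_per_plot_mean = 550,
                         collections_per_species = 700,
                         collector_bias_exponent = 0.5,
                         ra_max = 0.05,
                         error_rates = c(missing_coord = 0.05,
                                         zero_coord = 0.02,
                                         lat_eq_lon = 0.02,
                                         capital_assign = 0.03,
                                         centroid_assign = 0.03,
                                         duplicate = 0.10,
                                         misidentification = 0.03)) {
  need <- c("missing_coord", "zero_coord", "lat_eq_lon", "capital_assign",
            "centroid_assign", "duplicate", "misidentification")
  stopifnot(all(need %in% names(error_rates)),
            all(error_rates >= 0), all(error_rates < 0.5),
            sum(error_rates) < 1,
            collector_bias_exponent > 0, collector_bias_exponent <= 1,
            ra_max > 0, ra_max <= 1)
  structure(list(seed = as.integer(seed), grid = grid, n_env = n_env,
                 n_species = n_species, n_plots = n_plots,
                 stems_per_plot_mean = stems_per_plot_mean,
                 collections_per_species = collections_per_species,
                 collector_bias_exponent = collector_bias_exponent,
                 ra_max = ra_max, error_rates = error_rates[need]),
            class = "synth_config")
}

scale01 <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (r[2] == r[1]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

# separable Gaussian smoothing with replicate padding
smooth_matrix <- function(m, sigma) {
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  conv_cols <- function(mm) {
    pad_top <- mm[rep(1L, half), , drop = FALSE]
    pad_bot <- mm[rep(nrow(mm), half), , drop = FALSE]
    mp <- rbind(pad_top, mm, pad_bot)
    out <- apply(mp, 2L, function(col) stats::filter(col, k, sides = 2))
    out[(half + 1):(half + nrow(mm)), , drop = FALSE]
  }
  t(conv_cols(t(conv_cols(m))))
}

#' Fixed six-region partition of a synthetic grid
#'
#' Splits the grid rectangle into a 3 (west-east) by 2 (south-north) block
#' layout, mirroring the six biogeographic regions of the real study area.
#'
#' @param grid A `grid_spec`.
#' @return A `region_partition` raster.
#' @export
synth_regions <- function(grid) {
  rc <- cell_rowcol(seq_len(n_cells(grid)), grid)
  block_col <- pmin(2L, (rc$col - 1L) %/% ceiling(grid$n_cols / 3)) # 0..2
  block_row <- pmin(1L, (rc$row - 1L) %/% ceiling(grid$n_rows / 2)) # 0..1
  region_partition(raster_layer(grid, block_row * 3L + block_col + 1L))
}

#' Fixed forest mask of a synthetic grid
#'
#' All cells are forested except two naturally non-forested (savanna-like)
#' rectangles, one on the northern and one on the southern margin.
#'
#' @param grid A `grid_spec`.
#' @return A binary `raster_layer` (1 = forest, 0 = non-forest).
#' @export
synth_forest <- function(grid) {
  rc <- cell_rowcol(seq_len(n_cells(grid)), grid)
  north <- rc$row > grid$n_rows - 4 & rc$col >= 5 &
    rc$col <= ceiling(grid$n_cols / 4)
  south <- rc$row <= 3 & rc$col >= ceiling(grid$n_cols * 0.6) &
    rc$col <= ceiling(grid$n_cols * 0.9)
  raster_layer(grid, as.numeric(!(north | south)))
}

#' Synthetic countries and gazetteer
#'
#' Divides the grid rectangle into four rectangular "countries" (codes
#' C1-C4), each with a capital city and two province centroids. Used to
#' exercise the capital/centroid snap and country-mismatch checks.
#'
#' @param grid A `grid_spec`.
#' @return List with `countries` (data.frame of code + bounding box),
#'   `polygons` (named list of closed polygon matrices) and `gazetteer`
#'   (data.frame name, lon, lat, type).
#' @export
synth_countries <- function(grid) {
  e <- grid$west + grid$n_cols * grid$cell_size
  n <- grid$south + grid$n_rows * grid$cell_size
  mx <- (grid$west + e) / 2
  my <- (grid$south + n) / 2
  boxes <- data.frame(
    code = c("C1", "C2", "C3", "C4"),
    xmin = c(grid$west, mx, grid$west, mx),
    xmax = c(mx, e, mx, e),
    ymin = c(my, my, grid$south, grid$south),
    ymax = c(n, n, my, my))
  polys <- lapply(seq_len(4), function(i) {
    b <- boxes[i, ]
    cbind(lon = c(b$xmin, b$xmax, b$xmax, b$xmin, b$xmin),
          lat = c(b$ymin, b$ymin, b$ymax, b$ymax, b$ymin))
  })
  names(polys) <- boxes$code
  gaz <- do.call(rbind, lapply(seq_len(4), function(i) {
    b <- boxes[i, ]
    w <- b$xmax - b$xmin
    h <- b$ymax - b$ymin
    data.frame(
      name = paste0(b$code, c("_capital", "_prov1", "_prov2")),
      lon = c(b$xmin + 0.37 * w, b$xmin + 0.21 * w, b$xmin + 0.71 * w),
      lat = c(b$ymin + 0.43 * h, b$ymin + 0.67 * h, b$ymin + 0.29 * h),
      type = c("capital", "centroid", "centroid"))
  }))
  list(countries = boxes, polygons = polys, gazetteer = gaz)
}

country_code_of <- function(lon, lat, countries) {
  out <- rep(NA_character_, length(lon))
  for (i in seq_len(nrow(countries))) {
    b <- countries[i, ]
    hit <- !is.na(lon) & lon >= b$xmin & lon < b$xmax &
      lat >= b$ymin & lat < b$ymax
    out[hit] <- b$code
  }
  out
}

#' Generate the synthetic environmental stack
#'
#' Each layer is a low-order spatial trend blended with a smoothed noise
#' field and rescaled to `[0, 1]`. Two layer pairs are constructed to be
#' strongly rank-correlated (|rho| > 0.7) so the collinearity screen has
#' something to find. Layer names reuse familiar bioclimatic variable
#' names for readability; the values are synthetic.
#'
#' @param config A `synth_config`.
#' @return A named list of `raster_layer`s of class `env_stack`.
#' @export
gen_env_stack <- function(config) {
  g <- config$grid
  set.seed(config$seed + 101L)
  rc <- cell_rowcol(seq_len(n_cells(g)), g)
  X <- (rc$col - 0.5) / g$n_cols
  Y <- (rc$row - 0.5) / g$n_rows
  base_names <- c("isothermality", "temp_seasonality", "max_temp_warmest",
                  "annual_precip", "precip_wettest", "precip_driest")
  nm <- if (config$n_env <= 6) base_names[seq_len(config$n_env)] else
    c(base_names, paste0("env_", seq_len(config$n_env - 6)))
  layers <- vector("list", config$n_env)
  for (k in seq_len(config$n_env)) {
    a <- stats::runif(5, -1, 1)
    trend <- a[1] * X + a[2] * Y + a[3] * X * Y +
      a[4] * (X - 0.5)^2 + a[5] * (Y - 0.5)^2
    noise <- smooth_matrix(matrix(stats::rnorm(n_cells(g)), g$n_rows,
                                  g$n_cols), sigma = 3)
    noise_v <- as.numeric(t(noise))  # row-major flatten matches cell ids
    layers[[k]] <- 0.55 * scale01(trend) + 0.45 * scale01(noise_v)
  }
  # build two strongly correlated pairs: (1,2) and (4,5)
  if (config$n_env >= 2)
    layers[[2]] <- 0.85 * layers[[1]] + 0.15 * layers[[2]]
  if (config$n_env >= 5)
    layers[[5]] <- 0.85 * layers[[4]] + 0.15 * layers[[5]]
  out <- lapply(layers, function(v) raster_layer(g, scale01(v)))
  names(out) <- nm
  structure(out, class = "env_stack")
}

#' Generate one species' ground truth
#'
#' Suitability is a product of Gaussian responses on one or two
#' environmental layers; true relative abundance is suitability times a
#' dispersal kernel (a sum of isotropic Gaussian kernels around the
#' species' population centers), zeroed outside the dispersal envelope
#' (3 kernel radii) and outside forest, then normalised so the cell
#' maximum equals `ra_max`. Odd-indexed species are narrow (confined to
#' at most three regions); even-indexed species are wide.
#'
#' @param env An `env_stack`.
#' @param config A `synth_config`.
#' @param species_index Integer in `1..n_species`.
#' @param regions A `region_partition`.
#' @param forest Forest mask `raster_layer`.
#' @return List of class `species_truth` with elements `species`,
#'   `suitability` and `ra` (both `raster_layer`s), `niche`, `centers`,
#'   `tau`, `narrow`.
#' @export
gen_species_truth <- function(env, config, species_index, regions, forest) {
  g <- config$grid
  set.seed(config$seed + 1000L + species_index)
  narrow <- species_index %% 2L == 1L
  v1 <- (species_index - 1L) %% config$n_env + 1L
  use_two <- species_index %% 3L == 0L
  v2 <- species_index %% config$n_env + 1L
  mu1 <- stats::runif(1, 0.25, 0.75); s1 <- stats::runif(1, 0.12, 0.25)
  suit <- exp(-0.5 * ((env[[v1]]$values - mu1) / s1)^2)
  niche <- data.frame(variable = names(env)[v1], center = mu1, width = s1)
  if (use_two) {
    mu2 <- stats::runif(1, 0.25, 0.75); s2 <- stats::runif(1, 0.15, 0.3)
    suit <- suit * exp(-0.5 * ((env[[v2]]$values - mu2) / s2)^2)
    niche <- rbind(niche, data.frame(variable = names(env)[v2],
                                     center = mu2, width = s2))
  }
  suit <- suit / max(suit)
  forested <- forest$values == 1
  ctr <- cell_center(seq_len(n_cells(g)), g)
  if (narrow) {
    home <- ((species_index - 1L) %/% 2L) %% 6L + 1L
    cand <- which(regions$values == home & forested &
                    suit >= stats::quantile(suit[regions$values == home &
                                                   forested], 0.75))
    centers <- sample(cand, 1L, prob = suit[cand])
    tau <- 1.5
  } else {
    cand <- which(forested & suit >= stats::quantile(suit[forested], 0.75))
    ncent <- 2L + species_index %% 3L
    centers <- sample(cand, min(ncent, length(cand)), prob = suit[cand])
    tau <- 3.5
  }
  d2 <- sapply(centers, function(cc)
    (ctr$lon - ctr$lon[cc])^2 + (ctr$lat - ctr$lat[cc])^2)
  d2 <- matrix(d2, nrow = n_cells(g))
  kern <- pmin(1, rowSums(exp(-d2 / (2 * tau^2))))
  mind <- sqrt(apply(d2, 1L, min))
  ra <- suit * kern
  ra[mind > 3 * tau] <- 0
  ra[!forested] <- 0
  if (narrow) {
    # keep only the three regions holding the most abundance mass
    mass <- tapply(ra, regions$values, sum)
    keep <- as.integer(names(sort(mass, decreasing = TRUE)))[1:3]
    ra[!(regions$values %in% keep)] <- 0
  }
  ra <- ra * config$ra_max / max(ra)
  structure(list(species = sprintf("species_%02d", species_index),
                 suitability = raster_layer(g, suit),
                 ra = raster_layer(g, ra),
                 niche = niche,
                 centers = centers, tau = tau, narrow = narrow),
            class = "species_truth")
}

gen_all_truths <- function(env, config, regions, forest) {
  truths <- lapply(seq_len(config$n_species), function(j)
    gen_species_truth(env, config, j, regions, forest))
  names(truths) <- vapply(truths, `[[`, "", "species")
  total <- Reduce(`+`, lapply(truths, function(t) t$ra$values))
  if (max(total) > 0.95) {
    f <- 0.95 / max(total)
    for (j in seq_along(truths))
      truths[[j]]$ra$values <- truths[[j]]$ra$values * f
  }
  truths
}

#' Generate plot censuses from species truths
#'
#' Plot locations are sampled uniformly over forested cells and jittered
#' within the cell; each plot's census size is Poisson around
#' `stems_per_plot_mean`, and per-species stem counts are multinomial with
#' probabilities equal to the true relative abundances at the plot's cell
#' (residual mass goes to an unmodelled "other species" pool, so the
#' counts of the focal species remain jointly valid).
#'
#' @param truths List of `species_truth` (all species).
#' @param config A `synth_config`.
#' @param forest Forest mask `raster_layer`.
#' @return data.frame: `plot_id`, `lon`, `lat`, `N_total`, one stem-count
#'   column per species.
#' @export
gen_plots <- function(truths, config, forest) {
  g <- config$grid
  set.seed(config$seed + 201L)
  ra_mat <- vapply(truths, function(t) t$ra$values, numeric(n_cells(g)))
  cells_f <- which(forest$values == 1)
  cell <- sample(cells_f, config$n_plots, replace = TRUE)
  ctr <- cell_center(cell, g)
  half <- g$cell_size / 2
  lon <- ctr$lon + stats::runif(config$n_plots, -half * 0.98, half * 0.98)
  lat <- ctr$lat + stats::runif(config$n_plots, -half * 0.98, half * 0.98)
  N <- pmax(1L, stats::rpois(config$n_plots, config$stems_per_plot_mean))
  cnt <- vapply(seq_len(config$n_plots), function(i) {
    p <- ra_mat[cell[i], ]
    other <- max(0, 1 - sum(p))
    if (sum(p) + other <= 0) return(rep(0L, ncol(ra_mat)))
    draw <- stats::rmultinom(1L, N[i], c(p, other))
    as.integer(draw[seq_len(ncol(ra_mat)), 1L])
  }, integer(length(truths)))
  counts <- t(matrix(cnt, nrow = length(truths)))
  colnames(counts) <- names(truths)
  cbind(data.frame(plot_id = sprintf("plot_%04d", seq_len(config$n_plots)),
                   lon = lon, lat = lat, N_total = N),
        as.data.frame(counts))
}

#' Accessibility field for collection bias
#'
#' A distance-decay field around a few random polylines (synthetic rivers
#' or roads), emulating the spatial concentration of herbarium collecting
#' effort along access routes.
#'
#' @param config A `synth_config`.
#' @return A `raster_layer` of positive sampling weights.
#' @export
gen_accessibility <- function(config) {
  g <- config$grid
  set.seed(config$seed + 301L)
  e <- g$west + g$n_cols * g$cell_size
  n <- g$south + g$n_rows * g$cell_size
  pts <- list()
  for (r in 1:3) {
    lon0 <- stats::runif(1, g$west, e)
    lat0 <- stats::runif(1, g$south, n)
    theta <- stats::runif(1, 0, 2 * pi) +
      cumsum(stats::rnorm(50, 0, 0.25))
    lon <- lon0 + cumsum(0.8 * cos(theta))
    lat <- lat0 + cumsum(0.8 * sin(theta))
    pts[[r]] <- cbind(lon, lat)
  }
  pts <- do.call(rbind, pts)
  ctr <- cell_center(seq_len(n_cells(g)), g)
  dmin <- rep(Inf, n_cells(g))
  for (i in seq_len(nrow(pts)))
    dmin <- pmin(dmin, sqrt((ctr$lon - pts[i, 1])^2 +
                              (ctr$lat - pts[i, 2])^2))
  raster_layer(g, exp(-dmin / 1.5) + 0.05)
}

#' Per-cell collection sampling intensity
#'
#' Intensity is accessibility times `true_RA^gamma` on cells where the
#' species occurs (`RA > 0`), zero elsewhere. With `gamma = 1` and
#' uniform accessibility the intensity is exactly proportional to
#' relative abundance; `gamma < 1` flattens the abundance gradient,
#' over-representing low-abundance areas the way collectors do.
#'
#' @param ra Per-cell true relative abundance vector.
#' @param access Per-cell accessibility weights (same length).
#' @param gamma Collector-bias exponent in `(0, 1]`.
#' @return Per-cell non-negative sampling weights.
#' @export
collection_intensity <- function(ra, access, gamma) {
  stopifnot(length(ra) == length(access), gamma > 0, gamma <= 1)
  ifelse(ra > 0, access * ra^gamma, 0)
}

#' Generate biased, corrupted collection records
#'
#' Sampling intensity per cell is accessibility times `true_RA^gamma`
#' with gamma < 1, over-representing low-abundance areas (collectors'
#' bias). Collection cells are sampled without replacement per species, so
#' cell-level duplicates arise only by injection. Errors are then injected
#' at the configured rates, each record receiving at most one error type,
#' recorded in the `error` column ("clean" for uncorrupted records):
#' \describe{
#'   \item{missing_coord}{longitude, latitude and/or locality blanked}
#'   \item{zero_coord}{both coordinates set to exactly 0}
#'   \item{lat_eq_lon}{latitude overwritten with the longitude value}
#'   \item{capital_assign / centroid_assign}{coordinates snapped near a
#'     gazetteer capital or province centroid}
#'   \item{duplicate}{coordinates copied from an earlier clean record of
#'     the same species (same grid cell)}
#'   \item{misidentification}{record relabelled to a species whose range
#'     lies far (> 2.5 degrees) from the record's location}
#' }
#'
#' @param truths List of `species_truth`.
#' @param config A `synth_config`.
#' @param access Accessibility `raster_layer` (from [gen_accessibility()]).
#' @param world_countries Output of [synth_countries()].
#' @return data.frame: `record_id`, `species`, `lon`, `lat`, `locality`,
#'   `country`, `error`.
#' @export
gen_collections <- function(truths, config, access, world_countries) {
  g <- config$grid
  gaz <- world_countries$gazetteer
  set.seed(config$seed + 401L)
  gamma <- config$collector_bias_exponent
  half <- g$cell_size / 2
  recs <- list()
  for (j in seq_along(truths)) {
    ra <- truths[[j]]$ra$values
    intensity <- collection_intensity(ra, access$values, gamma)
    idx <- which(intensity > 0)
    w <- intensity[idx]
    n_rec <- min(config$collections_per_species, length(idx))
    cells <- sample(idx, n_rec, replace = FALSE, prob = w)
    ctr <- cell_center(cells, g)
    lon <- ctr$lon + stats::runif(n_rec, -half * 0.98, half * 0.98)
    lat <- ctr$lat + stats::runif(n_rec, -half * 0.98, half * 0.98)
    # keep genuine points clear of gazetteer snap radii
    for (tries in 1:30) {
      dmin <- rep(Inf, n_rec)
      for (i in seq_len(nrow(gaz)))
        dmin <- pmin(dmin, pmax(abs(lon - gaz$lon[i]), abs(lat - gaz$lat[i])))
      bad <- dmin <= 0.08
      if (!any(bad)) break
      lon[bad] <- ctr$lon[bad] + stats::runif(sum(bad), -half * 0.98,
                                              half * 0.98)
      lat[bad] <- ctr$lat[bad] + stats::runif(sum(bad), -half * 0.98,
                                              half * 0.98)
    }
    recs[[j]] <- data.frame(
      species = truths[[j]]$species, lon = lon, lat = lat,
      locality = sprintf("loc_%s_%d", truths[[j]]$species, cells),
      stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, recs)
  recs$country <- country_code_of(recs$lon, recs$lat,
                                  world_countries$countries)
  n <- nrow(recs)
  recs$record_id <- seq_len(n)
  # single multinomial assignment of error labels
  set.seed(config$seed + 501L)
  rates <- config$error_rates
  u <- stats::runif(n)
  br <- cumsum(c(0, rates))
  lab <- rep("clean", n)
  for (k in seq_along(rates))
    lab[u >= br[k] & u < br[k + 1]] <- names(rates)[k]
  # precompute occupied-cell centers per species for misidentification
  occ_xy <- lapply(truths, function(t)
    cell_center(which(t$ra$values > 0), g))
  sp_names <- names(truths)
  for (i in which(lab != "clean")) {
    type <- lab[i]
    if (type == "missing_coord") {
      field <- sample(c("lon", "lat", "both", "locality"), 1L)
      if (field %in% c("lon", "both")) recs$lon[i] <- NA_real_
      if (field %in% c("lat", "both")) recs$lat[i] <- NA_real_
      if (field == "locality") recs$locality[i] <- NA_character_
    } else if (type == "zero_coord") {
      recs$lon[i] <- 0; recs$lat[i] <- 0
    } else if (type == "lat_eq_lon") {
      recs$lat[i] <- recs$lon[i]
    } else if (type %in% c("capital_assign", "centroid_assign")) {
      pool <- gaz[gaz$type == (if (type == "capital_assign") "capital"
                               else "centroid"), ]
      k <- sample(nrow(pool), 1L)
      recs$lon[i] <- pool$lon[k] + stats::runif(1, -0.03, 0.03)
      recs$lat[i] <- pool$lat[k] + stats::runif(1, -0.03, 0.03)
    } else if (type == "duplicate") {
      prev <- which(recs$species == recs$species[i] & lab == "clean" &
                      recs$record_id < recs$record_id[i])
      if (length(prev) == 0) { lab[i] <- "clean"; next }
      p <- prev[length(prev)]
      recs$lon[i] <- recs$lon[p]; recs$lat[i] <- recs$lat[p]
      recs$locality[i] <- recs$locality[p]
    } else if (type == "misidentification") {
      dists <- vapply(seq_along(truths), function(s) {
        if (sp_names[s] == recs$species[i]) return(0)
        xy <- occ_xy[[s]]
        min(sqrt((xy$lon - recs$lon[i])^2 + (xy$lat - recs$lat[i])^2))
      }, numeric(1))
      if (max(dists) <= 2.5) { lab[i] <- "clean"; next }
      recs$species[i] <- sp_names[which.max(dists)]
    }
  }
  recs$error <- lab
  recs[, c("record_id", "species", "lon", "lat", "locality", "country",
           "error")]
}

#' Generate a complete synthetic world
#'
#' Runs every generator under the config's seed and bundles environments,
#' region partition, forest mask, gazetteer/countries, species truths,
#' plot censuses and corrupted collection records.
#'
#' @param config A `synth_config`.
#' @return A list of class `synth_world`.
#' @export
gen_world <- function(config = synth_config()) {
  regions <- synth_regions(config$grid)
  forest <- synth_forest(config$grid)
  cn <- synth_countries(config$grid)
  env <- gen_env_stack(config)
  truths <- gen_all_truths(env, config, regions, forest)
  plots <- gen_plots(truths, config, forest)
  access <- gen_accessibility(config)
  records <- gen_collections(truths, config, access, cn)
  structure(list(config = config, grid = config$grid, env = env,
                 regions = regions, forest = forest,
                 countries = cn$countries, country_polygons = cn$polygons,
                 gazetteer = cn$gazetteer, truths = truths, plots = plots,
                 access = access, records = records),
            class = "synth_world")
}

#' @export
print.synth_world <- function(x, ...) {
  cat(sprintf(paste0("<synth_world> seed %d: %d x %d grid, %d env layers, ",
                     "%d species, %d plots, %d records\n"),
              x$config$seed, x$grid$n_cols, x$grid$n_rows,
              length(x$env), length(x$truths), nrow(x$plots),
              nrow(x$records)))
  invisible(x)
}

#' Write a synthetic world to disk
#'
#' Emits the occurrence CSV (Darwin-Core-like column names), plot CSV,
#' environmental / region / forest / truth rasters (ESRI ASCII), the
#' gazetteer CSV and a JSON manifest of all generation parameters.
#'
#' @param world A `synth_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_occurrences(world$records, file.path(dir, "occurrences.csv"))
  utils::write.csv(world$plots, file.path(dir, "plots.csv"),
                   row.names = FALSE)
  utils::write.csv(world$gazetteer, file.path(dir, "gazetteer.csv"),
                   row.names = FALSE)
  for (nm in names(world$env))
    write_raster(world$env[[nm]], file.path(dir, paste0("env_", nm, ".asc")))
  write_raster(world$regions, file.path(dir, "regions.asc"))
  write_raster(world$forest, file.path(dir, "forest.asc"))
  for (nm in names(world$truths)) {
    write_raster(world$truths[[nm]]$ra,
                 file.path(dir, paste0("true_ra_", nm, ".asc")))
    write_raster(world$truths[[nm]]$suitability,
                 file.path(dir, paste0("true_suit_", nm, ".asc")))
  }
  cfg <- world$config
  manifest <- list(seed = cfg$seed,
                   grid = unclass(cfg$grid),
                   n_env = cfg$n_env, n_species = cfg$n_species,
                   n_plots = cfg$n_plots,
                   stems_per_plot_mean = cfg$stems_per_plot_mean,
                   collections_per_species = cfg$collections_per_species,
                   collector_bias_exponent = cfg$collector_bias_exponent,
                   ra_max = cfg$ra_max,
                   error_rates = as.list(cfg$error_rates))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read/write occurrence CSVs
#'
#' Occurrence files use a Darwin-Core-like layout with columns
#' `record_id`, `species`, `decimalLongitude`, `decimalLatitude`,
#' `locality`, `countryCode` (extra columns pass through).
#'
#' @param records Internal occurrence data.frame (`lon`/`lat` columns).
#' @param path File path.
#' @return `read_occurrences` returns the internal data.frame layout.
#' @export
write_occurrences <- function(records, path) {
  out <- records
  names(out)[names(out) == "lon"] <- "decimalLongitude"
  names(out)[names(out) == "lat"] <- "decimalLatitude"
  names(out)[names(out) == "country"] <- "countryCode"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(x)[names(x) == "decimalLongitude"] <- "lon"
  names(x)[names(x) == "decimalLatitude"] <- "lat"
  names(x)[names(x) == "countryCode"] <- "country"
  x
}
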