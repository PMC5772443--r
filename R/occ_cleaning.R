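#' Kernel-density outlier filter configuration
#'
#' The spatial-outlier stage ranks each record by a fixed-bandwidth
#' Gaussian kernel-density estimate of the point pattern and removes
#' records below an empirical quantile of those densities. The quantile is
#' larger for narrowly distributed species (records in 1-3 regions) than
#' for widely distributed ones (more than 3 regions), so that wide species
#' do not lose whole occurrence clusters.
#'
#' @param bandwidth Kernel bandwidth in degrees (default 1.0, about two
#'   grid cells; not dictated by the method, so kept configurable).
#' @param quantile_narrow Density quantile for narrow species
#'   (default 0.05).
#' @param quantile_wide Density quantile for wide species (default 0.01).
#' @return List of class `kde_config`.
#' @export
kde_config <- function(bandwidth = 1.0, quantile_narrow = 0.05,
                       quantile_wide = 0.01) {
  stopifnot(bandwidth > 0,
            quantile_narrow > 0, quantile_narrow < 0.5,
            quantile_wide > 0, quantile_wide < 0.5,
            quantile_narrow >= quantile_wide)
  structure(list(bandwidth = bandwidth, quantile_narrow = quantile_narrow,
                 quantile_wide = quantile_wide), class = "kde_config")
}

REASON_CODES <- c("MISSING_GEO", "LAT_EQ_LON", "ZERO_COORD", "CAPITAL",
                  "PROVINCE_CENTROID", "COUNTRY_MISMATCH", "DUPLICATE_CELL",
                  "KDE_OUTLIER")

new_report <- function(records) {
  data.frame(record_id = records$record_id,
             disposition = rep("kept", nrow(records)),
             reason = rep(NA_character_, nrow(records)),
             stringsAsFactors = FALSE)
}

#' Deterministic geo-validation of occurrence records
#'
#' Flags records in a fixed precedence order, so each removed record has
#' exactly one (first-triggering) reason code:
#' `MISSING_GEO` (longitude, latitude or locality absent) >
#' `LAT_EQ_LON` (latitude exactly equal to longitude, nonzero) >
#' `ZERO_COORD` (both coordinates exactly 0) >
#' `CAPITAL` / `PROVINCE_CENTROID` (within `tolerance` of a gazetteer
#' point) > `COUNTRY_MISMATCH` (outside the stated country polygon, only
#' checked when polygons are supplied). `(0, lat != 0)` is a legitimate
#' meridian point and is not flagged.
#'
#' @param records data.frame with `record_id`, `species`, `lon`, `lat`,
#'   `locality` and optionally `country`.
#' @param gazetteer data.frame with `lon`, `lat`, `type` in
#'   `"capital"`/`"centroid"`, or `NULL` (checks skipped with a warning).
#' @param country_polygons Optional named list of closed polygon matrices
#'   (columns lon, lat), names = country codes.
#' @param tolerance Gazetteer snap radius in degrees (default 0.05).
#' @return List with `records` (kept rows) and `report` (per-record
#'   disposition).
#' @export
validate_records <- function(records, gazetteer = NULL,
                             country_polygons = NULL, tolerance = 0.05) {
  rep_df <- new_report(records)
  lon <- records$lon; lat <- records$lat
  missing_geo <- is.na(lon) | is.na(lat) |
    is.na(records$locality) | !nzchar(trimws(as.character(records$locality)))
  flag <- function(cond, code) {
    hit <- cond & rep_df$disposition == "kept"
    rep_df$disposition[hit] <<- "removed"
    rep_df$reason[hit] <<- code
  }
  flag(missing_geo, "MISSING_GEO")
  coord_ok <- !is.na(lon) & !is.na(lat)
  flag(coord_ok & lat == lon & lat != 0, "LAT_EQ_LON")
  flag(coord_ok & lat == 0 & lon == 0, "ZERO_COORD")
  if (is.null(gazetteer)) {
    warning("no gazetteer supplied: capital/centroid checks skipped")
  } else {
    for (type in c("capital", "centroid")) {
      pts <- gazetteer[gazetteer$type == type, , drop = FALSE]
      if (nrow(pts) == 0) next
      near <- rep(FALSE, nrow(records))
      for (i in seq_len(nrow(pts))) {
        d <- sqrt((lon - pts$lon[i])^2 + (lat - pts$lat[i])^2)
        near <- near | (coord_ok & !is.na(d) & d <= tolerance)
      }
      flag(near, if (type == "capital") "CAPITAL" else "PROVINCE_CENTROID")
    }
  }
  if (!is.null(country_polygons) && !is.null(records$country)) {
    mism <- rep(FALSE, nrow(records))
    known <- !is.na(records$country) &
      records$country %in% names(country_polygons)
    for (i in which(known & coord_ok)) {
      poly <- country_polygons[[records$country[i]]]
      mism[i] <- !point_in_polygon(lon[i], lat[i], poly)
    }
    flag(mism, "COUNTRY_MISMATCH")
  }
  list(records = records[rep_df$disposition == "kept", , drop = FALSE],
       report = rep_df)
}

#' Deduplicate records to one per species and grid cell
#'
#' Within each (species, cell) group the record with the lowest
#' `record_id` is kept and the rest are removed with reason
#' `DUPLICATE_CELL`; multiple observations inside one cell count as a
#' single observation at the analysis resolution. Records falling outside
#' the grid cannot be assigned a cell and are kept unchanged.
#'
#' @param records data.frame with valid coordinates.
#' @param grid A `grid_spec`.
#' @return List with `records` and `report` as in [validate_records()].
#' @export
dedupe_to_cells <- function(records, grid) {
  rep_df <- new_report(records)
  if (nrow(records)) {
    cell <- point_to_cell(records$lon, records$lat, grid)
    key <- ifelse(is.na(cell), NA_character_,
                  paste(records$species, cell, sep = "\r"))
    ord <- order(records$record_id)
    seen <- duplicated(key[ord], incomparables = NA_character_)
    dup <- logical(nrow(records))
    dup[ord] <- seen
    rep_df$disposition[dup] <- "removed"
    rep_df$reason[dup] <- "DUPLICATE_CELL"
  }
  list(records = records[rep_df$disposition == "kept", , drop = FALSE],
       report = rep_df)
}

#' Fixed-bandwidth Gaussian kernel density at each point
#'
#' Density of the point pattern evaluated at every point: the sum over all
#' points (including the point itself) of an isotropic Gaussian kernel of
#' the pairwise distance in degrees. Only the ranking of the values is
#' used downstream, so no edge correction is applied.
#'
#' @param lon,lat Point coordinates (>= 2 points).
#' @param bandwidth Kernel standard deviation in degrees.
#' @return Numeric vector of positive densities, one per point,
#'   invariant to point order.
#' @export
kde_density <- function(lon, lat, bandwidth = 1.0) {
  n <- length(lon)
  stopifnot(n == length(lat), n >= 2, bandwidth > 0)
  d2 <- outer(lon, lon, "-")^2 + outer(lat, lat, "-")^2
  k <- exp(-d2 / (2 * bandwidth^2)) / (2 * pi * bandwidth^2)
  rowSums(k)
}

#' Kernel-density spatial-outlier filter
#'
#' Computes per-record densities with [kde_density()], chooses the
#' quantile by the species' regional spread (number of regions holding at
#' least one record: 1-3 regions uses `quantile_narrow`, more uses
#' `quantile_wide`), and removes records whose density falls strictly
#' below the empirical quantile with reason `KDE_OUTLIER`. With fewer
#' than 2 records the stage is skipped with a warning.
#'
#' @param records Deduplicated records of one species.
#' @param regions A `region_partition`.
#' @param config A `kde_config`.
#' @return List with `records`, `report`, and the `quantile_used`.
#' @export
kde_outlier_filter <- function(records, regions, config = kde_config()) {
  rep_df <- new_report(records)
  if (nrow(records) < 2) {
    if (nrow(records) > 0)
      warning("fewer than 2 records: KDE outlier stage skipped")
    return(list(records = records, report = rep_df, quantile_used = NA_real_))
  }
  dens <- kde_density(records$lon, records$lat, config$bandwidth)
  reg <- region_of(records$lon, records$lat, regions)
  n_regions <- length(unique(reg[!is.na(reg)]))
  q <- if (n_regions <= 3) config$quantile_narrow else config$quantile_wide
  thr <- stats::quantile(dens, q, names = FALSE)
  out <- dens < thr
  rep_df$disposition[out] <- "removed"
  rep_df$reason[out] <- "KDE_OUTLIER"
  list(records = records[!out, , drop = FALSE], report = rep_df,
       quantile_used = q)
}

#' Full two-step cleaning pipeline for one species
#'
#' Stage 1: deterministic geo-validation ([validate_records()]) followed
#' by grid-cell deduplication ([dedupe_to_cells()]). Stage 2:
#' kernel-density spatial-outlier removal ([kde_outlier_filter()]).
#' Re-running the pipeline on its own output removes nothing at the
#' deterministic stages. Zero surviving records is a valid outcome, not
#' an error.
#'
#' @param records Occurrence data.frame for one species.
#' @param grid A `grid_spec`.
#' @param gazetteer,country_polygons,tolerance Passed to
#'   [validate_records()].
#' @param regions A `region_partition`.
#' @param config A `kde_config`.
#' @return List of class `cleaning_result`: `records` (cleaned), `report`
#'   (per-record disposition over all input records), `stage_counts`,
#'   `fraction_removed`, `quantile_used`.
#' @export
clean_pipeline <- function(records, grid, gazetteer = NULL,
                           regions = NULL, config = kde_config(),
                           country_polygons = NULL, tolerance = 0.05) {
  n_in <- nrow(records)
  v <- validate_records(records, gazetteer, country_polygons, tolerance)
  d <- dedupe_to_cells(v$records, grid)
  quantile_used <- NA_real_
  if (!is.null(regions)) {
    k <- kde_outlier_filter(d$records, regions, config)
    quantile_used <- k$quantile_used
  } else {
    k <- list(records = d$records, report = new_report(d$records))
  }
  report <- v$report
  merge_stage <- function(report, stage) {
    i <- match(stage$record_id, report$record_id)
    rm <- stage$disposition == "removed"
    report$disposition[i[rm]] <- "removed"
    report$reason[i[rm]] <- stage$reason[rm]
    report
  }
  report <- merge_stage(report, d$report)
  report <- merge_stage(report, k$report)
  counts <- table(factor(report$reason, levels = REASON_CODES))
  structure(list(records = k$records, report = report,
                 stage_counts = c(input = n_in,
                                  stats::setNames(as.integer(counts),
                                                  REASON_CODES),
                                  kept = sum(report$disposition == "kept")),
                 reason_counts = counts,
                 fraction_removed = if (n_in > 0)
                   sum(report$disposition == "removed") / n_in else 0,
                 quantile_used = quantile_used),
            class = "cleaning_result")
}

#' @export
print.cleaning_result <- function(x, ...) {
  cat(sprintf("<cleaning_result> %d in, %d kept (%.1f%% removed)\n",
              x$stage_counts[["input"]],
              x$stage_counts[["kept"]], 100 * x$fraction_removed))
  nz <- x$reason_counts[x$reason_counts > 0]
  if (length(nz)) print(nz)
  invisible(x)
}

# even-odd ray casting; poly is a closed or open matrix of (lon, lat)
point_in_polygon <- function(lon, lat, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  if (px[1] == px[n] && py[1] == py[n]) { px <- px[-n]; py <- py[-n]; n <- n - 1 }
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if (((py[i] > lat) != (py[j] > lat)) &&
        (lon < (px[j] - px[i]) * (lat - py[i]) / (py[j] - py[i]) + px[i]))
      inside <- !inside
    j <- i
  }
  inside
}
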