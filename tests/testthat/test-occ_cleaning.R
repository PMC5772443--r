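mk_rec <- function(lon, lat, locality = "x", species = "sp",
                   country = NULL) {
  df <- data.frame(record_id = seq_along(lon),
                   species = rep_len(species, length(lon)),
                   lon = lon, lat = lat,
                   locality = rep_len(locality, length(lon)),
                   stringsAsFactors = FALSE)
  if (!is.null(country)) df$country <- country
  df
}

test_that("geo-validation flags each defect with its first-triggering code", {
  gaz <- data.frame(name = c("cap", "prov"), lon = c(-60, -70),
                    lat = c(5, -10), type = c("capital", "centroid"))
  rec <- mk_rec(lon = c(4.2, 0, 0, -60.01, -70.02, -65, NA, -65),
                lat = c(4.2, 0, -3, 5.02, -10.03, -5, -5, -6),
                locality = c("x", "x", "x", "x", "x", "x", "x", NA))
  v <- validate_records(rec, gaz)
  expect_equal(v$report$reason[1], "LAT_EQ_LON")
  expect_equal(v$report$reason[2], "ZERO_COORD")
  # longitude 0 with nonzero latitude is a legitimate meridian point
  expect_equal(v$report$disposition[3], "kept")
  expect_equal(v$report$reason[4], "CAPITAL")
  expect_equal(v$report$reason[5], "PROVINCE_CENTROID")
  expect_equal(v$report$disposition[6], "kept")
  expect_equal(v$report$reason[7], "MISSING_GEO")
  # missing locality counts as missing geographic information
  expect_equal(v$report$reason[8], "MISSING_GEO")
  # precedence: a record that is both lat==lon and near a gazetteer point
  # reports the earlier code
  rec2 <- mk_rec(lon = 5, lat = 5)
  gaz2 <- data.frame(name = "cap", lon = 5, lat = 5, type = "capital")
  expect_equal(validate_records(rec2, gaz2)$report$reason, "LAT_EQ_LON")
})

test_that("validation without a gazetteer warns and skips the snap checks", {
  rec <- mk_rec(lon = -60, lat = 5)
  expect_warning(v <- validate_records(rec, NULL), "gazetteer")
  expect_equal(v$report$disposition, "kept")
})

test_that("country mismatch fires only when polygons are supplied", {
  poly <- list(C1 = cbind(c(0, 10, 10, 0, 0), c(0, 0, 10, 10, 0)))
  rec <- mk_rec(lon = c(5, 15), lat = c(4, 4), country = "C1")
  gaz <- data.frame(name = character(), lon = numeric(), lat = numeric(),
                    type = character())
  v <- validate_records(rec, gaz, country_polygons = poly)
  expect_equal(v$report$disposition, c("kept", "removed"))
  expect_equal(v$report$reason[2], "COUNTRY_MISMATCH")
  v2 <- validate_records(rec, gaz)
  expect_equal(v2$report$disposition, c("kept", "kept"))
})

test_that("cell deduplication keeps one record per species and cell", {
  g <- grid_spec(-80, -20, 0.5, 60, 60)
  # many records inside one cell collapse to a single observation
  rec <- mk_rec(lon = runif(543, -70.49, -70.01), lat = runif(543, -10.49, -10.01))
  d <- dedupe_to_cells(rec, g)
  expect_equal(nrow(d$records), 1L)
  expect_equal(d$records$record_id, 1L)
  expect_equal(sum(d$report$reason == "DUPLICATE_CELL", na.rm = TRUE), 542L)
  # distinct cells all survive
  rec2 <- mk_rec(lon = c(-70.2, -70.7, -71.2), lat = rep(-10.2, 3))
  expect_equal(nrow(dedupe_to_cells(rec2, g)$records), 3L)
  # two records straddling a cell boundary are different observations
  rec3 <- mk_rec(lon = c(-70.5 - 1e-9, -70.5), lat = rep(-10.2, 2))
  expect_equal(nrow(dedupe_to_cells(rec3, g)$records), 2L)
  # different species are deduplicated independently
  rec4 <- mk_rec(lon = rep(-70.2, 2), lat = rep(-10.2, 2),
                 species = c("a", "b"))
  expect_equal(nrow(dedupe_to_cells(rec4, g)$records), 2L)
})

test_that("kernel densities match the direct kernel sum and its symmetries", {
  # coincident points share a density
  d <- kde_density(c(0, 0), c(0, 0), 1)
  expect_equal(d[1], d[2])
  # direct evaluation oracle on a cluster plus an isolated point
  set.seed(4)
  lon <- c(rnorm(20, 0, 0.3), 10)
  lat <- c(rnorm(20, 0, 0.3), 0)
  dens <- kde_density(lon, lat, 1)
  oracle <- sapply(seq_along(lon), function(i)
    sum(exp(-((lon - lon[i])^2 + (lat - lat[i])^2) / 2) / (2 * pi)))
  expect_equal(dens, oracle, tolerance = 1e-12)
  expect_equal(which.min(dens), 21L)
  # invariant to point ordering
  perm <- sample(seq_along(lon))
  expect_equal(kde_density(lon[perm], lat[perm], 1), dens[perm],
               tolerance = 1e-12)
  expect_error(kde_density(1, 1, 1), "n >= 2")
})

test_that("the outlier filter removes isolated points and keeps clusters", {
  rec <- kde_fixture()
  regions <- synth_regions(grid_spec(-80, -20, 0.5, 60, 60))
  k <- kde_outlier_filter(rec, regions, kde_config())
  expect_equal(k$quantile_used, 0.05)  # cluster spans <= 3 regions
  removed <- setdiff(rec$record_id, k$records$record_id)
  expect_setequal(removed, rec$record_id[rec$error == "misidentification"])
})

test_that("uniformly dense lattices lose points only at the margin", {
  g <- grid_spec(-80, -20, 0.5, 60, 60)
  pts <- expand.grid(lon = seq(-75, -68, 0.5), lat = seq(-15, -8, 0.5))
  rec <- data.frame(record_id = seq_len(nrow(pts)), species = "sp",
                    lon = pts$lon, lat = pts$lat, locality = "x")
  k <- kde_outlier_filter(rec, synth_regions(g), kde_config())
  gone <- rec[!(rec$record_id %in% k$records$record_id), ]
  on_margin <- gone$lon %in% range(pts$lon) | gone$lat %in% range(pts$lat)
  expect_true(all(on_margin))
})

test_that("narrow-species quantiles remove at least as many points", {
  rec <- kde_fixture(n_cluster = 40, n_far = 3)
  g <- grid_spec(-80, -20, 0.5, 60, 60)
  # same points, two region labellings: all-one-region vs the real spread
  reg_narrow <- region_partition(raster_layer(g, 1))
  reg_wide <- region_partition(raster_layer(
    g, rep(1:6, length.out = n_cells(g))))
  k_n <- kde_outlier_filter(rec, reg_narrow, kde_config())
  k_w <- kde_outlier_filter(rec, reg_wide, kde_config())
  expect_equal(k_n$quantile_used, 0.05)
  expect_equal(k_w$quantile_used, 0.01)
  expect_lte(nrow(k_n$records), nrow(k_w$records))
  # removal count is monotone in the quantile threshold
  removed <- sapply(c(0.01, 0.05, 0.1, 0.2), function(q)
    nrow(rec) - nrow(kde_outlier_filter(
      rec, reg_narrow, kde_config(quantile_narrow = max(q, 0.01),
                                  quantile_wide = 0.01))$records))
  expect_true(all(diff(removed) >= 0))
})

test_that("the full pipeline removes labelled records with correct codes", {
  w <- small_world()
  sp <- names(w$truths)[2]
  rec <- w$records[w$records$species == sp, ]
  out <- clean_pipeline(rec, w$grid, w$gazetteer, w$regions, kde_config())
  rep <- merge(out$report, rec[c("record_id", "error")], by = "record_id")
  expected <- c(missing_coord = "MISSING_GEO", zero_coord = "ZERO_COORD",
                lat_eq_lon = "LAT_EQ_LON", capital_assign = "CAPITAL",
                centroid_assign = "PROVINCE_CENTROID",
                duplicate = "DUPLICATE_CELL")
  for (lab in names(expected)) {
    sub <- rep[rep$error == lab, ]
    if (nrow(sub) == 0) next
    expect_true(all(sub$disposition == "removed"), label = lab)
    expect_true(all(sub$reason == expected[[lab]]), label = lab)
  }
  # no clean record is removed by a deterministic stage
  clean_rm <- rep[rep$error == "clean" & rep$disposition == "removed", ]
  expect_true(all(clean_rm$reason == "KDE_OUTLIER"))
  expect_equal(out$fraction_removed,
               sum(out$report$disposition == "removed") / nrow(rec))
  # output is a subset of the input
  expect_true(all(out$records$record_id %in% rec$record_id))
})

test_that("re-cleaning cleaned records removes nothing deterministically", {
  w <- small_world()
  sp <- names(w$truths)[1]
  rec <- w$records[w$records$species == sp, ]
  once <- clean_pipeline(rec, w$grid, w$gazetteer, w$regions, kde_config())
  again <- validate_records(once$records, w$gazetteer)
  expect_equal(nrow(again$records), nrow(once$records))
  re_dedup <- dedupe_to_cells(again$records, w$grid)
  expect_equal(nrow(re_dedup$records), nrow(once$records))
})

test_that("degenerate inputs are handled without error", {
  g <- grid_spec(-80, -20, 0.5, 60, 60)
  reg <- synth_regions(g)
  one <- mk_rec(lon = -70, lat = -10)
  expect_warning(k <- kde_outlier_filter(one, reg), "fewer than 2")
  expect_equal(nrow(k$records), 1L)
  empty <- mk_rec(lon = numeric(), lat = numeric())
  out <- clean_pipeline(empty, g, NULL, reg, kde_config()) |>
    suppressWarnings()
  expect_equal(nrow(out$records), 0L)
  expect_equal(out$fraction_removed, 0)
})
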