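test_that("the generator is fully deterministic under the seed", {
  w1 <- gen_world(small_config(seed = 7))
  w2 <- gen_world(small_config(seed = 7))
  expect_identical(w1$records, w2$records)
  expect_identical(w1$plots, w2$plots)
  expect_identical(lapply(w1$env, `[[`, "values"),
                   lapply(w2$env, `[[`, "values"))
  w3 <- gen_world(small_config(seed = 8))
  expect_false(identical(w1$records, w3$records))
})

test_that("environmental layers are in [0,1] with built-in collinearity", {
  env <- std_world()$env
  for (l in env) {
    expect_true(all(l$values >= 0 & l$values <= 1))
  }
  M <- sapply(env, `[[`, "values")
  rho <- cor(M, method = "spearman")
  n_high <- sum(abs(rho[upper.tri(rho)]) > 0.7)
  expect_gte(n_high, 2)
})

test_that("species truths obey niche, envelope and region-count structure", {
  w <- std_world()
  for (t in w$truths) {
    sv <- t$suitability$values
    ra <- t$ra$values
    expect_equal(max(sv), 1)
    expect_true(all(ra >= 0 & ra <= w$config$ra_max + 1e-12))
    # abundance implies suitability
    expect_true(all(sv[ra > 0] > 0))
    # abundance vanishes outside the dispersal envelope
    ctr <- cell_center(seq_len(n_cells(w$grid)), w$grid)
    cxy <- cell_center(t$centers, w$grid)
    mind <- Reduce(pmin, lapply(seq_len(nrow(cxy)), function(i)
      sqrt((ctr$lon - cxy$lon[i])^2 + (ctr$lat - cxy$lat[i])^2)))
    expect_true(all(ra[mind > 3 * t$tau] == 0))
  }
  n_reg <- vapply(w$truths, function(t)
    length(unique(w$regions$values[t$ra$values > 0])), numeric(1))
  narrow <- vapply(w$truths, `[[`, logical(1), "narrow")
  expect_true(all(n_reg[narrow] <= 3))
  expect_true(any(n_reg[!narrow] > 3))
  # per-cell abundance never exceeds the all-species budget
  total <- Reduce(`+`, lapply(w$truths, function(t) t$ra$values))
  expect_true(all(total <= 1))
})

test_that("plot censuses are multinomial draws from the local abundances", {
  w <- std_world()
  counts <- as.matrix(w$plots[names(w$truths)])
  expect_true(all(rowSums(counts) <= w$plots$N_total))
  expect_true(all(counts >= 0))
  # plots all fall on forested cells
  cells <- point_to_cell(w$plots$lon, w$plots$lat, w$grid)
  expect_true(all(w$forest$values[cells] == 1))
  # a species absent everywhere yields no stems anywhere
  truths0 <- w$truths[1]
  truths0[[1]]$ra$values[] <- 0
  cfg <- w$config
  p0 <- gen_plots(truths0, cfg, w$forest)
  expect_true(all(p0[[names(truths0)]] == 0))
})

test_that("observed plot abundance is unbiased for the true abundance", {
  # constant-RA patch: mean observed RA over 200 plots within 3 binomial SEs
  cfg <- synth_config(seed = 12, n_plots = 200)
  forest <- synth_forest(cfg$grid)
  truth <- list(species_01 = structure(list(
    species = "species_01",
    ra = raster_layer(cfg$grid, ifelse(forest$values == 1, 0.02, 0))),
    class = "species_truth"))
  plots <- gen_plots(truth, cfg, forest)
  ra_obs <- plots$species_01 / plots$N_total
  se <- sqrt(0.02 * 0.98 / mean(plots$N_total)) / sqrt(nrow(plots))
  expect_lt(abs(mean(ra_obs) - 0.02), 3 * se)
})

test_that("collection intensity reduces to abundance when bias is off", {
  ra <- c(0, 0.01, 0.02, 0.05)
  expect_equal(collection_intensity(ra, rep(2, 4), gamma = 1), 2 * ra)
  # gamma < 1 over-represents low-abundance cells
  i <- collection_intensity(ra, rep(1, 4), gamma = 0.5)
  expect_gt(i[2] / i[4], ra[2] / ra[4])
})

test_that("sampled collection counts track abundance under the neutral config", {
  # gamma = 1, uniform accessibility: cell counts proportional to RA
  w <- std_world()
  cfg <- synth_config(seed = 13, collections_per_species = 300,
                      collector_bias_exponent = 1,
                      error_rates = c(missing_coord = 0, zero_coord = 0,
                                      lat_eq_lon = 0, capital_assign = 0,
                                      centroid_assign = 0, duplicate = 0,
                                      misidentification = 0))
  uniform_access <- raster_layer(w$grid, 1)
  cn <- synth_countries(w$grid)
  recs <- gen_collections(w$truths["species_14"], cfg, uniform_access, cn)
  cells <- point_to_cell(recs$lon, recs$lat, w$grid)
  ra <- w$truths$species_14$ra$values
  # bin occupied cells into abundance quintiles; expected counts follow RA
  occ <- which(ra > 0)
  bins <- cut(ra[occ], quantile(ra[occ], 0:5 / 5), include.lowest = TRUE)
  obs <- tapply(tabulate(match(cells, occ), nbins = length(occ)), bins, sum)
  p_exp <- tapply(ra[occ], bins, sum) / sum(ra[occ])
  gof <- suppressWarnings(chisq.test(obs, p = p_exp))
  expect_gt(gof$p.value, 0.01)
})

test_that("injected error labels appear at their configured rates", {
  w <- corpus_world()
  n <- nrow(w$records)
  expect_gte(n, 10000)
  rates <- table(w$records$error) / n
  for (nm in names(w$config$error_rates)) {
    got <- if (nm %in% names(rates)) as.numeric(rates[[nm]]) else 0
    expect_lt(abs(got - w$config$error_rates[[nm]]), 0.02)
  }
})

test_that("injected corruptions have the promised shapes", {
  w <- corpus_world()
  r <- w$records
  miss <- r[r$error == "missing_coord", ]
  expect_true(all(is.na(miss$lon) | is.na(miss$lat) | is.na(miss$locality)))
  zero <- r[r$error == "zero_coord", ]
  expect_true(all(zero$lon == 0 & zero$lat == 0))
  lel <- r[r$error == "lat_eq_lon", ]
  expect_true(all(lel$lat == lel$lon & lel$lat != 0))
  # every snap lands within the validation tolerance of a gazetteer point
  for (type in c("capital_assign", "centroid_assign")) {
    sub <- r[r$error == type, ]
    gaz <- w$gazetteer[w$gazetteer$type ==
                         sub("_assign", "", type, fixed = TRUE), ]
    dmin <- sapply(seq_len(nrow(sub)), function(i)
      min(sqrt((gaz$lon - sub$lon[i])^2 + (gaz$lat - sub$lat[i])^2)))
    expect_true(all(dmin <= 0.05))
  }
  # duplicates share species and grid cell with an earlier clean record
  dup <- r[r$error == "duplicate", ]
  cell <- point_to_cell(ifelse(is.na(r$lon), -999, r$lon),
                        ifelse(is.na(r$lat), -999, r$lat), w$grid)
  for (i in sample(which(r$error == "duplicate"), 25)) {
    mates <- which(r$species == r$species[i] & r$error == "clean" &
                     cell == cell[i] & r$record_id < r$record_id[i])
    expect_gt(length(mates), 0)
  }
  # misidentified records sit far from their (new) species' true range
  mis <- r[r$error == "misidentification", ]
  for (i in sample(nrow(mis), 25)) {
    occ <- cell_center(which(w$truths[[mis$species[i]]]$ra$values > 0),
                       w$grid)
    expect_gt(min(sqrt((occ$lon - mis$lon[i])^2 +
                         (occ$lat - mis$lat[i])^2)), 2.5)
  }
})

test_that("a world can be written to and read back from plain-text files", {
  w <- small_world()
  dir <- withr::local_tempdir()
  write_world(w, dir)
  occ <- read_occurrences(file.path(dir, "occurrences.csv"))
  expect_equal(nrow(occ), nrow(w$records))
  expect_equal(occ$lon, w$records$lon)
  env1 <- read_raster(file.path(dir, paste0("env_", names(w$env)[1], ".asc")),
                      grid = w$grid)
  expect_equal(env1$values, w$env[[1]]$values, tolerance = 1e-12)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, w$config$seed)
})
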