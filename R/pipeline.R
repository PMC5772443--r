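#' Pipeline configuration
#'
#' Bundles the per-module configurations and gates of the full
#' per-species workflow (clean -> interpolate -> fit -> clip -> validate
#' -> compare). All randomness downstream (background sampling, null
#' draws, bootstrap) derives deterministically from `seed`.
#'
#' @param seed Master seed.
#' @param idw An `idw_config`.
#' @param kde A `kde_config`.
#' @param gazetteer_tolerance Gazetteer snap radius, degrees.
#' @param reg_multiplier,tol,max_iter Maximum-entropy fit settings.
#' @param n_bg Background sample size (default 10000; capped at the
#'   number of bias-positive cells).
#' @param n_null Null models per species (default 99).
#' @param min_presences Minimum unique presence cells to model a species
#'   (default 5).
#' @param buffer_deg Hull buffer distance, degrees (default 3).
#' @param n_boot Bootstrap replicates for the quantile regression.
#' @param tau Quantile level (default 0.9).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, idw = idw_config(),
                            kde = kde_config(),
                            gazetteer_tolerance = 0.05,
                            reg_multiplier = 1.0, tol = 1e-7,
                            max_iter = 500, n_bg = 10000, n_null = 99,
                            min_presences = 5, buffer_deg = 3.0,
                            n_boot = 200, tau = 0.9) {
  structure(list(seed = as.integer(seed), idw = idw, kde = kde,
                 gazetteer_tolerance = gazetteer_tolerance,
                 reg_multiplier = reg_multiplier, tol = tol,
                 max_iter = max_iter, n_bg = n_bg, n_null = n_null,
                 min_presences = min_presences, buffer_deg = buffer_deg,
                 n_boot = n_boot, tau = tau),
            class = "pipeline_config")
}

#' Shared cohort context
#'
#' Precomputes everything shared across species: the cleaning of every
#' species' records (whose union defines the survey-effort bias file),
#' the collinearity-screened variable set, the background sample and the
#' scaled feature matrix.
#'
#' @param world A `synth_world` (or an equivalent list with `records`,
#'   `plots`, `env`, `regions`, `forest`, `gazetteer`, `grid`).
#' @param config A `pipeline_config`.
#' @return List of class `cohort_context`.
#' @export
cohort_context <- function(world, config = pipeline_config()) {
  species <- sort(unique(world$records$species))
  cleaned <- lapply(species, function(sp)
    clean_pipeline(world$records[world$records$species == sp, , drop = FALSE],
                   world$grid, world$gazetteer, world$regions, config$kde,
                   tolerance = config$gazetteer_tolerance))
  names(cleaned) <- species
  all_clean <- do.call(rbind, lapply(cleaned, `[[`, "records"))
  bias <- bias_file(all_clean, world$grid)
  screen <- collinearity_screen(world$env)
  bg <- sample_background(bias, config$n_bg, seed = config$seed)
  features <- build_features(world$env, bg, screen$retained)
  study_cells <- which(world$forest$values == 1 & world$forest$mask)
  structure(list(species = species, cleaned = cleaned, bias = bias,
                 screen = screen, background = bg, features = features,
                 study_cells = study_cells),
            class = "cohort_context")
}

species_seed <- function(config, index) config$seed + 7919L * index

#' Run the full workflow for one species
#'
#' Executes clean -> IDW surface and binary map -> maximum-entropy fit
#' with target-group background -> null-model gate -> hull-buffer clip ->
#' 10% training-presence binarisation -> comparison statistics. Species
#' failing a gate (too few cleaned presences, or a suitability model not
#' distinguishable from the bias-corrected random expectation) are
#' reported with the gate that removed them and excluded from the
#' comparison statistics, but their cleaning report is retained.
#'
#' @param species Species name (must appear in `world$records`).
#' @param world A `synth_world`.
#' @param config A `pipeline_config`.
#' @param ctx A `cohort_context` (built on the fly if omitted).
#' @return List of class `species_result` with `stats` (one-row
#'   data.frame) and artifacts (`surface`, `model`, `suitability`,
#'   `binary_idw`, `binary_maxent`, `hull`, `null_test`, `cleaning`).
#' @export
run_species <- function(species, world, config = pipeline_config(),
                        ctx = NULL) {
  if (is.null(ctx)) ctx <- cohort_context(world, config)
  idx <- match(species, ctx$species)
  if (is.na(idx)) stop("unknown species: ", species)
  sseed <- species_seed(config, idx)
  cleaning <- ctx$cleaned[[species]]
  rec <- cleaning$records
  raw_n <- sum(world$records$species == species)
  row <- data.frame(species = species, n_records_raw = raw_n,
                    n_cleaned = nrow(rec),
                    fraction_removed = cleaning$fraction_removed,
                    status = "ok", auc = NA_real_, null_rank = NA_integer_,
                    significant = NA, rho = NA_real_, rho_p = NA_real_,
                    q_slope = NA_real_, q_slope_lo = NA_real_,
                    q_slope_hi = NA_real_, q_p = NA_real_,
                    glm_beta1 = NA_real_, glm_p = NA_real_,
                    glm_significant_positive = NA,
                    sens_idw_vs_collections = NA_real_,
                    sens_maxent_vs_plots = NA_real_,
                    aoo_maxent = NA_integer_, aoo_idw = NA_integer_,
                    stringsAsFactors = FALSE)
  out <- list(stats = row, cleaning = cleaning)
  class(out) <- "species_result"

  pres_cells <- unique(point_to_cell(rec$lon, rec$lat, world$grid))
  pres_cells <- pres_cells[!is.na(pres_cells)]
  pres_cells <- pres_cells[!is.na(ctx$features$values[pres_cells, 1])]
  if (length(pres_cells) < config$min_presences) {
    out$stats$status <- "insufficient_presences"
    return(out)
  }

  # plot-based abundance surface
  plots <- world$plots
  plots$ra <- plot_relative_abundance(plots[[species]], plots$N_total)
  surface <- idw_surface(plots, world$grid, config$idw, world$forest)
  bin_idw <- idw_binary_map(surface, world$forest)

  # presence-only model
  model <- fit_maxent(pres_cells, ctx$background, ctx$features,
                      config$reg_multiplier, config$tol, config$max_iter)
  suit <- logistic_map(model, ctx$features)
  nt <- null_model_test(pres_cells, ctx$features, ctx$background,
                        ctx$bias, seed = sseed, n_null = config$n_null,
                        reg_multiplier = config$reg_multiplier,
                        tol = config$tol, max_iter = config$max_iter,
                        observed_model = model)
  out$surface <- surface; out$binary_idw <- bin_idw
  out$model <- model; out$suitability <- suit; out$null_test <- nt
  out$stats$auc <- nt$observed_auc
  out$stats$null_rank <- nt$rank
  out$stats$significant <- nt$significant

  # GLM: probability of being collected vs interpolated abundance
  glm_res <- glm_collection_vs_abundance(pres_cells, surface,
                                         ctx$study_cells)
  out$stats$glm_beta1 <- glm_res$slope
  out$stats$glm_p <- glm_res$p
  out$stats$glm_significant_positive <- glm_res$significant_positive

  # IDW map scored against collection localities
  out$stats$sens_idw_vs_collections <- sensitivity(bin_idw, rec$lon, rec$lat)
  out$stats$aoo_idw <- area_of_occupancy(bin_idw)

  if (!nt$significant) {
    out$stats$status <- "null_model_not_significant"
    return(out)
  }

  # hull-buffer clip and 10% training-presence binarisation
  hull <- hull_buffer(rec$lon, rec$lat, config$buffer_deg)
  suit_clipped <- clip_to_range(suit, hull)
  thr <- threshold_10pct(suit$values[pres_cells])
  bmax <- raster_layer(world$grid,
                       as.numeric(!is.na(suit_clipped$values) &
                                    suit_clipped$values >= thr &
                                    world$forest$values == 1))
  out$hull <- hull; out$binary_maxent <- bmax; out$threshold <- thr
  out$stats$aoo_maxent <- area_of_occupancy(bmax)
  pres_plots <- plots[plots$ra > 0, , drop = FALSE]
  out$stats$sens_maxent_vs_plots <- sensitivity(bmax, pres_plots$lon,
                                                pres_plots$lat)

  # suitability vs plot abundance at plot localities
  plot_cells <- point_to_cell(plots$lon, plots$lat, world$grid)
  suit_at_plots <- suit$values[plot_cells]
  ok <- !is.na(suit_at_plots)
  sp_res <- spearman_suit_vs_abundance(suit_at_plots[ok], plots$ra[ok])
  out$stats$rho <- sp_res$rho
  out$stats$rho_p <- sp_res$p
  qr <- quantile_reg_90(suit_at_plots[ok], plots$ra[ok], tau = config$tau,
                        n_boot = config$n_boot, seed = sseed + 1L)
  out$stats$q_slope <- qr$slope
  out$stats$q_slope_lo <- qr$ci[1]
  out$stats$q_slope_hi <- qr$ci[2]
  out$stats$q_p <- qr$p
  out$quantreg <- qr
  out
}

#' Run the workflow for a species cohort
#'
#' Per-species isolation: one species' failure is recorded in its row and
#' never aborts the cohort.
#'
#' @param world A `synth_world`.
#' @param config A `pipeline_config`.
#' @param species Character vector (default: every species present in
#'   the records).
#' @param keep_artifacts Keep per-species maps/models in the result
#'   (default FALSE to bound memory).
#' @return List of class `cohort_result`: `stats` (one row per species),
#'   `results` (if `keep_artifacts`), `ctx`.
#' @export
run_cohort <- function(world, config = pipeline_config(), species = NULL,
                       keep_artifacts = FALSE) {
  ctx <- cohort_context(world, config)
  if (is.null(species)) species <- ctx$species
  results <- vector("list", length(species))
  names(results) <- species
  rows <- vector("list", length(species))
  for (i in seq_along(species)) {
    res <- tryCatch(run_species(species[i], world, config, ctx),
                    error = function(e) {
                      row <- data.frame(species = species[i],
                                        status = paste0("error: ",
                                                        conditionMessage(e)),
                                        stringsAsFactors = FALSE)
                      list(stats = row)
                    })
    rows[[i]] <- res$stats
    if (keep_artifacts) results[[i]] <- res
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  })
  structure(list(stats = do.call(rbind, rows),
                 results = if (keep_artifacts) results,
                 ctx = ctx, config = config),
            class = "cohort_result")
}

#' Summarise a cohort run
#'
#' Cohort-level report: how many species passed each gate, the proportion
#' with a significant positive collection-vs-abundance relationship, mean
#' Spearman rho and mean 90th-percentile slope over species with
#' comparison statistics, median sensitivities in both directions, median
#' areas of occupancy for both map types and their per-species size
#' comparison, plus the mean fraction of records removed by cleaning.
#'
#' @param stats The `stats` data.frame of a `cohort_result` (or the
#'   `cohort_result` itself).
#' @return One-row data.frame of cohort summaries.
#' @export
summarize_cohort <- function(stats) {
  if (inherits(stats, "cohort_result")) stats <- stats$stats
  if (nrow(stats) == 0) stop("empty cohort")
  modelled <- stats[!is.na(stats$auc), , drop = FALSE]
  comp <- stats[stats$status == "ok" & !is.na(stats$rho), , drop = FALSE]
  both_aoo <- comp[!is.na(comp$aoo_maxent) & !is.na(comp$aoo_idw), ,
                   drop = FALSE]
  data.frame(
    n_species = nrow(stats),
    n_modelled = nrow(modelled),
    n_significant = sum(modelled$significant, na.rm = TRUE),
    n_compared = nrow(comp),
    mean_fraction_removed = mean(stats$fraction_removed, na.rm = TRUE),
    prop_glm_significant_positive =
      mean(modelled$glm_significant_positive, na.rm = TRUE),
    mean_rho = mean(comp$rho),
    mean_q_slope = mean(comp$q_slope),
    prop_rho_significant = mean(comp$rho_p < 0.05),
    median_sens_idw_vs_collections =
      stats::median(modelled$sens_idw_vs_collections, na.rm = TRUE),
    median_sens_maxent_vs_plots =
      stats::median(comp$sens_maxent_vs_plots, na.rm = TRUE),
    median_aoo_maxent = stats::median(comp$aoo_maxent, na.rm = TRUE),
    median_aoo_idw = stats::median(comp$aoo_idw, na.rm = TRUE),
    prop_aoo_maxent_larger = if (nrow(both_aoo))
      mean(both_aoo$aoo_maxent > both_aoo$aoo_idw) else NA_real_)
}
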