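#!/usr/bin/env Rscript
# Stage 5: the model contrast.
#
# Runs the full per-species workflow and assembles the cohort report:
# does the chance of being collected track interpolated abundance (GLM)?
# how strongly do suitability and plot abundance agree (Spearman,
# 90th-percentile quantile regression)? how do the two binary maps score
# against each other's occurrence data (sensitivity) and how do their
# areas of occupancy compare? Histograms of the per-species statistics
# are written alongside the tables.

suppressPackageStartupMessages(library(sdmabund))
seed <- 42
dir.create("results", showWarnings = FALSE)

world <- gen_world(synth_config(seed = seed))
cohort <- run_cohort(world, pipeline_config(seed = seed))
summ <- summarize_cohort(cohort)

write.csv(cohort$stats, "results/species_stats.csv", row.names = FALSE)
jsonlite::write_json(as.list(summ), "results/cohort_summary.json",
                     auto_unbox = TRUE, digits = NA)

ok <- cohort$stats[cohort$stats$status == "ok" & !is.na(cohort$stats$rho), ]
grDevices::png("results/comparison_histograms.png", width = 1200,
               height = 900, res = 130)
op <- par(mfrow = c(2, 2), mar = c(4, 4, 2.5, 1))
hist(ok$rho, breaks = 10, main = "Suitability vs abundance (Spearman)",
     xlab = expression(rho), col = "grey80")
hist(ok$q_slope, breaks = 10, main = "90th-percentile regression slope",
     xlab = "slope", col = "grey80")
hist(cohort$stats$sens_idw_vs_collections, breaks = 10,
     main = "IDW map vs collection localities", xlab = "sensitivity",
     col = "grey80")
hist(ok$sens_maxent_vs_plots, breaks = 10,
     main = "Suitability map vs plot presences", xlab = "sensitivity",
     col = "grey80")
par(op); dev.off()

cat("Cohort of", summ$n_species, "species:\n")
cat(sprintf("  cleaning removed %.0f%% of records on average\n",
            100 * summ$mean_fraction_removed))
cat(sprintf("  %d/%d species passed the null-model gate\n",
            summ$n_significant, summ$n_modelled))
cat(sprintf("  significant positive collection~abundance GLM: %.0f%%\n",
            100 * summ$prop_glm_significant_positive))
cat(sprintf("  suitability vs abundance: mean rho %.2f (%.0f%% significant)\n",
            summ$mean_rho, 100 * summ$prop_rho_significant))
cat(sprintf("  mean 90th-percentile slope: %.3f\n", summ$mean_q_slope))
cat(sprintf("  median sensitivity: IDW vs collections %.2f, suitability vs plots %.2f\n",
            summ$median_sens_idw_vs_collections,
            summ$median_sens_maxent_vs_plots))
cat(sprintf("  median area of occupancy: suitability %d cells, IDW %d cells\n",
            summ$median_aoo_maxent, summ$median_aoo_idw))
cat(sprintf("  suitability AOO larger than IDW AOO for %.0f%% of species\n",
            100 * summ$prop_aoo_maxent_larger))
cat("Tables in results/, figure in results/comparison_histograms.png\n")
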