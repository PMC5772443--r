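#!/usr/bin/env Rscript
# Stage 1: build the synthetic study system.
#
# Generates the 60 x 60 half-degree world — six environmental fields (two
# built-in collinear pairs), six regions, a forest mask, 15 tree species
# with known suitability and relative-abundance surfaces, 400 plot
# censuses (~550 stems each) and biased collection records with labelled
# injected georeferencing errors — and writes every piece to
# results/world/ as plain-text rasters and CSVs.
#
# Everything downstream re-derives this world deterministically from the
# same seed, so the files here are for inspection, not a handoff.

suppressPackageStartupMessages(library(sdmabund))
seed <- 42

world <- gen_world(synth_config(seed = seed))
write_world(world, "results/world")

cat("World written to results/world\n")
cat(sprintf("  %d collection records (%d labelled clean)\n",
            nrow(world$records), sum(world$records$error == "clean")))
print(table(world$records$error))
cat(sprintf("  %d plots, mean %.0f stems\n", nrow(world$plots),
            mean(world$plots$N_total)))
occ <- colSums(as.matrix(world$plots[names(world$truths)]) > 0)
cat(sprintf("  species occupy %d-%d plots (median %.0f)\n",
            min(occ), max(occ), median(occ)))
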