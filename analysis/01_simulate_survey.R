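#!/usr/bin/env Rscript
# Stage 1: generate the synthetic scat survey at study scale and write its
# raw data files (the inputs every later stage consumes).
# Usage: Rscript analysis/01_simulate_survey.R [seed]

suppressPackageStartupMessages(library(scatcap))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1

out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- default_fixture_config()
sim <- simulate_scat_survey(cfg, seed = seed)

write_replicate_set(sim$replicates, file.path(out, "replicates.csv"))
write.csv(sim$scats[c("scat_id", "fragment_bp")],
          file.path(out, "fragments.csv"), row.names = FALSE)
write_detections(sim$scats[c("scat_id", "x", "y", "occasion")],
                 file.path(out, "detections.csv"))
write_geojson(sim$geometry$transects, file.path(out, "transects.geojson"),
              "LineString")
write_geojson(sim$geometry$habitat, file.path(out, "habitat.geojson"),
              "Polygon")
# truth tables for later comparison
write.csv(sim$scats[c("scat_id", "true_species", "individual_id")],
          file.path(out, "truth_scats.csv"), row.names = FALSE)
write.csv(sim$population$pedigree, file.path(out, "truth_pedigree.csv"),
          row.names = FALSE)
write_genotype_table(sim$population$genotypes,
                     file.path(out, "truth_genotypes.csv"))

n_bob <- sum(sim$scats$true_species == "BOBCAT")
cat(sprintf(
  "Simulated survey (seed %d): %d scats collected along %d transects;\n",
  seed, nrow(sim$scats), length(sim$geometry$transects)))
cat(sprintf(
  "  %d from the %d bobcats (activity centers in a %.0f ha island), %d from coyotes.\n",
  n_bob, length(unique(na.omit(sim$scats$individual_id))),
  3500 * 20000 / 1e4, sum(sim$scats$true_species == "COYOTE")))
cat("Raw files written under", out, "\n")
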