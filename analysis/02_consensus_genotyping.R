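#!/usr/bin/env Rscript
# Stage 2: species assignment from mtDNA fragment lengths, then per-locus
# consensus genotypes from the replicate PCRs (pair confirmed in >= 3
# successful PCRs; homozygote only if every successful PCR shows the single
# allele); scats retained at >= 6 consensus loci.

suppressPackageStartupMessages(library(scatcap))
src <- "results/synthetic"
out <- "results"

reps <- read_replicate_set(file.path(src, "replicates.csv"))
frag <- read.csv(file.path(src, "fragments.csv"))
species <- setNames(classify_species(frag$fragment_bp), frag$scat_id)

profiles <- build_scat_profiles(reps, species)
rates <- locus_rates(reps, profiles)
write.csv(rates, file.path(out, "locus_rates.csv"), row.names = FALSE)

prof_tab <- do.call(rbind, lapply(profiles, function(p)
  data.frame(scat_id = p$scat_id, species = p$species,
             n_amplified_loci = p$n_amplified_loci,
             n_consensus_loci = p$n_consensus_loci,
             screened_out = p$screened_out, retained = p$retained)))
write.csv(prof_tab, file.path(out, "scat_profiles.csv"), row.names = FALSE)
gt <- profiles_to_genotypes(profiles)
write_genotype_table(gt, file.path(out, "retained_scat_genotypes.csv"))

cat(sprintf("Species assignment: %d bobcat, %d coyote, %d unknown scats.\n",
            sum(species == "BOBCAT"), sum(species == "COYOTE"),
            sum(species == "UNKNOWN")))
cat(sprintf("Per-locus amplification rates span %.0f%%-%.0f%% (genotyping %.0f%%-%.0f%%).\n",
            100 * min(rates$amplification_rate),
            100 * max(rates$amplification_rate),
            100 * min(rates$genotyping_rate),
            100 * max(rates$genotyping_rate)))
cat(sprintf("%d of %d scats retained with consensus genotypes at >= 6 loci.\n",
            sum(prof_tab$retained), nrow(prof_tab)))
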