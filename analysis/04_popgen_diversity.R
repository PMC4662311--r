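#!/usr/bin/env Rscript
# Stage 4: genetic diversity of the identified individuals - heterozygosity,
# allelic richness, Hardy-Weinberg tests, FIS - and the two
# effective-number-of-breeders estimators.

suppressPackageStartupMessages(library(scatcap))
out <- "results"
gt <- read_genotype_table(file.path(out, "individual_genotypes.csv"))

het <- heterozygosity_stats(gt)
hwe <- hwe_test_all(gt)
f <- fis(gt)
per_locus <- merge(het$per_locus, hwe, by = "locus_id")
per_locus <- merge(per_locus, f$per_locus[c("locus_id", "FIS")],
                   by = "locus_id", all.x = TRUE)
write.csv(per_locus, file.path(out, "popgen_per_locus.csv"), row.names = FALSE)

nb_he <- ne_heterozygote_excess(gt)
nb_co <- tryCatch(ne_coancestry(gt), error = function(e) NULL)
jsonlite::write_json(list(
  mean_Ho = het$mean_Ho, se_Ho = het$se_Ho,
  mean_uHe = het$mean_uHe, se_uHe = het$se_uHe, AR = het$AR,
  mean_FIS = f$mean_FIS, se_FIS = f$se_FIS,
  D_weighted = nb_he$D_weighted, Nb_het = nb_he$Nb,
  Nb_het_ci = as.list(nb_he$ci),
  Nb_coancestry = if (is.null(nb_co)) NA else nb_co$Nb,
  Nb_coancestry_ci = if (is.null(nb_co)) NULL else as.list(nb_co$ci)),
  file.path(out, "popgen_summary.json"), auto_unbox = TRUE, digits = NA,
  na = "string")

cat(sprintf("Diversity over %d loci: mean Ho = %.3f (SE %.3f), mean uHe = %.3f, AR = %.2f.\n",
            nrow(het$per_locus), het$mean_Ho, het$se_Ho, het$mean_uHe, het$AR))
cat(sprintf("Mean FIS = %.3f (negative = heterozygote excess); min HWE p = %.3f.\n",
            f$mean_FIS, min(hwe$p, na.rm = TRUE)))
cat(sprintf("Effective breeders: heterozygote excess %.1f (D = %.3f), coancestry %.1f.\n",
            nb_he$Nb, nb_he$D_weighted,
            if (is.null(nb_co)) NA else nb_co$Nb))
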