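#' Assign species from an mtDNA control-region fragment length
#'
#' Scat species are diagnosed by the size of a conserved-primer mtDNA
#' fragment; the two candidate species differ by 16 bp, so a fragment is
#' assigned to the species whose reference length lies within
#' \code{tolerance_bp}. Fragments matching neither window (or failed reads,
#' NA) are UNKNOWN.
#'
#' @param fragment_length_bp numeric vector, NA = failed read.
#' @param reference_lengths named numeric vector, e.g.
#'   \code{c(BOBCAT = 180, COYOTE = 196)}.
#' @param tolerance_bp half-width of each species window; must be less than
#'   half the smallest gap between reference lengths.
#' @return character vector of species labels ("UNKNOWN" when unmatched).
#' @export
classify_species <- function(fragment_length_bp,
                             reference_lengths = c(BOBCAT = 180, COYOTE = 196),
                             tolerance_bp = 3) {
  if (length(reference_lengths) < 2 || is.null(names(reference_lengths)))
    stop("config error: need >= 2 named reference lengths")
  gap <- min(dist(reference_lengths))
  if (tolerance_bp * 2 >= gap)
    stop("config error: species windows overlap (tolerance ", tolerance_bp,
         " vs inter-species gap ", gap, ")")
  vapply(fragment_length_bp, function(len) {
    if (is.na(len)) return("UNKNOWN")
    d <- abs(reference_lengths - len)
    hit <- which(d <= tolerance_bp)
    if (length(hit) == 1) names(reference_lengths)[hit] else "UNKNOWN"
  }, character(1))
}

#' Consensus genotype call at one scat x locus from replicate PCRs
#'
#' Acceptance rules for low-template fecal DNA: a heterozygous pair is
#' accepted only if that exact unordered pair is observed in at least
#' \code{min_obs} successful PCRs; a homozygote is accepted only if every
#' successful PCR shows only that single allele and at least \code{min_obs}
#' PCRs did so. Failed PCRs count neither for nor against. Anything else is
#' NO_CALL (ALL_FAILED when no PCR succeeded). Replicate order never affects
#' the result.
#'
#' @param calls data.frame with columns allele_a, allele_b (one row per
#'   PCR; NA,NA = failed; a==b = single allele observed).
#' @param min_obs minimum supporting PCRs (default 3).
#' @return list(status, genotype = c(a, b) or NULL, n_successful_pcrs,
#'   n_supporting_pcrs).
#' @export
call_locus_consensus <- function(calls, min_obs = 3) {
  ok <- !is.na(calls$allele_a)
  n_succ <- sum(ok)
  if (n_succ == 0)
    return(list(status = "ALL_FAILED", genotype = NULL,
                n_successful_pcrs = 0L, n_supporting_pcrs = 0L))
  a <- calls$allele_a[ok]; b <- calls$allele_b[ok]
  het <- a != b
  # heterozygote rule: identical pair in >= min_obs successful PCRs
  if (any(het)) {
    key <- paste(a[het], b[het])
    tab <- sort(table(key), decreasing = TRUE)
    if (tab[1] >= min_obs && sum(tab == tab[1]) == 1) {
      pair <- as.integer(strsplit(names(tab)[1], " ")[[1]])
      return(list(status = "ACCEPTED_HET", genotype = pair,
                  n_successful_pcrs = n_succ,
                  n_supporting_pcrs = as.integer(tab[1])))
    }
  }
  # homozygote rule: one allele, seen alone in ALL successful PCRs
  if (!any(het) && length(unique(a)) == 1 && n_succ >= min_obs) {
    return(list(status = "ACCEPTED_HOM", genotype = c(a[1], a[1]),
                n_successful_pcrs = n_succ, n_supporting_pcrs = n_succ))
  }
  list(status = "NO_CALL", genotype = NULL,
       n_successful_pcrs = n_succ, n_supporting_pcrs = 0L)
}

#' Build a per-scat consensus profile
#'
#' Applies \code{\link{call_locus_consensus}} to every locus of one scat and
#' the two sample-retention filters: scats amplifying (any successful PCR) at
#' fewer than \code{min_amplified} loci are screened out, and a scat is
#' retained for identification only if it is the focal species and holds
#' accepted consensus calls at \code{min_consensus} or more loci.
#'
#' @param scat_replicates replicate_set rows for one scat.
#' @param species species label for the scat.
#' @param min_obs,min_amplified,min_consensus thresholds (defaults 3, 4, 6).
#' @param focal_species species retained for analysis (default "BOBCAT").
#' @return scat_profile: list(scat_id, species, calls, n_amplified_loci,
#'   n_consensus_loci, screened_out, retained).
#' @export
build_scat_profile <- function(scat_replicates, species, min_obs = 3,
                               min_amplified = 4, min_consensus = 6,
                               focal_species = "BOBCAT") {
  scat_id <- unique(scat_replicates$scat_id)
  stopifnot(length(scat_id) == 1)
  calls <- lapply(split(scat_replicates, scat_replicates$locus_id),
                  call_locus_consensus, min_obs = min_obs)
  n_amp <- sum(vapply(calls, function(cl) cl$n_successful_pcrs > 0, logical(1)))
  n_con <- sum(vapply(calls, function(cl)
    cl$status %in% c("ACCEPTED_HET", "ACCEPTED_HOM"), logical(1)))
  structure(list(scat_id = scat_id, species = species, calls = calls,
                 n_amplified_loci = n_amp, n_consensus_loci = n_con,
                 screened_out = n_amp < min_amplified,
                 retained = identical(species, focal_species) &&
                            n_amp >= min_amplified && n_con >= min_consensus),
            class = "scat_profile")
}

#' Consensus profiles for every scat in a replicate set
#'
#' @param replicates replicate_set.
#' @param species named character vector (names = scat ids) or data.frame
#'   (scat_id, species).
#' @inheritParams build_scat_profile
#' @return named list of scat_profile objects.
#' @export
build_scat_profiles <- function(replicates, species, min_obs = 3,
                                min_amplified = 4, min_consensus = 6,
                                focal_species = "BOBCAT") {
  if (is.data.frame(species))
    species <- setNames(species$species, species$scat_id)
  by_scat <- split(as.data.frame(replicates), replicates$scat_id)
  out <- lapply(names(by_scat), function(sid)
    build_scat_profile(by_scat[[sid]],
                       species = if (sid %in% names(species)) species[[sid]]
                                 else "UNKNOWN",
                       min_obs = min_obs, min_amplified = min_amplified,
                       min_consensus = min_consensus,
                       focal_species = focal_species))
  names(out) <- names(by_scat)
  out
}

#' Genotype table of retained scat profiles
#'
#' Accepted consensus calls become genotypes; unaccepted loci are missing.
#'
#' @param profiles list of scat_profile.
#' @param retained_only keep only retained profiles (default TRUE).
#' @return genotype_table keyed by scat_id.
#' @export
profiles_to_genotypes <- function(profiles, retained_only = TRUE) {
  keep <- if (retained_only)
    Filter(function(p) isTRUE(p$retained), profiles) else profiles
  if (length(keep) == 0) stop("no retained scat profiles")
  rows <- do.call(rbind, lapply(keep, function(p) {
    do.call(rbind, lapply(names(p$calls), function(l) {
      cl <- p$calls[[l]]
      g <- if (!is.null(cl$genotype)) cl$genotype else c(NA_integer_, NA_integer_)
      data.frame(sample_id = p$scat_id, locus_id = l,
                 allele_a = g[1], allele_b = g[2], stringsAsFactors = FALSE)
    }))
  }))
  genotype_table(rows)
}

#' Wrap an already-consensused genotype table as scat profiles
#'
#' Entry point for datasets where consensus calling was done upstream and
#' only per-scat multilocus genotypes are available: each non-missing
#' genotype becomes an accepted call so matching and clustering can run.
#'
#' @param gt genotype_table keyed by scat_id.
#' @param species species label applied to all scats (default "BOBCAT").
#' @param min_consensus retention threshold (default 6).
#' @return named list of scat_profile objects.
#' @export
genotypes_to_profiles <- function(gt, species = "BOBCAT", min_consensus = 6) {
  out <- lapply(unique(gt$sample_id), function(sid) {
    rows <- gt[gt$sample_id == sid, ]
    calls <- setNames(lapply(seq_len(nrow(rows)), function(i) {
      if (is.na(rows$allele_a[i]))
        list(status = "ALL_FAILED", genotype = NULL,
             n_successful_pcrs = 0L, n_supporting_pcrs = 0L)
      else
        list(status = if (rows$allele_a[i] == rows$allele_b[i])
               "ACCEPTED_HOM" else "ACCEPTED_HET",
             genotype = c(rows$allele_a[i], rows$allele_b[i]),
             n_successful_pcrs = NA_integer_, n_supporting_pcrs = NA_integer_)
    }), rows$locus_id)
    n_con <- sum(!is.na(rows$allele_a))
    structure(list(scat_id = sid, species = species, calls = calls,
                   n_amplified_loci = n_con, n_consensus_loci = n_con,
                   screened_out = FALSE,
                   retained = n_con >= min_consensus),
              class = "scat_profile")
  })
  names(out) <- unique(gt$sample_id)
  out
}

#' Per-locus amplification and genotyping rates across scats
#'
#' Amplification rate = fraction of scat x PCR reactions at the locus that
#' succeeded; genotyping rate = fraction of scats with an accepted consensus
#' call at the locus. These are the survey's quality diagnostics.
#'
#' @param replicates replicate_set.
#' @param profiles list of scat_profile (same scats).
#' @return data.frame(locus_id, amplification_rate, genotyping_rate).
#' @export
locus_rates <- function(replicates, profiles) {
  by_locus <- split(as.data.frame(replicates), replicates$locus_id)
  amp <- vapply(by_locus, function(d) mean(!is.na(d$allele_a)), numeric(1))
  loci <- names(by_locus)
  gtyped <- vapply(loci, function(l) {
    mean(vapply(profiles, function(p)
      p$calls[[l]]$status %in% c("ACCEPTED_HET", "ACCEPTED_HOM"), logical(1)))
  }, numeric(1))
  data.frame(locus_id = loci, amplification_rate = as.numeric(amp),
             genotyping_rate = as.numeric(gtyped), stringsAsFactors = FALSE,
             row.names = NULL)
}
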