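# Shared fixtures and independent oracles, built in code at test time.

# balanced k-allele frequency panel over n loci
eq_freqs <- function(n_loci, k) {
  as_allele_freqs(setNames(
    lapply(seq_len(n_loci), function(i)
      setNames(rep(1 / k, k), as.character(100 + 2 * (0:(k - 1))))),
    sprintf("L%02d", seq_len(n_loci))))
}

# a genotype table built from a list: list(sample = list(locus = c(a, b)))
gt_from_list <- function(x) {
  rows <- do.call(rbind, lapply(names(x), function(s) {
    do.call(rbind, lapply(names(x[[s]]), function(l) {
      g <- x[[s]][[l]]
      data.frame(sample_id = s, locus_id = l, allele_a = g[1], allele_b = g[2],
                 stringsAsFactors = FALSE)
    }))
  }))
  genotype_table(rows)
}

# a minimal scat_profile with accepted calls at the given genotypes
fake_profile <- function(scat_id, genotypes, species = "BOBCAT") {
  calls <- lapply(genotypes, function(g) {
    if (anyNA(g)) list(status = "NO_CALL", genotype = NULL,
                       n_successful_pcrs = 3L, n_supporting_pcrs = 0L)
    else list(status = if (g[1] == g[2]) "ACCEPTED_HOM" else "ACCEPTED_HET",
              genotype = as.integer(sort(g)), n_successful_pcrs = 3L,
              n_supporting_pcrs = 3L)
  })
  n_con <- sum(vapply(calls, function(cl)
    cl$status %in% c("ACCEPTED_HET", "ACCEPTED_HOM"), logical(1)))
  structure(list(scat_id = scat_id, species = species, calls = calls,
                 n_amplified_loci = length(calls), n_consensus_loci = n_con,
                 screened_out = FALSE,
                 retained = species == "BOBCAT" && n_con >= 6),
            class = "scat_profile")
}

# replicate calls for one scat x locus as a data.frame; each element of
# `pcrs` is c(a, b) or NA (failed)
rep_calls <- function(pcrs) {
  do.call(rbind, lapply(seq_along(pcrs), function(i) {
    g <- pcrs[[i]]
    if (length(g) == 1 && is.na(g)) g <- c(NA_integer_, NA_integer_)
    data.frame(scat_id = "S1", pcr_id = paste0("P", i), locus_id = "L1",
               allele_a = min(g), allele_b = max(g), stringsAsFactors = FALSE)
  }))
}

# exact-enumeration oracle for PID: sum over genotypes of P(g)^2 under HWE
pid_enum <- function(p) {
  al <- seq_along(p)
  tot <- 0
  for (i in al) for (j in al[al >= i]) {
    pg <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
    tot <- tot + pg^2
  }
  tot
}

# exact-enumeration oracle for PIDsib: enumerate parental genotype pairs,
# then the Mendelian offspring distribution, then P(two sibs identical)
pidsib_enum <- function(p) {
  al <- seq_along(p)
  genos <- list()
  for (i in al) for (j in al[al >= i]) genos[[length(genos) + 1]] <- c(i, j)
  gp <- vapply(genos, function(g)
    if (g[1] == g[2]) p[g[1]]^2 else 2 * p[g[1]] * p[g[2]], numeric(1))
  tot <- 0
  for (f in seq_along(genos)) for (m in seq_along(genos)) {
    # offspring genotype distribution for this parent pair
    off <- table(vapply(1:4, function(c4) {
      a <- genos[[f]][(c4 - 1) %/% 2 + 1]
      b <- genos[[m]][(c4 - 1) %% 2 + 1]
      paste(min(a, b), max(a, b))
    }, character(1))) / 4
    tot <- tot + gp[f] * gp[m] * sum(off^2)
  }
  tot
}

# canonical signature of a partition (list of character vectors)
partition_key <- function(groups) {
  paste(sort(vapply(groups, function(g) paste(sort(g), collapse = ","),
                    character(1))), collapse = ";")
}

# truth partition of retained scats by unique multilocus genotype
truth_partition <- function(sim, retained_ids) {
  truthmap <- setNames(sim$scats$individual_id, sim$scats$scat_id)
  gt <- sim$population$genotypes
  gkey <- vapply(unique(truthmap[retained_ids]), function(id) {
    r <- gt[gt$sample_id == id, ]
    paste(r$allele_a, r$allele_b, collapse = "|")
  }, character(1))
  split(retained_ids, gkey[truthmap[retained_ids]])
}
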