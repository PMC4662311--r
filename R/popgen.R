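#' Heterozygosity and allelic richness per locus
#'
#' Observed heterozygosity Ho is the fraction of heterozygotes among typed
#' individuals; expected heterozygosity He = 1 - sum(p_i^2); unbiased
#' expected heterozygosity uHe = 2n/(2n-1) * He (Nei's small-sample
#' correction with n typed individuals); A is the allele count. Allelic
#' richness is reported as the raw mean allele count over loci (the total
#' number of alleles observed, not a rarefied richness). Means carry their
#' standard errors over loci.
#'
#' @param gt genotype_table.
#' @return list(per_locus = data.frame(locus_id, n_typed, A, Ho, He, uHe),
#'   mean_Ho, se_Ho, mean_He, se_He, mean_uHe, se_uHe, AR).
#' @export
heterozygosity_stats <- function(gt) {
  freqs <- allele_frequencies(gt)
  per <- do.call(rbind, lapply(names(freqs), function(l) {
    rows <- gt[gt$locus_id == l & !is.na(gt$allele_a), ]
    n <- nrow(rows)
    p <- freqs[[l]]$freq
    He <- 1 - sum(p^2)
    data.frame(locus_id = l, n_typed = n, A = length(p),
               Ho = mean(rows$allele_a != rows$allele_b),
               He = He, uHe = He * 2 * n / (2 * n - 1),
               stringsAsFactors = FALSE)
  }))
  se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  list(per_locus = per,
       mean_Ho = mean(per$Ho), se_Ho = se(per$Ho),
       mean_He = mean(per$He), se_He = se(per$He),
       mean_uHe = mean(per$uHe), se_uHe = se(per$uHe),
       AR = mean(per$A))
}

#' Hardy-Weinberg equilibrium test at one locus
#'
#' Chi-square goodness of fit over all k(k+1)/2 genotype categories with
#' expected counts from the sample allele frequencies, df = k(k-1)/2.
#' Optionally a Monte Carlo exact test: alleles are permuted among
#' genotypes and the chi-square statistic recomputed; the p-value is the
#' fraction of permuted statistics at least as large as the observed one
#' (with the observed table counted once).
#'
#' @param gt genotype_table.
#' @param locus locus_id to test.
#' @param method "chi2" (default) or "exact".
#' @param n_perm Monte Carlo permutations for the exact test.
#' @param seed seed for the exact test.
#' @return list(locus_id, chi2, df, p, method, n_typed, reliable).
#'   Monomorphic loci return NA statistics.
#' @export
hwe_test <- function(gt, locus, method = c("chi2", "exact"),
                     n_perm = 10000, seed = 1) {
  method <- match.arg(method)
  rows <- gt[gt$locus_id == locus & !is.na(gt$allele_a), ]
  n <- nrow(rows)
  alleles <- sort(unique(c(rows$allele_a, rows$allele_b)))
  k <- length(alleles)
  if (k < 2)
    return(list(locus_id = locus, chi2 = NA_real_, df = NA_integer_,
                p = NA_real_, method = method, n_typed = n, reliable = FALSE))
  chi2_stat <- function(a, b) {
    p <- table(factor(c(a, b), levels = alleles)) / (2 * length(a))
    obs <- table(factor(paste(pmin(a, b), pmax(a, b)),
                        levels = outer_pairs(alleles)))
    expc <- vapply(names(obs), function(key) {
      ij <- as.integer(strsplit(key, " ")[[1]])
      pi <- p[[as.character(ij[1])]]; pj <- p[[as.character(ij[2])]]
      if (ij[1] == ij[2]) length(a) * pi^2 else length(a) * 2 * pi * pj
    }, numeric(1))
    ok <- expc > 0
    sum((as.numeric(obs)[ok] - expc[ok])^2 / expc[ok])
  }
  chi2 <- chi2_stat(rows$allele_a, rows$allele_b)
  df <- k * (k - 1) / 2
  if (method == "chi2") {
    p <- pchisq(chi2, df, lower.tail = FALSE)
  } else {
    pool <- c(rows$allele_a, rows$allele_b)
    hits <- with_seed(seed, {
      h <- 0
      for (r in seq_len(n_perm)) {
        perm <- sample(pool)
        if (chi2_stat(perm[seq_len(n)], perm[n + seq_len(n)]) >= chi2 - 1e-12)
          h <- h + 1
      }
      h
    })
    p <- (hits + 1) / (n_perm + 1)
  }
  list(locus_id = locus, chi2 = chi2, df = df, p = p, method = method,
       n_typed = n, reliable = n >= 5)
}

outer_pairs <- function(alleles) {
  out <- character(0)
  for (i in seq_along(alleles)) for (j in i:length(alleles))
    out <- c(out, paste(alleles[i], alleles[j]))
  out
}

#' HWE tests at every locus
#' @inheritParams hwe_test
#' @return data.frame(locus_id, chi2, df, p, n_typed, reliable).
#' @export
hwe_test_all <- function(gt, method = "chi2", n_perm = 10000, seed = 1) {
  do.call(rbind, lapply(unique(gt$locus_id), function(l) {
    h <- hwe_test(gt, l, method, n_perm, seed)
    data.frame(locus_id = l, chi2 = h$chi2, df = h$df, p = h$p,
               n_typed = h$n_typed, reliable = h$reliable,
               stringsAsFactors = FALSE)
  }))
}

#' Per-locus and mean FIS
#'
#' FIS = (He - Ho)/He with He = 1 - sum(p_i^2), the within-individual share
#' of subpopulation genetic variance; negative values indicate heterozygote
#' excess. Monomorphic loci (He = 0) are excluded; the mean is unweighted
#' over polymorphic loci and carries its SE.
#'
#' @param gt genotype_table.
#' @return list(per_locus = data.frame(locus_id, Ho, He, FIS), mean_FIS,
#'   se_FIS).
#' @export
fis <- function(gt) {
  hs <- heterozygosity_stats(gt)$per_locus
  poly <- hs[hs$He > 0, ]
  if (nrow(poly) == 0) stop("no polymorphic loci")
  poly$FIS <- (poly$He - poly$Ho) / poly$He
  list(per_locus = poly[c("locus_id", "Ho", "He", "FIS")],
       mean_FIS = mean(poly$FIS),
       se_FIS = if (nrow(poly) > 1) sd(poly$FIS) / sqrt(nrow(poly)) else NA_real_)
}

#' Effective number of breeders from the per-breeding-cycle excess-heterozygosity formula
#'
#' When few breeders produce a cohort, binomial sampling of parental alleles
#' inflates heterozygosity above its expectation; the excess
#' D = (Ho - He)/He converts to the effective number of breeders as
#' \eqn{Nb = 1/(2\bar D) + 1/(2(\bar D + 1))}.
#'
#' @param D weighted mean heterozygote-excess statistic.
#' @return Nb (Inf when D <= 0, by convention: no excess, no information).
#' @export
nb_from_D <- function(D) {
  if (!is.finite(D) || D <= 0) return(Inf)
  1 / (2 * D) + 1 / (2 * (D + 1))
}

#' Heterozygote-excess estimator of the effective number of breeders
#'
#' Per locus D_l = (Ho_l - He_l)/He_l; the mean weighted D weights loci by
#' their number of independent alleles (k_l - 1), and an unweighted mean is
#' also reported. Nb comes from \code{\link{nb_from_D}}; the confidence
#' interval is a jackknife over loci on the D scale, with Nb bounds obtained
#' by transforming the D bounds (upper bound Inf whenever the lower D bound
#' is <= 0).
#'
#' @param gt genotype_table.
#' @param conf confidence level (default 0.95).
#' @return list(D_weighted, D_unweighted, Nb, Nb_unweighted, ci = c(lower,
#'   upper), per_locus).
#' @export
ne_heterozygote_excess <- function(gt, conf = 0.95) {
  hs <- heterozygosity_stats(gt)$per_locus
  poly <- hs[hs$He > 0, ]
  if (nrow(poly) == 0) stop("all loci monomorphic: D undefined")
  poly$D <- (poly$Ho - poly$He) / poly$He
  w <- poly$A - 1
  Dw <- sum(w * poly$D) / sum(w)
  Du <- mean(poly$D)
  L <- nrow(poly)
  if (L > 1) {
    jack <- vapply(seq_len(L), function(i)
      sum(w[-i] * poly$D[-i]) / sum(w[-i]), numeric(1))
    se_D <- sqrt((L - 1) / L * sum((jack - mean(jack))^2))
    z <- qnorm(1 - (1 - conf) / 2)
    D_lo <- Dw - z * se_D; D_hi <- Dw + z * se_D
    ci <- c(lower = nb_from_D(D_hi), upper = nb_from_D(D_lo))
  } else {
    ci <- c(lower = NA_real_, upper = NA_real_)
  }
  list(D_weighted = Dw, D_unweighted = Du,
       Nb = nb_from_D(Dw), Nb_unweighted = nb_from_D(Du),
       ci = ci, per_locus = poly[c("locus_id", "A", "Ho", "He", "D")])
}

#' Molecular-coancestry estimator of the effective number of breeders
#'
#' Pairwise molecular similarity at a locus for genotypes (a,b) and (c,d) is
#' f0 = [I(a=c)+I(a=d)+I(b=c)+I(b=d)]/4. In a single offspring cohort
#' produced by Nb random-mating unrelated breeders, the expected
#' between-individual similarity exceeds identity-in-state by
#' (1 - s)/(2 Nb), and the within-individual identity (observed
#' homozygosity) is an unbiased estimate of the identity-in-state s of the
#' parental gene pool. The corrected mean coancestry per locus is therefore
#' f1_l = (mean f0_l - s_l)/(1 - s_l) with s_l = observed homozygote
#' fraction, averaged over loci, and the single-cohort estimator is
#' Nb = 1/(2 f1) (Inf when f1 <= 0, by convention). The CI is a jackknife
#' over loci on the f1 scale.
#'
#' @param gt genotype_table of one cohort (>= 2 individuals).
#' @param conf confidence level.
#' @return list(f1, Nb, ci, n_pairs, per_locus).
#' @export
ne_coancestry <- function(gt, conf = 0.95) {
  ids <- unique(gt$sample_id)
  if (length(ids) < 2) stop("need >= 2 individuals")
  loci <- unique(gt$locus_id)
  f1l <- vapply(loci, function(l) {
    rows <- gt[gt$locus_id == l & !is.na(gt$allele_a), ]
    n <- nrow(rows)
    if (n < 2) return(NA_real_)
    G <- cbind(rows$allele_a, rows$allele_b)
    s <- mean(G[, 1] == G[, 2])
    if (s >= 1) return(NA_real_)  # no heterozygotes: identity saturated
    f0 <- 0; cnt <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      f0 <- f0 + (sum(G[i, 1] == G[j, ]) + sum(G[i, 2] == G[j, ])) / 4
      cnt <- cnt + 1
    }
    (f0 / cnt - s) / (1 - s)
  }, numeric(1))
  use <- which(!is.na(f1l))
  if (length(use) == 0) stop("no usable polymorphic loci")
  f1 <- mean(f1l[use])
  Nb <- if (f1 <= 0) Inf else 1 / (2 * f1)
  if (length(use) > 1) {
    jack <- vapply(seq_along(use), function(i) mean(f1l[use[-i]]), numeric(1))
    se_f <- sqrt((length(use) - 1) / length(use) *
                   sum((jack - mean(jack))^2))
    z <- qnorm(1 - (1 - conf) / 2)
    f_lo <- f1 - z * se_f; f_hi <- f1 + z * se_f
    ci <- c(lower = if (f_hi <= 0) Inf else 1 / (2 * f_hi),
            upper = if (f_lo <= 0) Inf else 1 / (2 * f_lo))
  } else ci <- c(lower = NA_real_, upper = NA_real_)
  n <- length(ids)
  list(f1 = f1, Nb = Nb, ci = ci, n_pairs = n * (n - 1) / 2,
       per_locus = data.frame(locus_id = loci, f1 = f1l,
                              stringsAsFactors = FALSE))
}
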