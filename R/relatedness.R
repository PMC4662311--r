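#' Extract one sample's genotypes as a named per-locus list
#' @param gt genotype_table.
#' @param sample_id sample to extract.
#' @return named list locus_id -> integer pair (missing loci are NA pairs).
#' @export
genotype_list <- function(gt, sample_id) {
  rows <- gt[gt$sample_id == sample_id, ]
  if (nrow(rows) == 0) stop("unknown sample: ", sample_id)
  setNames(lapply(seq_len(nrow(rows)),
                  function(i) c(rows$allele_a[i], rows$allele_b[i])),
           rows$locus_id)
}

# Per-locus probabilities of an unordered genotype pair given 0/1/2 alleles
# shared identical by descent (non-inbred dyad tables). Returns a 3 x L
# matrix (rows P0, P1, P2) over co-typed loci present in `freqs`.
dyad_P012 <- function(g1, g2, freqs) {
  loci <- intersect(names(freqs),
                    intersect(names(g1)[!vapply(g1, anyNA, logical(1))],
                              names(g2)[!vapply(g2, anyNA, logical(1))]))
  P <- matrix(0, 3, length(loci), dimnames = list(c("P0", "P1", "P2"), loci))
  for (l in loci) {
    p <- freqs[[l]]$freq
    pr <- function(al) {
      f <- p[as.character(al)]
      if (anyNA(f)) stop("allele ", al[is.na(f)][1],
                         " absent from frequency vector at locus ", l)
      unname(f)
    }
    a <- sort(g1[[l]]); b <- sort(g2[[l]])
    ha <- a[1] == a[2]; hb <- b[1] == b[2]
    hwe <- function(g) if (g[1] == g[2]) pr(g[1])^2 else 2 * pr(g[1]) * pr(g[2])
    P0 <- hwe(a) * hwe(b)
    shared <- intersect(a, b)
    if (ha && hb) {
      if (a[1] == b[1]) { P1 <- pr(a[1])^3; P2 <- pr(a[1])^2 }
      else { P1 <- 0; P2 <- 0 }
    } else if (ha || hb) {
      hom <- if (ha) a else b; het <- if (ha) b else a
      if (hom[1] %in% het) { P1 <- pr(hom[1])^2 * pr(setdiff(het, hom[1])); P2 <- 0 }
      else { P1 <- 0; P2 <- 0 }
    } else {
      if (identical(a, b)) {
        P1 <- pr(a[1]) * pr(a[2]) * (pr(a[1]) + pr(a[2]))
        P2 <- 2 * pr(a[1]) * pr(a[2])
      } else if (length(shared) == 1) {
        s <- shared
        P1 <- pr(s) * pr(setdiff(a, s)) * pr(setdiff(b, s))
        P2 <- 0
      } else { P1 <- 0; P2 <- 0 }
    }
    P[, l] <- c(P0, P1, P2)
  }
  P
}

#' Log-likelihood of a dyad's genotypes given IBD-sharing probabilities
#'
#' Per co-typed locus, P(g1, g2 | k) = k0 P0 + k1 P1 + k2 P2, where P0 is
#' the product of the two Hardy-Weinberg genotype probabilities and P1/P2
#' are the standard one-/two-alleles-IBD terms for unordered genotypes
#' (non-inbred dyads). The log-likelihood sums over co-typed loci; missing
#' loci are skipped.
#'
#' @param g1,g2 named per-locus genotype lists (see
#'   \code{\link{genotype_list}}).
#' @param k numeric length-3 vector (k0, k1, k2), summing to 1.
#' @param freqs allele_freqs.
#' @return log-likelihood (can be -Inf, e.g. a parent-offspring k with a
#'   locus sharing no allele).
#' @export
dyad_loglik <- function(g1, g2, k, freqs) {
  if (abs(sum(k) - 1) > 1e-9 || any(k < -1e-12))
    stop("k must be a probability vector over 0/1/2 IBD alleles")
  P <- dyad_P012(g1, g2, freqs)
  if (ncol(P) == 0) stop("no co-typed locus")
  sum(log(as.numeric(k %*% P)))
}

# Delta-step simplex grid over (k0, k1, k2); cached per step size.
.k_grid_cache <- new.env(parent = emptyenv())
k_simplex_grid <- function(step = 0.01) {
  key <- format(step, digits = 12)
  if (!is.null(.k_grid_cache[[key]])) return(.k_grid_cache[[key]])
  v <- seq(0, 1, by = step)
  g <- expand.grid(k0 = v, k1 = v, KEEP.OUT.ATTRS = FALSE)
  g <- g[g$k0 + g$k1 <= 1 + 1e-12, ]
  G <- cbind(k0 = g$k0, k1 = g$k1, k2 = pmax(0, 1 - g$k0 - g$k1))
  .k_grid_cache[[key]] <- G
  G
}

#' Maximum-likelihood relatedness of a dyad over the k simplex
#'
#' Maximizes \code{\link{dyad_loglik}} over all (k0, k1, k2) by a 0.01-step
#' grid search followed by a 0.001-step local refinement around the best
#' grid point. Relatedness is r = k1/2 + k2. Likelihood ties are broken
#' toward smaller r.
#'
#' @param g1,g2 named per-locus genotype lists.
#' @param freqs allele_freqs.
#' @return list(status, k = c(k0,k1,k2), r, loglik). status "UNDEFINED" when
#'   every co-typed locus is monomorphic (or none is co-typed).
#' @export
estimate_r_ml <- function(g1, g2, freqs) {
  P <- dyad_P012(g1, g2, freqs)
  poly <- vapply(colnames(P), function(l) length(freqs[[l]]$freq) > 1,
                 logical(1))
  if (ncol(P) == 0 || !any(poly))
    return(list(status = "UNDEFINED", k = rep(NA_real_, 3), r = NA_real_,
                loglik = NA_real_))
  best <- grid_best(k_simplex_grid(0.01), P)
  # local refinement on a fine grid clipped to the simplex
  fine <- local_k_grid(best$k, half_width = 0.01, step = 0.001)
  ref <- grid_best(fine, P)
  if (ref$loglik > best$loglik + 1e-12) best <- ref
  list(status = "OK", k = unname(best$k),
       r = unname(best$k[2] / 2 + best$k[3]), loglik = best$loglik)
}

grid_best <- function(G, P) {
  L <- G %*% P                       # npts x nloci per-locus likelihoods
  ll <- rowSums(log(pmax(L, 1e-300)))
  r <- G[, 2] / 2 + G[, 3]
  top <- which(ll >= max(ll) - 1e-12)
  pick <- top[which.min(r[top])]     # tie -> smaller r
  list(k = G[pick, ], loglik = ll[pick])
}

local_k_grid <- function(k, half_width, step) {
  v0 <- seq(max(0, k[1] - half_width), min(1, k[1] + half_width), by = step)
  v1 <- seq(max(0, k[2] - half_width), min(1, k[2] + half_width), by = step)
  g <- expand.grid(k0 = v0, k1 = v1, KEEP.OUT.ATTRS = FALSE)
  g <- g[g$k0 + g$k1 <= 1 + 1e-12, ]
  cbind(k0 = g$k0, k1 = g$k1, k2 = pmax(0, 1 - g$k0 - g$k1))
}

# canonical IBD-sharing anchors for the four pedigree relationships
relationship_anchors <- function() {
  list(U = c(1, 0, 0), HS = c(0.5, 0.5, 0),
       FS = c(0.25, 0.5, 0.25), PO = c(0, 1, 0))
}

#' Most likely pedigree relationship of a dyad
#'
#' Evaluates the dyad log-likelihood at the four canonical IBD anchors,
#' unrelated U = (1,0,0), half-sib HS = (0.5,0.5,0), full-sib
#' FS = (0.25,0.5,0.25) and parent-offspring PO = (0,1,0), and returns the
#' best. Ties are broken toward the less related category (U > HS > FS >
#' PO).
#'
#' @param g1,g2 named per-locus genotype lists.
#' @param freqs allele_freqs.
#' @return list(status, category, loglik = named vector over the four
#'   anchors).
#' @export
classify_relationship <- function(g1, g2, freqs) {
  P <- dyad_P012(g1, g2, freqs)
  poly <- vapply(colnames(P), function(l) length(freqs[[l]]$freq) > 1,
                 logical(1))
  if (ncol(P) == 0 || !any(poly))
    return(list(status = "UNDEFINED", category = NA_character_,
                loglik = NULL))
  anchors <- relationship_anchors()
  ll <- vapply(anchors, function(k)
    sum(log(pmax(as.numeric(k %*% P), 0))), numeric(1))
  best <- names(ll)[which.max(ll)]   # which.max takes the first max: U>HS>FS>PO
  list(status = "OK", category = best, loglik = ll)
}

#' Maximum-likelihood individual inbreeding coefficient
#'
#' Maximizes over F in [0, 1] the product across typed polymorphic loci of
#' P(aa | F) = p_a^2 + F p_a (1 - p_a) and P(ab | F) = 2 p_a p_b (1 - F).
#' The confidence interval is a percentile bootstrap over loci.
#'
#' @param genotype named per-locus genotype list for one individual.
#' @param freqs allele_freqs.
#' @param n_boot bootstrap replicates (default 100).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level.
#' @return list(F, ci = c(lower, upper), n_loci, loglik).
#' @export
estimate_F_ml <- function(genotype, freqs, n_boot = 100, seed = 1,
                          conf = 0.95) {
  loci <- intersect(names(freqs),
                    names(genotype)[!vapply(genotype, anyNA, logical(1))])
  loci <- loci[vapply(loci, function(l) length(freqs[[l]]$freq) > 1,
                      logical(1))]
  if (length(loci) < 3) stop("need >= 3 typed polymorphic loci")
  terms <- lapply(loci, function(l) {
    p <- freqs[[l]]$freq
    g <- genotype[[l]]
    pa <- unname(p[as.character(g[1])]); pb <- unname(p[as.character(g[2])])
    if (is.na(pa) || is.na(pb)) stop("allele absent from frequencies at ", l)
    if (g[1] == g[2]) c(hom = 1, p1 = pa, p2 = pa) else c(hom = 0, p1 = pa, p2 = pb)
  })
  Tm <- do.call(rbind, terms)
  ll_of <- function(F_, idx = seq_len(nrow(Tm))) {
    t <- Tm[idx, , drop = FALSE]
    l_hom <- log(t[, "p1"]^2 + F_ * t[, "p1"] * (1 - t[, "p1"]))
    l_het <- log(pmax(2 * t[, "p1"] * t[, "p2"] * (1 - F_), 1e-300))
    sum(ifelse(t[, "hom"] == 1, l_hom, l_het))
  }
  fhat_of <- function(idx) {
    opt <- optimize(ll_of, c(0, 1), idx = idx, maximum = TRUE, tol = 1e-9)
    cand <- c(0, opt$maximum, 1)
    cand[which.max(vapply(cand, ll_of, numeric(1), idx = idx))]
  }
  Fhat <- fhat_of(seq_len(nrow(Tm)))
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(b)
    fhat_of(sample.int(nrow(Tm), replace = TRUE)), numeric(1)))
  alpha <- (1 - conf) / 2
  list(F = Fhat,
       ci = unname(quantile(boot, c(alpha, 1 - alpha), names = FALSE)),
       n_loci = length(loci), loglik = ll_of(Fhat))
}

#' Pairwise relatedness matrix with ML estimates and best categories
#'
#' Runs \code{\link{estimate_r_ml}} and \code{\link{classify_relationship}}
#' on every unordered pair of individuals, using allele frequencies computed
#' from the supplied (composite) genotypes unless given.
#'
#' @param gt genotype_table of individuals.
#' @param freqs optional allele_freqs (computed from \code{gt} if NULL).
#' @return list(individuals, r = symmetric matrix (NA diagonal), category =
#'   character matrix, n_cotyped = integer matrix).
#' @export
relatedness_matrix <- function(gt, freqs = NULL) {
  ids <- unique(gt$sample_id)
  if (length(ids) < 2) stop("need >= 2 individuals")
  if (is.null(freqs)) freqs <- allele_frequencies(gt)
  gls <- lapply(ids, function(id) genotype_list(gt, id))
  names(gls) <- ids
  n <- length(ids)
  R <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  Cat <- matrix(NA_character_, n, n, dimnames = list(ids, ids))
  Nc <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    est <- estimate_r_ml(gls[[i]], gls[[j]], freqs)
    cls <- classify_relationship(gls[[i]], gls[[j]], freqs)
    R[i, j] <- R[j, i] <- est$r
    Cat[i, j] <- Cat[j, i] <- cls$category
    Nc[i, j] <- Nc[j, i] <- ncol(dyad_P012(gls[[i]], gls[[j]], freqs))
  }
  list(individuals = ids, r = R, category = Cat, n_cotyped = Nc)
}

#' Summarize a pairwise relatedness matrix
#'
#' Mean and SD over the n(n-1)/2 unordered pairs, plus counts of pairs below
#' the first threshold (near-zero, i.e. typical of unrelated animals), at or
#' above the second, and strictly above the second.
#'
#' @param r symmetric relatedness matrix (or an upper-triangle vector).
#' @param bins two thresholds, default c(0.25, 0.5).
#' @return list(mean, sd, n_pairs, n_below, n_at_or_above, n_above).
#' @export
summarize_relatedness <- function(r, bins = c(0.25, 0.5)) {
  vals <- if (is.matrix(r)) r[upper.tri(r)] else as.numeric(r)
  vals <- vals[!is.na(vals)]
  list(mean = mean(vals), sd = sd(vals), n_pairs = length(vals),
       n_below = sum(vals < bins[1]),
       n_at_or_above = sum(vals >= bins[2]),
       n_above = sum(vals > bins[2]))
}

#' Simulate genotype dyads with a given IBD-sharing structure
#'
#' Per locus, the number of IBD alleles is drawn from k; shared alleles are
#' drawn once from the locus frequencies and placed in both genotypes,
#' remaining alleles independently. Used as the simulation oracle for the
#' dyad likelihood and the recovery tests.
#'
#' @param n_dyads number of dyads.
#' @param k IBD vector (k0, k1, k2) or anchor name "U"/"HS"/"FS"/"PO".
#' @param freqs allele_freqs.
#' @param seed RNG seed.
#' @return list of list(g1, g2) named per-locus genotype lists.
#' @export
simulate_dyads <- function(n_dyads, k, freqs, seed = 1) {
  if (is.character(k)) k <- relationship_anchors()[[k]]
  stopifnot(abs(sum(k) - 1) < 1e-9)
  loci <- names(freqs)
  draw <- function(l, n) {
    f <- freqs[[l]]$freq
    as.integer(sample(names(f), n, replace = TRUE, prob = f))
  }
  with_seed(seed, lapply(seq_len(n_dyads), function(d) {
    g1 <- list(); g2 <- list()
    for (l in loci) {
      m <- sample(0:2, 1, prob = k)
      sh <- if (m > 0) draw(l, m) else integer(0)
      g1[[l]] <- sort(c(sh, draw(l, 2 - m)))
      g2[[l]] <- sort(c(sh, draw(l, 2 - m)))
    }
    list(g1 = g1, g2 = g2)
  }))
}
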