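#' Probability of identity for unrelated individuals (PID)
#'
#' Per-locus probability that two unrelated individuals drawn from
#' Hardy-Weinberg proportions share an identical genotype:
#' \eqn{PID = 2 (\sum p_i^2)^2 - \sum p_i^4}. The multilocus value is the
#' product over loci (independence).
#'
#' @param freqs allele_freqs.
#' @return list(per_locus = named numeric, cumulative = numeric).
#' @export
pid_unrelated <- function(freqs) {
  per <- vapply(freqs, function(l) {
    p <- l$freq
    if (length(p) < 2) warning("monomorphic locus: PID = 1")
    2 * sum(p^2)^2 - sum(p^4)
  }, numeric(1))
  list(per_locus = per, cumulative = prod(per))
}

#' Probability of identity for full siblings (PIDsib)
#'
#' The sibling analogue of \code{\link{pid_unrelated}}, the conservative
#' criterion for deciding how many loci are needed before two samples with
#' the same genotype are called the same animal:
#' \eqn{PIDsib = 0.25 + 0.5 \sum p_i^2 + 0.5 (\sum p_i^2)^2 -
#' 0.25 \sum p_i^4}.
#'
#' @param freqs allele_freqs.
#' @param threshold multilocus probability below which sibling
#'   misidentification is considered negligible (default 1e-6).
#' @return list(per_locus, cumulative, below_threshold).
#' @export
pid_sib <- function(freqs, threshold = 1e-6) {
  per <- vapply(freqs, function(l) {
    p <- l$freq
    if (length(p) < 2) warning("monomorphic locus: PIDsib = 1")
    s2 <- sum(p^2)
    0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * sum(p^4)
  }, numeric(1))
  list(per_locus = per, cumulative = prod(per),
       below_threshold = prod(per) < threshold)
}

#' Compare two scat profiles locus by locus
#'
#' Only loci with accepted consensus calls in both profiles are compared
#' (unordered-pair equality). The pair is declared SAME when at least
#' \code{min_match} co-typed loci match and at most \code{max_mismatch}
#' mismatch; DIFFERENT otherwise; INDETERMINATE when no locus is co-typed.
#'
#' @param a,b scat_profile objects.
#' @param min_match minimum matching loci (default 5).
#' @param max_mismatch maximum mismatching loci tolerated (default 0).
#' @return list(decision, n_compared, n_match, n_mismatch).
#' @export
match_profiles <- function(a, b, min_match = 5, max_mismatch = 0) {
  ga <- profile_genotype_list(a)
  gb <- profile_genotype_list(b)
  shared <- intersect(names(ga), names(gb))
  if (length(shared) < 1)
    return(list(decision = "INDETERMINATE", n_compared = 0L,
                n_match = 0L, n_mismatch = 0L))
  eq <- vapply(shared, function(l) identical(sort(ga[[l]]), sort(gb[[l]])),
               logical(1))
  n_match <- sum(eq); n_mis <- sum(!eq)
  list(decision = if (n_match >= min_match && n_mis <= max_mismatch)
         "SAME" else "DIFFERENT",
       n_compared = length(shared), n_match = as.integer(n_match),
       n_mismatch = as.integer(n_mis))
}

profile_genotype_list <- function(p) {
  g <- lapply(p$calls, function(cl) cl$genotype)
  g[!vapply(g, is.null, logical(1))]
}

#' Cluster scats into individuals by genotype matching
#'
#' All retained profiles are compared pairwise; the transitive closure of
#' SAME decisions (union-find) defines individuals. Composite genotypes take
#' the majority accepted call across member scats at each locus, with ties
#' resolved to missing. Clusters containing a DIFFERENT pair (an
#' inconsistency introduced by transitive chaining) are flagged.
#'
#' @param profiles list of scat_profile (only retained ones are clustered).
#' @param min_match,max_mismatch passed to \code{\link{match_profiles}}.
#' @return list of individual_record: list(individual_id, scat_ids,
#'   composite = per-locus genotype list, n_loci_typed, support = per-locus
#'   supporting scat counts, inconsistent).
#' @export
cluster_scats <- function(profiles, min_match = 5, max_mismatch = 0) {
  keep <- Filter(function(p) isTRUE(p$retained), profiles)
  keep <- keep[order(vapply(keep, function(p) p$scat_id, character(1)))]
  n <- length(keep)
  if (n == 0) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  different <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    m <- match_profiles(keep[[i]], keep[[j]], min_match, max_mismatch)
    if (m$decision == "SAME") {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    } else if (m$decision == "DIFFERENT") {
      different[i, j] <- different[j, i] <- TRUE
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  clusters <- split(seq_len(n), roots)
  out <- lapply(seq_along(clusters), function(ci) {
    members <- clusters[[ci]]
    profs <- keep[members]
    loci <- unique(unlist(lapply(profs, function(p) names(p$calls))))
    composite <- list(); support <- integer(0)
    for (l in sort(loci)) {
      gs <- lapply(profs, function(p)
        if (!is.null(p$calls[[l]]) && !is.null(p$calls[[l]]$genotype))
          p$calls[[l]]$genotype else NULL)
      gs <- gs[!vapply(gs, is.null, logical(1))]
      if (length(gs) == 0) next
      key <- vapply(gs, function(g) paste(sort(g), collapse = "/"), character(1))
      tab <- sort(table(key), decreasing = TRUE)
      if (length(tab) > 1 && tab[1] == tab[2]) next  # tie -> missing
      composite[[l]] <- as.integer(strsplit(names(tab)[1], "/")[[1]])
      support[l] <- as.integer(tab[1])
    }
    list(individual_id = sprintf("B%02d", ci),
         scat_ids = vapply(profs, function(p) p$scat_id, character(1)),
         composite = composite, n_loci_typed = length(composite),
         support = support,
         inconsistent = any(different[members, members]))
  })
  out
}

#' Composite genotypes of clustered individuals as a genotype table
#' @param individuals output of \code{\link{cluster_scats}}.
#' @param loci full locus set (so untyped loci become missing).
#' @return genotype_table keyed by individual_id.
#' @export
individuals_to_genotypes <- function(individuals, loci = NULL) {
  if (length(individuals) == 0) stop("no individuals to tabulate")
  if (is.null(loci))
    loci <- sort(unique(unlist(lapply(individuals,
                                      function(ind) names(ind$composite)))))
  rows <- do.call(rbind, lapply(individuals, function(ind) {
    do.call(rbind, lapply(loci, function(l) {
      g <- ind$composite[[l]]
      if (is.null(g)) g <- c(NA_integer_, NA_integer_)
      data.frame(sample_id = ind$individual_id, locus_id = l,
                 allele_a = g[1], allele_b = g[2], stringsAsFactors = FALSE)
    }))
  }))
  genotype_table(rows)
}

#' Map scats to their assigned individual
#' @param individuals output of \code{\link{cluster_scats}}.
#' @return data.frame(scat_id, individual_id).
#' @export
scat_individual_map <- function(individuals) {
  do.call(rbind, lapply(individuals, function(ind)
    data.frame(scat_id = ind$scat_ids, individual_id = ind$individual_id,
               stringsAsFactors = FALSE)))
}
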