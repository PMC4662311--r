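#' Simulation configuration for a synthetic scat survey
#'
#' Bundles every knob of the generator: locus panel, founder allele
#' frequencies, pedigree structure, spatial detection parameters, and the
#' PCR error model. All probabilities are checked to lie in [0, 1] and all
#' frequency vectors to sum to 1.
#'
#' The PCR error model is the standard fecal-DNA one: a PCR x locus fails
#' outright with \code{pcr_failure_rate}; otherwise each allele of a
#' heterozygote drops out independently with \code{dropout_rate} (both
#' dropping = failure), and each surviving allele copy is replaced by a
#' random other allele of the locus with \code{false_allele_rate}. Scats are
#' heterogeneous in DNA quality: a fraction \code{degraded_scat_prob} are
#' degraded and use \code{degraded_failure_rate} instead of
#' \code{pcr_failure_rate}, which is what produces realistic per-locus
#' amplification rates (tens of percent) while still letting intact scats
#' yield full multilocus genotypes.
#'
#' @param n_loci number of microsatellite loci.
#' @param alleles_per_locus integer scalar or length-\code{n_loci} vector.
#' @param founder_allele_freqs optional named list of per-locus named
#'   frequency vectors; generated with \code{\link{make_founder_freqs}} if
#'   NULL.
#' @param pedigree_spec list(n_founders, n_generations, n_offspring,
#'   selfing_prob); \code{n_offspring} recycles over generations.
#' @param N_true number of individuals alive in the surveyed population
#'   (truncates/uses all pedigree members, newest first).
#' @param g0 detection probability at distance zero, in [0, 1).
#' @param sigma_m half-normal spatial scale, meters (> 0).
#' @param n_occasions sampling occasions (transect passes).
#' @param dropout_rate,false_allele_rate,pcr_failure_rate per-PCR error
#'   probabilities.
#' @param degraded_scat_prob,degraded_failure_rate scat-quality mixture.
#' @param n_replicates independent PCRs per scat x locus.
#' @param n_coyote_scats sympatric-species scats added to the survey.
#' @param frag_fail_rate probability the mtDNA fragment read fails.
#' @param bobcat_frag_bp,coyote_frag_bp mtDNA control-region fragment sizes;
#'   defaults differ by the diagnostic 16 bp.
#' @return sim_config object (validated list).
#' @export
sim_config <- function(n_loci = 12,
                       alleles_per_locus = rep(c(3L, 4L, 5L), length.out = 12),
                       founder_allele_freqs = NULL,
                       pedigree_spec = list(n_founders = 5, n_generations = 1,
                                            n_offspring = 4, selfing_prob = 0),
                       N_true = NULL,
                       g0 = 0.22, sigma_m = 770, n_occasions = 2,
                       dropout_rate = 0.10, false_allele_rate = 0.02,
                       pcr_failure_rate = 0.15,
                       degraded_scat_prob = 0.45, degraded_failure_rate = 0.9,
                       n_replicates = 4,
                       n_coyote_scats = 46, frag_fail_rate = 0.2,
                       bobcat_frag_bp = 180, coyote_frag_bp = 196) {
  alleles_per_locus <- rep(as.integer(alleles_per_locus), length.out = n_loci)
  if (any(alleles_per_locus < 1)) stop("config error: locus with no alleles")
  if (is.null(founder_allele_freqs))
    founder_allele_freqs <- make_founder_freqs(n_loci, alleles_per_locus)
  if (length(founder_allele_freqs) != n_loci)
    stop("config error: founder_allele_freqs length != n_loci")
  for (f in founder_allele_freqs) {
    if (length(f) == 0) stop("config error: degenerate (zero-length) frequency vector")
    if (abs(sum(f) - 1) > 1e-9) stop("config error: frequencies do not sum to 1")
    if (any(f < 0)) stop("config error: negative allele frequency")
  }
  probs <- c(g0 = g0, dropout_rate = dropout_rate,
             false_allele_rate = false_allele_rate,
             pcr_failure_rate = pcr_failure_rate,
             degraded_scat_prob = degraded_scat_prob,
             degraded_failure_rate = degraded_failure_rate,
             frag_fail_rate = frag_fail_rate,
             selfing_prob = pedigree_spec$selfing_prob %||% 0)
  if (any(probs < 0 | probs > 1))
    stop("config error: probability outside [0,1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  if (!is.finite(sigma_m) || sigma_m <= 0) stop("config error: sigma_m must be > 0")
  cfg <- list(n_loci = n_loci, alleles_per_locus = alleles_per_locus,
              founder_allele_freqs = founder_allele_freqs,
              pedigree_spec = pedigree_spec, N_true = N_true,
              g0 = g0, sigma_m = sigma_m, n_occasions = as.integer(n_occasions),
              dropout_rate = dropout_rate, false_allele_rate = false_allele_rate,
              pcr_failure_rate = pcr_failure_rate,
              degraded_scat_prob = degraded_scat_prob,
              degraded_failure_rate = degraded_failure_rate,
              n_replicates = as.integer(n_replicates),
              n_coyote_scats = as.integer(n_coyote_scats),
              frag_fail_rate = frag_fail_rate,
              bobcat_frag_bp = bobcat_frag_bp, coyote_frag_bp = coyote_frag_bp)
  class(cfg) <- "sim_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Seed the RNG for one computation without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Deterministic founder allele frequencies for a locus panel
#'
#' Dirichlet-like frequency vectors drawn with a fixed internal RNG stream so
#' the default panel is reproducible independent of the caller's seed.
#' Allele "sizes" are even fragment lengths starting at 100 bp.
#'
#' @param n_loci loci count.
#' @param alleles_per_locus integer vector.
#' @param freq_seed internal seed for the panel (fixed default).
#' @return named list of named per-locus frequency vectors.
#' @export
make_founder_freqs <- function(n_loci, alleles_per_locus, freq_seed = 20120101) {
  alleles_per_locus <- rep(as.integer(alleles_per_locus), length.out = n_loci)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(freq_seed)
  out <- list()
  for (l in seq_len(n_loci)) {
    k <- alleles_per_locus[l]
    g <- -log(runif(k))  # Gamma(1) draws -> Dirichlet(1,...,1)
    f <- g / sum(g)
    names(f) <- as.character(100 + 2 * (seq_len(k) - 1))
    out[[sprintf("L%02d", l)]] <- f
  }
  out
}

#' Default synthetic fixture configuration
#'
#' The shipped study-scale conditions: 12 polymorphic loci with 3-5 alleles,
#' a 9-animal population (5 founders + 4 first-generation offspring, giving a
#' mix of unrelated, full-sib and parent-offspring dyads), half-normal
#' detection with sigma = 770 m over two transect passes, and a PCR error
#' model tuned so per-locus amplification sits near 45% and roughly half of
#' the simulated scats survive the 6-locus consensus filter.
#'
#' @return sim_config.
#' @export
default_fixture_config <- function() sim_config()

#' Default island-like survey geometry
#'
#' A 3.5 x 20 km rectangular habitat (7,000 ha, comparable to a barrier
#' island's upland area) with three lengthwise search transects.
#'
#' @return survey_geometry (no detections).
#' @export
default_fixture_geometry <- function() {
  habitat <- list(cbind(x = c(0, 3500, 3500, 0), y = c(0, 0, 20000, 20000)))
  transects <- lapply(c(700, 1750, 2800), function(xx)
    cbind(x = c(xx, xx), y = c(200, 19800)))
  survey_geometry(transects, habitat)
}

# ---- pedigree ----

#' Generate a pedigreed population with Mendelian genotypes
#'
#' Founders are drawn from Hardy-Weinberg proportions at the configured
#' allele frequencies; each offspring receives one uniformly chosen allele
#' from each parent. Matings are random pairs from the previous generation,
#' with optional selfing (probability \code{selfing_prob}) to create inbred
#' individuals. Pedigree inbreeding coefficients F and pairwise kinships are
#' computed by the standard recursive algorithm, and each dyad is labelled
#' U / HS / FS / PO from the pedigree.
#'
#' @param config sim_config.
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @return list(genotypes = genotype_table, pedigree = data.frame(
#'   individual_id, sire, dam, generation, F), kinship = matrix,
#'   relationships = character matrix with entries U/HS/FS/PO).
#' @export
generate_population <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  ps <- config$pedigree_spec
  n_off <- rep(ps$n_offspring %||% 0, length.out = max(ps$n_generations, 1))
  if (ps$n_generations == 0) n_off <- integer(0)
  selfing <- ps$selfing_prob %||% 0

  ids <- sprintf("I%02d", seq_len(ps$n_founders))
  sire <- rep(NA_character_, ps$n_founders)
  dam <- rep(NA_character_, ps$n_founders)
  gen <- rep(0L, ps$n_founders)
  for (g in seq_along(n_off)) {
    pool <- ids[gen == g - 1L]
    if (length(pool) == 0) stop("config error: empty parental pool at generation ", g)
    for (o in seq_len(n_off[g])) {
      if (length(pool) >= 2 && runif(1) >= selfing) {
        pr <- sample(pool, 2)
      } else {
        pr <- rep(sample(pool, 1), 2)  # selfing
      }
      ids <- c(ids, sprintf("I%02d", length(ids) + 1L))
      sire <- c(sire, pr[1]); dam <- c(dam, pr[2]); gen <- c(gen, g)
    }
  }
  ped <- data.frame(individual_id = ids, sire = sire, dam = dam,
                    generation = gen, stringsAsFactors = FALSE)
  kin <- pedigree_kinship(ped)
  ped$F <- vapply(seq_len(nrow(ped)), function(i) {
    if (is.na(ped$sire[i])) 0 else kin[ped$sire[i], ped$dam[i]]
  }, numeric(1))

  # Mendelian genotypes
  loci <- names(config$founder_allele_freqs)
  geno <- list()  # geno[[id]][[locus]] = c(a, b)
  for (i in seq_len(nrow(ped))) {
    id <- ped$individual_id[i]
    geno[[id]] <- list()
    for (l in loci) {
      if (is.na(ped$sire[i])) {
        f <- config$founder_allele_freqs[[l]]
        al <- sample(as.integer(names(f)), 2, replace = TRUE, prob = f)
      } else {
        gs <- geno[[ped$sire[i]]][[l]]
        gd <- geno[[ped$dam[i]]][[l]]
        al <- c(gs[sample.int(2, 1)], gd[sample.int(2, 1)])
      }
      geno[[id]][[l]] <- al
    }
  }
  gt <- do.call(rbind, lapply(ped$individual_id, function(id)
    data.frame(sample_id = id, locus_id = loci,
               allele_a = vapply(geno[[id]], `[`, integer(1), 1),
               allele_b = vapply(geno[[id]], `[`, integer(1), 2),
               stringsAsFactors = FALSE)))
  rel <- pedigree_relationships(ped)
  list(genotypes = genotype_table(gt), pedigree = ped, kinship = kin,
       relationships = rel)
}

#' Kinship matrix from a pedigree (recursive, founders unrelated)
#' @param ped data.frame(individual_id, sire, dam) with parents listed
#'   before offspring.
#' @return symmetric kinship matrix (self-kinship on the diagonal).
#' @export
pedigree_kinship <- function(ped) {
  n <- nrow(ped)
  ids <- ped$individual_id
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      K[i, i] <- 0.5
    } else {
      K[i, i] <- 0.5 * (1 + K[si[i], di[i]])
      for (j in seq_len(i - 1)) {
        K[i, j] <- K[j, i] <- 0.5 * (K[si[i], j] + K[di[i], j])
      }
    }
  }
  K
}

#' Dyad relationship categories from a pedigree
#' @param ped pedigree data.frame.
#' @return character matrix with entries "PO", "FS", "HS", "U" ("" diagonal).
#' @export
pedigree_relationships <- function(ped) {
  ids <- ped$individual_id
  n <- length(ids)
  R <- matrix("U", n, n, dimnames = list(ids, ids))
  diag(R) <- ""
  par <- function(i) stats::na.omit(c(ped$sire[i], ped$dam[i]))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (ids[i] %in% par(j) || ids[j] %in% par(i)) { R[i, j] <- "PO"; next }
    pi <- par(i); pj <- par(j)
    if (length(pi) && length(pj)) {
      if (setequal(pi, pj) && length(unique(pi)) == length(unique(pj))) {
        R[i, j] <- "FS"
      } else if (length(intersect(pi, pj)) >= 1) {
        R[i, j] <- "HS"
      }
    }
  }
  R
}

# ---- spatial survey ----

#' Simulate scat detections around latent activity centers
#'
#' Activity centers are drawn uniformly over the habitat polygon (homogeneous
#' Poisson conditioned on the number of individuals); individual i leaves a
#' detectable scat at detector j on occasion k independently with probability
#' \code{g0 * exp(-d_ij^2 / (2 sigma_m^2))}. Each success emits one scat
#' record located at the detector.
#'
#' @param individual_ids character vector of animals alive.
#' @param geometry survey_geometry (transects required; habitat used for
#'   center placement when present).
#' @param g0 detection probability at distance 0, in [0, 1).
#' @param sigma_m half-normal scale (m), > 0.
#' @param n_occasions number of transect passes.
#' @param seed optional integer seed.
#' @param section_length transect section length (m) defining detectors.
#' @param centers optional matrix of activity centers (rows match
#'   \code{individual_ids}); drawn uniformly if NULL.
#' @return list(detections = data.frame(scat_id, individual_id, detector_id,
#'   x, y, occasion), centers, detectors).
#' @export
simulate_survey <- function(individual_ids, geometry, g0, sigma_m,
                            n_occasions = 2, seed = NULL,
                            section_length = 200, centers = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.finite(sigma_m) || sigma_m <= 0) stop("sigma_m must be > 0")
  if (g0 < 0 || g0 >= 1) stop("g0 must lie in [0, 1)")
  detectors <- segment_transects(geometry$transects, section_length)
  n <- length(individual_ids)
  if (is.null(centers)) {
    centers <- draw_uniform_centers(n, geometry, detectors, sigma_m)
  }
  dx <- outer(centers[, 1], detectors$x, "-")
  dy <- outer(centers[, 2], detectors$y, "-")
  p <- g0 * exp(-(dx^2 + dy^2) / (2 * sigma_m^2))  # n x J
  recs <- list()
  for (k in seq_len(n_occasions)) {
    hit <- matrix(runif(length(p)) < p, nrow = n)
    idx <- which(hit, arr.ind = TRUE)
    if (nrow(idx)) {
      recs[[k]] <- data.frame(individual_id = individual_ids[idx[, 1]],
                              detector_id = detectors$detector_id[idx[, 2]],
                              x = detectors$x[idx[, 2]],
                              y = detectors$y[idx[, 2]],
                              occasion = k, stringsAsFactors = FALSE)
    }
  }
  det <- if (length(recs)) do.call(rbind, recs)
         else data.frame(individual_id = character(), detector_id = character(),
                         x = numeric(), y = numeric(), occasion = integer(),
                         stringsAsFactors = FALSE)
  if (nrow(det)) {
    det <- det[order(det$occasion, det$detector_id, det$individual_id), ]
    det <- cbind(scat_id = sprintf("S%03d", seq_len(nrow(det))), det)
    rownames(det) <- NULL
  } else {
    det <- cbind(scat_id = character(0), det)
  }
  rownames(centers) <- individual_ids
  list(detections = det, centers = centers, detectors = detectors)
}

draw_uniform_centers <- function(n, geometry, detectors, sigma_m) {
  if (!is.null(geometry$habitat)) {
    ring <- geometry$habitat[[1]]
    bx <- range(ring[, 1]); by <- range(ring[, 2])
    pts <- matrix(NA_real_, n, 2)
    got <- 0
    while (got < n) {
      m <- max(2 * (n - got), 16)
      cand <- cbind(runif(m, bx[1], bx[2]), runif(m, by[1], by[2]))
      inside <- mgcv::in.out(rbind(ring, ring[1, , drop = FALSE]), cand)
      cand <- cand[inside, , drop = FALSE]
      take <- min(nrow(cand), n - got)
      if (take > 0) pts[(got + 1):(got + take), ] <- cand[seq_len(take), ]
      got <- got + take
    }
    pts
  } else {
    pad <- 4 * sigma_m
    cbind(runif(n, min(detectors$x) - pad, max(detectors$x) + pad),
          runif(n, min(detectors$y) - pad, max(detectors$y) + pad))
  }
}

# ---- PCR replicates ----

#' Simulate replicate-PCR microsatellite calls for a set of scats
#'
#' Applies the configured error model to the true genotype of the depositing
#' individual, per scat x locus x PCR. A call records the distinct alleles
#' seen: a clean heterozygote shows its pair; a dropout (or a homozygote)
#' shows a single allele (stored as (a, a)); a failed PCR carries no alleles.
#'
#' @param genotypes genotype_table of true individual genotypes.
#' @param scat_map data.frame(scat_id, individual_id); coyote/unknown scats
#'   may carry individual_id NA and yield all-failed PCRs.
#' @param config sim_config.
#' @param seed optional integer seed.
#' @return list(replicates = replicate_set, scat_quality = data.frame(
#'   scat_id, degraded)).
#' @export
simulate_pcr_replicates <- function(genotypes, scat_map, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loci <- names(config$founder_allele_freqs)
  allele_sets <- lapply(config$founder_allele_freqs,
                        function(f) as.integer(names(f)))
  gidx <- split(seq_len(nrow(genotypes)), genotypes$sample_id)
  degraded <- runif(nrow(scat_map)) < config$degraded_scat_prob
  out <- vector("list", nrow(scat_map))
  for (s in seq_len(nrow(scat_map))) {
    sid <- scat_map$scat_id[s]
    ind <- scat_map$individual_id[s]
    fail_rate <- if (degraded[s]) config$degraded_failure_rate
                 else config$pcr_failure_rate
    gl <- if (!is.na(ind)) genotypes[gidx[[ind]], ] else NULL
    n_rep <- config$n_replicates
    aa <- ab <- matrix(NA_integer_, length(loci), n_rep)
    for (li in seq_along(loci)) {
      true <- if (is.null(gl)) c(NA, NA) else {
        r <- gl[gl$locus_id == loci[li], ]
        c(r$allele_a, r$allele_b)
      }
      for (p in seq_len(n_rep)) {
        if (is.na(true[1]) || runif(1) < fail_rate) next  # failed PCR
        surv <- true
        if (true[1] != true[2]) {
          keep <- runif(2) >= config$dropout_rate
          if (!any(keep)) next  # both alleles dropped: scored as failure
          surv <- true[keep]
        }
        pool <- allele_sets[[loci[li]]]
        for (q in seq_along(surv)) {
          if (length(pool) > 1 && runif(1) < config$false_allele_rate) {
            surv[q] <- sample(setdiff(pool, surv[q]), 1)
          }
        }
        surv <- sort(unique(surv))
        aa[li, p] <- surv[1]
        ab[li, p] <- surv[length(surv)]
      }
    }
    out[[s]] <- data.frame(scat_id = sid,
                           pcr_id = rep(sprintf("P%d", seq_len(n_rep)),
                                        each = length(loci)),
                           locus_id = rep(loci, times = n_rep),
                           allele_a = as.vector(aa), allele_b = as.vector(ab),
                           stringsAsFactors = FALSE)
  }
  list(replicates = replicate_set(do.call(rbind, out)),
       scat_quality = data.frame(scat_id = scat_map$scat_id,
                                 degraded = degraded,
                                 stringsAsFactors = FALSE))
}

#' Simulate mtDNA fragment lengths for species assignment
#'
#' Bobcat and coyote scats produce fragments at their species' reference
#' length with +/-1 bp measurement jitter; a fraction of reads fail
#' (degraded DNA) and return NA.
#'
#' @param species character vector ("BOBCAT"/"COYOTE").
#' @param config sim_config.
#' @param seed optional seed.
#' @return numeric vector of fragment lengths (bp), NA for failed reads.
#' @export
simulate_fragments <- function(species, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- ifelse(species == "BOBCAT", config$bobcat_frag_bp,
                 config$coyote_frag_bp)
  len <- base + sample(-1:1, length(species), replace = TRUE)
  len[runif(length(species)) < config$frag_fail_rate] <- NA
  len
}

#' Run the full synthetic scat-survey generator
#'
#' One call produces everything the analysis pipeline consumes plus the
#' truth tables needed for recovery tests: a pedigreed population with
#' genotypes, activity centers, scat detections along the transects,
#' sympatric coyote scats dropped at random detectors, mtDNA fragment
#' lengths, and replicate-PCR calls under the configured error model.
#'
#' @param config sim_config.
#' @param geometry survey_geometry; defaults to
#'   \code{\link{default_fixture_geometry}}.
#' @param seed integer seed driving a single RNG stream for the whole
#'   generator (same config + seed = identical output).
#' @return list(population, survey, scats = data.frame(scat_id, true_species,
#'   fragment_bp, x, y, occasion, individual_id), replicates, scat_quality,
#'   config, geometry).
#' @export
simulate_scat_survey <- function(config = default_fixture_config(),
                                 geometry = default_fixture_geometry(),
                                 seed = 1) {
  set.seed(seed)
  pop <- generate_population(config)
  ids <- pop$pedigree$individual_id
  if (!is.null(config$N_true) && config$N_true < length(ids))
    ids <- utils::tail(ids, config$N_true)
  surv <- simulate_survey(ids, geometry, config$g0, config$sigma_m,
                          config$n_occasions,
                          section_length = 200)
  bob <- surv$detections
  scats <- data.frame(scat_id = bob$scat_id, true_species = "BOBCAT",
                      x = bob$x, y = bob$y, occasion = bob$occasion,
                      individual_id = bob$individual_id,
                      stringsAsFactors = FALSE)
  if (config$n_coyote_scats > 0) {
    j <- sample.int(nrow(surv$detectors), config$n_coyote_scats, replace = TRUE)
    coy <- data.frame(scat_id = sprintf("C%03d", seq_len(config$n_coyote_scats)),
                      true_species = "COYOTE",
                      x = surv$detectors$x[j], y = surv$detectors$y[j],
                      occasion = sample.int(config$n_occasions,
                                            config$n_coyote_scats, replace = TRUE),
                      individual_id = NA_character_, stringsAsFactors = FALSE)
    scats <- rbind(scats, coy)
  }
  scats$fragment_bp <- simulate_fragments(scats$true_species, config)
  pcr <- simulate_pcr_replicates(pop$genotypes,
                                 scats[c("scat_id", "individual_id")], config)
  list(population = pop, survey = surv, scats = scats,
       replicates = pcr$replicates, scat_quality = pcr$scat_quality,
       config = config, geometry = geometry)
}
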