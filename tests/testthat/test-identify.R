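test_that("PID and PIDsib match exact enumeration and the worked examples", {
  f <- as_allele_freqs(list(L1 = c("100" = 0.5, "102" = 0.5)))
  expect_equal(pid_unrelated(f)$cumulative, 0.375)
  expect_equal(pid_sib(f)$cumulative, 0.59375)
  # arbitrary frequency vectors against the enumeration oracles
  set.seed(31)
  for (i in 1:10) {
    k <- sample(2:6, 1)
    p <- rgamma(k, 1); p <- p / sum(p)
    fr <- as_allele_freqs(list(LX = setNames(p, as.character(seq_len(k) * 2 + 98))))
    expect_equal(pid_unrelated(fr)$per_locus[["LX"]], pid_enum(p),
                 tolerance = 1e-12)
    expect_equal(pid_sib(fr)$per_locus[["LX"]], pidsib_enum(p),
                 tolerance = 1e-12)
    expect_gte(pid_sib(fr)$per_locus[["LX"]], pid_unrelated(fr)$per_locus[["LX"]])
  }
  # independence across loci: product rule
  f6 <- as_allele_freqs(setNames(rep(list(c("100" = 0.5, "102" = 0.5)), 6),
                                 paste0("L", 1:6)))
  expect_equal(pid_unrelated(f6)$cumulative, 0.375^6)
  expect_true(pid_sib(f6, threshold = 0.1)$below_threshold)
  # monomorphic locus contributes 1, with a warning
  fm <- as_allele_freqs(list(L1 = c("100" = 1)))
  expect_warning(pm <- pid_unrelated(fm), "monomorphic")
  expect_equal(pm$cumulative, 1)
})

test_that("PIDsib cumulative never increases with added loci", {
  set.seed(13)
  for (rep in 1:5) {
    fl <- lapply(1:8, function(i) {
      k <- sample(2:5, 1); p <- rgamma(k, 1)
      setNames(p / sum(p), as.character(100 + 2 * seq_len(k)))
    })
    names(fl) <- paste0("L", 1:8)
    cums <- vapply(1:8, function(j)
      pid_sib(as_allele_freqs(fl[1:j]))$cumulative, numeric(1))
    expect_true(all(diff(cums) <= 1e-15))
  }
})

test_that("profile matching counts co-typed loci and applies the thresholds", {
  mk <- function(pairs) fake_profile("SX", pairs)
  gA <- setNames(lapply(1:6, function(i) c(100, 102)), paste0("L", 1:6))
  gB <- gA; gB$L6 <- c(104, 106)
  a <- fake_profile("S1", gA); b <- fake_profile("S2", gB)
  m0 <- match_profiles(a, b, min_match = 5, max_mismatch = 0)
  expect_equal(m0$decision, "DIFFERENT")
  m1 <- match_profiles(a, b, min_match = 5, max_mismatch = 1)
  expect_equal(m1$decision, "SAME")
  expect_equal(m1$n_match, 5); expect_equal(m1$n_mismatch, 1)
  # only 4 matching loci: below threshold even with tolerance
  gC <- gA; gC$L5 <- c(104, 106); gC$L6 <- c(104, 106)
  expect_equal(match_profiles(a, fake_profile("S3", gC), 5, 2)$decision,
               "DIFFERENT")
  # identical profiles
  mi <- match_profiles(a, fake_profile("S4", gA))
  expect_equal(mi$decision, "SAME"); expect_equal(mi$n_mismatch, 0)
  # disjoint typed loci: indeterminate
  gD <- setNames(lapply(1:6, function(i) c(100, 102)), paste0("M", 1:6))
  expect_equal(match_profiles(a, fake_profile("S5", gD))$decision,
               "INDETERMINATE")
})

test_that("clustering is a transitive closure, order invariant, with majority composites", {
  g <- setNames(lapply(1:7, function(i) c(100, 102)), paste0("L", 1:7))
  g_conflict <- g; g_conflict$L7 <- c(104, 104)
  profs <- list(fake_profile("S1", g), fake_profile("S2", g),
                fake_profile("S3", g_conflict))
  # S1-S2 identical; S3 matches both at 6 loci with 1 mismatch -> same with
  # max_mismatch 1; composite at L7 by majority (2 of 3)
  inds <- cluster_scats(profs, min_match = 5, max_mismatch = 1)
  expect_length(inds, 1)
  expect_setequal(inds[[1]]$scat_ids, c("S1", "S2", "S3"))
  expect_equal(inds[[1]]$composite$L7, c(100, 102))
  # tie at a locus -> missing
  inds2 <- cluster_scats(list(fake_profile("S1", g),
                              fake_profile("S3", g_conflict)),
                         min_match = 5, max_mismatch = 1)
  expect_length(inds2, 1)
  expect_null(inds2[[1]]$composite$L7)
  expect_equal(inds2[[1]]$n_loci_typed, 6)
  # input order never changes the partition
  key <- function(inds) partition_key(lapply(inds, function(i) i$scat_ids))
  for (i in 1:4) {
    perm <- sample(profs)
    expect_equal(key(cluster_scats(perm, 5, 1)), key(inds))
  }
  # three scats pairwise SAME -> one individual observed in 3 scats
  expect_length(inds[[1]]$scat_ids, 3)
})

test_that("zero-error synthetic surveys cluster scats exactly to truth", {
  cfg <- sim_config(dropout_rate = 0, false_allele_rate = 0,
                    pcr_failure_rate = 0, degraded_scat_prob = 0,
                    frag_fail_rate = 0, n_coyote_scats = 0)
  for (seed in c(2, 9)) {
    sim <- simulate_scat_survey(cfg, seed = seed)
    sp <- setNames(classify_species(sim$scats$fragment_bp), sim$scats$scat_id)
    profs <- build_scat_profiles(sim$replicates, sp)
    inds <- cluster_scats(profs)
    ret <- names(Filter(function(p) isTRUE(p$retained), profs))
    expect_equal(partition_key(lapply(inds, function(i) i$scat_ids)),
                 partition_key(truth_partition(sim, ret)))
  }
})

test_that("individual counts recover truth in >=95% of low-error surveys", {
  # low genotyping error, full replicate success: the regime in which exact
  # genotype-identity recovery is expected; see the vignette for behavior at
  # the fixture's full error rates
  cfg <- sim_config(dropout_rate = 0.02, false_allele_rate = 0.01,
                    pcr_failure_rate = 0, degraded_scat_prob = 0,
                    frag_fail_rate = 0, n_coyote_scats = 0)
  ok <- vapply(1:200, function(s) {
    sim <- simulate_scat_survey(cfg, seed = s)
    sp <- setNames(classify_species(sim$scats$fragment_bp), sim$scats$scat_id)
    profs <- build_scat_profiles(sim$replicates, sp)
    inds <- cluster_scats(profs)
    ret <- names(Filter(function(p) isTRUE(p$retained), profs))
    length(inds) == length(truth_partition(sim, ret))
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
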