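test_that("dyad likelihood reduces to HWE products and IBD identities", {
  fr <- as_allele_freqs(list(L1 = c("100" = 0.5, "102" = 0.3, "104" = 0.2)))
  pA <- 0.5; pB <- 0.3
  gAB <- list(L1 = c(100L, 102L))
  gAA <- list(L1 = c(100L, 100L))
  # k = U: product of the two HWE genotype probabilities
  expect_equal(dyad_loglik(gAB, gAA, c(1, 0, 0), fr),
               log(2 * pA * pB) + log(pA^2))
  # k = (0,0,1) with identical hets: per-locus likelihood 2 pA pB
  expect_equal(dyad_loglik(gAB, gAB, c(0, 0, 1), fr), log(2 * pA * pB))
  expect_error(dyad_loglik(gAB, gAB, c(0.5, 0.6, -0.1), fr), "probability")
})

test_that("dyad likelihood matches Monte Carlo frequencies of simulated dyads", {
  fr <- as_allele_freqs(list(L1 = c("100" = 0.5, "102" = 0.3, "104" = 0.2)))
  n <- 2e5
  for (kname in c("FS", "HS")) {
    dy <- simulate_dyads(n, kname, fr, seed = 17)
    k <- if (kname == "FS") c(0.25, 0.5, 0.25) else c(0.5, 0.5, 0)
    for (pair in list(list(c(100L, 102L), c(100L, 102L)),
                      list(c(100L, 100L), c(100L, 104L)))) {
      theo <- exp(dyad_loglik(list(L1 = pair[[1]]), list(L1 = pair[[2]]), k, fr))
      emp <- mean(vapply(dy, function(d)
        identical(d$g1$L1, pair[[1]]) && identical(d$g2$L1, pair[[2]]),
        logical(1)))
      se <- sqrt(theo * (1 - theo) / n)
      expect_lt(abs(emp - theo), 3.5 * se)
    }
  }
})

test_that("ML relatedness beats every 0.01-grid point and respects symmetries", {
  fr <- eq_freqs(8, 4)
  dy <- simulate_dyads(5, "FS", fr, seed = 23)
  G <- scatcap:::k_simplex_grid(0.01)
  for (d in dy) {
    est <- estimate_r_ml(d$g1, d$g2, fr)
    P <- scatcap:::dyad_P012(d$g1, d$g2, fr)
    grid_ll <- rowSums(log(pmax(G %*% P, 1e-300)))
    expect_gte(est$loglik, max(grid_ll) - 1e-9)
    # swapping the dyad and relabeling alleles leave r unchanged
    expect_equal(estimate_r_ml(d$g2, d$g1, fr)$r, est$r)
    shift <- function(g) lapply(g, function(x) x + 1000L)
    fr_shift <- as_allele_freqs(lapply(fr, function(l)
      setNames(l$freq, as.integer(names(l$freq)) + 1000L)))
    expect_equal(estimate_r_ml(shift(d$g1), shift(d$g2), fr_shift)$r, est$r)
  }
})

test_that("identical genotypes at rare alleles give near-maximal relatedness", {
  # 20 loci, each heterozygous for two alleles at frequency 0.05
  fr <- as_allele_freqs(setNames(lapply(1:20, function(i)
    setNames(c(0.05, 0.05, 0.45, 0.45), c("100", "102", "104", "106"))),
    sprintf("L%02d", 1:20)))
  g <- setNames(rep(list(c(100L, 102L)), 20), names(fr))
  est <- estimate_r_ml(g, g, fr)
  expect_gte(est$r, 0.9)
  # all co-typed loci monomorphic: undefined with explicit status
  frm <- as_allele_freqs(list(L1 = c("100" = 1)))
  gm <- list(L1 = c(100L, 100L))
  expect_equal(estimate_r_ml(gm, gm, frm)$status, "UNDEFINED")
})

test_that("relationship classification picks the right anchors", {
  fr <- eq_freqs(12, 4)
  # a locus sharing no alleles makes PO impossible
  g1 <- setNames(rep(list(c(100L, 102L)), 12), names(fr))
  g2 <- g1; g2$L01 <- c(104L, 106L)
  cls <- classify_relationship(g1, g2, fr)
  expect_equal(cls$loglik[["PO"]], -Inf)
  expect_false(cls$category == "PO")
  # identical genotypes at common alleles: FS most likely of the four anchors
  frc <- as_allele_freqs(setNames(lapply(1:12, function(i)
    setNames(c(0.4, 0.4, 0.1, 0.1), c("100", "102", "104", "106"))),
    sprintf("L%02d", 1:12)))
  gi <- setNames(rep(list(c(100L, 102L)), 12), names(frc))
  expect_equal(classify_relationship(gi, gi, frc)$category, "FS")
})

test_that("ML inbreeding coefficient behaves at its boundaries and beats a grid", {
  fr <- eq_freqs(20, 2)
  het <- setNames(rep(list(c(100L, 102L)), 20), names(fr))
  hom <- setNames(rep(list(c(100L, 100L)), 20), names(fr))
  expect_equal(estimate_F_ml(het, fr, n_boot = 10)$F, 0, tolerance = 1e-6)
  expect_equal(estimate_F_ml(hom, fr, n_boot = 10)$F, 1, tolerance = 1e-6)
  expect_error(estimate_F_ml(het[1:2], fr, n_boot = 2), ">= 3")
  # optimum at least as good as a 1,000-point grid on [0, 1]
  fr5 <- eq_freqs(12, 5)
  dy <- simulate_dyads(1, "U", fr5, seed = 5)[[1]]
  est <- estimate_F_ml(dy$g1, fr5, n_boot = 2)
  llF <- function(F_) {
    sum(vapply(names(fr5), function(l) {
      p <- fr5[[l]]$freq; g <- dy$g1[[l]]
      pa <- p[[as.character(g[1])]]; pb <- p[[as.character(g[2])]]
      if (g[1] == g[2]) log(pa^2 + F_ * pa * (1 - pa))
      else log(2 * pa * pb * (1 - F_))
    }, numeric(1)))
  }
  grid <- seq(0, 1, length.out = 1000)
  expect_gte(est$loglik, max(vapply(grid, llF, numeric(1))) - 1e-9)
  # bootstrap CI brackets the estimate
  expect_lte(est$ci[1], est$F + 1e-9)
  expect_gte(est$ci[2], est$F - 1e-9)
})

test_that("relatedness summaries reproduce the published pairwise table", {
  pub <- published_study()
  s_ml <- summarize_relatedness(pub$r_ml)
  expect_equal(s_ml$n_pairs, 36)
  expect_equal(round(s_ml$mean, 3), 0.155)
  expect_equal(s_ml$n_below, 27)        # near-zero pairs (< 0.25)
  expect_equal(s_ml$n_at_or_above, 8)   # r >= 0.5
  s_tri <- summarize_relatedness(pub$r_triadic)
  expect_equal(s_tri$n_above, 2)        # triadic r > 0.5
  # degenerate input
  z <- summarize_relatedness(matrix(0, 3, 3))
  expect_equal(z$mean, 0); expect_equal(z$sd, 0)
})

test_that("relatedness matrix is symmetric with an undefined diagonal", {
  pop <- generate_population(default_fixture_config(), seed = 21)
  gt <- pop$genotypes
  gt <- gt[gt$sample_id %in% unique(gt$sample_id)[1:5], ]
  class(gt) <- c("genotype_table", "data.frame")
  rm <- relatedness_matrix(gt)
  expect_true(isSymmetric(rm$r))
  expect_true(all(is.na(diag(rm$r))))
  expect_true(all(rm$r[upper.tri(rm$r)] >= 0 & rm$r[upper.tri(rm$r)] <= 1))
})
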