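test_that("heterozygosity statistics match hand computation", {
  gt <- gt_from_list(list(A = list(L1 = c(100, 102), L2 = c(100, 100)),
                          B = list(L1 = c(100, 102), L2 = c(100, 100))))
  hs <- heterozygosity_stats(gt)
  l1 <- hs$per_locus[hs$per_locus$locus_id == "L1", ]
  expect_equal(l1$Ho, 1)
  expect_equal(l1$He, 0.5)
  expect_equal(l1$uHe, 4 / 3 * 0.5)    # 2n/(2n-1) with n = 2
  expect_equal(l1$A, 2)
  l2 <- hs$per_locus[hs$per_locus$locus_id == "L2", ]
  expect_equal(l2$Ho, 0); expect_equal(l2$He, 0); expect_equal(l2$A, 1)
  # uHe/He ratio is exactly 2n/(2n-1) at every polymorphic locus
  sim <- generate_population(default_fixture_config(), seed = 8)
  hsim <- heterozygosity_stats(sim$genotypes)$per_locus
  poly <- hsim[hsim$He > 0, ]
  expect_equal(poly$uHe / poly$He, 2 * poly$n_typed / (2 * poly$n_typed - 1))
})

test_that("HWE chi-square matches hand-computed statistics", {
  mk_counts <- function(nAA, nAB, nBB) {
    gt_from_list(setNames(c(
      rep(list(list(L1 = c(100, 100))), nAA),
      rep(list(list(L1 = c(100, 102))), nAB),
      rep(list(list(L1 = c(102, 102))), nBB)),
      paste0("I", seq_len(nAA + nAB + nBB))))
  }
  h0 <- hwe_test(mk_counts(25, 50, 25), "L1")
  expect_equal(h0$chi2, 0, tolerance = 1e-12)
  expect_equal(h0$p, 1)
  h1 <- hwe_test(mk_counts(50, 0, 50), "L1")
  expect_equal(h1$chi2, 100)
  expect_equal(h1$df, 1)
  # Monte Carlo p matches the exact Levene conditional distribution (oracle:
  # enumerate heterozygote counts given the allele counts)
  levene_p <- function(nAA, nAB, nBB) {
    n <- nAA + nAB + nBB; nA <- 2 * nAA + nAB
    hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
    logpr <- vapply(hets, function(h) {
      naa <- (nA - h) / 2; nbb <- n - naa - h
      lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
        h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
    }, numeric(1))
    pr <- exp(logpr - max(logpr)); pr <- pr / sum(pr)
    chi2 <- vapply(hets, function(h) {
      naa <- (nA - h) / 2; nbb <- n - naa - h
      p <- nA / (2 * n); e <- c(n * p^2, 2 * n * p * (1 - p), n * (1 - p)^2)
      sum((c(naa, h, nbb) - e)^2 / e)
    }, numeric(1))
    sum(pr[chi2 >= chi2[hets == nAB] - 1e-12])
  }
  gt_mc <- mk_counts(30, 45, 25)
  pe <- hwe_test(gt_mc, "L1", method = "exact", n_perm = 10000, seed = 2)$p
  expect_lt(abs(pe - levene_p(30, 45, 25)), 0.02)
  # asymptotic agreement: exact and chi-square p converge for a large sample
  gt_big <- mk_counts(110, 180, 110)
  pc2 <- hwe_test(gt_big, "L1", method = "chi2")$p
  pe2 <- hwe_test(gt_big, "L1", method = "exact", n_perm = 10000, seed = 2)$p
  expect_lt(abs(pc2 - pe2), 0.02)
  # monomorphic locus: NA
  expect_true(is.na(hwe_test(mk_counts(10, 0, 0), "L1")$chi2))
})

test_that("FIS follows its definition and is invariant to allele relabeling", {
  gt <- gt_from_list(list(A = list(L1 = c(100, 102)),
                          B = list(L1 = c(100, 102))))
  expect_equal(fis(gt)$mean_FIS, -1)   # (0.5 - 1)/0.5
  # Ho = He gives FIS 0
  gt0 <- gt_from_list(list(A = list(L1 = c(100, 102)),
                           B = list(L1 = c(100, 100))))
  hs <- heterozygosity_stats(gt0)$per_locus
  expect_equal(fis(gt0)$per_locus$FIS, (hs$He - hs$Ho) / hs$He)
  # relabeling alleles changes nothing
  relab <- gt_from_list(list(A = list(L1 = c(200, 250)),
                             B = list(L1 = c(200, 250))))
  expect_equal(fis(relab)$mean_FIS, fis(gt)$mean_FIS)
})

test_that("heterozygote-excess Nb follows the closed form and its conventions", {
  expect_equal(round(nb_from_D(0.11), 1), 5.0)
  expect_equal(nb_from_D(0.11), 1 / 0.22 + 1 / 2.22)
  expect_equal(nb_from_D(0), Inf)
  expect_equal(nb_from_D(-0.2), Inf)
  # strictly decreasing in D for D > 0
  D <- seq(0.01, 2, by = 0.01)
  expect_true(all(diff(vapply(D, nb_from_D, numeric(1))) < 0))
  # weighted D on a constructed table: weights k-1 per locus
  gt <- gt_from_list(list(
    A = list(L1 = c(100, 102), L2 = c(100, 102)),
    B = list(L1 = c(100, 102), L2 = c(100, 104)),
    C = list(L1 = c(100, 100), L2 = c(102, 104))))
  ne <- ne_heterozygote_excess(gt)
  pl <- ne$per_locus
  expect_equal(ne$D_weighted,
               sum((pl$A - 1) * pl$D) / sum(pl$A - 1))
  expect_equal(ne$D_unweighted, mean(pl$D))
  # Ho < He everywhere: infinite Nb by convention
  gthom <- gt_from_list(list(A = list(L1 = c(100, 100)),
                             B = list(L1 = c(102, 102))))
  expect_equal(ne_heterozygote_excess(gthom)$Nb, Inf)
})

test_that("molecular coancestry similarity behaves on elementary pairs", {
  # identical heterozygotes: f0 = 0.5, no homozygotes so s = 0 -> Nb = 1
  gt <- gt_from_list(list(A = list(L1 = c(100, 102)),
                          B = list(L1 = c(100, 102))))
  expect_equal(ne_coancestry(gt)$Nb, 1)
  # no shared alleles: f0 = 0 -> f1 = 0 -> Nb = Inf
  gt2 <- gt_from_list(list(A = list(L1 = c(100, 102)),
                           B = list(L1 = c(104, 106))))
  expect_equal(ne_coancestry(gt2)$Nb, Inf)
  expect_error(ne_coancestry(gt_from_list(list(A = list(L1 = c(100, 102))))),
               ">= 2")
})

test_that("coancestry Nb recovers the number of parents in simulated cohorts", {
  fr <- make_founder_freqs(20, 5)
  sim_cohort <- function(n_par, n_off, seed) {
    set.seed(seed)
    parents <- lapply(seq_len(n_par), function(i) lapply(fr, function(p)
      sample(as.integer(names(p)), 2, TRUE, p)))
    gt_from_list(setNames(lapply(seq_len(n_off), function(o) {
      pr <- sample(seq_len(n_par), 2)
      setNames(lapply(names(fr), function(l)
        c(parents[[pr[1]]][[l]][sample(1:2, 1)],
          parents[[pr[2]]][[l]][sample(1:2, 1)])), names(fr))
    }), sprintf("O%02d", seq_len(n_off))))
  }
  nb <- vapply(1:100, function(s) ne_coancestry(sim_cohort(4, 40, 4000 + s))$Nb,
               numeric(1))
  expect_lt(abs(median(nb) / 4 - 1), 0.5)
})
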