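test_that("transect segmentation follows the half-section remainder rule", {
  line1000 <- list(cbind(x = c(0, 1000), y = c(0, 0)))
  d5 <- segment_transects(line1000, 200)
  expect_equal(nrow(d5), 5)
  expect_equal(d5$x, c(100, 300, 500, 700, 900))
  expect_equal(d5$y, rep(0, 5))
  # 500 m: 200 + 200 + 100; the half-length remainder merges into the last
  d2 <- segment_transects(list(cbind(x = c(0, 500), y = c(0, 0))), 200)
  expect_equal(d2$x, c(100, 350))
  # 510 m: remainder 110 > 100 stays its own section
  d3 <- segment_transects(list(cbind(x = c(0, 510), y = c(0, 0))), 200)
  expect_equal(d3$x, c(100, 300, 455))
  # along-path positions on a bent polyline
  bent <- list(cbind(x = c(0, 300, 300), y = c(0, 0, 300)))
  db <- segment_transects(bent, 200)
  expect_equal(nrow(db), 3)
  expect_equal(unname(unlist(db[2, c("x", "y")])), c(300, 0))  # midpoint at 300 m
  expect_warning(segment_transects(list(cbind(x = c(5, 5), y = c(5, 5)),
                                        line1000[[1]]), 200), "zero-length")
})

test_that("detections snap to nearest detectors and collapse binarily", {
  dets <- segment_transects(list(cbind(x = c(0, 1000), y = c(0, 0))), 200)
  det <- data.frame(scat_id = c("S1", "S2", "S3", "S4"),
                    x = c(110, 110, 200, 90), y = c(10, -10, 5, 0),
                    occasion = c(1L, 1L, 1L, 2L))
  map <- data.frame(scat_id = c("S1", "S2", "S3", "S4"),
                    individual_id = c("A", "A", "A", "B"))
  capt <- assign_detections(det, dets, map)
  # S1, S2, S3 are all A's, all snap to detector (100, 0) on occasion 1
  # (S3 at x = 200 is equidistant to 100 and 300: lowest detector_id wins),
  # and collapse to a single binary entry
  expect_equal(sum(capt$ch["A", , 1]), 1)
  expect_equal(capt$ch["A", "D0001", 1], 1L)
  expect_equal(capt$ch["A", "D0002", 1], 0L)
  expect_equal(capt$ch["B", "D0001", 2], 1L)
  # far-away scat excluded with warning
  det2 <- rbind(det, data.frame(scat_id = "S5", x = 5000, y = 5000,
                                occasion = 1L))
  map2 <- rbind(map, data.frame(scat_id = "S5", individual_id = "B"))
  expect_warning(assign_detections(det2, dets, map2), "excluded")
})

test_that("half-normal detection has its closed form and domain checks", {
  expect_equal(halfnormal_detect(0, 0.3, 500), 0.3)
  expect_equal(halfnormal_detect(500, 0.3, 500), 0.3 * exp(-0.5))
  d <- seq(1, 2000, by = 1)
  expect_true(all(diff(halfnormal_detect(d, 0.3, 500)) < 0))
  expect_error(halfnormal_detect(-1, 0.3, 500), "domain")
  expect_error(halfnormal_detect(0, 1.2, 500), "domain")
  expect_error(halfnormal_detect(0, 0.3, 0), "domain")
})

test_that("SECR log-likelihood equals a brute-force 3-cell computation", {
  mask <- structure(list(x = c(0, 100, 200), y = c(0, 0, 0), cell_ha = 1,
                         A_ha = 3, resolution = 100), class = "habitat_mask")
  dets <- data.frame(detector_id = "D0001", x = 50, y = 0, transect = 1)
  ch <- array(1L, dim = c(1, 1, 1), dimnames = list("A", "D0001", NULL))
  capt <- structure(list(ch = ch, individuals = "A", detectors = dets,
                         n_occasions = 1), class = "capture_history")
  D <- 0.02; g0 <- 0.3; sigma <- 80
  p <- g0 * exp(-c(50, 50, 150)^2 / (2 * sigma^2))
  by_hand <- -D * sum(p) * 1 + log(D * sum(p) * 1)
  expect_equal(secr_loglik(c(D, g0, sigma), capt, dets, mask), by_hand,
               tolerance = 1e-9)
})

test_that("SECR likelihood is invariant to detector relabeling and mask refinement", {
  geom <- default_fixture_geometry()
  geom <- survey_geometry(geom$transects[1], geom$habitat)
  dets <- segment_transects(geom$transects, 400)
  set.seed(6)
  sv <- simulate_survey(sprintf("I%02d", 1:6), geom, g0 = 0.25, sigma_m = 770,
                        n_occasions = 2, section_length = 400)
  map <- data.frame(scat_id = sv$detections$scat_id,
                    individual_id = sv$detections$individual_id)
  capt <- assign_detections(sv$detections[c("scat_id", "x", "y", "occasion")],
                            dets, map, n_occasions = 2)
  mask <- make_mask(dets, geom$habitat, resolution = 500)
  par <- c(6 / mask$A_ha, 0.25, 770)
  ll <- secr_loglik(par, capt, dets, mask)
  # permute detectors together with capture-history columns
  perm <- sample(nrow(dets))
  dets_p <- dets[perm, ]
  capt_p <- capt; capt_p$ch <- capt$ch[, perm, , drop = FALSE]
  expect_equal(secr_loglik(par, capt_p, dets_p, mask), ll, tolerance = 1e-9)
  # halving the cell size changes the log-likelihood negligibly
  mask2 <- make_mask(dets, geom$habitat, resolution = 250)
  par2 <- c(par[1], par[2], par[3])
  expect_lt(abs(secr_loglik(par2, capt, dets, mask2) - ll), 0.01)
})

test_that("SECR fit satisfies N >= n and beats random parameter vectors", {
  geom <- default_fixture_geometry()
  cfg <- default_fixture_config()
  dets <- segment_transects(geom$transects, 200)
  mask <- make_mask(dets, geom$habitat, resolution = 400)
  set.seed(14)
  sv <- simulate_survey(sprintf("I%02d", 1:9), geom, g0 = cfg$g0,
                        sigma_m = cfg$sigma_m, n_occasions = 2)
  map <- data.frame(scat_id = sv$detections$scat_id,
                    individual_id = sv$detections$individual_id)
  capt <- assign_detections(sv$detections[c("scat_id", "x", "y", "occasion")],
                            dets, map, n_occasions = 2)
  fit <- fit_secr(capt, dets, mask)
  expect_gte(fit$N, fit$n)
  expect_true(fit$estimate$est[3] > 0)
  expect_true(fit$estimate$est[2] > 0 && fit$estimate$est[2] < 1)
  set.seed(15)
  for (i in 1:100) {
    cand <- c(exp(runif(1, log(1e-4), log(0.05))), runif(1, 0.01, 0.9),
              exp(runif(1, log(50), log(5000))))
    expect_gte(fit$loglik + 1e-6, secr_loglik(cand, capt, dets, mask))
  }
})

test_that("abundance is insensitive to extending the buffer beyond 4 sigma", {
  # two parallel transects (cross-line spacing identifies sigma), buffered
  # rectangular mask (no habitat polygon)
  lines <- list(cbind(x = c(0, 6000), y = c(0, 0)),
                cbind(x = c(0, 6000), y = c(800, 800)))
  geom <- survey_geometry(lines, habitat = NULL)
  dets <- segment_transects(lines, 300)
  set.seed(30)
  centers <- cbind(runif(14, -1200, 7200), runif(14, -1200, 2000))
  sv <- simulate_survey(sprintf("I%02d", 1:14), geom, g0 = 0.3, sigma_m = 400,
                        n_occasions = 2, section_length = 300,
                        centers = centers)
  map <- data.frame(scat_id = sv$detections$scat_id,
                    individual_id = sv$detections$individual_id)
  capt <- assign_detections(sv$detections[c("scat_id", "x", "y", "occasion")],
                            dets, map, n_occasions = 2)
  m4 <- make_mask(dets, NULL, resolution = 200, buffer = 4 * 400)
  m6 <- make_mask(dets, NULL, resolution = 200, buffer = 6 * 400)
  f4 <- fit_secr(capt, dets, m4)
  f6 <- fit_secr(capt, dets, m6)
  # with an adequate buffer the density estimate has converged; abundance
  # for a buffered mask is D times the (growing) mask area, so density is
  # the invariant quantity
  expect_lt(abs(f6$estimate$est[1] / f4$estimate$est[1] - 1), 0.02)
  expect_lt(abs(f6$estimate$est[3] / f4$estimate$est[3] - 1), 0.02)
})
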