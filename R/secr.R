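#' Cut transect polylines into sections and place proximity detectors
#'
#' Each polyline is divided into consecutive sections of
#' \code{section_length} measured along the path. A final remainder longer
#' than half a section becomes its own section; otherwise it is merged into
#' the previous one. The detector sits at each section's along-path
#' midpoint.
#'
#' @param polylines list of 2-column (x, y) vertex matrices.
#' @param section_length section length in meters (default 200).
#' @return data.frame(detector_id, x, y, transect) ordered by transect and
#'   position.
#' @export
segment_transects <- function(polylines, section_length = 200) {
  stopifnot(section_length > 0)
  out <- list()
  for (t in seq_along(polylines)) {
    m <- polylines[[t]]
    seg <- sqrt(diff(m[, 1])^2 + diff(m[, 2])^2)
    L <- sum(seg)
    if (L <= 0) { warning("zero-length polyline ", t, " skipped"); next }
    n_full <- floor(L / section_length)
    rem <- L - n_full * section_length
    bounds <- if (n_full == 0) c(0, L)
      else if (rem > section_length / 2 + 1e-9)
        c(seq(0, n_full * section_length, by = section_length), L)
      else c(seq(0, (n_full - 1) * section_length, by = section_length), L)
    mids <- (bounds[-1] + bounds[-length(bounds)]) / 2
    pts <- t(vapply(mids, function(s) point_along(m, seg, s), numeric(2)))
    out[[length(out) + 1]] <- data.frame(x = pts[, 1], y = pts[, 2],
                                         transect = t)
  }
  if (length(out) == 0) stop("no usable transects")
  det <- do.call(rbind, out)
  det <- cbind(detector_id = sprintf("D%04d", seq_len(nrow(det))), det)
  det$detector_id <- as.character(det$detector_id)
  rownames(det) <- NULL
  det
}

# interpolate the point at along-path distance s on polyline m
point_along <- function(m, seg, s) {
  cum <- c(0, cumsum(seg))
  i <- max(which(cum <= s + 1e-9))
  if (i >= length(cum)) return(c(m[nrow(m), 1], m[nrow(m), 2]))
  f <- (s - cum[i]) / seg[i]
  c(m[i, 1] + f * (m[i + 1, 1] - m[i, 1]),
    m[i, 2] + f * (m[i + 1, 2] - m[i, 2]))
}

#' Assemble a binary capture history from scat detections
#'
#' Each scat is snapped to its nearest detector (Euclidean; ties go to the
#' lowest detector_id) and attributed to its individual; multiple scats of
#' one individual at one detector x occasion collapse to a single binary
#' detection (proximity detector). Scats farther than \code{max_snap} from
#' every detector are excluded with a warning.
#'
#' @param detections data.frame(scat_id, x, y, occasion).
#' @param detectors data.frame from \code{\link{segment_transects}}.
#' @param individuals_map data.frame(scat_id, individual_id); scats absent
#'   from the map are ignored (unidentified samples).
#' @param n_occasions number of occasions K (default: max occasion seen).
#' @param max_snap maximum snap distance in meters (default 500).
#' @return capture_history: list(ch = n x J x K binary array, individuals,
#'   detectors, n_occasions).
#' @export
assign_detections <- function(detections, detectors, individuals_map,
                              n_occasions = NULL, max_snap = 500) {
  det <- merge(detections, individuals_map, by = "scat_id")
  det <- det[!is.na(det$individual_id), ]
  if (nrow(det) == 0) stop("no identified detections")
  if (is.null(n_occasions)) n_occasions <- max(det$occasion)
  ids <- sort(unique(det$individual_id))
  J <- nrow(detectors)
  ch <- array(0L, dim = c(length(ids), J, n_occasions),
              dimnames = list(ids, detectors$detector_id, NULL))
  dropped <- 0
  for (r in seq_len(nrow(det))) {
    d2 <- (detectors$x - det$x[r])^2 + (detectors$y - det$y[r])^2
    j <- which.min(d2)  # detectors are ordered by detector_id: ties -> lowest
    if (sqrt(d2[j]) > max_snap) { dropped <- dropped + 1; next }
    ch[det$individual_id[r], j, det$occasion[r]] <- 1L
  }
  if (dropped > 0)
    warning(dropped, " scat(s) farther than ", max_snap,
            " m from any detector were excluded")
  detected <- apply(ch, 1, sum) > 0
  ch <- ch[detected, , , drop = FALSE]
  structure(list(ch = ch, individuals = ids[detected], detectors = detectors,
                 n_occasions = n_occasions), class = "capture_history")
}

#' Half-normal detection function
#'
#' Probability that an animal with activity center at distance \code{d} from
#' a detector is detected there on one occasion:
#' \eqn{g(d) = g_0 \exp(-d^2 / (2\sigma^2))}.
#'
#' @param d distance in meters (>= 0).
#' @param g0 detection probability at distance 0, in (0, 1).
#' @param sigma spatial scale in meters (> 0).
#' @return detection probability (vectorized over d).
#' @export
halfnormal_detect <- function(d, g0, sigma) {
  if (any(d < 0) || !is.finite(sigma) || sigma <= 0 ||
      g0 <= 0 || g0 >= 1)
    stop("invalid domain: need d >= 0, sigma > 0, g0 in (0, 1)")
  g0 * exp(-d^2 / (2 * sigma^2))
}

#' Habitat integration mask for the SECR likelihood
#'
#' The habitat polygon is discretized into square cells of side
#' \code{resolution}; cell centers inside the polygon form the mask. Without
#' a polygon a rectangular buffer of \code{buffer} meters around the
#' detectors is used.
#'
#' @param detectors detector data.frame.
#' @param habitat list of polygon ring matrices, or NULL.
#' @param resolution cell side, meters (default 250).
#' @param buffer buffer width when no polygon is given (default 4 * 770 m).
#' @return habitat_mask: list(x, y, cell_ha, A_ha, resolution).
#' @export
make_mask <- function(detectors, habitat = NULL, resolution = 250,
                      buffer = 3080) {
  if (!is.null(habitat)) {
    ring <- habitat[[1]]
    bx <- range(ring[, 1]); by <- range(ring[, 2])
    gx <- seq(bx[1] + resolution / 2, bx[2], by = resolution)
    gy <- seq(by[1] + resolution / 2, by[2], by = resolution)
    grid <- as.matrix(expand.grid(x = gx, y = gy))
    inside <- mgcv::in.out(rbind(ring, ring[1, , drop = FALSE]), grid)
    grid <- grid[inside, , drop = FALSE]
  } else {
    gx <- seq(min(detectors$x) - buffer + resolution / 2,
              max(detectors$x) + buffer, by = resolution)
    gy <- seq(min(detectors$y) - buffer + resolution / 2,
              max(detectors$y) + buffer, by = resolution)
    grid <- as.matrix(expand.grid(x = gx, y = gy))
  }
  if (nrow(grid) == 0) stop("empty habitat mask")
  cell_ha <- resolution^2 / 1e4
  structure(list(x = grid[, 1], y = grid[, 2], cell_ha = cell_ha,
                 A_ha = cell_ha * nrow(grid), resolution = resolution),
            class = "habitat_mask")
}

#' SECR log-likelihood for binary proximity detectors
#'
#' Homogeneous-Poisson maximum-likelihood formulation with the half-normal
#' detection function, integrating over activity centers by summation over
#' the habitat mask: with per-occasion detection probability
#' p_j(x) = g0 exp(-d_j(x)^2/(2 sigma^2)) and overall
#' p.(x) = 1 - prod_{j,k} (1 - p_j(x)),
#' \deqn{\log L = -D \sum_x p.(x) a + \sum_i \log [ D \sum_x \Pr(\omega_i |
#' x) a ]}
#' where a is the mask cell area (ha) and D the density (animals/ha).
#'
#' @param params c(D, g0, sigma) on the natural scale.
#' @param capthist capture_history.
#' @param detectors detector data.frame (must match the capture history).
#' @param mask habitat_mask.
#' @return log-likelihood value.
#' @export
secr_loglik <- function(params, capthist, detectors, mask) {
  d2 <- outer(mask$x, detectors$x, "-")^2 + outer(mask$y, detectors$y, "-")^2
  nmat <- apply(capthist$ch, c(1, 2), sum)  # detections per ind x detector
  secr_loglik_core(params[1], params[2], params[3], d2, nmat,
                   capthist$n_occasions, mask$cell_ha)
}

secr_loglik_core <- function(D, g0, sigma, d2, nmat, K, a) {
  if (!is.finite(D) || D <= 0 || g0 <= 0 || g0 >= 1 || sigma <= 0)
    return(-Inf)
  P <- g0 * exp(-d2 / (2 * sigma^2))      # M x J
  log1mP <- log1p(-P)
  # p.(x): at least one detection anywhere over J detectors x K occasions
  log_pdot_c <- K * rowSums(log1mP)       # log prod (1-p)^K
  pdot <- -expm1(log_pdot_c)
  # log Pr(omega_i | x): nmat is n x J counts of occasions with detection
  # (clamp so that 0-count detectors with underflowed P stay 0 * finite)
  logP <- log(pmax(P, 1e-300))
  lpr <- nmat %*% t(logP) + (K - nmat) %*% t(log1mP)   # n x M
  m <- apply(lpr, 1, max)
  li <- m + log(rowSums(exp(lpr - m)))    # log sum_x Pr(omega|x)
  sum(log(D) + li + log(a)) - D * sum(pdot) * a
}

#' Fit the SECR model by maximum likelihood
#'
#' Maximizes \code{\link{secr_loglik}} over (log D, logit g0, log sigma)
#' with Nelder-Mead, computes standard errors from the inverse numerical
#' Hessian on the link scale, back-transforms Wald confidence intervals, and
#' reports abundance N = D * A with a delta-method SE and a lognormal CI.
#'
#' @param capthist capture_history.
#' @param detectors detector data.frame.
#' @param mask habitat_mask.
#' @param start optional c(D, g0, sigma) natural-scale starting values;
#'   defaults are D = n/A, g0 = 0.1, sigma = half the mean inter-detection
#'   distance.
#' @return secr_fit: list(estimate = data.frame(parameter, est, se, lcl,
#'   ucl), N, se_N, N_ci, loglik, convergence, n, A_ha, vcov_link).
#' @export
fit_secr <- function(capthist, detectors, mask, start = NULL) {
  nmat <- apply(capthist$ch, c(1, 2), sum)
  n <- nrow(nmat)
  if (n < 2) warning("fewer than 2 detected individuals; estimates unstable")
  d2 <- outer(mask$x, detectors$x, "-")^2 + outer(mask$y, detectors$y, "-")^2
  K <- capthist$n_occasions
  a <- mask$cell_ha
  if (is.null(start)) {
    locs <- which(nmat > 0, arr.ind = TRUE)
    pts <- cbind(detectors$x[locs[, 2]], detectors$y[locs[, 2]])
    sigma0 <- if (nrow(pts) > 1) mean(dist(pts)) / 2 else 500
    start <- c(n / mask$A_ha, 0.1, sigma0)
  }
  th0 <- c(log(start[1]), stats::qlogis(start[2]), log(start[3]))
  negll <- function(th) {
    -secr_loglik_core(exp(th[1]), stats::plogis(th[2]), exp(th[3]),
                      d2, nmat, K, a)
  }
  if (!is.finite(negll(th0)))
    th0 <- c(log(n / mask$A_ha), stats::qlogis(0.1), log(500))
  opt <- optim(th0, negll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  if (opt$convergence != 0)
    warning("optimizer did not report convergence (code ", opt$convergence, ")")
  th <- opt$par
  H <- optimHess(th, negll)
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 3, 3))
  se_link <- sqrt(pmax(diag(vc), 0))
  z <- qnorm(0.975)
  back <- list(function(x) exp(x), function(x) stats::plogis(x),
               function(x) exp(x))
  est <- vapply(1:3, function(i) back[[i]](th[i]), numeric(1))
  lcl <- vapply(1:3, function(i) back[[i]](th[i] - z * se_link[i]), numeric(1))
  ucl <- vapply(1:3, function(i) back[[i]](th[i] + z * se_link[i]), numeric(1))
  # delta method on the natural scale: d(exp)/dx = exp, d(plogis)/dx = p(1-p)
  grad <- c(est[1], est[2] * (1 - est[2]), est[3])
  se_nat <- se_link * grad
  D <- est[1]
  Nhat <- D * mask$A_ha
  se_N <- se_nat[1] * mask$A_ha
  N_ci <- c(lcl[1], ucl[1]) * mask$A_ha
  if (est[2] > 0.95) warning("g0 estimate near boundary")
  structure(list(
    estimate = data.frame(parameter = c("D", "g0", "sigma"),
                          est = est, se = se_nat, lcl = lcl, ucl = ucl,
                          stringsAsFactors = FALSE),
    N = Nhat, se_N = se_N, N_ci = N_ci,
    loglik = -opt$value, convergence = opt$convergence,
    n = n, A_ha = mask$A_ha, vcov_link = vc), class = "secr_fit")
}

#' @export
print.secr_fit <- function(x, ...) {
  cat("SECR fit (half-normal, binary proximity):",
      x$n, "individuals, mask", round(x$A_ha), "ha\n")
  print(x$estimate, row.names = FALSE)
  cat(sprintf("N-hat = %.2f (SE %.3f, 95%% CI %.1f-%.1f), logLik = %.3f\n",
              x$N, x$se_N, x$N_ci[1], x$N_ci[2], x$loglik))
  invisible(x)
}
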