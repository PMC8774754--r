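## Shared fixtures and independent oracles.

## Points on an ellipse (center, semi-axes a >= b, orientation th), at
## parametric angles u.
ellipsePts <- function(u, cx = 0, cy = 0, a = 1, b = 1, th = 0) {
  cbind(cx + a * cos(u) * cos(th) - b * sin(u) * sin(th),
        cy + a * cos(u) * sin(th) + b * sin(u) * cos(th))
}

## A clean circular 9+2 section: A-centers on a circle of radius R, B-centers
## on the same circle at chord distance rA+rB (aligned), except doublets in
## `tiltIdx`, whose axis is rotated outward about the A-center by tiltDeg.
makeSection <- function(R = 60, rA = 12, rB = 14, tiltIdx = integer(0),
                        tiltDeg = 40, id = "t", disorganized = FALSE,
                        centralPairCount = 2L, oda = TRUE, ida = TRUE,
                        drop = integer(0)) {
  L <- rA + rB
  dphi <- 2 * asin(L / (2 * R))          # chord of length L on the circle
  th <- pi / 2 + (0:8) * 2 * pi / 9
  axy <- cbind(R * cos(th), R * sin(th))
  rows <- lapply(setdiff(1:9, drop), function(i) {
    chord <- (c(R * cos(th[i] + dphi), R * sin(th[i] + dphi)) - axy[i, ]) / L
    t <- if (i %in% tiltIdx) tiltDeg * pi / 180 else 0
    nrm <- axy[i, ] / R
    d1 <- c(cos(t) * chord[1] - sin(t) * chord[2], sin(t) * chord[1] + cos(t) * chord[2])
    d2 <- c(cos(t) * chord[1] + sin(t) * chord[2], -sin(t) * chord[1] + cos(t) * chord[2])
    dir <- if (sum(d1 * nrm) >= sum(d2 * nrm)) d1 else d2
    b <- axy[i, ] + L * dir
    data.frame(index = i, ax = axy[i, 1], ay = axy[i, 2], bx = b[1], by = b[2],
               r_a = rA, r_b = rB, oda = oda, ida = ida)
  })
  CrossSection(id, do.call(rbind, rows), centralPairCount = centralPairCount,
               disorganized = disorganized)
}

## --- independent ellipse-fit oracle -----------------------------------
## Objective: summed squared distances to a dense polygonal approximation
## of the ellipse (independent of the package's projection code). The
## coarse default is used during the oracle's grid search; comparisons
## against the package fit use a fine polygon (m = 4096), where the
## vertex-discretization bias is negligible.
polyObjective <- function(par, pts, m = 720L) {
  u <- seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]
  E <- ellipsePts(u, par[1], par[2], par[3], par[4], par[5])
  s <- 0
  for (i in seq_len(nrow(pts)))
    s <- s + min((E[, 1] - pts[i, 1])^2 + (E[, 2] - pts[i, 2])^2)
  s
}

## Brute-force minimizer: moment-based start, then coordinate-descent grid
## refinement down to 1e-3 resolution.
oracleEllipseFit <- function(pts) {
  ctr <- colMeans(pts)
  cpts <- sweep(pts, 2, ctr)
  ev <- eigen(stats::cov(cpts), symmetric = TRUE)
  th0 <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) %% pi
  proj <- cpts %*% ev$vectors
  par <- c(ctr, max(abs(proj[, 1])), max(abs(proj[, 2])), th0)
  if (par[3] < par[4]) { par[3:4] <- par[4:3]; par[5] <- (par[5] + pi / 2) %% pi }
  step <- c(2, 2, 2, 2, 0.2)
  best <- polyObjective(par, pts)
  for (iter in 1:60) {
    improved <- FALSE
    for (k in 1:5) for (s in c(-1, 1)) {
      cand <- par; cand[k] <- cand[k] + s * step[k]
      if (cand[3] <= 0 || cand[4] <= 0) next
      obj <- polyObjective(cand, pts)
      if (obj < best - 1e-12) { par <- cand; best <- obj; improved <- TRUE }
    }
    if (!improved) step <- step / 2
    if (max(step) < 1e-3) break
  }
  list(par = par, objective = best)
}

## Independent tangent oracle: nearest curve point found by golden-section
## search over the parameter, tangent by central finite differences.
oracleTangentAngle <- function(cx, cy, a, b, th, p, v) {
  d2 <- function(u) {
    e <- ellipsePts(u, cx, cy, a, b, th)
    (e[1] - p[1])^2 + (e[2] - p[2])^2
  }
  us <- seq(0, 2 * pi, length.out = 721L)
  u0 <- us[which.min(vapply(us, d2, numeric(1)))]
  opt <- stats::optimize(d2, c(u0 - 0.02, u0 + 0.02), tol = 1e-12)
  h <- 1e-6
  tg <- (ellipsePts(opt$minimum + h, cx, cy, a, b, th) -
           ellipsePts(opt$minimum - h, cx, cy, a, b, th)) / (2 * h)
  cosang <- abs(sum(v * tg)) / (sqrt(sum(v^2)) * sqrt(sum(tg^2)))
  acos(min(1, cosang)) * 180 / pi
}

## Well-separated tilt regime: exactly k rotated doublets at 40 degrees,
## aligned doublets flat, no coordinate jitter unless overridden.
wellSeparatedSpec <- function(k, n = 10L, seed = 1L, ...) {
  d <- rep(0, 10); d[k + 1] <- 1
  sceneSpec(nSections = n, aCenterJitterSd = 0, angularJitterSd = 0,
            tiltAlignedSd = 0, tiltRotatedMean = 40, tiltRotatedSd = 0,
            tiltRotatedRange = c(40, 40), nRotatedDist = d, seed = seed, ...)
}

## As above, also without blur or noise (exact renders).
cleanSpec <- function(k = 0L, seed = 1L, ...)
  wellSeparatedSpec(k, n = 1L, seed = seed, psfSigma = 0, noiseSd = 0, ...)
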