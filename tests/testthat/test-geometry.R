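test_that("noiseless circle points are recovered exactly", {
  th <- seq(0, 320, by = 40) * pi / 180
  f <- fitCircumference(cbind(100 * cos(th), 100 * sin(th)), kind = "circle")
  p <- fitParams(f)
  expect_equal(p$center, c(0, 0), tolerance = 1e-9)
  expect_equal(p$semiMajor, 100, tolerance = 1e-9)
  expect_lt(p$rmsResidual, 1e-9)
})

test_that("noiseless ellipse points are recovered to 1e-6 relative error", {
  u <- seq(0, 2 * pi, length.out = 10L)[-10L]
  for (case in list(c(120, 90, pi / 6), c(80, 60, 1.1), c(60, 51, 2.8))) {
    pts <- ellipsePts(u, 10, -5, case[1], case[2], case[3])
    f <- fitCircumference(pts, kind = "ellipse")
    p <- fitParams(f)
    expect_equal(p$center, c(10, -5), tolerance = 1e-6)
    expect_equal(p$semiMajor, case[1], tolerance = 1e-6)
    expect_equal(p$semiMinor, case[2], tolerance = 1e-6)
    expect_equal(p$orientation %% pi, case[3] %% pi, tolerance = 1e-6)
  }
})

test_that("kind = auto fits an ellipse when warranted and falls back to circle", {
  u <- seq(0, 2 * pi, length.out = 10L)[-10L]
  f <- fitCircumference(ellipsePts(u, 0, 0, 120, 90, 0.5), kind = "auto")
  expect_identical(fitParams(f)$kind, "ellipse")
  ## highly eccentric configuration exceeds the cap -> circle fallback
  f2 <- fitCircumference(ellipsePts(u, 0, 0, 120, 30, 0.5), kind = "auto")
  expect_identical(fitParams(f2)$kind, "circle")
  ## with 5 points auto must use a circle even if they lie on an ellipse
  f3 <- fitCircumference(ellipsePts(u[1:5], 0, 0, 120, 90, 0.5), kind = "auto")
  expect_identical(fitParams(f3)$kind, "circle")
})

test_that("jittered fits agree with the brute-force grid oracle", {
  set.seed(11)
  u <- seq(0, 2 * pi, length.out = 10L)[-10L]
  for (i in 1:5) {
    pts <- ellipsePts(u, 0, 0, 120, 90, pi / 7) +
      matrix(rnorm(18, sd = 2), ncol = 2)
    f <- fitCircumference(pts, kind = "ellipse")
    p <- fitParams(f)
    orc <- oracleEllipseFit(pts)
    ## parameters agree to the oracle's own discretization accuracy
    ## (720-vertex polygon, ~0.45 px vertex spacing)
    expect_lt(max(abs(p$center - orc$par[1:2])), 0.3)
    expect_lt(max(abs(c(p$semiMajor, p$semiMinor) - orc$par[3:4])), 0.3)
    ## under a fine, unbiased polygonal metric the package fit must be at
    ## least as good as the brute-force solution
    ours <- polyObjective(c(p$center, p$semiMajor, p$semiMinor, p$orientation),
                          pts, m = 4096L)
    expect_lte(ours, polyObjective(orc$par, pts, m = 4096L) + 1e-3)
  }
})

test_that("degenerate configurations raise typed errors", {
  expect_error(fitCircumference(cbind(1:2, 1:2), kind = "circle"),
               class = "axosymPreconditionError")
  expect_error(fitCircumference(cbind(1:9, 2 * (1:9)), kind = "circle"),
               class = "axosymDegenerateFitError")
  expect_error(fitCircumference(matrix(1, 9, 2), kind = "ellipse"),
               class = "axosymDegenerateFitError")
  expect_error(fitCircumference(ellipsePts(c(0, 1, 2, 3), a = 10, b = 8),
                                kind = "ellipse"),
               class = "axosymPreconditionError")
  ## error names the section
  expect_error(fitCircumference(cbind(1:9, 2 * (1:9)), sectionId = "sec7"),
               regexp = "sec7")
})

test_that("radial clearance is a signed orthogonal distance", {
  th <- seq(0, 320, by = 40) * pi / 180
  fc <- fitCircumference(cbind(100 * cos(th), 100 * sin(th)), kind = "circle")
  expect_equal(radialClearance(fc, c(100, 0)), 0, tolerance = 1e-9)
  expect_equal(radialClearance(fc, c(130, 0)), 30, tolerance = 1e-9)
  expect_equal(radialClearance(fc, c(0, 50)), -50, tolerance = 1e-9)
  u <- seq(0, 2 * pi, length.out = 10L)[-10L]
  fe <- fitCircumference(ellipsePts(u, a = 120, b = 90), kind = "ellipse")
  expect_equal(radialClearance(fe, c(0, 100)), 10, tolerance = 1e-6)
  expect_equal(radialClearance(fe, c(125, 0)), 5, tolerance = 1e-6)
})

test_that("clearance sign agrees with the implicit point-in-ellipse test", {
  set.seed(42)
  u <- seq(0, 2 * pi, length.out = 10L)[-10L]
  a <- 120; b <- 90; th <- 0.7; ctr <- c(3, -8)
  fe <- fitCircumference(ellipsePts(u, ctr[1], ctr[2], a, b, th),
                         kind = "ellipse")
  n <- 10000L
  pts <- cbind(runif(n, -180, 180), runif(n, -180, 180))
  cl <- radialClearance(fe, pts)
  loc <- sweep(pts, 2, ctr) %*% matrix(c(cos(th), -sin(th), sin(th), cos(th)),
                                       2, 2, byrow = TRUE)
  impl <- (loc[, 1] / a)^2 + (loc[, 2] / b)^2 - 1
  off <- abs(cl) > 1e-7
  expect_true(all(sign(cl[off]) == sign(impl[off])))
})

test_that("tilt angle matches limiting cases and the finite-difference oracle", {
  u <- seq(0, 2 * pi, length.out = 10L)[-10L]
  fe <- fitCircumference(ellipsePts(u, a = 120, b = 90), kind = "ellipse")
  ## at (120, 0) the tangent is vertical, the normal horizontal
  expect_equal(tiltAngle(fe, c(120, 0), c(120, 10)), 0, tolerance = 1e-9)
  expect_equal(tiltAngle(fe, c(120, 0), c(140, 0)), 90, tolerance = 1e-9)
  expect_error(tiltAngle(fe, c(120, 0), c(120, 0)),
               class = "axosymDegenerateDoubletError")
  set.seed(5)
  for (i in 1:25) {
    a <- runif(1, 60, 140); b <- a * runif(1, 0.6, 1); th <- runif(1, 0, pi)
    ctr <- rnorm(2, sd = 10)
    f <- fitCircumference(ellipsePts(u, ctr[1], ctr[2], a, b, th),
                          kind = "ellipse")
    p <- ellipsePts(runif(1, 0, 2 * pi), ctr[1], ctr[2], a, b, th) +
      rnorm(2, sd = 4)
    v <- rnorm(2); v <- v / sqrt(sum(v^2)) * 26
    got <- tiltAngle(f, drop(p), drop(p) + v)
    want <- oracleTangentAngle(ctr[1], ctr[2], a, b, th, drop(p), v)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("clearance and calls are invariant under rigid motion and scaling", {
  sec <- makeSection(tiltIdx = c(2, 5, 9), tiltDeg = 40)
  base <- rotationCalls(sec)
  set.seed(9)
  for (i in 1:5) {
    th <- runif(1, 0, 2 * pi); sc <- runif(1, 0.5, 3); tr <- rnorm(2, sd = 50)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    d <- doublets(sec)
    ab <- as.matrix(d[, c("ax", "ay")]) %*% t(R) * sc
    bb <- as.matrix(d[, c("bx", "by")]) %*% t(R) * sc
    d2 <- data.frame(index = d$index, ax = ab[, 1] + tr[1], ay = ab[, 2] + tr[2],
                     bx = bb[, 1] + tr[1], by = bb[, 2] + tr[2],
                     r_a = d$r_a * sc, r_b = d$r_b * sc)
    calls <- rotationCalls(CrossSection("x", d2))
    expect_identical(calls$rotated, base$rotated)
    expect_equal(calls$clearance, base$clearance * sc, tolerance = 1e-4)
  }
})
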