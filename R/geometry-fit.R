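## Geometric fitting of the axonemal circumference and point-to-curve
## primitives. All coordinates are in the mathematical frame (y up, angles
## CCW from +x).

.err <- function(msg, class) stop(errorCondition(msg, class = c(class, "axosymError")))

.rotmat <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

.asPoints <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 2L) stop("points must be an n x 2 matrix")
    p
  } else {
    if (length(p) != 2L) stop("a point must have 2 coordinates")
    matrix(p, 1L, 2L)
  }
}

## ---- circle -----------------------------------------------------------

## Kasa algebraic circle fit: linear least squares on
## x^2 + y^2 = 2 cx x + 2 cy y + (r^2 - cx^2 - cy^2).
.circleKasa <- function(pts) {
  A <- cbind(2 * pts[, 1], 2 * pts[, 2], 1)
  z <- pts[, 1]^2 + pts[, 2]^2
  sol <- tryCatch(qr.solve(A, z), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  list(center = sol[1:2], r = sqrt(r2))
}

## Geometric circle fit: given the center, the optimal radius is the mean
## distance, so only the center is optimized.
.fitCircleGeom <- function(pts) {
  init <- .circleKasa(pts)
  if (is.null(init)) init <- list(center = colMeans(pts),
                                  r = mean(sqrt(rowSums(sweep(pts, 2, colMeans(pts))^2))))
  obj <- function(c0) {
    d <- sqrt((pts[, 1] - c0[1])^2 + (pts[, 2] - c0[2])^2)
    sum((d - mean(d))^2)
  }
  opt <- stats::optim(init$center, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  c0 <- opt$par
  d <- sqrt((pts[, 1] - c0[1])^2 + (pts[, 2] - c0[2])^2)
  list(center = c0, r = mean(d), rms = sqrt(mean((d - mean(d))^2)))
}

## ---- ellipse ----------------------------------------------------------

## Direct least-squares conic fit (Halir & Flusser's numerically stable
## variant of the Fitzgibbon method); used to initialize the geometric fit.
.ellipseAlgebraic <- function(pts) {
  x <- pts[, 1] - mean(pts[, 1]); y <- pts[, 2] - mean(pts[, 2])
  D1 <- cbind(x^2, x * y, y^2); D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T1)) return(NULL)
  M <- S1 + S2 %*% T1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- tryCatch(eigen(M), error = function(e) NULL)
  if (is.null(ev)) return(NULL)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) return(NULL)
  a1 <- V[, ok[1]]
  coefs <- c(a1, T1 %*% a1)      # A B C D E F on centered coords
  g <- .conicToGeom(coefs)
  if (is.null(g)) return(NULL)
  g$center <- g$center + c(mean(pts[, 1]), mean(pts[, 2]))
  g
}

## Conic A x^2 + B x y + C y^2 + D x + E y + F = 0 -> center/axes/angle.
.conicToGeom <- function(k) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  den <- 4 * A * C - B^2
  if (den <= 0) return(NULL)
  cx <- (B * E - 2 * C * D) / den
  cy <- (B * D - 2 * A * E) / den
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  if (Fc >= 0) return(NULL)
  M <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  ev <- eigen(M, symmetric = TRUE)
  ax2 <- -Fc / ev$values
  if (any(ax2 <= 0)) return(NULL)
  ax <- sqrt(ax2)                # eigen() sorts values decreasingly,
  i <- which.max(ax)             # so the larger axis is the smaller eigenvalue
  theta <- atan2(ev$vectors[2, i], ev$vectors[1, i])
  theta <- theta %% pi
  list(center = c(cx, cy), a = max(ax), b = min(ax), theta = theta)
}

## Nearest point on the axis-aligned ellipse x^2/a^2 + y^2/b^2 = 1 to (p, q),
## by root-finding on the orthogonal-projection equation. Returns the foot
## point, the unsigned distance and the inside/outside sign.
.ellipseNearest <- function(a, b, p, q) {
  if (a - b < 1e-12 * a) {       # effectively a circle
    r <- sqrt(p^2 + q^2)
    if (r == 0) return(list(x = a, y = 0, dist = a, sgn = -1))
    return(list(x = a * p / r, y = a * q / r, dist = abs(r - a),
                sgn = if (r >= a) (r > a) * 2 - 1 else -1))
  }
  sp <- if (p >= 0) 1 else -1; sq <- if (q >= 0) 1 else -1
  P <- abs(p); Q <- abs(q)
  impl <- (p / a)^2 + (q / b)^2 - 1
  sgn <- if (impl > 0) 1 else if (impl < 0) -1 else 0
  if (P == 0 && Q == 0)
    return(list(x = 0, y = b, dist = b, sgn = -1))
  if (Q < 1e-14 * b && P < (a^2 - b^2) / a) {
    # interior point near the major axis: the foot is off-axis
    x <- a^2 * P / (a^2 - b^2)
    y <- b * sqrt(max(0, 1 - (x / a)^2))
    return(list(x = sp * x, y = sq * y, dist = sqrt((x - P)^2 + y^2), sgn = -1))
  }
  ## F(t) is convex and decreasing on (-b^2, Inf), so Newton iteration from
  ## any point with F > 0 converges monotonically (quadratically) to the root
  aP <- a * P; bQ <- b * Q
  t0 <- max(aP - a^2, bQ - b^2)
  for (it in 1:60) {
    ta <- t0 + a^2; tb <- t0 + b^2
    Fv <- (aP / ta)^2 + (bQ / tb)^2 - 1
    if (Fv < 1e-14) break
    dF <- -2 * ((aP^2) / ta^3 + (bQ^2) / tb^3)
    t0 <- t0 - Fv / dF
  }
  x <- a^2 * P / (t0 + a^2); y <- b^2 * Q / (t0 + b^2)
  list(x = sp * x, y = sq * y, dist = sqrt((x - P)^2 + (y - Q)^2), sgn = sgn)
}

## World-frame projection onto a CircumferenceFit: foot point, signed
## clearance, unit tangent and outward unit normal at the foot.
.curveProject <- function(fit, p) {
  if (fit@kind == "circle") {
    v <- p - fit@center
    r <- sqrt(sum(v^2))
    u <- if (r == 0) c(1, 0) else v / r
    foot <- fit@center + fit@semiMajor * u
    return(list(foot = foot, clearance = r - fit@semiMajor,
                tangent = c(-u[2], u[1]), normal = u))
  }
  R <- .rotmat(fit@orientation)
  pl <- drop(t(R) %*% (p - fit@center))
  np <- .ellipseNearest(fit@semiMajor, fit@semiMinor, pl[1], pl[2])
  footl <- c(np$x, np$y)
  nrm <- c(footl[1] / fit@semiMajor^2, footl[2] / fit@semiMinor^2)
  nrm <- nrm / sqrt(sum(nrm^2))
  tng <- c(-nrm[2], nrm[1])
  list(foot = drop(R %*% footl) + fit@center,
       clearance = np$sgn * np$dist,
       tangent = drop(R %*% tng), normal = drop(R %*% nrm))
}

.geomResiduals <- function(pts, center, a, b, theta) {
  R <- .rotmat(theta)
  dx <- pts[, 1] - center[1]; dy <- pts[, 2] - center[2]
  P <- abs(dx * R[1, 1] + dy * R[2, 1])
  Q <- abs(dx * R[1, 2] + dy * R[2, 2])
  ## vectorized Newton on the projection equation (see .ellipseNearest);
  ## adequate for fit residuals, where points lie near the curve
  aP <- a * P; bQ <- b * Q
  a2 <- a * a; b2 <- b * b
  t0 <- pmax(aP - a2, bQ - b2, -0.999 * b2)
  for (it in 1:12) {
    ta <- t0 + a2; tb <- t0 + b2
    Fv <- (aP / ta)^2 + (bQ / tb)^2 - 1
    dF <- -2 * (aP * aP / (ta * ta * ta) + bQ * bQ / (tb * tb * tb))
    t0 <- t0 - pmax(Fv, 0) / dF
  }
  x <- a^2 * P / (t0 + a^2); y <- b^2 * Q / (t0 + b^2)
  sqrt((x - P)^2 + (y - Q)^2)
}

.fitEllipseGeom <- function(pts) {
  init <- .ellipseAlgebraic(pts)
  if (is.null(init)) {
    cg <- .fitCircleGeom(pts)
    init <- list(center = cg$center, a = cg$r * 1.05, b = cg$r * 0.95, theta = 0)
  }
  ## canonical form: semi-major first; swapping the axes rotates the
  ## orientation by 90 degrees (objective and extraction must agree)
  canon <- function(par) {
    a <- exp(par[3]); b <- exp(par[4]); th <- par[5]
    if (a < b) { tmp <- a; a <- b; b <- tmp; th <- th + pi / 2 }
    list(a = a, b = b, th = th)
  }
  resid <- function(par) {
    g <- canon(par)
    if (!is.finite(g$a) || !is.finite(g$b)) return(rep(1e6, nrow(pts)))
    .geomResiduals(pts, par[1:2], g$a, g$b, g$th)
  }
  par0 <- c(init$center, log(init$a), log(init$b), init$theta)
  opt <- minpack.lm::nls.lm(par0, fn = resid,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-15, ptol = 1e-13, maxiter = 200))
  g <- canon(opt$par)
  a <- g$a; b <- g$b
  theta <- g$th %% pi
  res <- .geomResiduals(pts, opt$par[1:2], a, b, theta)
  list(center = opt$par[1:2], a = a, b = b, theta = theta,
       rms = sqrt(mean(res^2)))
}

## ---- public operations ------------------------------------------------

#' Fit the axonemal circumference through A-tubule centers
#'
#' Fits the closed curve joining the centers of the A-tubules of a
#' cross-section — a circle or an ellipse — by least squares on the
#' geometric (orthogonal) residuals. The algebraic direct ellipse fit (or
#' the Kasa circle fit) provides the starting point; Nelder-Mead refinement
#' then minimizes the summed squared orthogonal distances.
#'
#' With \code{kind = "auto"} an ellipse is fitted when at least 6 points are
#' available and the result is non-degenerate (eccentricity at most
#' \code{eccentricityCap}); otherwise the fit falls back to a circle.
#'
#' @param aCenters n x 2 matrix of A-tubule centers (pixels); at least 3
#'   points for a circle, 5 for an ellipse, not all collinear.
#' @param kind "circle", "ellipse" or "auto".
#' @param eccentricityCap maximum eccentricity \eqn{\sqrt{1-(b/a)^2}}
#'   accepted for an auto ellipse fit before falling back to a circle.
#' @param sectionId optional identifier used in error messages.
#' @return A \linkS4class{CircumferenceFit}.
#' @examples
#' th <- seq(0, 320, by = 40) * pi / 180
#' fitCircumference(cbind(100 * cos(th), 100 * sin(th)), kind = "circle")
#' @export
fitCircumference <- function(aCenters, kind = c("auto", "ellipse", "circle"),
                             eccentricityCap = 0.8, sectionId = NULL) {
  kind <- match.arg(kind)
  pts <- .asPoints(aCenters)
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  who <- if (is.null(sectionId)) "" else paste0(" [section ", sectionId, "]")
  need <- if (kind == "ellipse") 5L else 3L
  if (nrow(pts) < need)
    .err(sprintf("need at least %d points for a %s fit, got %d%s",
                 need, kind, nrow(pts), who), "axosymPreconditionError")
  if (nrow(unique(pts)) < need)
    .err(paste0("degenerate configuration: coincident points", who),
         "axosymDegenerateFitError")
  sv <- svd(sweep(pts, 2, colMeans(pts)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    .err(paste0("degenerate configuration: points are collinear", who),
         "axosymDegenerateFitError")

  circleFit <- function() {
    cf <- .fitCircleGeom(pts)
    CircumferenceFit("circle", cf$center, cf$r, cf$r, 0, cf$rms)
  }
  if (kind == "circle") return(circleFit())

  ef <- tryCatch(.fitEllipseGeom(pts), error = function(e) NULL)
  if (kind == "ellipse") {
    if (is.null(ef))
      .err(paste0("ellipse fit failed: degenerate configuration", who),
           "axosymDegenerateFitError")
    return(CircumferenceFit("ellipse", ef$center, ef$a, ef$b, ef$theta, ef$rms))
  }
  ## auto
  if (nrow(pts) >= 6L && !is.null(ef)) {
    ecc <- sqrt(max(0, 1 - (ef$b / ef$a)^2))
    if (ecc <= eccentricityCap)
      return(CircumferenceFit("ellipse", ef$center, ef$a, ef$b, ef$theta, ef$rms))
  }
  circleFit()
}

#' Signed orthogonal clearance from the fitted circumference
#'
#' Signed distance from a point to the fitted curve: positive outside,
#' negative inside, zero on the curve. The magnitude is the orthogonal
#' distance to the nearest curve point (for an ellipse, by iterative
#' projection). This is the quantity the rotated-doublet rule thresholds:
#' a B-tubule outside the axonemal circumference has positive clearance.
#'
#' @param fit a \linkS4class{CircumferenceFit}.
#' @param p a point \code{c(x, y)} or an n x 2 matrix of points.
#' @return numeric vector of signed clearances (pixels).
#' @examples
#' f <- fitCircumference(cbind(100 * cos(0:8 * 0.698), 100 * sin(0:8 * 0.698)),
#'                       kind = "circle")
#' radialClearance(f, c(130, 0))   # ~ +30
#' @export
radialClearance <- function(fit, p) {
  stopifnot(is(fit, "CircumferenceFit"))
  pts <- .asPoints(p)
  vapply(seq_len(nrow(pts)), function(i)
    .curveProject(fit, pts[i, ])$clearance, numeric(1))
}

#' Tilt angle of a doublet relative to the circumference
#'
#' Unsigned angle in [0, 90] degrees between the doublet axis (A-center to
#' B-center) and the tangent of the fitted curve at the orthogonal
#' projection of the A-center. 0 means the doublet lies flat along the
#' circumference; 90 means it points along the outward normal.
#'
#' @param fit a \linkS4class{CircumferenceFit}.
#' @param aCenter,bCenter A- and B-tubule centers, each \code{c(x, y)}.
#' @return angle in degrees.
#' @export
tiltAngle <- function(fit, aCenter, bCenter) {
  stopifnot(is(fit, "CircumferenceFit"))
  v <- bCenter - aCenter
  nv <- sqrt(sum(v^2))
  if (nv == 0)
    .err("degenerate doublet: A and B centers coincide", "axosymDegenerateDoubletError")
  tg <- .curveProject(fit, aCenter)$tangent
  cosang <- abs(sum(v * tg)) / nv
  acos(min(1, max(0, cosang))) * 180 / pi
}
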