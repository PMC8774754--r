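## Ring detection and doublet assembly from cross-section images.
## Detection is an annular matched filter bank (zero-mean center-surround
## kernels over a radius band) followed by greedy non-maximum suppression,
## sub-pixel peak refinement, per-candidate radius selection and a
## ring-completeness score used to tell complete A-tubules from C-shaped
## B-tubules.

#' Detection configuration
#'
#' Thresholds for detection and assembly, derived from the pixel scale:
#' the tubule radius band, minimum candidate separation, pairing tolerance,
#' completeness tie margin and the rotated-doublet threshold kappa.
#'
#' @param pixelSizeNm nanometres per pixel (default 2; tubule radii scale
#'   as 1/pixel size).
#' @param rA,rB expected A-/B-tubule radii in px at this scale.
#' @param rPad radius band half-width around \code{c(rA, rB)} (px).
#' @param wall expected wall thickness (px).
#' @param pairTol relative tolerance on the A--B pairing distance.
#' @param completenessMargin completeness tie margin for A/B assignment.
#' @param completenessMin minimum ring completeness accepted as a tubule
#'   candidate (rejects matched-filter responses arising between
#'   structures, which have most of their perimeter empty).
#' @param kappa rotated-doublet clearance threshold (fraction of rB).
#' @param armMin arm-call threshold passed to defect calling.
#' @param minResponse absolute matched-filter response floor.
#' @return named list of configuration values.
#' @export
detectionConfig <- function(pixelSizeNm = 2, rA = 24 / pixelSizeNm,
                            rB = 28 / pixelSizeNm, rPad = 2, wall = 4,
                            pairTol = 0.3, completenessMargin = 0.05,
                            completenessMin = 0.6,
                            kappa = 0.5, armMin = 2L, minResponse = 0.1) {
  list(pixelSizeNm = pixelSizeNm, rA = rA, rB = rB,
       rMin = max(3, floor(min(rA, rB) - rPad)),
       rMax = ceiling(max(rA, rB) + rPad), wall = wall,
       pairTol = pairTol, completenessMargin = completenessMargin,
       completenessMin = completenessMin, kappa = kappa, armMin = as.integer(armMin), minResponse = minResponse)
}

#' Read a detection configuration from YAML
#'
#' Any field of \code{\link{detectionConfig}} may be set in the file;
#' unset fields take their derived defaults.
#'
#' @param path YAML file.
#' @return named list as \code{\link{detectionConfig}}.
#' @export
readDetectionConfig <- function(path) {
  v <- yaml::read_yaml(path)
  known <- names(formals(detectionConfig))
  bad <- setdiff(names(v), c(known, "minResponse"))
  if (length(bad))
    .err(paste("unknown config fields:", paste(bad, collapse = ", ")),
         "axosymConfigError")
  do.call(detectionConfig, v[intersect(names(v), known)])
}

## Zero-mean center-surround annular kernel: positive on the ring band
## [r - w/2, r + w/2], negative on the interior disc, zero elsewhere.
.annularKernel <- function(r, wall) {
  s <- 2L * ceiling(r + wall) + 1L
  c0 <- (s + 1) / 2
  dd <- sqrt(outer((1:s - c0)^2, rep(1, s)) + outer(rep(1, s), (1:s - c0)^2))
  band <- abs(dd - r) <= wall / 2
  inner <- dd < r - wall / 2
  k <- matrix(0, s, s)
  k[band] <- 1 / sum(band)
  k[inner] <- -1 / max(1, sum(inner))
  k
}

.bilinear <- function(img, x, y) {
  w <- nrow(img); h <- ncol(img)
  x <- pmin(pmax(x, 1), w - 1e-9); y <- pmin(pmax(y, 1), h - 1e-9)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1, w); y1 <- pmin(y0 + 1, h)
  img[cbind(x0, y0)] * (1 - fx) * (1 - fy) + img[cbind(x1, y0)] * fx * (1 - fy) +
    img[cbind(x0, y1)] * (1 - fx) * fy + img[cbind(x1, y1)] * fx * fy
}

## Fraction of angular bins with wall signal near the ring radius. Each bin
## takes the strongest of three radial samples (blur widens the wall and
## localization is approximate), which keeps the score stable under noise:
## complete A-rings stay at ~1 while the empty corners flanking a B-tubule's
## opening stay empty at every radius.
.ringCompleteness <- function(sig, cx, cy, r, wallAmp, nBins = 36L) {
  ang <- (seq_len(nBins) - 0.5) * 2 * pi / nBins
  v <- pmax(.bilinear(sig, cx + (r - 1.5) * cos(ang), cy + (r - 1.5) * sin(ang)),
            .bilinear(sig, cx + r * cos(ang), cy + r * sin(ang)),
            .bilinear(sig, cx + (r + 1.5) * cos(ang), cy + (r + 1.5) * sin(ang)))
  mean(v > 0.35 * wallAmp)
}

#' Detect tubule rings in a grayscale cross-section image
#'
#' Runs the annular matched-filter bank over the configured radius band,
#' takes the per-pixel maximum response across scales, extracts peaks by
#' greedy non-maximum suppression at minimum separation
#' \code{1.2 * rMin}, refines each peak to sub-pixel precision by local
#' response centroid, assigns each candidate the best-responding radius and
#' scores ring completeness (fraction of perimeter with wall signal). A
#' blank or flat image yields an empty candidate list.
#'
#' @param img numeric matrix in [0, 1], [x, y] (as produced by
#'   \code{\link{renderSectionImage}} / \code{\link{readSectionTiff}}).
#' @param config list from \code{\link{detectionConfig}}.
#' @param maxCandidates cap on the number of returned candidates.
#' @return data.frame sorted by decreasing contrast: \code{x, y} (canvas
#'   px), \code{radius}, \code{completeness}, \code{contrast}.
#' @export
detectTubules <- function(img, config = detectionConfig(), maxCandidates = 40L) {
  stopifnot(is.matrix(img))
  bg <- stats::median(img)
  sig <- pmax(bg - img, 0)                 # walls dark -> positive signal
  wallAmp <- bg - stats::quantile(img, 0.02, names = FALSE)
  radii <- seq(config$rMin, config$rMax)
  ebi <- EBImage::Image(sig)
  resp <- matrix(-Inf, nrow(img), ncol(img))
  best <- matrix(1L, nrow(img), ncol(img))
  for (i in seq_along(radii)) {
    k <- .annularKernel(radii[i], config$wall)
    r1 <- EBImage::imageData(EBImage::filter2(ebi, k, boundary = "replicate"))
    upd <- r1 > resp
    resp[upd] <- r1[upd]
    best[upd] <- i
  }
  thr <- max(config$minResponse, 0.35 * max(resp))
  cand <- which(resp > thr, arr.ind = TRUE)
  if (!nrow(cand)) return(data.frame(x = numeric(), y = numeric(),
                                     radius = numeric(), completeness = numeric(),
                                     contrast = numeric()))
  ord <- order(resp[cand], decreasing = TRUE)
  cand <- cand[ord[seq_len(min(length(ord), 5000L))], , drop = FALSE]
  minSep <- 1.2 * config$rMin
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (!length(kx) || all((kx - p[1])^2 + (ky - p[2])^2 >= minSep^2)) {
      kx <- c(kx, p[1]); ky <- c(ky, p[2])
    }
    if (length(kx) >= maxCandidates) break
  }
  keep <- cbind(kx, ky)
  out <- lapply(seq_len(nrow(keep)), function(i) {
    px <- keep[i, 1]; py <- keep[i, 2]
    ## sub-pixel: response-weighted centroid on a 3x3 neighborhood
    xs <- max(1, px - 1):min(nrow(img), px + 1)
    ys <- max(1, py - 1):min(ncol(img), py + 1)
    wgt <- pmax(resp[xs, ys, drop = FALSE], 0)
    cx <- sum(outer(xs, rep(1, length(ys))) * wgt) / sum(wgt)
    cy <- sum(outer(rep(1, length(xs)), ys) * wgt) / sum(wgt)
    r <- radii[best[px, py]]
    data.frame(x = cx, y = cy, radius = r,
               completeness = .ringCompleteness(sig, cx, cy, r, wallAmp),
               contrast = resp[px, py])
  })
  out <- do.call(rbind, out)
  out <- out[out$completeness >= config$completenessMin, , drop = FALSE]
  out <- out[order(out$contrast, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## C-ring scorer for a putative B-center: wall signal sampled on the
## annulus of radius rB, restricted to the sector facing away from the
## partner A-tubule (the B-tubule is C-shaped, opening toward its A). The
## score is the lower quartile across angular bins: a genuine ring carries
## wall in essentially every kept bin, while a spurious position whose
## annulus merely crosses other walls leaves most bins empty.
.cringScorer <- function(img, config) {
  bg <- stats::median(img)
  sig <- pmax(bg - img, 0)
  ringAng <- (seq_len(36L) - 0.5) * 2 * pi / 36
  lowerQ <- function(v) {
    k <- max(1L, ceiling(0.25 * length(v)))
    sort(v, partial = k)[k]
  }
  ringQ <- function(p, r, keep = TRUE) {
    v <- pmax(.bilinear(sig, p[1] + (r - 1.5) * cos(ringAng[keep]),
                        p[2] + (r - 1.5) * sin(ringAng[keep])),
              .bilinear(sig, p[1] + r * cos(ringAng[keep]),
                        p[2] + r * sin(ringAng[keep])))
    lowerQ(v)
  }
  list(wallAmp = bg - stats::quantile(img, 0.02, names = FALSE),
       score = function(p, aXY) {
         keep <- abs(((ringAng - atan2(aXY[2] - p[2], aXY[1] - p[1]) + pi) %%
                        (2 * pi)) - pi) > pi / 3
         ringQ(p, config$rB, keep)
       },
       ## batched variant: scores many candidate B positions sharing one
       ## opening sector (taken at their common center)
       scoreGrid = function(ps, aXY) {
         pc <- colMeans(ps)
         keep <- abs(((ringAng - atan2(aXY[2] - pc[2], aXY[1] - pc[1]) + pi) %%
                        (2 * pi)) - pi) > pi / 3
         ca <- cos(ringAng[keep]); sa <- sin(ringAng[keep])
         r <- config$rB
         nk <- length(ca); np <- nrow(ps)
         X <- rep(ps[, 1], each = nk); Y <- rep(ps[, 2], each = nk)
         v <- pmax(.bilinear(sig, X + (r - 1.5) * ca, Y + (r - 1.5) * sa),
                   .bilinear(sig, X + r * ca, Y + r * sa))
         apply(matrix(v, nk, np), 2, lowerQ)
       },
       scoreFull = function(p, r) ringQ(p, r))
}

## Local grid refinement of a B-center against the C-ring score.
.refineB <- function(scorer, aXY, bXY, coarse = 6, step = 2) {
  for (g in list(seq(-coarse, coarse, by = step), seq(-1.5, 1.5, by = 0.5))) {
    grd <- as.matrix(expand.grid(dx = g, dy = g))
    sc <- scorer$scoreGrid(cbind(bXY[1] + grd[, 1], bXY[2] + grd[, 2]), aXY)
    bXY <- bXY + grd[which.max(sc), ]
  }
  list(p = bXY, score = scorer$score(bXY, aXY))
}

## Model-driven rescue of a doublet partner: given an unpaired complete
## ring (an A-tubule), scan the circle of radius L around it for the
## strongest C-shaped ring opening toward A. Directions are tried in score
## order; a direction whose refined position fails the score threshold or
## the caller's acceptance test (e.g. lands on an already-assigned tubule)
## falls through to the next. Returns the refined partner center or NULL.
.rescuePartner <- function(scorer, aXY, config, acceptable = function(p) TRUE,
                           ccwFrom = NULL) {
  L <- config$rA + config$rB
  phis <- seq(0, 2 * pi, length.out = 73L)[-73L]
  if (!is.null(ccwFrom)) {       # chirality: B lies counter-clockwise of A
    u <- aXY - ccwFrom
    phis <- phis[u[1] * sin(phis) - u[2] * cos(phis) > 0]
  }
  sc <- vapply(phis, function(ph)
    scorer$score(aXY + L * c(cos(ph), sin(ph)), aXY), numeric(1))
  for (k in utils::head(order(sc, decreasing = TRUE), 6L)) {
    ref <- .refineB(scorer, aXY, aXY + L * c(cos(phis[k]), sin(phis[k])),
                    coarse = 3, step = 1)
    if (ref$score > 0.5 * scorer$wallAmp && acceptable(ref$p)) return(ref$p)
  }
  NULL
}

#' Assemble detected ring candidates into a CrossSection
#'
#' Structure-first assembly exploiting the stereotyped 9+2 architecture and
#' its chirality. Central-pair candidates (those well inside the ring of
#' candidates) are split off first. The nine A-tubules form the skeleton:
#' complete rings (completeness >= 0.97) picked greedily by completeness
#' and contrast under a minimum center separation, so duplicate or
#' spurious detections never enter. Each A-tubule's B is then sought in its
#' chirality sector — the angular wedge from that A to the next one in
#' conventional (clockwise-on-image) order, where the B-tubule always sits
#' — at the expected doublet spacing \code{rA + rB}. When the source image
#' is supplied every B is validated and re-localized against the image (the
#' lower-quartile C-ring wall score must hold up), and a doublet whose B
#' candidate was lost to an overlapping neighbor is recovered by a
#' model-driven search on the circle of one doublet length around its A.
#'
#' Doublets are indexed in conventional angular order (index 1 nearest 12
#' o'clock, clockwise on the image). The section is flagged disorganized
#' when the nine-fold A-skeleton cannot be established or more than one
#' doublet partner is unrecoverable. Fewer than 12 candidates yield a
#' not-assessable section (no doublets, annotated in \code{notes}).
#'
#' @param candidates data.frame from \code{\link{detectTubules}}.
#' @param config list from \code{\link{detectionConfig}}.
#' @param sectionId identifier for the assembled section.
#' @param img optional source image matrix enabling B validation,
#'   re-localization and partner rescue.
#' @return A \linkS4class{CrossSection} with coordinates in canvas pixels.
#' @export
assembleSection <- function(candidates, config = detectionConfig(),
                            sectionId = "image", img = NULL) {
  if (nrow(candidates) < 12L)
    return(CrossSection(sectionId, centralPairCount = 0L,
                        notes = sprintf("not_assessable: %d candidate(s) detected",
                                        nrow(candidates))))
  c0 <- c(mean(candidates$x), mean(candidates$y))
  dd <- sqrt((candidates$x - c0[1])^2 + (candidates$y - c0[2])^2)
  centralIdx <- which(dd < 0.5 * stats::median(dd))
  per <- candidates[setdiff(seq_len(nrow(candidates)), centralIdx), , drop = FALSE]
  ang <- atan2(per$y - c0[2], per$x - c0[1])

  ## nine-fold A-skeleton: complete rings picked greedily by contrast,
  ## with a minimum center separation of 0.75 doublet lengths so a
  ## displaced duplicate detection of the same A-tubule is never picked
  ## twice (duplicates lie within the suppression radius; distinct
  ## A-tubules sit ~1.6 doublet lengths apart)
  elig <- which(per$completeness >= 0.97)
  elig <- elig[order(-per$completeness[elig], -per$contrast[elig])]
  minAsep <- 0.75 * (config$rA + config$rB)
  aIdx <- integer(0)
  for (i in elig) {
    if (length(aIdx) >= 9L) break
    sep <- sqrt((per$x[i] - per$x[aIdx])^2 + (per$y[i] - per$y[aIdx])^2)
    if (!length(aIdx) || all(sep >= minAsep)) aIdx <- c(aIdx, i)
  }
  if (length(aIdx) < 3L)
    return(CrossSection(sectionId, centralPairCount = length(centralIdx),
                        disorganized = TRUE,
                        notes = "not_assessable: no nine-fold skeleton found"))
  ## conventional order: index 1 nearest 12 o'clock, clockwise on the image
  ## = counter-clockwise in this y-up frame
  aIdx <- aIdx[order((ang[aIdx] - pi / 2) %% (2 * pi))]

  L <- config$rA + config$rB
  scorer <- if (!is.null(img)) .cringScorer(img, config)

  ## A-rescue: a gap in the nine-fold angular spacing marks an A-tubule
  ## whose peak was suppressed or displaced; predict its position from a
  ## provisional circumference fit and localize it by the full-ring score
  if (length(aIdx) < 9L && length(aIdx) >= 5L && !is.null(scorer)) {
    pfit <- tryCatch(fitCircumference(cbind(per$x[aIdx], per$y[aIdx])),
                     error = function(e) NULL)
    if (!is.null(pfit)) {
      angsA <- (ang[aIdx] - pi / 2) %% (2 * pi)
      grd <- as.matrix(expand.grid(dx = seq(-6, 6, by = 2), dy = seq(-6, 6, by = 2)))
      for (k in seq_along(aIdx)) {
        if (length(aIdx) >= 9L) break
        width <- ((angsA[if (k == length(angsA)) 1L else k + 1L] - angsA[k]) %%
                    (2 * pi))
        m <- round(width / (2 * pi / 9)) - 1L
        if (m < 1L) next
        for (j in seq_len(m)) {
          t0 <- pi / 2 + angsA[k] + width * j / (m + 1)
          far <- fitParams(pfit)$center + 500 * c(cos(t0), sin(t0))
          p0 <- .curveProject(pfit, far)$foot
          sc <- vapply(seq_len(nrow(grd)), function(g)
            scorer$scoreFull(p0 + grd[g, ], config$rA), numeric(1))
          p1 <- p0 + grd[which.max(sc)]
          sc2 <- vapply(seq_len(nrow(grd)), function(g)
            scorer$scoreFull(p1 + grd[g, ] / 4, config$rA), numeric(1))
          p1 <- p1 + grd[which.max(sc2)] / 4
          if (max(sc2) <= 0.5 * scorer$wallAmp) next
          per <- rbind(per, data.frame(x = p1[1], y = p1[2], radius = config$rA,
                                       completeness = 1, contrast = NA_real_))
          ang <- c(ang, atan2(p1[2] - c0[2], p1[1] - c0[1]))
          aIdx <- c(aIdx, nrow(per))
        }
      }
      aIdx <- aIdx[order((ang[aIdx] - pi / 2) %% (2 * pi))]
    }
  }

  ## chirality: B-tubules all sit on the same rotational side of their A
  ## (axonemes are handed, and a mirrored image flips the handedness), but
  ## which side cannot be told locally when detections are degraded -- so
  ## the doublets are assembled under both hypotheses and the one
  ## explaining more doublets (then scoring higher) wins
  ## rescue = FALSE gives the cheap probe used only to compare the two
  ## chirality hypotheses: candidates are scored in place, not refined
  assembleArm <- function(sgn, rescue = TRUE) {
    usedB <- logical(nrow(per))
    rows <- list(); nMissing <- 0L; total <- 0
    for (k in seq_along(aIdx)) {
      i <- aIdx[k]
      aXY <- c(per$x[i], per$y[i])
      angA <- ang[i]
      nbr <- if (sgn > 0) { if (k == length(aIdx)) 1L else k + 1L
      } else { if (k == 1L) length(aIdx) else k - 1L }
      angNext <- ang[aIdx[nbr]]
      width <- ((angNext - angA) * sgn) %% (2 * pi)
      inSector <- function(t) (((t - angA) * sgn) %% (2 * pi)) < width
      distA <- sqrt((per$x - aXY[1])^2 + (per$y - aXY[2])^2)
      cnd <- setdiff(which(!usedB & abs(distA - L) <= config$pairTol * L &
                             inSector(ang)), aIdx)
      cnd <- cnd[order(-per$contrast[cnd])]
      bXY <- NULL; rb <- config$rB; bi <- NA_integer_; sc <- 0
      for (j in cnd) {
        p <- c(per$x[j], per$y[j])
        if (is.null(scorer)) {
          bXY <- p; rb <- per$radius[j]; bi <- j
          sc <- -abs(distA[j] - L)      # closeness to the expected spacing
          break
        }
        if (!rescue) {                  # probe: score in place
          s0 <- scorer$score(p, aXY)
          if (s0 > 0.4 * scorer$wallAmp) {
            bXY <- p; rb <- per$radius[j]; bi <- j; sc <- s0
            break
          }
          next
        }
        ref <- .refineB(scorer, aXY, p)
        if (ref$score > 0.5 * scorer$wallAmp &&
            abs(sqrt(sum((ref$p - aXY)^2)) - L) <= config$pairTol * L &&
            inSector(atan2(ref$p[2] - c0[2], ref$p[1] - c0[1]))) {
          bXY <- ref$p; rb <- per$radius[j]; bi <- j; sc <- ref$score
          break
        }
      }
      if (is.null(bXY) && rescue && !is.null(scorer)) {
        ok <- function(p) inSector(atan2(p[2] - c0[2], p[1] - c0[1])) &&
          (!length(rows) || min(vapply(rows, function(r)
            min(sqrt((r$bx - p[1])^2 + (r$by - p[2])^2),
                sqrt((r$ax - p[1])^2 + (r$ay - p[2])^2)), numeric(1))) >= 8)
        bXY <- .rescuePartner(scorer, aXY, config, acceptable = ok)
        if (!is.null(bXY)) sc <- scorer$score(bXY, aXY)
      }
      if (is.null(bXY)) { nMissing <- nMissing + 1L; next }
      if (!is.na(bi)) usedB[bi] <- TRUE
      total <- total + sc
      rows[[length(rows) + 1L]] <- data.frame(ax = aXY[1], ay = aXY[2],
                                              bx = bXY[1], by = bXY[2],
                                              r_a = per$radius[i], r_b = rb)
    }
    list(rows = rows, nMissing = nMissing, total = total)
  }
  armP <- assembleArm(1, rescue = FALSE)
  armM <- assembleArm(-1, rescue = FALSE)
  sgn <- if (armM$nMissing < armP$nMissing ||
             (armM$nMissing == armP$nMissing && armM$total > armP$total))
    -1 else 1
  best <- assembleArm(sgn)
  rows <- best$rows; nMissing <- best$nMissing

  disorganized <- length(aIdx) != 9L || nMissing > 1L
  if (!length(rows))
    return(CrossSection(sectionId, centralPairCount = length(centralIdx),
                        disorganized = TRUE,
                        notes = "not_assessable: no doublet could be assembled"))
  d <- do.call(rbind, rows)
  d$index <- seq_len(nrow(d))
  notes <- character(0)
  if (nMissing) notes <- c(notes, sprintf("%d doublet(s) missing a B-tubule", nMissing))
  if (length(aIdx) != 9L) notes <- c(notes, sprintf("%d A-tubule(s) found", length(aIdx)))
  CrossSection(sectionId, d, centralPairCount = length(centralIdx),
               disorganized = disorganized, notes = paste(notes, collapse = "; "))
}

#' Analyze a cross-section image end to end
#'
#' detect -> assemble -> circumference fit -> rotation calls -> defect
#' calls. Arm flags cannot be read from images and stay NA in the defect
#' call. Stage failures are tagged with the stage name.
#'
#' @param img numeric matrix in [0, 1] (see \code{\link{detectTubules}}).
#' @param config list from \code{\link{detectionConfig}}.
#' @param sectionId identifier used in the report.
#' @return list: \code{section_id}, \code{n_candidates}, \code{section}
#'   (the assembled \linkS4class{CrossSection}), \code{report} (the
#'   \code{\link{assessSection}} result), \code{defects} (one-row
#'   data.frame from \code{\link{callSectionDefects}}).
#' @export
analyzeImage <- function(img, config = detectionConfig(), sectionId = "image") {
  cand <- tryCatch(detectTubules(img, config),
                   error = function(e) stop("detect: ", conditionMessage(e)))
  sec <- tryCatch(assembleSection(cand, config, sectionId = sectionId, img = img),
                  error = function(e) stop("assemble: ", conditionMessage(e)))
  rep <- tryCatch(assessSection(sec, kappa = config$kappa),
                  error = function(e) stop("assess: ", conditionMessage(e)))
  def <- tryCatch(callSectionDefects(sec, armMin = config$armMin,
                                     kappa = config$kappa),
                  error = function(e) stop("defects: ", conditionMessage(e)))
  list(section_id = sectionId, n_candidates = nrow(cand), section = sec,
       report = rep, defects = def)
}
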