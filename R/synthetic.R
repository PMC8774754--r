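## Synthetic 9+2 axoneme cross-section generator with ground-truth labels.
## Doublet geometry: A-centers sit on a sampled ellipse at jittered
## 40-degree spacing. The zero-tilt doublet axis is the chord from the
## A-center's curve point to the curve point one doublet length away, so an
## aligned B-tubule lies on the circumference exactly; a tilt rotates that
## axis outward about the A-center, swinging the B-tubule outside the curve.

#' Construct a SceneSpec
#'
#' Builds a \linkS4class{SceneSpec} with defaults emulating well-preserved
#' respiratory ciliary cross-sections at ~2 nm/px: circumference ring
#' radius 60 +/- 3 px, mild obliquity (aspect 0.85--1: the cut stretches
#' the major axis by up to ~18 percent), A/B tubule radii 12/14 px, 1 px A-center
#' localization jitter, 3-degree angular jitter on the nominal 40-degree
#' doublet spacing. Aligned doublets tilt as |Normal(0, 4)| degrees; rotated
#' doublets as Normal(35, 8) truncated to [15, 75] degrees. The default
#' per-section rotated-doublet distribution is control-like (mostly 0--2
#' rotated doublets); defect probabilities default to 0.
#'
#' @param nSections number of sections.
#' @param ringRadiusMean,ringRadiusSd distribution of the circumference
#'   semi-minor axis = the true ring radius (px).
#' @param ellipseAspectRange interval in (0,1] for minor/major aspect; an
#'   oblique cut at angle theta stretches the semi-major axis to
#'   ring radius / cos(theta), so aspect = cos(theta).
#' @param aCenterJitterSd A-center jitter sd (px).
#' @param rA,rB tubule radii (px).
#' @param angularJitterSd doublet-spacing jitter sd (degrees).
#' @param tiltRotatedMean,tiltRotatedSd,tiltRotatedRange rotated-doublet
#'   tilt: Normal(mean, sd) truncated to range (degrees).
#' @param tiltAlignedSd aligned-doublet tilt |Normal(0, sd)| (degrees).
#' @param nRotatedDist 10 weights: probability of 0..9 rotated doublets.
#' @param pOdaAbsent,pIdaAbsent,pCentralDefect,pDisorganized per-section
#'   defect probabilities.
#' @param pixelSizeNm nanometres per pixel.
#' @param psfSigma render blur sigma (px).
#' @param noiseSd render additive noise sd ([0,1] intensity scale).
#' @param seed RNG seed.
#' @return A \linkS4class{SceneSpec}.
#' @export
sceneSpec <- function(nSections = 50L,
                      ringRadiusMean = 60, ringRadiusSd = 3,
                      ellipseAspectRange = c(0.85, 1),
                      aCenterJitterSd = 1,
                      rA = 12, rB = 14,
                      angularJitterSd = 3,
                      tiltRotatedMean = 35, tiltRotatedSd = 8,
                      tiltRotatedRange = c(15, 75),
                      tiltAlignedSd = 4,
                      nRotatedDist = c(0.35, 0.3, 0.2, 0.1, 0.05, 0, 0, 0, 0, 0),
                      pOdaAbsent = 0, pIdaAbsent = 0,
                      pCentralDefect = 0, pDisorganized = 0,
                      pixelSizeNm = 2, psfSigma = 2, noiseSd = 0.04,
                      seed = 20220106L) {
  new("SceneSpec", nSections = as.integer(nSections),
      ringRadiusMean = ringRadiusMean, ringRadiusSd = ringRadiusSd,
      ellipseAspectRange = as.numeric(ellipseAspectRange),
      aCenterJitterSd = aCenterJitterSd, rA = rA, rB = rB,
      angularJitterSd = angularJitterSd,
      tiltRotatedMean = tiltRotatedMean, tiltRotatedSd = tiltRotatedSd,
      tiltRotatedRange = as.numeric(tiltRotatedRange),
      tiltAlignedSd = tiltAlignedSd,
      nRotatedDist = as.numeric(nRotatedDist),
      pOdaAbsent = pOdaAbsent, pIdaAbsent = pIdaAbsent,
      pCentralDefect = pCentralDefect, pDisorganized = pDisorganized,
      pixelSizeNm = pixelSizeNm, psfSigma = psfSigma, noiseSd = noiseSd,
      seed = as.integer(seed))
}

## Truncated-normal draw via inverse CDF (one uniform per value, keeps the
## RNG stream length deterministic).
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

.ellipsePoint <- function(center, a, b, phi, u) {
  drop(.rotmat(phi) %*% c(a * cos(u), b * sin(u))) + center
}

## Outward unit normal of the ellipse at parametric angle u.
.ellipseNormal <- function(a, b, phi, u) {
  n <- drop(.rotmat(phi) %*% c(cos(u) / a, sin(u) / b))
  n / sqrt(sum(n^2))
}

## Parametric advance from u covering chord length L along the ellipse.
.chordAdvance <- function(a, b, phi, u, L) {
  f <- function(d) {
    p1 <- c(a * cos(u), b * sin(u)); p2 <- c(a * cos(u + d), b * sin(u + d))
    sqrt(sum((p2 - p1)^2)) - L
  }
  stats::uniroot(f, c(1e-6, pi), tol = 1e-12)$root
}

#' Generate one synthetic cross-section with ground truth
#'
#' Places nine A-centers at jittered 40-degree spacing on a sampled
#' ellipse, draws the number of rotated doublets from
#' \code{nRotatedDist}, tilts each doublet by an angle from its (rotated or
#' aligned) distribution and places the B-center one doublet length
#' (\code{rA + rB}) along the tilted axis, rotated doublets swinging
#' outward. Section-level defect flags (dynein arms, central pair,
#' disorganization) are sampled from the spec's probabilities.
#'
#' Uses the current RNG state unless \code{seed} is given; see
#' \code{\link{generateSections}} for seeded batch generation.
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @param sectionId identifier for the generated section.
#' @param seed optional seed set before generation.
#' @return list with \code{section} (a \linkS4class{CrossSection}) and
#'   \code{truth} (rotated flags, tilt angles, rotated count, break flag,
#'   defect flags, ellipse parameters, tubule centers including the central
#'   pair).
#' @export
generateSectionCoords <- function(spec, sectionId = "s1", seed = NULL) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  if (!is.null(seed)) set.seed(seed)
  ## oblique sectioning stretches the ring: the semi-minor axis is the true
  ## ring radius, the semi-major axis is enlarged by 1/cos(cut angle)
  b <- max(spec@rA + spec@rB + 1,
           stats::rnorm(1, spec@ringRadiusMean, spec@ringRadiusSd))
  aspect <- stats::runif(1, spec@ellipseAspectRange[1], spec@ellipseAspectRange[2])
  a <- b / aspect
  phi <- stats::runif(1, 0, pi)
  center <- c(0, 0)
  L <- spec@rA + spec@rB

  ## index 1 nearest 12 o'clock, increasing clockwise on the image
  ## (counter-clockwise in this y-up frame)
  u <- (pi / 2 - phi) + (0:8) * (2 * pi / 9) +
    stats::rnorm(9, 0, spec@angularJitterSd * pi / 180)

  nRot <- sample(0:9, 1, prob = spec@nRotatedDist)
  rotIdx <- if (nRot > 0) sort(sample.int(9, nRot)) else integer(0)
  rotated <- seq_len(9) %in% rotIdx
  tilt <- abs(stats::rnorm(9, 0, spec@tiltAlignedSd))
  if (nRot > 0)
    tilt[rotIdx] <- .rtruncnorm(nRot, spec@tiltRotatedMean, spec@tiltRotatedSd,
                                spec@tiltRotatedRange[1], spec@tiltRotatedRange[2])

  axy <- bxy <- matrix(NA_real_, 9, 2)
  for (i in 1:9) {
    curvePt <- .ellipsePoint(center, a, b, phi, u[i])
    aC <- curvePt + stats::rnorm(2, 0, spec@aCenterJitterSd)
    dAdv <- .chordAdvance(a, b, phi, u[i], L)
    chord <- (.ellipsePoint(center, a, b, phi, u[i] + dAdv) - curvePt) / L
    nrm <- .ellipseNormal(a, b, phi, u[i])
    t <- tilt[i] * pi / 180
    d1 <- drop(.rotmat(t) %*% chord); d2 <- drop(.rotmat(-t) %*% chord)
    dir <- if (sum(d1 * nrm) >= sum(d2 * nrm)) d1 else d2   # swing outward
    axy[i, ] <- aC
    bxy[i, ] <- aC + L * dir
  }

  odaAbsent <- stats::runif(1) < spec@pOdaAbsent
  idaAbsent <- stats::runif(1) < spec@pIdaAbsent
  centralDefect <- stats::runif(1) < spec@pCentralDefect
  disorganized <- stats::runif(1) < spec@pDisorganized

  cpCount <- if (centralDefect) 0L else 2L
  cpAngle <- stats::runif(1, 0, pi)
  cpOff <- (spec@rA + 1) * c(cos(cpAngle), sin(cpAngle))
  cpCenters <- if (cpCount == 2L) rbind(center + cpOff, center - cpOff)
  else matrix(numeric(0), 0, 2)

  d <- data.frame(index = 1:9, ax = axy[, 1], ay = axy[, 2],
                  bx = bxy[, 1], by = bxy[, 2],
                  r_a = spec@rA, r_b = spec@rB,
                  oda = !odaAbsent, ida = !idaAbsent)
  section <- CrossSection(sectionId, d, centralPairCount = cpCount,
                          disorganized = disorganized)
  truth <- list(section_id = sectionId, rotated = rotated, tilt_deg = tilt,
                n_rotated = nRot, symmetry_break = nRot >= 4L,
                oda_absent = odaAbsent, ida_absent = idaAbsent,
                central_defect = centralDefect, disorganized = disorganized,
                ellipse = list(center = center, a = a, b = b, phi = phi),
                a_centers = axy, b_centers = bxy, cp_centers = cpCenters)
  list(section = section, truth = truth)
}

#' Generate a batch of synthetic sections (seeded)
#'
#' Generates \code{spec@nSections} sections reproducibly from the spec's
#' seed (or an override). Identical spec and seed give byte-identical
#' output.
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @param seed seed; defaults to \code{spec@seed}.
#' @param idPrefix section identifiers are \code{<idPrefix><i>}.
#' @return list with \code{sections} (list of \linkS4class{CrossSection})
#'   and \code{truths} (list of truth records).
#' @export
generateSections <- function(spec, seed = NULL, idPrefix = "s") {
  stopifnot(is(spec, "SceneSpec"))
  set.seed(if (is.null(seed)) spec@seed else seed)
  out <- lapply(seq_len(spec@nSections), function(i)
    generateSectionCoords(spec, sectionId = paste0(idPrefix, i)))
  list(sections = lapply(out, `[[`, "section"),
       truths = lapply(out, `[[`, "truth"))
}

#' Generate a synthetic two-arm cohort
#'
#' Generates per-patient section sets for a disease-like and a control-like
#' arm, scores every patient (defect calls, AA percentage, TEM class) and
#' optionally writes the dataset to disk: per-patient coordinate and
#' section CSVs, truth JSON, rendered TIFF stacks and a YAML manifest.
#' Per-patient expected AA equals \code{P(n_rotated >= 4)} under the arm's
#' \code{nRotatedDist}.
#'
#' @param specPcd,specCtrl \linkS4class{SceneSpec}s for the two arms.
#' @param nPatientsPerArm patients per arm.
#' @param sectionsPerPatient sections generated per patient.
#' @param outDir directory to write to; NULL keeps everything in memory.
#' @param writeImages also render and write TIFF images (slow).
#' @param seed base seed; per-patient seeds are derived from it.
#' @return list with \code{patients} (each: id, group, sections, truths,
#'   summary row, true_aa) and \code{manifest}.
#' @export
generateCohort <- function(specPcd, specCtrl, nPatientsPerArm = 20L,
                           sectionsPerPatient = 50L, outDir = NULL,
                           writeImages = FALSE, seed = NULL) {
  stopifnot(is(specPcd, "SceneSpec"), is(specCtrl, "SceneSpec"))
  baseSeed <- if (is.null(seed)) specPcd@seed else as.integer(seed)
  arms <- list(PCD = specPcd, control = specCtrl)
  patients <- list()
  k <- 0L
  for (ai in seq_along(arms)) {
    spec <- arms[[ai]]
    grp <- names(arms)[ai]
    for (i in seq_len(nPatientsPerArm)) {
      k <- k + 1L
      pid <- sprintf("%s%02d", if (grp == "PCD") "P" else "C", i)
      pseed <- (baseSeed + 7919L * ai + i) %% .Machine$integer.max
      gen <- generateSections(methods::initialize(spec,
                                nSections = as.integer(sectionsPerPatient)),
                              seed = pseed, idPrefix = paste0(pid, "_s"))
      summ <- scorePatient(gen$sections, patientId = pid)
      trueAA <- 100 * mean(vapply(gen$truths, `[[`, logical(1), "symmetry_break"))
      patients[[k]] <- list(id = pid, group = grp, seed = pseed,
                            sections = gen$sections, truths = gen$truths,
                            summary = summ, true_aa = trueAA)
    }
  }
  manifest <- list(n_patients_per_arm = nPatientsPerArm,
                   sections_per_patient = sectionsPerPatient,
                   base_seed = baseSeed,
                   patients = lapply(patients, function(p)
                     list(id = p$id, group = p$group, seed = p$seed,
                          aa_pct = p$summary$aa_pct)))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (p in patients) {
      pdir <- file.path(outDir, p$id)
      dir.create(pdir, showWarnings = FALSE)
      writeSectionCoords(p$sections, file.path(pdir, "doublets.csv"),
                         file.path(pdir, "sections.csv"))
      jsonlite::write_json(p$truths, file.path(pdir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      utils::write.csv(p$summary, file.path(pdir, "summary.csv"),
                       row.names = FALSE)
      if (writeImages) {
        spec <- arms[[if (p$group == "PCD") 1L else 2L]]
        for (si in seq_along(p$sections)) {
          img <- renderSectionImage(p$sections[[si]], spec)
          writeSectionTiff(img, file.path(pdir, sprintf("section_%03d.tiff", si)))
        }
      }
    }
    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  }
  list(patients = patients, manifest = manifest)
}
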