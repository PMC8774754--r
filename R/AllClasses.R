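#' @import methods
NULL

## Column layout shared by every doublet table in the package. oda/ida are
## logical with NA = arm visibility unknown.
.doubletCols <- c("index", "ax", "ay", "bx", "by", "r_a", "r_b", "oda", "ida")

.emptyDoublets <- function() {
  data.frame(index = integer(), ax = numeric(), ay = numeric(),
             bx = numeric(), by = numeric(), r_a = numeric(), r_b = numeric(),
             oda = logical(), ida = logical())
}

#' CrossSection: one axoneme transverse section
#'
#' Container for a single ciliary cross-section: up to nine peripheral
#' doublet observations (A- and B-tubule centers and radii, dynein-arm
#' flags), the number of central microtubules observed (normal = 2), and a
#' microtubular-disorganization flag. Disorganized sections are never
#' assessed for a symmetry break; they are excluded from both the numerator
#' and denominator of the asymmetry percentage.
#'
#' Coordinates are in pixels in a mathematical frame (y up, angles
#' counter-clockwise from +x). Doublet indices follow the conventional
#' angular order: index 1 nearest 12 o'clock, increasing clockwise as seen
#' on the image.
#'
#' @slot sectionId character scalar identifier.
#' @slot doublets data.frame with columns \code{index, ax, ay, bx, by, r_a,
#'   r_b, oda, ida} (one row per localized doublet, 0..9 rows).
#' @slot centralPairCount integer, number of central microtubules observed.
#' @slot disorganized logical, microtubular disorganization present.
#' @slot notes character, free text.
#'
#' @aliases CrossSection-class
#' @export
setClass("CrossSection",
  representation(sectionId = "character", doublets = "data.frame",
                 centralPairCount = "integer", disorganized = "logical",
                 notes = "character"),
  prototype(sectionId = "section", doublets = .emptyDoublets(),
            centralPairCount = 2L, disorganized = FALSE, notes = ""))

setValidity("CrossSection", function(object) {
  d <- object@doublets
  msgs <- character()
  if (length(object@sectionId) != 1L) msgs <- c(msgs, "sectionId must be a single string")
  if (!all(.doubletCols %in% names(d)))
    msgs <- c(msgs, paste("doublets must have columns:", paste(.doubletCols, collapse = ", ")))
  else if (nrow(d) > 0L) {
    if (nrow(d) > 9L) msgs <- c(msgs, "at most 9 peripheral doublets")
    if (anyDuplicated(d$index)) msgs <- c(msgs, "doublet indices must be unique")
    if (!all(d$index %in% 1:9)) msgs <- c(msgs, "doublet index must be in 1..9")
    ok <- stats::complete.cases(d[, c("ax", "ay", "bx", "by", "r_a", "r_b")])
    if (!all(ok)) msgs <- c(msgs, "tubule centers and radii must be non-missing")
    else {
      if (any(d$r_a <= 0) || any(d$r_b <= 0)) msgs <- c(msgs, "tubule radii must be positive")
      if (any(d$ax == d$bx & d$ay == d$by)) msgs <- c(msgs, "A and B centers must differ")
    }
  }
  if (length(object@centralPairCount) != 1L || is.na(object@centralPairCount) ||
      object@centralPairCount < 0L)
    msgs <- c(msgs, "centralPairCount must be a single non-negative integer")
  if (length(object@disorganized) != 1L || is.na(object@disorganized))
    msgs <- c(msgs, "disorganized must be TRUE or FALSE")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CrossSection
#'
#' @param sectionId section identifier.
#' @param doublets data.frame with columns \code{index, ax, ay, bx, by, r_a,
#'   r_b} and optionally \code{oda, ida} (logical, NA = unknown).
#' @param centralPairCount number of central microtubules observed (normal 2).
#' @param disorganized microtubular disorganization flag; disorganized
#'   sections are excluded from asymmetry assessment.
#' @param notes free-text annotation.
#' @return A \linkS4class{CrossSection}.
#' @examples
#' d <- data.frame(index = 1:9,
#'                 ax = 45 * cospi((90 - 40 * (0:8)) / 180),
#'                 ay = 45 * sinpi((90 - 40 * (0:8)) / 180),
#'                 bx = 68 * cospi((90 - 40 * (0:8)) / 180),
#'                 by = 68 * sinpi((90 - 40 * (0:8)) / 180),
#'                 r_a = 12, r_b = 14)
#' CrossSection("s1", d)
#' @export
CrossSection <- function(sectionId, doublets = .emptyDoublets(),
                         centralPairCount = 2L, disorganized = FALSE,
                         notes = "") {
  if (!is.data.frame(doublets)) stop("doublets must be a data.frame")
  if (is.null(doublets$oda)) doublets$oda <- NA
  if (is.null(doublets$ida)) doublets$ida <- NA
  doublets$oda <- as.logical(doublets$oda)
  doublets$ida <- as.logical(doublets$ida)
  doublets$index <- as.integer(doublets$index)
  doublets <- doublets[, .doubletCols]
  new("CrossSection", sectionId = as.character(sectionId), doublets = doublets,
      centralPairCount = as.integer(centralPairCount),
      disorganized = isTRUE(disorganized), notes = as.character(notes))
}

#' @describeIn CrossSection section identifier accessor
#' @param object,x a \code{CrossSection}
#' @export
setGeneric("sectionId", function(object) standardGeneric("sectionId"))
#' @rdname CrossSection
#' @export
setMethod("sectionId", "CrossSection", function(object) object@sectionId)

#' @rdname CrossSection
#' @export
setGeneric("doublets", function(object) standardGeneric("doublets"))
#' @rdname CrossSection
#' @export
setMethod("doublets", "CrossSection", function(object) object@doublets)

#' @rdname CrossSection
#' @export
setGeneric("centralPairCount", function(object) standardGeneric("centralPairCount"))
#' @rdname CrossSection
#' @export
setMethod("centralPairCount", "CrossSection", function(object) object@centralPairCount)

#' @rdname CrossSection
#' @export
setGeneric("isDisorganized", function(object) standardGeneric("isDisorganized"))
#' @rdname CrossSection
#' @export
setMethod("isDisorganized", "CrossSection", function(object) object@disorganized)

setMethod("show", "CrossSection", function(object) {
  cat("CrossSection '", object@sectionId, "': ", nrow(object@doublets),
      " doublet(s), central pair count ", object@centralPairCount,
      if (object@disorganized) ", DISORGANIZED" else "", "\n", sep = "")
})

#' CircumferenceFit: fitted axonemal circumference
#'
#' Least-squares circle or ellipse fitted through the A-tubule centers of a
#' cross-section — the axonemal circumference, the closed curve joining the
#' centers of all the A-tubules. For \code{kind = "circle"},
#' \code{semiMajor == semiMinor} and \code{orientation == 0}.
#'
#' @slot kind "circle" or "ellipse".
#' @slot center numeric(2), curve center (pixels, mathematical frame).
#' @slot semiMajor,semiMinor semi-axis lengths (pixels), major >= minor.
#' @slot orientation major-axis angle in radians, CCW from +x.
#' @slot rmsResidual root-mean-square orthogonal residual of the fitted
#'   points (pixels).
#'
#' @aliases CircumferenceFit-class
#' @export
setClass("CircumferenceFit",
  representation(kind = "character", center = "numeric", semiMajor = "numeric",
                 semiMinor = "numeric", orientation = "numeric",
                 rmsResidual = "numeric"),
  prototype(kind = "circle", center = c(0, 0), semiMajor = 1, semiMinor = 1,
            orientation = 0, rmsResidual = 0))

setValidity("CircumferenceFit", function(object) {
  msgs <- character()
  if (!object@kind %in% c("circle", "ellipse")) msgs <- c(msgs, "kind must be 'circle' or 'ellipse'")
  if (length(object@center) != 2L || any(!is.finite(object@center)))
    msgs <- c(msgs, "center must be two finite coordinates")
  if (!(is.finite(object@semiMajor) && is.finite(object@semiMinor) &&
        object@semiMinor > 0 && object@semiMajor >= object@semiMinor))
    msgs <- c(msgs, "need semiMajor >= semiMinor > 0")
  if (object@kind == "circle" &&
      (object@semiMajor != object@semiMinor || object@orientation != 0))
    msgs <- c(msgs, "a circle has equal semi-axes and orientation 0")
  if (length(msgs)) msgs else TRUE
})

CircumferenceFit <- function(kind, center, semiMajor, semiMinor,
                             orientation = 0, rmsResidual = NA_real_) {
  new("CircumferenceFit", kind = kind, center = as.numeric(center),
      semiMajor = as.numeric(semiMajor), semiMinor = as.numeric(semiMinor),
      orientation = as.numeric(orientation), rmsResidual = as.numeric(rmsResidual))
}

#' @describeIn CircumferenceFit fit parameters as a named list
#' @param object a \code{CircumferenceFit}
#' @export
setGeneric("fitParams", function(object) standardGeneric("fitParams"))
#' @rdname CircumferenceFit
#' @export
setMethod("fitParams", "CircumferenceFit", function(object) {
  list(kind = object@kind, center = object@center,
       semiMajor = object@semiMajor, semiMinor = object@semiMinor,
       orientation = object@orientation, rmsResidual = object@rmsResidual)
})

setMethod("show", "CircumferenceFit", function(object) {
  cat(sprintf("CircumferenceFit [%s] center (%.2f, %.2f) axes (%.2f, %.2f) theta %.1f deg rms %.3g px\n",
              object@kind, object@center[1], object@center[2],
              object@semiMajor, object@semiMinor,
              object@orientation * 180 / pi, object@rmsResidual))
})

#' SceneSpec: parameters of the synthetic axoneme generator
#'
#' Full parameterization of the synthetic 9+2 cross-section generator:
#' circumference size and ellipticity, coordinate jitter, doublet geometry,
#' tilt-angle distributions for aligned and rotated doublets, the per-section
#' distribution of the number of rotated doublets, defect probabilities, and
#' rendering parameters (pixel scale, point-spread blur, additive noise).
#' Generation is fully reproducible from \code{seed}.
#'
#' Lengths are in pixels at \code{pixelSizeNm} nanometres per pixel
#' (default 2 nm/px, plausible for high-magnification TEM); angles in
#' degrees.
#'
#' @slot nSections number of sections to generate.
#' @slot ringRadiusMean,ringRadiusSd distribution of the circumference
#'   semi-minor axis, i.e. the true ring radius (px); oblique sectioning
#'   stretches the semi-major axis by 1/aspect.
#' @slot ellipseAspectRange range (0,1] of minor/major aspect ratios sampled
#'   uniformly (aspect = cosine of the cut angle).
#' @slot aCenterJitterSd isotropic Gaussian jitter of A-centers off the
#'   curve (px).
#' @slot rA,rB A- and B-tubule outer radii (px).
#' @slot angularJitterSd jitter of the nominal 40-degree doublet spacing
#'   (degrees).
#' @slot tiltRotatedMean,tiltRotatedSd,tiltRotatedRange tilt distribution of
#'   rotated doublets: Normal truncated to the range (degrees).
#' @slot tiltAlignedSd aligned doublets tilt as |Normal(0, sd)| (degrees).
#' @slot nRotatedDist numeric(10), probability of 0..9 rotated doublets per
#'   section (normalized internally).
#' @slot pOdaAbsent,pIdaAbsent,pCentralDefect,pDisorganized per-section
#'   defect probabilities.
#' @slot pixelSizeNm nm per pixel (rendering metadata).
#' @slot psfSigma Gaussian point-spread sigma (px) applied to renders.
#' @slot noiseSd additive Gaussian noise sigma on the [0,1] intensity scale.
#' @slot seed integer RNG seed.
#'
#' @aliases SceneSpec-class
#' @export
setClass("SceneSpec",
  representation(nSections = "integer",
                 ringRadiusMean = "numeric", ringRadiusSd = "numeric",
                 ellipseAspectRange = "numeric", aCenterJitterSd = "numeric",
                 rA = "numeric", rB = "numeric", angularJitterSd = "numeric",
                 tiltRotatedMean = "numeric", tiltRotatedSd = "numeric",
                 tiltRotatedRange = "numeric", tiltAlignedSd = "numeric",
                 nRotatedDist = "numeric",
                 pOdaAbsent = "numeric", pIdaAbsent = "numeric",
                 pCentralDefect = "numeric", pDisorganized = "numeric",
                 pixelSizeNm = "numeric", psfSigma = "numeric",
                 noiseSd = "numeric", seed = "integer"))

setValidity("SceneSpec", function(object) {
  msgs <- character()
  num1pos <- function(x, nm) if (length(x) != 1L || !is.finite(x) || x <= 0)
    paste(nm, "must be a single positive number") else character()
  msgs <- c(msgs,
            num1pos(object@ringRadiusMean, "ringRadiusMean"),
            num1pos(object@rA, "rA"), num1pos(object@rB, "rB"),
            num1pos(object@pixelSizeNm, "pixelSizeNm"))
  for (nm in c("ringRadiusSd", "aCenterJitterSd", "angularJitterSd",
               "tiltRotatedSd", "tiltAlignedSd", "psfSigma", "noiseSd")) {
    x <- slot(object, nm)
    if (length(x) != 1L || !is.finite(x) || x < 0)
      msgs <- c(msgs, paste(nm, "must be a single non-negative number"))
  }
  if (object@nSections < 0L) msgs <- c(msgs, "nSections must be >= 0")
  ar <- object@ellipseAspectRange
  if (length(ar) != 2L || any(ar <= 0) || any(ar > 1) || ar[1] > ar[2])
    msgs <- c(msgs, "ellipseAspectRange must be an increasing interval in (0, 1]")
  tr <- object@tiltRotatedRange
  if (length(tr) != 2L || tr[1] < 0 || tr[2] > 90 || tr[1] > tr[2])
    msgs <- c(msgs, "tiltRotatedRange must be an increasing interval in [0, 90]")
  if (length(object@nRotatedDist) != 10L || any(object@nRotatedDist < 0) ||
      sum(object@nRotatedDist) <= 0)
    msgs <- c(msgs, "nRotatedDist must be 10 non-negative weights over 0..9")
  for (nm in c("pOdaAbsent", "pIdaAbsent", "pCentralDefect", "pDisorganized")) {
    p <- slot(object, nm)
    if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
      msgs <- c(msgs, paste(nm, "must be a probability in [0, 1]"))
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(paste0("SceneSpec: %d section(s), ring %.1f +/- %.1f px, aspect [%.2f, %.2f]\n",
                     "  tilt aligned |N(0, %.1f)| deg, rotated N(%.1f, %.1f) in [%.0f, %.0f] deg\n",
                     "  P(rotated doublets 0..9) = %s\n",
                     "  defects: ODA %.2f IDA %.2f central %.2f disorganized %.2f; psf %.1f px, noise %.3f; seed %d\n"),
              object@nSections, object@ringRadiusMean, object@ringRadiusSd,
              object@ellipseAspectRange[1], object@ellipseAspectRange[2],
              object@tiltAlignedSd, object@tiltRotatedMean, object@tiltRotatedSd,
              object@tiltRotatedRange[1], object@tiltRotatedRange[2],
              paste(signif(object@nRotatedDist / sum(object@nRotatedDist), 2), collapse = " "),
              object@pOdaAbsent, object@pIdaAbsent, object@pCentralDefect,
              object@pDisorganized, object@psfSigma, object@noiseSd, object@seed))
})
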