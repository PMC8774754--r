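## Rotated-doublet calls and the per-section symmetry break.

#' Rotated-doublet call for a single doublet
#'
#' A doublet is called rotated when its B-tubule lies outside the axonemal
#' circumference: the signed clearance of the B-center from the fitted curve
#' must reach \code{kappa * rB} (boundary equality counts as rotated). Only
#' outward displacement counts; a B-center inside the curve has negative
#' clearance and is never called rotated, although the clearance is
#' reported.
#'
#' @param fit a \linkS4class{CircumferenceFit}.
#' @param aCenter,bCenter A- and B-tubule centers, each \code{c(x, y)}.
#' @param rB B-tubule outer radius (px).
#' @param kappa dimensionless threshold (>= 0): fraction of \code{rB} the
#'   B-center must clear the curve by. Default 0.5 (half the B-tubule
#'   protruding).
#' @param index doublet index carried into the call.
#' @return one-row data.frame: \code{doublet_index}, \code{clearance} (px,
#'   signed, positive = outside), \code{tilt_deg} (angle between the doublet
#'   axis and the local tangent), \code{rotated} (logical).
#' @export
isRotated <- function(fit, aCenter, bCenter, rB, kappa = 0.5, index = NA_integer_) {
  if (length(kappa) != 1L || is.na(kappa) || kappa < 0)
    .err("kappa must be a single non-negative number", "axosymConfigError")
  if (rB <= 0) .err("rB must be positive", "axosymConfigError")
  cl <- radialClearance(fit, bCenter)
  data.frame(doublet_index = as.integer(index),
             clearance = cl,
             tilt_deg = tiltAngle(fit, aCenter, bCenter),
             rotated = cl >= kappa * rB)
}

#' Rotated-doublet calls for every doublet of a section
#'
#' @param section a \linkS4class{CrossSection}.
#' @param fit a \linkS4class{CircumferenceFit}; fitted to the section's
#'   A-centers when NULL.
#' @inheritParams isRotated
#' @param fitKind curve model passed to \code{\link{fitCircumference}} when
#'   \code{fit} is NULL.
#' @return data.frame with one row per doublet, ordered by doublet index.
#' @export
rotationCalls <- function(section, fit = NULL, kappa = 0.5, fitKind = "auto") {
  stopifnot(is(section, "CrossSection"))
  d <- doublets(section)
  if (is.null(fit))
    fit <- fitCircumference(cbind(d$ax, d$ay), kind = fitKind,
                            sectionId = sectionId(section))
  d <- d[order(d$index), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(d)), function(i)
    isRotated(fit, c(d$ax[i], d$ay[i]), c(d$bx[i], d$by[i]), d$r_b[i],
              kappa = kappa, index = d$index[i])))
  rownames(out) <- NULL
  out
}

.assessableStatus <- function(section, minDoublets) {
  if (isDisorganized(section)) return("disorganized")
  d <- doublets(section)
  ok <- stats::complete.cases(d[, c("ax", "ay", "bx", "by")])
  if (sum(ok) < minDoublets) return("too_few_doublets")
  "assessable"
}

#' Count rotated doublets in a section
#'
#' Requires an assessable section: not disorganized and at least
#' \code{minDoublets} (default 8 of 9) doublets with both tubule centers
#' localized. Non-assessable sections return \code{NA} carrying a
#' \code{status} attribute ("disorganized" or "too_few_doublets") rather
#' than raising an error, so they can be excluded from both the numerator
#' and denominator of the asymmetry percentage.
#'
#' @inheritParams rotationCalls
#' @param minDoublets minimum number of localized doublets for assessment.
#' @return integer count in 0..9, or NA with attribute \code{status}.
#' @export
countRotated <- function(section, fit = NULL, kappa = 0.5, minDoublets = 8L,
                         fitKind = "auto") {
  st <- .assessableStatus(section, minDoublets)
  if (st != "assessable")
    return(structure(NA_integer_, status = st))
  calls <- rotationCalls(section, fit = fit, kappa = kappa, fitKind = fitKind)
  structure(sum(calls$rotated), status = "assessable")
}

#' Per-section axonemal symmetry break
#'
#' A cross-section has an axonemal symmetry break when more than 3 of its
#' peripheral doublets are rotated, i.e. \code{countRotated >= 4}.
#'
#' @inheritParams countRotated
#' @return logical, or NA with attribute \code{status} for non-assessable
#'   sections.
#' @export
hasSymmetryBreak <- function(section, fit = NULL, kappa = 0.5, minDoublets = 8L,
                             fitKind = "auto") {
  n <- countRotated(section, fit = fit, kappa = kappa,
                    minDoublets = minDoublets, fitKind = fitKind)
  structure(ifelse(is.na(n), NA, n > 3L), status = attr(n, "status"))
}

#' Full geometric assessment of one cross-section
#'
#' Fits the circumference, produces per-doublet rotation calls, counts
#' rotated doublets and calls the symmetry break. Non-assessable sections
#' (disorganized, or fewer than \code{minDoublets} localized doublets) are
#' returned with \code{assessable = FALSE} and no calls.
#'
#' @inheritParams countRotated
#' @param eccentricityCap passed to \code{\link{fitCircumference}}.
#' @return a list of class \code{axosymSectionReport}: \code{section_id},
#'   \code{assessable}, \code{status}, \code{fit} (parameter list or NULL),
#'   \code{calls} (data.frame or NULL), \code{n_rotated},
#'   \code{symmetry_break}.
#' @examples
#' spec <- sceneSpec(nRotatedDist = c(rep(0, 5), 1, rep(0, 4)))
#' sec <- generateSectionCoords(spec, seed = 1)$section
#' assessSection(sec)$n_rotated
#' @export
assessSection <- function(section, kappa = 0.5, fitKind = "auto",
                          minDoublets = 8L, eccentricityCap = 0.8) {
  stopifnot(is(section, "CrossSection"))
  st <- .assessableStatus(section, minDoublets)
  rep0 <- list(section_id = sectionId(section), assessable = st == "assessable",
               status = st, fit = NULL, calls = NULL,
               n_rotated = NA_integer_, symmetry_break = NA)
  class(rep0) <- "axosymSectionReport"
  if (st != "assessable") return(rep0)
  d <- doublets(section)
  fit <- fitCircumference(cbind(d$ax, d$ay), kind = fitKind,
                          eccentricityCap = eccentricityCap,
                          sectionId = sectionId(section))
  calls <- rotationCalls(section, fit = fit, kappa = kappa)
  rep0$fit <- fitParams(fit)
  rep0$calls <- calls
  rep0$n_rotated <- sum(calls$rotated)
  rep0$symmetry_break <- rep0$n_rotated > 3L
  rep0
}

#' @export
print.axosymSectionReport <- function(x, ...) {
  cat("Section", x$section_id, "-",
      if (!x$assessable) paste0("not assessable (", x$status, ")")
      else sprintf("%d rotated doublet(s); symmetry break: %s",
                   x$n_rotated, x$symmetry_break), "\n")
  invisible(x)
}
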