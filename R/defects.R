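## Per-section ultrastructural defect calls, the modified BEAT-PCD Class 1 /
## Class 2 patient classification, and the per-patient axonemal asymmetry
## percentage.

#' Per-section ultrastructural defect call
#'
#' Calls outer/inner dynein arm absence, a central-complex defect and the
#' symmetry break for one cross-section. An arm is called absent when at
#' most \code{armMin} of the doublets with a known flag bear it (sections
#' score as a whole; a couple of unresolvable arms are tolerated). A
#' central-complex defect is any central microtubule count other than 2.
#' Sections without any known arm flag get an NA (not-assessable) arm call;
#' disorganized sections carry \code{symmetry_break = NA}.
#'
#' @param section a \linkS4class{CrossSection}.
#' @param armMin maximum number of arm-bearing doublets compatible with an
#'   "absent" call (default 2 of 9).
#' @inheritParams countRotated
#' @return one-row data.frame: \code{section_id}, \code{oda_absent},
#'   \code{ida_absent}, \code{central_defect}, \code{disorganized},
#'   \code{symmetry_break} (all logical; NA = not assessable).
#' @export
callSectionDefects <- function(section, armMin = 2L, kappa = 0.5,
                               minDoublets = 8L, fitKind = "auto") {
  stopifnot(is(section, "CrossSection"))
  d <- doublets(section)
  armCall <- function(flags) {
    flags <- flags[!is.na(flags)]
    if (!length(flags)) NA else sum(flags) <= armMin
  }
  br <- if (nrow(d) >= 3L)
    hasSymmetryBreak(section, kappa = kappa, minDoublets = minDoublets,
                     fitKind = fitKind)
  else structure(NA, status = "too_few_doublets")
  data.frame(section_id = sectionId(section),
             oda_absent = armCall(d$oda),
             ida_absent = armCall(d$ida),
             central_defect = centralPairCount(section) != 2L,
             disorganized = isDisorganized(section),
             symmetry_break = as.logical(br))
}

#' Modified BEAT-PCD ultrastructural class of a patient
#'
#' Maps per-patient defect percentages to Class 1 (hallmark diagnostic
#' defect), Class 2 (supporting defect) or none:
#' \itemize{
#'   \item C1: outer dynein arm absence, or combined outer+inner absence,
#'     in more than 50\% of cross-sections;
#'   \item C2: either absence in 25--50\% of sections (bounds inclusive), or
#'     a central-complex defect in more than \code{centralThreshold}\% of
#'     sections;
#'   \item none otherwise.
#' }
#' Microtubular disorganization is excluded upstream and plays no role here.
#'
#' @param pctOdaAbsent,pctOdaIdaAbsent,pctCentralDefect percentages in
#'   [0, 100] of cross-sections with the defect (vectorized).
#' @param centralThreshold Class-2 threshold for the central-complex defect
#'   percentage (the classification table gives no number; default 25,
#'   aligned with the other Class-2 band).
#' @return character vector of "C1", "C2" or "none".
#' @examples
#' classifyPatient(56, 0, 0)   # "C1"
#' classifyPatient(30, 0, 0)   # "C2"
#' classifyPatient(16, 0, 0)   # "none"
#' @export
classifyPatient <- function(pctOdaAbsent, pctOdaIdaAbsent = 0,
                            pctCentralDefect = 0, centralThreshold = 25) {
  n <- max(length(pctOdaAbsent), length(pctOdaIdaAbsent), length(pctCentralDefect))
  oda <- rep_len(as.numeric(pctOdaAbsent), n)
  both <- rep_len(as.numeric(pctOdaIdaAbsent), n)
  cen <- rep_len(as.numeric(pctCentralDefect), n)
  vals <- c(oda, both, cen)
  if (any(is.na(vals)) || any(vals < 0) || any(vals > 100))
    .err("defect percentages must lie in [0, 100]", "axosymValidationError")
  cls <- rep("none", n)
  c2 <- (oda >= 25 & oda <= 50) | (both >= 25 & both <= 50) | cen > centralThreshold
  c1 <- oda > 50 | both > 50
  cls[c2] <- "C2"
  cls[c1] <- "C1"
  cls
}

#' Axonemal asymmetry percentage
#'
#' AA = 100 x (number of sections with a symmetry break) / (number of
#' assessable sections). Non-assessable sections (disorganized, too few
#' localized doublets: \code{NA} entries) are excluded from both numerator
#' and denominator.
#'
#' @param breaks logical vector of per-section symmetry-break calls, NA for
#'   non-assessable sections (e.g. the \code{symmetry_break} column of
#'   \code{\link{callSectionDefects}} rows).
#' @param warnBelow emit a low-coverage warning when fewer assessable
#'   sections than this are available (diagnostic practice evaluates at
#'   least 50).
#' @return percentage in [0, 100].
#' @examples
#' computeAA(c(rep(TRUE, 19), rep(FALSE, 31)))   # 38
#' @export
computeAA <- function(breaks, warnBelow = 50L) {
  breaks <- as.logical(breaks)
  n <- sum(!is.na(breaks))
  if (n == 0L)
    .err("no assessable sections: AA denominator is empty", "axosymEmptyDenominatorError")
  if (n < warnBelow)
    warning(sprintf("only %d assessable sections (at least %d recommended)",
                    n, warnBelow), call. = FALSE)
  100 * sum(breaks, na.rm = TRUE) / n
}

#' Per-patient defect summary and TEM class
#'
#' Aggregates per-section defect calls for one patient: defect percentages
#' over the sections where each call was assessable, the axonemal asymmetry
#' percentage, and the modified BEAT-PCD class. Percentages are reported to
#' one decimal. Fewer than 50 sections triggers a low-coverage warning
#' recorded in the \code{warnings} column.
#'
#' @param calls data.frame of per-section calls, one row per section, as
#'   returned by \code{\link{callSectionDefects}} (rows rbind-ed).
#' @param patientId identifier carried into the summary.
#' @param centralThreshold passed to \code{\link{classifyPatient}}.
#' @return one-row data.frame: \code{patient_id}, \code{n_sections},
#'   \code{n_assessable_aa}, \code{pct_oda_absent}, \code{pct_oda_ida_absent},
#'   \code{pct_central_defect}, \code{aa_pct}, \code{tem_class},
#'   \code{warnings}.
#' @export
summarizePatientSections <- function(calls, patientId = "patient",
                                     centralThreshold = 25) {
  stopifnot(is.data.frame(calls), nrow(calls) >= 1L)
  pct <- function(x) {
    n <- sum(!is.na(x))
    if (n == 0L) NA_real_ else round(100 * sum(x, na.rm = TRUE) / n, 1)
  }
  nAA <- sum(!is.na(calls$symmetry_break))
  aa <- if (nAA > 0L)
    round(suppressWarnings(computeAA(calls$symmetry_break)), 1)
  else NA_real_
  pOda <- pct(calls$oda_absent)
  pBoth <- pct(calls$oda_absent & calls$ida_absent)
  pCen <- pct(calls$central_defect)
  warn <- character(0)
  if (nrow(calls) < 50L)
    warn <- c(warn, sprintf("low coverage: %d sections (<50)", nrow(calls)))
  if (nAA < nrow(calls))
    warn <- c(warn, sprintf("%d section(s) excluded from AA", nrow(calls) - nAA))
  cls <- classifyPatient(ifelse(is.na(pOda), 0, pOda),
                         ifelse(is.na(pBoth), 0, pBoth),
                         ifelse(is.na(pCen), 0, pCen),
                         centralThreshold = centralThreshold)
  data.frame(patient_id = as.character(patientId),
             n_sections = nrow(calls), n_assessable_aa = nAA,
             pct_oda_absent = pOda, pct_oda_ida_absent = pBoth,
             pct_central_defect = pCen, aa_pct = aa, tem_class = cls,
             warnings = paste(warn, collapse = "; "))
}

#' Score a patient's sections end to end
#'
#' Convenience wrapper: per-section defect calls for a list of
#' \linkS4class{CrossSection}s, then the per-patient summary.
#'
#' @param sections list of \linkS4class{CrossSection}.
#' @inheritParams callSectionDefects
#' @inheritParams summarizePatientSections
#' @return as \code{\link{summarizePatientSections}}.
#' @export
scorePatient <- function(sections, patientId = "patient", armMin = 2L,
                         kappa = 0.5, minDoublets = 8L, fitKind = "auto",
                         centralThreshold = 25) {
  calls <- do.call(rbind, lapply(sections, callSectionDefects, armMin = armMin,
                                 kappa = kappa, minDoublets = minDoublets,
                                 fitKind = fitKind))
  summarizePatientSections(calls, patientId = patientId,
                           centralThreshold = centralThreshold)
}
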