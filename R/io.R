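## Plain-text interchange: coordinate CSVs and JSON section reports.

#' Write / read section coordinate CSVs
#'
#' Two companion files: a doublet table (one row per doublet:
#' \code{section_id, doublet_index, ax, ay, bx, by, r_a, r_b, oda_present,
#' ida_present} with arm flags coded 0/1/NA) and a section table
#' (\code{section_id, central_pair_count, disorganized, n_peripheral}).
#'
#' @param sections list of \linkS4class{CrossSection}.
#' @param doubletPath,sectionPath CSV paths.
#' @return \code{readSectionCoords} returns a list of
#'   \linkS4class{CrossSection}; \code{writeSectionCoords} returns the
#'   paths invisibly.
#' @export
writeSectionCoords <- function(sections, doubletPath, sectionPath) {
  dts <- do.call(rbind, lapply(sections, function(s) {
    d <- doublets(s)
    if (!nrow(d)) return(NULL)
    data.frame(section_id = sectionId(s), doublet_index = d$index,
               ax = d$ax, ay = d$ay, bx = d$bx, by = d$by,
               r_a = d$r_a, r_b = d$r_b,
               oda_present = as.integer(d$oda), ida_present = as.integer(d$ida))
  }))
  if (is.null(dts)) dts <- data.frame(section_id = character(), doublet_index = integer(),
                                      ax = numeric(), ay = numeric(), bx = numeric(),
                                      by = numeric(), r_a = numeric(), r_b = numeric(),
                                      oda_present = integer(), ida_present = integer())
  secs <- do.call(rbind, lapply(sections, function(s)
    data.frame(section_id = sectionId(s),
               central_pair_count = centralPairCount(s),
               disorganized = as.integer(isDisorganized(s)),
               n_peripheral = nrow(doublets(s)))))
  utils::write.csv(dts, doubletPath, row.names = FALSE)
  utils::write.csv(secs, sectionPath, row.names = FALSE)
  invisible(c(doubletPath, sectionPath))
}

#' @rdname writeSectionCoords
#' @export
readSectionCoords <- function(doubletPath, sectionPath) {
  dts <- utils::read.csv(doubletPath, stringsAsFactors = FALSE)
  secs <- utils::read.csv(sectionPath, stringsAsFactors = FALSE)
  need <- c("section_id", "doublet_index", "ax", "ay", "bx", "by", "r_a", "r_b")
  if (!all(need %in% names(dts)))
    .err(paste("doublet CSV must have columns:",
               paste(need, collapse = ", ")), "axosymParseError")
  lapply(seq_len(nrow(secs)), function(i) {
    sid <- secs$section_id[i]
    di <- dts[dts$section_id == sid, , drop = FALSE]
    d <- data.frame(index = di$doublet_index, ax = di$ax, ay = di$ay,
                    bx = di$bx, by = di$by, r_a = di$r_a, r_b = di$r_b,
                    oda = as.logical(di$oda_present),
                    ida = as.logical(di$ida_present))
    CrossSection(sid, d, centralPairCount = secs$central_pair_count[i],
                 disorganized = secs$disorganized[i] == 1)
  })
}

#' Write a per-section assessment report as JSON
#'
#' Serializes an \code{\link{assessSection}} result (fit parameters,
#' per-doublet clearance/tilt/rotated calls, rotated count, break flag and
#' assessable status) to JSON.
#'
#' @param report an \code{axosymSectionReport}.
#' @param path output path.
#' @export
writeSectionReport <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", na = "null")
  invisible(path)
}
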