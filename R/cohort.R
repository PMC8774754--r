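## Patient-level cohort stage: table ingest, group summaries in the
## Mean (SD) / Median (Q1, Q3) / n (%) layout, and the AA range/overlap
## report.

.hsvaTokens <- c("Dyskinetic", "Immotile", "Normal", "N")
.temTokens <- c("C1", "C2", "none")

#' Ingest a patient-level table
#'
#' Reads a CSV of study participants (one row each) with columns
#' \code{id, cci, gene, hsva, tem_class, aa} and optionally \code{group}.
#' \code{cci} and \code{aa} are percentages in [0, 100]; \code{hsva} must
#' be one of Dyskinetic / Immotile / Normal / N (N is read as Normal in
#' summaries); \code{tem_class} one of C1 / C2 / none (the token "No" is
#' normalized to "none"). Gene entries are carried verbatim (including
#' "Not identified", "*" = not tested and "VUS <gene>").
#'
#' The packaged fixtures \code{table2_pcd_patients.csv} and
#' \code{table3_controls.csv} under \code{system.file("extdata", package =
#' "axosym")} hold the 20 PCD patients and the 20 controls of the study
#' cohort in this format.
#'
#' @param path CSV path.
#' @param group group label applied to all rows when the file has no
#'   \code{group} column.
#' @return data.frame of patient records: \code{id, group, cci, gene,
#'   hsva, tem_class, aa}.
#' @examples
#' pcd <- ingestPatientTable(system.file("extdata", "table2_pcd_patients.csv",
#'                                       package = "axosym"))
#' range(pcd$aa)   # 38 68
#' @export
ingestPatientTable <- function(path, group = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    warning("empty patient table: ", path, call. = FALSE)
    return(data.frame(id = character(), group = character(), cci = numeric(),
                      gene = character(), hsva = character(),
                      tem_class = character(), aa = numeric()))
  }
  need <- c("id", "cci", "gene", "hsva", "tem_class", "aa")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    .err(paste("patient table missing column(s):", paste(miss, collapse = ", ")),
         "axosymParseError")
  if (is.null(tab$group)) {
    if (is.null(group))
      .err("no group column and no group= argument given", "axosymParseError")
    tab$group <- group
  }
  tab$id <- as.character(tab$id)
  if (anyDuplicated(tab$id))
    .err(paste("duplicate patient id(s):",
               paste(unique(tab$id[duplicated(tab$id)]), collapse = ", ")),
         "axosymValidationError")
  tab$tem_class <- ifelse(tab$tem_class %in% c("No", "no", "None"), "none",
                          tab$tem_class)
  for (i in seq_len(nrow(tab))) {
    bad <- character(0)
    if (!tab$hsva[i] %in% .hsvaTokens) bad <- c(bad, paste("hsva =", tab$hsva[i]))
    if (!tab$tem_class[i] %in% .temTokens) bad <- c(bad, paste("tem_class =", tab$tem_class[i]))
    for (f in c("cci", "aa")) {
      v <- suppressWarnings(as.numeric(tab[[f]][i]))
      if (is.na(v) || v < 0 || v > 100) bad <- c(bad, paste(f, "=", tab[[f]][i]))
    }
    if (length(bad))
      .err(sprintf("row %d (id %s): invalid %s", i, tab$id[i],
                   paste(bad, collapse = "; ")), "axosymParseError")
  }
  data.frame(id = tab$id, group = as.character(tab$group),
             cci = as.numeric(tab$cci), gene = as.character(tab$gene),
             hsva = as.character(tab$hsva), tem_class = tab$tem_class,
             aa = as.numeric(tab$aa))
}

.numSummary <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  q <- if (n) stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  else rep(NA_real_, 3)
  data.frame(n = n,
             mean = if (n) mean(x) else NA_real_,
             sd = if (n >= 2) stats::sd(x) else NA_real_,
             median = q[2], q1 = q[1], q3 = q[3])
}

#' Group summaries in the cohort-table layout
#'
#' Summarizes numeric fields with mean (SD) and median (1st, 3rd
#' quartiles; linear interpolation between order statistics) and
#' categorical fields with absolute frequency and percentage, per level of
#' a grouping field — the layout of the study's distribution tables. A
#' single observation yields an undefined (NA) SD; an empty level yields
#' n = 0 with NA statistics. HSVA token "N" is summarized as "Normal".
#'
#' @param records patient data.frame from \code{\link{ingestPatientTable}}.
#' @param groupBy grouping field (e.g. "group", "tem_class", "hsva").
#' @param numericFields,categoricalFields fields to summarize.
#' @return named list (one entry per group level): \code{n},
#'   \code{numeric} (data.frame field x statistics), \code{categorical}
#'   (list of frequency data.frames with \code{level, n, pct}).
#' @export
summarizeCohort <- function(records, groupBy = "group",
                            numericFields = c("cci", "aa"),
                            categoricalFields = c("hsva", "tem_class")) {
  stopifnot(groupBy %in% names(records))
  recs <- records
  if ("hsva" %in% names(recs)) recs$hsva[recs$hsva == "N"] <- "Normal"
  categoricalFields <- setdiff(categoricalFields, groupBy)
  lv <- unique(recs[[groupBy]])
  out <- lapply(lv, function(g) {
    r <- recs[recs[[groupBy]] == g, , drop = FALSE]
    num <- do.call(rbind, lapply(numericFields, function(f)
      cbind(field = f, .numSummary(r[[f]]))))
    cat <- lapply(categoricalFields, function(f) {
      tb <- table(r[[f]])
      data.frame(level = names(tb), n = as.integer(tb),
                 pct = if (nrow(r)) round(100 * as.integer(tb) / nrow(r), 2)
                 else numeric(length(tb)))
    })
    names(cat) <- categoricalFields
    list(n = nrow(r), numeric = num, categorical = cat)
  })
  names(out) <- as.character(lv)
  out
}

#' AA range and between-group overlap report
#'
#' Per-group axonemal-asymmetry minimum and maximum, the list of control
#' participants whose AA reaches the PCD minimum (the diagnostic
#' gray zone), and the fraction of PCD records with no TEM defect
#' (normal-ultrastructure PCD).
#'
#' @param records patient data.frame with a \code{group} column holding
#'   "PCD" and "control".
#' @return list: \code{pcd_range}, \code{control_range} (each
#'   \code{c(min, max)}), \code{overlap_ids} (character vector),
#'   \code{pct_pcd_no_defect}, \code{n_pcd}, \code{n_control}. Absent
#'   groups yield a partial report with a warning.
#' @examples
#' pcd <- ingestPatientTable(system.file("extdata", "table2_pcd_patients.csv",
#'                                       package = "axosym"))
#' ctl <- ingestPatientTable(system.file("extdata", "table3_controls.csv",
#'                                       package = "axosym"))
#' rangeOverlapReport(rbind(pcd, ctl))$overlap_ids   # "25" "59"
#' @export
rangeOverlapReport <- function(records) {
  pcd <- records[records$group == "PCD", , drop = FALSE]
  ctl <- records[records$group == "control", , drop = FALSE]
  out <- list(pcd_range = NULL, control_range = NULL, overlap_ids = character(),
              pct_pcd_no_defect = NA_real_,
              n_pcd = nrow(pcd), n_control = nrow(ctl))
  if (!nrow(pcd) || !nrow(ctl))
    warning("group(s) missing: partial report", call. = FALSE)
  if (nrow(pcd)) {
    out$pcd_range <- range(pcd$aa)
    out$pct_pcd_no_defect <- 100 * mean(pcd$tem_class == "none")
  }
  if (nrow(ctl)) out$control_range <- range(ctl$aa)
  if (nrow(pcd) && nrow(ctl)) {
    ov <- ctl[ctl$aa >= out$pcd_range[1], , drop = FALSE]
    out$overlap_ids <- ov$id[order(ov$aa)]
  }
  out
}
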