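pcdPath <- function() system.file("extdata", "table2_pcd_patients.csv",
                                  package = "axosym")
ctlPath <- function() system.file("extdata", "table3_controls.csv",
                                  package = "axosym")

test_that("the packaged patient tables ingest as 20 + 20 validated records", {
  pcd <- ingestPatientTable(pcdPath())
  ctl <- ingestPatientTable(ctlPath())
  expect_identical(nrow(pcd), 20L)
  expect_identical(nrow(ctl), 20L)
  expect_identical(unique(pcd$group), "PCD")
  expect_identical(unique(ctl$group), "control")
  expect_true(all(pcd$aa >= 0 & pcd$aa <= 100))
  ## "No" normalizes to "none"
  expect_setequal(unique(pcd$tem_class), c("C1", "C2", "none"))
  expect_identical(unique(ctl$tem_class), "none")
})

test_that("ingest rejects malformed tables with row-level messages", {
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,group,cci,gene,hsva,tem_class,aa",
               "1,PCD,40,DNAH5,Dyskinetic,C1,38",
               "2,PCD,50,DNAH5,Wobbly,C1,40"), bad)
  expect_error(ingestPatientTable(bad), regexp = "row 2.*hsva",
               class = "axosymParseError")
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,group,cci,gene,hsva,tem_class,aa",
               "1,PCD,40,DNAH5,Dyskinetic,C1,38",
               "1,PCD,50,DNAH5,Immotile,C1,40"), dup)
  expect_error(ingestPatientTable(dup), class = "axosymValidationError")
  oor <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,group,cci,gene,hsva,tem_class,aa",
               "1,PCD,40,DNAH5,Dyskinetic,C1,138"), oor)
  expect_error(ingestPatientTable(oor), regexp = "aa")
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,group,cci,gene,hsva,tem_class,aa", empty)
  expect_warning(res <- ingestPatientTable(empty), regexp = "empty")
  expect_identical(nrow(res), 0L)
})

test_that("re-serializing and re-ingesting records is idempotent", {
  pcd <- ingestPatientTable(pcdPath())
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(pcd, tmp, row.names = FALSE)
  again <- ingestPatientTable(tmp)
  expect_equal(again, pcd)
})

test_that("group summaries follow the mean/SD and quartile conventions", {
  pcd <- ingestPatientTable(pcdPath())
  s <- summarizeCohort(rbind(pcd, ingestPatientTable(ctlPath())))
  expect_identical(s$PCD$n, 20L)
  aaRow <- s$PCD$numeric[s$PCD$numeric$field == "aa", ]
  expect_equal(aaRow$mean, mean(pcd$aa))
  expect_equal(aaRow$sd, sd(pcd$aa))
  expect_equal(aaRow$median, median(pcd$aa))
  expect_equal(aaRow$q1, unname(quantile(pcd$aa, 0.25)))
  ## two-point arithmetic example
  two <- data.frame(id = c("a", "b"), group = "g", cci = 50, gene = "x",
                    hsva = "Normal", tem_class = "none", aa = c(38, 68))
  s2 <- summarizeCohort(two)$g$numeric
  expect_equal(s2[s2$field == "aa", c("mean", "median")],
               data.frame(mean = 53, median = 53), ignore_attr = TRUE)
  ## single record: undefined SD
  one <- two[1, ]
  s1 <- summarizeCohort(one)$g$numeric
  expect_true(is.na(s1[s1$field == "aa", "sd"]))
  expect_equal(s1[s1$field == "aa", "median"], 38)
})

test_that("TEM class frequencies in the PCD table match the printed cohort", {
  pcd <- ingestPatientTable(pcdPath())
  s <- summarizeCohort(pcd, groupBy = "group")
  tab <- s$PCD$categorical$tem_class
  expect_identical(tab$n[match(c("C1", "C2", "none"), tab$level)],
                   c(11L, 2L, 7L))
  ## summaries are invariant to row order
  set.seed(1)
  s2 <- summarizeCohort(pcd[sample(20), ], groupBy = "group")
  expect_equal(s2$PCD$numeric, s$PCD$numeric)
})

test_that("the range and overlap report isolates the diagnostic gray zone", {
  recs <- rbind(ingestPatientTable(pcdPath()), ingestPatientTable(ctlPath()))
  r <- rangeOverlapReport(recs)
  expect_identical(r$pcd_range, c(38, 68))
  expect_identical(r$control_range, c(2, 63))
  expect_identical(r$overlap_ids, c("25", "59"))
  expect_equal(r$pct_pcd_no_defect, 35)
  ## degenerate constructions
  same <- recs; same$aa <- 50
  expect_setequal(rangeOverlapReport(same)$overlap_ids,
                  same$id[same$group == "control"])
  low <- recs; low$aa[low$group == "control"] <- 1
  expect_identical(rangeOverlapReport(low)$overlap_ids, character(0))
  expect_warning(r2 <- rangeOverlapReport(recs[recs$group == "PCD", ]),
                 regexp = "missing")
  expect_identical(r2$pcd_range, c(38, 68))
  expect_length(r2$overlap_ids, 0L)
})
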