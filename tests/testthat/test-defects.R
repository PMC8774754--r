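test_that("per-section defect calls follow the arm and central-pair rules", {
  allAbsent <- makeSection(oda = FALSE, ida = FALSE)
  call <- callSectionDefects(allAbsent)
  expect_true(call$oda_absent)
  expect_true(call$ida_absent)
  expect_false(call$central_defect)

  normal <- makeSection()
  call2 <- callSectionDefects(normal)
  expect_false(any(call2$oda_absent, call2$ida_absent, call2$central_defect))
  expect_false(call2$symmetry_break)

  noCP <- makeSection(centralPairCount = 0L)
  expect_true(callSectionDefects(noCP)$central_defect)

  ## unknown arm flags propagate as not-assessable
  unk <- makeSection()
  unk@doublets$oda <- NA
  expect_true(is.na(callSectionDefects(unk)$oda_absent))

  ## disorganized sections carry a not-assessable break
  dis <- makeSection(disorganized = TRUE)
  expect_true(is.na(callSectionDefects(dis)$symmetry_break))
  expect_true(callSectionDefects(dis)$disorganized)
})

test_that("classification reproduces the Class 1 / Class 2 bands", {
  expect_identical(classifyPatient(56), "C1")
  expect_identical(classifyPatient(30), "C2")
  expect_identical(classifyPatient(16), "none")
  expect_identical(classifyPatient(22), "none")
  ## boundaries: 50 and 25 belong to Class 2
  expect_identical(classifyPatient(50), "C2")
  expect_identical(classifyPatient(25), "C2")
  expect_identical(classifyPatient(50.0001), "C1")
  ## combined-arm and central-complex routes
  expect_identical(classifyPatient(0, pctOdaIdaAbsent = 60), "C1")
  expect_identical(classifyPatient(0, pctOdaIdaAbsent = 30), "C2")
  expect_identical(classifyPatient(0, pctCentralDefect = 30), "C2")
  expect_identical(classifyPatient(0, pctCentralDefect = 25), "none")
  expect_error(classifyPatient(120), class = "axosymValidationError")
  expect_error(classifyPatient(-2), class = "axosymValidationError")
})

test_that("the class rules partition the percentage grid without gaps", {
  grid <- expand.grid(oda = 0:100, central = c(0, 20, 30))
  cls <- classifyPatient(grid$oda, 0, grid$central)
  expect_true(all(cls %in% c("C1", "C2", "none")))
  ## semantics on the ODA axis with no other defect
  pure <- classifyPatient(0:100, 0, 0)
  expect_identical(unique(pure[0:100 < 25]), "none")
  expect_identical(unique(pure[0:100 >= 25 & 0:100 <= 50]), "C2")
  expect_identical(unique(pure[0:100 > 50]), "C1")
  ## monotone severity: increasing ODA absence never de-escalates the class
  sev <- c(none = 0L, C2 = 1L, C1 = 2L)
  expect_true(all(diff(sev[pure]) >= 0))
})

test_that("AA is breaks over assessable sections, order-invariant", {
  expect_equal(computeAA(c(rep(TRUE, 19), rep(FALSE, 31))), 38)
  expect_equal(computeAA(rep(FALSE, 50)), 0)
  expect_equal(computeAA(rep(TRUE, 50)), 100)
  ## NA (not-assessable) sections leave numerator and denominator
  ## (40 assessable sections: below diagnostic coverage, hence quiet here)
  x <- c(rep(TRUE, 10), rep(FALSE, 30), rep(NA, 10))
  expect_equal(suppressWarnings(computeAA(x)), 25)
  set.seed(3)
  expect_equal(suppressWarnings(computeAA(sample(x))),
               suppressWarnings(computeAA(x)))
  expect_error(computeAA(c(NA, NA)), class = "axosymEmptyDenominatorError")
  expect_warning(computeAA(c(TRUE, FALSE)), regexp = "recommended")
})

test_that("patient summaries aggregate section calls into class and AA", {
  sections <- c(lapply(1:30, function(i) makeSection(tiltIdx = 1:5, id = i,
                                                     oda = FALSE)),
                lapply(31:50, function(i) makeSection(id = i)))
  s <- scorePatient(sections, patientId = "p1")
  expect_identical(s$n_sections, 50L)
  expect_identical(s$n_assessable_aa, 50L)
  expect_equal(s$aa_pct, 60)
  expect_equal(s$pct_oda_absent, 60)
  expect_identical(s$tem_class, "C1")
  expect_identical(s$warnings, "")
  ## low coverage flagged below 50 sections
  s2 <- scorePatient(sections[1:20], patientId = "p2")
  expect_match(s2$warnings, "low coverage")
})
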