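test_that("generation is byte-identical for a fixed seed", {
  spec <- sceneSpec(nSections = 5L, nRotatedDist = c(rep(0.1, 10)), seed = 99L)
  g1 <- generateSections(spec)
  g2 <- generateSections(spec)
  expect_identical(g1, g2)
  g3 <- generateSections(spec, seed = 100L)
  expect_false(identical(g1$truths, g3$truths))
})

test_that("noiseless sections round-trip through the rotation classifier", {
  for (k in c(0L, 1L, 3L, 4L, 6L, 9L)) {
    g <- generateSections(wellSeparatedSpec(k, n = 8L, seed = 300L + k))
    for (i in seq_along(g$sections)) {
      expect_identical(as.integer(countRotated(g$sections[[i]])), k)
      expect_identical(as.logical(hasSymmetryBreak(g$sections[[i]])), k >= 4L)
      expect_identical(g$truths[[i]]$n_rotated, k)
    }
  }
})

test_that("generated geometry honors the scene parameters", {
  spec <- sceneSpec(nSections = 6L, seed = 17L, pCentralDefect = 1,
                    pOdaAbsent = 1)
  g <- generateSections(spec)
  for (i in seq_along(g$sections)) {
    s <- g$sections[[i]]; tr <- g$truths[[i]]
    d <- doublets(s)
    expect_identical(nrow(d), 9L)
    ## doublet length is exactly rA + rB
    expect_equal(sqrt((d$bx - d$ax)^2 + (d$by - d$ay)^2), rep(26, 9),
                 tolerance = 1e-9)
    expect_identical(centralPairCount(s), 0L)    # forced central defect
    expect_true(all(!d$oda))                     # forced ODA absence
    ## true tilt labels match the rotated flags
    expect_identical(tr$rotated, tr$tilt_deg %in%
                       tr$tilt_deg[tr$rotated])
    ## semi-minor axis is the ring radius scale
    expect_gt(tr$ellipse$a, tr$ellipse$b - 1e-9)
  }
})

test_that("zero-tilt scenes never break and forced-tilt scenes always do", {
  g0 <- generateSections(wellSeparatedSpec(0L, n = 6L, seed = 7L))
  expect_true(all(!vapply(g0$sections, function(s)
    as.logical(hasSymmetryBreak(s)), logical(1))))
  g5 <- generateSections(wellSeparatedSpec(5L, n = 6L, seed = 8L))
  expect_true(all(vapply(g5$sections, function(s)
    as.logical(hasSymmetryBreak(s)), logical(1))))
})

test_that("cohort generation scores patients and reports expected AA", {
  d <- c(0.5, 0, 0, 0, 0, 0.5, 0, 0, 0, 0)      # P(break) = 0.5
  specP <- sceneSpec(nRotatedDist = d, tiltAlignedSd = 0, aCenterJitterSd = 0.5,
                     seed = 1234L)
  specC <- sceneSpec(seed = 1234L)
  co <- generateCohort(specP, specC, nPatientsPerArm = 2L,
                       sectionsPerPatient = 10L)
  expect_length(co$patients, 4L)
  expect_identical(vapply(co$patients, `[[`, character(1), "group"),
                   c("PCD", "PCD", "control", "control"))
  for (p in co$patients) {
    expect_length(p$sections, 10L)
    expect_equal(p$true_aa,
                 100 * mean(vapply(p$truths, `[[`, logical(1), "symmetry_break")))
    expect_true(p$summary$aa_pct >= 0 && p$summary$aa_pct <= 100)
  }
})

test_that("cohort datasets round-trip through disk", {
  dir <- withr::local_tempdir()
  specP <- wellSeparatedSpec(5L, seed = 55L)
  specC <- wellSeparatedSpec(0L, seed = 56L)
  co <- generateCohort(specP, specC, nPatientsPerArm = 1L,
                       sectionsPerPatient = 3L, outDir = dir)
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_identical(man$n_patients_per_arm, 1L)
  p1 <- co$patients[[1]]
  back <- readSectionCoords(file.path(dir, p1$id, "doublets.csv"),
                            file.path(dir, p1$id, "sections.csv"))
  expect_length(back, 3L)
  expect_equal(doublets(back[[1]])$ax, doublets(p1$sections[[1]])$ax)
  expect_identical(sectionId(back[[2]]), sectionId(p1$sections[[2]]))
})
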