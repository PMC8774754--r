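test_that("a blank image yields an empty candidate list, not an error", {
  expect_identical(nrow(detectTubules(matrix(0.85, 128, 128))), 0L)
  expect_identical(nrow(detectTubules(matrix(0, 128, 128))), 0L)
})

test_that("noiseless detection localizes all 20 tubules within 2 px", {
  spec <- cleanSpec(4L, seed = 31L)
  g <- generateSections(spec)
  tr <- g$truths[[1]]
  img <- renderSectionImage(g$sections[[1]], spec, cpCenters = tr$cp_centers)
  cand <- detectTubules(img)
  o <- attr(img, "origin")[1]
  truthPts <- rbind(tr$a_centers, tr$b_centers, tr$cp_centers) + o
  expect_gte(nrow(cand), 20L)
  best <- cand[seq_len(20L), ]
  err <- vapply(seq_len(nrow(truthPts)), function(i)
    min(sqrt((best$x - truthPts[i, 1])^2 + (best$y - truthPts[i, 2])^2)),
    numeric(1))
  expect_lt(max(err), 2)
})

test_that("assembly recovers 9 doublets with correct A/B orientation", {
  spec <- cleanSpec(2L, seed = 37L)
  g <- generateSections(spec)
  tr <- g$truths[[1]]
  img <- renderSectionImage(g$sections[[1]], spec, cpCenters = tr$cp_centers)
  sec <- assembleSection(detectTubules(img), sectionId = "det", img = img)
  expect_s4_class(sec, "CrossSection")
  d <- doublets(sec)
  expect_identical(nrow(d), 9L)
  expect_false(isDisorganized(sec))
  expect_identical(centralPairCount(sec), 2L)
  o <- attr(img, "origin")[1]
  for (i in 1:9) {
    ## the detected A of the doublet nearest this truth A must be the A
    da <- sqrt((d$ax - tr$a_centers[i, 1] - o)^2 +
                 (d$ay - tr$a_centers[i, 2] - o)^2)
    j <- which.min(da)
    expect_lt(da[j], 2.5)
    expect_lt(sqrt((d$bx[j] - tr$b_centers[i, 1] - o)^2 +
                     (d$by[j] - tr$b_centers[i, 2] - o)^2), 3.5)
  }
})

test_that("a missing central pair propagates to a central-complex defect", {
  spec <- cleanSpec(0L, seed = 41L, pCentralDefect = 1)
  g <- generateSections(spec)
  img <- renderSectionImage(g$sections[[1]], spec)
  res <- analyzeImage(img)
  expect_identical(centralPairCount(res$section), 0L)
  expect_true(res$defects$central_defect)
})

test_that("too sparse a candidate set yields a not-assessable section", {
  few <- data.frame(x = c(40, 90), y = c(40, 90), radius = 12,
                    completeness = 1, contrast = 0.5)
  sec <- assembleSection(few)
  expect_identical(nrow(doublets(sec)), 0L)
  expect_match(sec@notes, "not_assessable")
  ## and the downstream count is NA with a status, not an error
  expect_true(is.na(countRotated(sec)))
})

test_that("noiseless image analysis reproduces the generated break truth", {
  for (k in c(0L, 5L)) {
    spec <- cleanSpec(k, seed = 47L + k)
    g <- generateSections(spec)
    tr <- g$truths[[1]]
    img <- renderSectionImage(g$sections[[1]], spec, cpCenters = tr$cp_centers)
    res <- analyzeImage(img)
    expect_identical(res$report$n_rotated, k)
    expect_identical(res$report$symmetry_break, k >= 4L)
  }
})

test_that("break calls are invariant under image rotation and flip", {
  spec <- wellSeparatedSpec(5L, n = 1L, seed = 53L)
  g <- generateSections(spec)
  tr <- g$truths[[1]]
  img <- renderSectionImage(g$sections[[1]], spec, cpCenters = tr$cp_centers,
                            noiseSeed = 7L)
  base <- analyzeImage(img)$report
  rot90 <- t(img)[, seq_len(nrow(img))[order(-seq_len(nrow(img)))], drop = FALSE]
  rot90 <- t(img)[, rev(seq_len(nrow(img))), drop = FALSE]
  flip <- img[rev(seq_len(nrow(img))), , drop = FALSE]
  for (m in list(rot90, flip)) {
    rep <- analyzeImage(m)$report
    expect_identical(rep$n_rotated, base$n_rotated)
    expect_identical(rep$symmetry_break, base$symmetry_break)
  }
})

test_that("detection configuration round-trips through YAML", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(pixelSizeNm = 4, kappa = 0.6), tmp)
  cfg <- readDetectionConfig(tmp)
  expect_equal(cfg$rA, 6)          # radii scale with pixel size
  expect_equal(cfg$kappa, 0.6)
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(bogusField = 1), bad)
  expect_error(readDetectionConfig(bad), class = "axosymConfigError")
})
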