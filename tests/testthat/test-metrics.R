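toyPred <- matrix(c(1L, 1L, 1L, 0L), 2, 2)   # fg at (1,1), (2,1), (1,2)
toyTrue <- matrix(c(0L, 1L, 1L, 1L), 2, 2)   # fg at (2,1), (1,2), (2,2)

test_that("confusion counts match hand counting on the 2x2 toy", {
  cc <- confusionCounts(toyPred, toyTrue, 1L)
  expect_identical(cc, c(tp = 2L, tn = 0L, fp = 1L, fn = 1L))
  expect_identical(sum(cc), 4L)

  perfect <- confusionCounts(toyTrue, toyTrue, 1L)
  expect_identical(perfect[["fp"]], 0L)
  expect_identical(perfect[["fn"]], 0L)

  compl <- confusionCounts(1L - toyTrue, toyTrue, 1L)
  expect_identical(compl[["tp"]], 0L)
  expect_identical(compl[["tn"]], 0L)

  expect_error(confusionCounts(toyPred, matrix(0L, 3, 3), 1L), "shape")
})

test_that("confusion metrics reproduce the toy values and identities", {
  cc <- confusionCounts(toyPred, toyTrue, 1L)
  expect_equal(dscScore(cc), 2 / 3)
  expect_equal(recallScore(cc), 2 / 3)
  expect_equal(precisionScore(cc), 2 / 3)
  expect_equal(accScore(cc), 0.5)
  expect_equal(jaccardScore(cc), 0.5)
  # DSC = 2 JC / (1 + JC)
  expect_equal(dscScore(cc), 2 * jaccardScore(cc) / (1 + jaccardScore(cc)))

  perfect <- c(tp = 10L, tn = 6L, fp = 0L, fn = 0L)
  for (f in list(dscScore, recallScore, precisionScore, accScore,
                 jaccardScore))
    expect_equal(f(perfect), 1)

  # zero-overlap and empty-denominator conventions
  expect_equal(dscScore(c(tp = 0L, tn = 0L, fp = 2L, fn = 3L)), 0)
  expect_equal(dscScore(c(tp = 0L, tn = 5L, fp = 0L, fn = 0L)), 1)
  expect_equal(recallScore(c(tp = 0L, tn = 5L, fp = 1L, fn = 0L)), 1)
})

test_that("DSC = 2JC/(1+JC) holds across random confusion counts", {
  set.seed(2)
  for (i in 1:50) {
    cc <- setNames(as.integer(rmultinom(1, 400, rep(0.25, 4))),
                   c("tp", "tn", "fp", "fn"))
    if (2 * cc[["tp"]] + cc[["fp"]] + cc[["fn"]] == 0) next
    jc <- jaccardScore(cc)
    expect_equal(dscScore(cc), 2 * jc / (1 + jc), tolerance = 1e-12)
    expect_true(dscScore(cc) >= 0 && dscScore(cc) <= 1)
  }
})

test_that("contour extraction finds boundary pixels", {
  m <- matrix(0L, 6, 6)
  m[3, 3] <- 1L
  ct <- extractContour(m, 1L)
  expect_identical(nrow(ct), 1L)
  expect_equal(unname(ct[1, ]), c(3, 3))

  sq <- matrix(0L, 8, 8)
  sq[3:6, 3:6] <- 1L
  ct <- extractContour(sq, 1L)
  expect_identical(nrow(ct), 12L)         # 4x4 square: 12 perimeter pixels
  inner <- ct[, 1] %in% 4:5 & ct[, 2] %in% 4:5
  expect_false(any(inner))

  expect_identical(nrow(extractContour(m, 3L)), 0L)

  # pixels on the image edge belong to the contour
  full <- matrix(1L, 4, 4)
  expect_identical(nrow(extractContour(full, 1L)), 12L)
})

test_that("Hausdorff and MAD match closed-form toy cases", {
  a <- matrix(c(0, 0), 1)
  b <- matrix(c(3, 4), 1)
  expect_equal(hausdorffDistance(a, b, spacing = 1), 5)
  expect_equal(hausdorffDistance(a, a, spacing = 1), 0)
  expect_equal(meanAbsDistance(a, b, spacing = 1), 5)
  # spacing scales distances
  expect_equal(hausdorffDistance(a, b, spacing = 2), 10)

  # identical square contours offset by (3, 0)
  sq <- matrix(0L, 20, 20)
  sq[5:8, 5:8] <- 1L
  sh <- matrix(0L, 20, 20)
  sh[8:11, 5:8] <- 1L
  ca <- extractContour(sq, 1L)
  cb <- extractContour(sh, 1L)
  expect_equal(hausdorffDistance(ca, cb), 3)
  expect_equal(meanAbsDistance(cb, ca), bruteMAD(cb, ca))

  # symmetry and translation invariance
  expect_equal(hausdorffDistance(ca, cb), hausdorffDistance(cb, ca))
  shift <- cbind(ca[, 1] + 7, ca[, 2] + 2)
  shiftB <- cbind(cb[, 1] + 7, cb[, 2] + 2)
  expect_equal(hausdorffDistance(shift, shiftB, spacing = 1),
               hausdorffDistance(ca, cb, spacing = 1))
  expect_equal(meanAbsDistance(shift, shiftB, spacing = 1),
               meanAbsDistance(ca, cb, spacing = 1))
})

test_that("distance metrics agree with brute force and MAD <= HD", {
  set.seed(9)
  for (i in 1:30) {
    n <- sample(8:32, 1)
    m1 <- matrix(as.integer(matrix(runif(n * n), n, n) > 0.6), n, n)
    m2 <- matrix(as.integer(matrix(runif(n * n), n, n) > 0.6), n, n)
    a <- extractContour(m1, 1L)
    b <- extractContour(m2, 1L)
    if (nrow(a) == 0 || nrow(b) == 0) next
    hd <- hausdorffDistance(a, b)
    expect_equal(hd, bruteHausdorff(a, b), tolerance = 1e-9)
    mad <- meanAbsDistance(a, b)
    expect_equal(mad, bruteMAD(a, b), tolerance = 1e-9)
    expect_lte(mad, hd + 1e-12)
    madSym <- meanAbsDistance(a, b, symmetric = TRUE)
    expect_equal(madSym, (bruteMAD(a, b) + bruteMAD(b, a)) / 2,
                 tolerance = 1e-9)
    expect_lte(madSym, hd + 1e-12)
  }
})

test_that("empty-contour conventions: 0 for both empty, NA for one empty", {
  e <- extractContour(matrix(0L, 4, 4), 1L)
  a <- matrix(c(1, 1), 1)
  expect_identical(hausdorffDistance(e, e), 0)
  expect_identical(meanAbsDistance(e, e), 0)
  expect_warning(expect_true(is.na(hausdorffDistance(a, e))), "empty")
  expect_warning(expect_true(is.na(meanAbsDistance(e, a))), "empty")
})

test_that("evaluateSegmentation reports all seven metrics per class", {
  s <- generatePhantom(phantomSpec(noiseSigma = 0, biasFieldAmplitude = 0),
                       seed = 5)
  m <- sampleMask(s)
  r <- evaluateSegmentation(m, m, spacing = 1.5)
  expect_identical(r$class, c("1", "2", "3", "macro"))
  expect_equal(r$dsc, rep(1, 4))
  expect_equal(r$recall, rep(1, 4))
  expect_equal(r$acc, rep(1, 4))
  expect_equal(r$precision, rep(1, 4))
  expect_equal(r$jc, rep(1, 4))
  expect_equal(r$hd, rep(0, 4))
  expect_equal(r$mad, rep(0, 4))

  # toy case embeds into the per-class report
  r2 <- evaluateSegmentation(toyPred, toyTrue, numClasses = 2L)
  expect_equal(r2$dsc[1], 2 / 3)
  expect_equal(r2$jc[1], 0.5)

  # all-background prediction: zero overlap, NA distances for present class
  pred <- matrix(0L, nrow(m), ncol(m))
  r3 <- suppressWarnings(evaluateSegmentation(pred, m))
  expect_equal(r3$dsc[1:3], rep(0, 3))
  expect_true(all(is.na(r3$hd[1:3])))
})
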