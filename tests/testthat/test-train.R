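# Small, fast configurations: 32x32 phantoms, depth-2 network.
smallConfig <- function(seed = 1L, epochs = 1L, ...) {
  experimentConfig(
    network = networkConfig(depth = 2L, baseChannels = 4L,
                            attentionPoolThreshold = 64L),
    phantom = phantomSpec(imageSize = 32L),
    nTrain = 8L, nTest = 4L, epochs = epochs, seed = seed, ...)
}

test_that("one training epoch runs, logs finite losses and checkpoints", {
  ckpt <- tempfile(fileext = ".rds")
  fit <- trainModel(smallConfig(seed = 2), checkpointPath = ckpt)
  expect_s4_class(fit$model, "CASNetModel")
  expect_identical(nrow(fit$log), 1L)
  expect_true(all(is.finite(fit$log$trainLoss)))
  expect_true(all(is.finite(fit$log$valLoss)))
  expect_true(file.exists(ckpt))
  unlink(ckpt)
})

test_that("training is deterministic in the experiment seed", {
  a <- trainModel(smallConfig(seed = 5))
  b <- trainModel(smallConfig(seed = 5))
  expect_equal(a$log$trainLoss[1], b$log$trainLoss[1], tolerance = 1e-6)
  expect_identical(a$model@params, b$model@params)
  c <- trainModel(smallConfig(seed = 6))
  expect_false(isTRUE(all.equal(a$log$trainLoss[1], c$log$trainLoss[1],
                                tolerance = 1e-9)))
})

test_that("the learning rate halves after a validation plateau", {
  # synthetic plateau: a frozen validation loss must halve the rate after
  # more than `patience` epochs, and an improving one must not
  sched <- list(lr = 1e-4, best = Inf, since = 0L)
  flat <- rep(0.42, 25)
  lrs <- numeric(length(flat))
  for (e in seq_along(flat)) {
    sched <- casnet:::schedulerStep(sched, flat[e], patience = 10L)
    lrs[e] <- sched$lr
  }
  expect_equal(lrs[11], 1e-4)       # within patience: unchanged
  expect_equal(lrs[12], 5e-5)       # plateau exceeded patience: halved
  expect_equal(lrs[23], 2.5e-5)     # halves again after the next plateau
  # an improving sequence never triggers
  sched <- list(lr = 1e-4, best = Inf, since = 0L)
  for (v in seq(1, 0.5, length.out = 20))
    sched <- casnet:::schedulerStep(sched, v, patience = 3L)
  expect_equal(sched$lr, 1e-4)
  # the training log records the rate per epoch and it never increases
  fit <- trainModel(smallConfig(seed = 3, epochs = 2, lrPatience = 0L))
  expect_true(all(diff(fit$log$lr) <= 0))
})

test_that("checkpoints round-trip to bit-identical predictions", {
  fit <- trainModel(smallConfig(seed = 7))
  imgs <- lapply(generateDataset(phantomSpec(imageSize = 32L), 3, seed = 9),
                 sampleImage)
  before <- predictMasks(fit$model, imgs)
  p <- tempfile(fileext = ".rds")
  saveCheckpoint(fit$model, p)
  loaded <- loadCheckpoint(p)
  expect_identical(loaded@params, fit$model@params)
  after <- predictMasks(loaded, imgs)
  expect_identical(before, after)
  unlink(p)
})

test_that("predictions are valid label masks in preserved order", {
  m <- initCASNet(networkConfig(depth = 2, baseChannels = 4), seed = 1)
  imgs <- list(matrix(0.5, 32, 32), matrix(runif(1024), 32, 32))
  masks <- predictMasks(m, imgs)
  expect_length(masks, 2)
  for (mk in masks) {
    expect_identical(dim(mk), c(32L, 32L))
    expect_true(all(mk %in% 0:3))
  }
  # same input twice gives identical masks; constant image does not crash
  expect_identical(predictMasks(m, imgs[[1]]), masks[[1]])
  # batch order preserved: singleton calls match the batched call
  expect_identical(predictMasks(m, imgs[[2]]), masks[[2]])
})

test_that("training diverges loudly on non-finite losses", {
  cfg <- smallConfig(seed = 4, epochs = 3L, learningRate = 1e20)
  expect_error(trainModel(cfg), "diverged|finite")
})

test_that("the ablation grid covers all eight variants", {
  g <- casnet:::ablationGrid()
  expect_identical(nrow(g), 8L)
  expect_identical(nrow(unique(g)), 8L)
  expect_false(any(g[1, c("mscb", "casc", "curv")] == TRUE))
  expect_true(all(g[8, c("mscb", "casc", "curv")] == TRUE))
})

test_that("runAblation reports finite metrics for every variant", {
  tab <- suppressWarnings(runAblation(smallConfig(seed = 8)))
  expect_identical(nrow(tab), 8L)
  expect_true(all(c("dsc", "recall", "acc", "precision", "jc", "hd", "mad")
                  %in% names(tab)))
  expect_true(all(is.finite(tab$dsc)))
  expect_true(all(tab$dsc >= 0 & tab$dsc <= 1))
  expect_true(all(is.finite(tab$hd) | is.na(tab$hd)))
  # the CSV side-channel mirrors the table
  f <- tempfile(fileext = ".csv")
  tab2 <- suppressWarnings(runAblation(smallConfig(seed = 8),
                                       variants = casnet:::ablationGrid()[1, ],
                                       outCsv = f))
  expect_true(file.exists(f))
  expect_equal(utils::read.csv(f)$dsc, tab2$dsc, tolerance = 1e-12)
  unlink(f)
})
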