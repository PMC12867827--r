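# Training harness: Adam optimisation of the composite loss with
# validation-based learning-rate halving and best-checkpoint selection.
# Everything random (phantom split, weight initialisation, shuffling,
# augmentation) derives from the experiment's master seed.

batchArrays <- function(samples, idx) {
  H <- nrow(samples[[1]]@image)
  W <- ncol(samples[[1]]@image)
  n <- length(idx)
  x <- array(0, dim = c(H, W, 1L, n))
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    s <- samples[[idx[i]]]
    x[, , 1L, i] <- s@image
    masks[[i]] <- s@mask
  }
  list(x = x, masks = masks)
}

batchLossAndGrad <- function(prob, masks, weights, wantGrad = TRUE) {
  d <- dim(prob)
  n <- d[4]
  total <- 0
  dprob <- if (wantGrad) array(0, dim = d) else NULL
  for (i in seq_len(n)) {
    p <- prob[, , , i]
    dim(p) <- d[1:3]
    total <- total + compositeLoss(p, masks[[i]], weights)
    if (wantGrad) {
      g <- compositeLossGrad(p, masks[[i]], weights) / n
      dprob[, , , i] <- g
    }
  }
  list(loss = total / n, dprob = dprob)
}

evalLoss <- function(params, state, netcfg, samples, weights, batchSize) {
  n <- length(samples)
  total <- 0
  for (start in seq(1, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1, n)
    b <- batchArrays(samples, idx)
    out <- casnetFwd(params, state, netcfg, b$x, train = FALSE,
                     keepCache = FALSE)
    total <- total + batchLossAndGrad(out$prob, b$masks, weights,
                                      wantGrad = FALSE)$loss * length(idx)
  }
  total / n
}

# Validation-plateau learning-rate schedule: halve the rate after more than
# `patience` epochs without the validation loss improving on its best value
# by at least `tol`.
schedulerStep <- function(sched, valLoss, patience, tol = 1e-5) {
  if (valLoss < sched$best - tol) {
    sched$best <- valLoss
    sched$since <- 0L
  } else {
    sched$since <- sched$since + 1L
    if (sched$since > patience) {
      sched$lr <- sched$lr / 2
      sched$since <- 0L
    }
  }
  sched
}

#' Train a CASNet model
#'
#' Runs Adam on the composite loss over the configured data source. A
#' held-out validation subset of the training data drives the learning-rate
#' schedule (halving after \code{lrPatience} epochs without improvement)
#' and best-checkpoint selection (lowest validation composite loss). The
#' whole run is deterministic given \code{config@seed}: the phantom split,
#' the weight initialisation and every augmentation draw derive from it.
#'
#' @param config an [ExperimentConfig-class].
#' @param checkpointPath optional path; when given, the best model is saved
#'   there with [saveCheckpoint()].
#' @param verbose print a per-epoch line to stderr.
#' @return A list with elements \code{model} (the best-validation
#'   [CASNetModel-class]) and \code{log} (data.frame with columns
#'   \code{epoch, trainLoss, valLoss, lr}).
#' @export
trainModel <- function(config, checkpointPath = NULL, verbose = FALSE) {
  validObject(config)
  sd <- childSeeds(config@seed, 3L)
  if (nzchar(config@manifest)) {
    manifest <- loadManifest(config@manifest)
    allTrain <- loadSamplesFromManifest(manifest, split = "train")
  } else {
    allTrain <- generateDataset(config@phantom, config@nTrain, sd[1])
  }
  nVal <- max(1L, round(config@valFraction * length(allTrain)))
  valIdx <- withSeed(sd[1], sample(length(allTrain), nVal))
  valSamples <- allTrain[valIdx]
  trainSamples <- allTrain[-valIdx]
  model <- initCASNet(config@network, sd[2])
  params <- model@params
  state <- model@state
  opt <- adamInit(params)
  lr <- config@learningRate
  weights <- config@loss
  netcfg <- config@network
  best <- list(val = Inf, params = params, state = state)
  sched <- list(lr = lr, best = Inf, since = 0L)
  log <- vector("list", config@epochs)
  withSeed(sd[3], {
    for (epoch in seq_len(config@epochs)) {
      ord <- sample(length(trainSamples))
      epochLoss <- 0
      nSeen <- 0L
      for (start in seq(1, length(ord), by = config@batchSize)) {
        idx <- ord[start:min(start + config@batchSize - 1, length(ord))]
        sams <- trainSamples[idx]
        if (config@augment)
          sams <- lapply(sams, function(s)
            augmentSample(s, seed = sample.int(.Machine$integer.max - 1L, 1)))
        b <- batchArrays(sams, seq_along(sams))
        out <- casnetFwd(params, state, netcfg, b$x, train = TRUE)
        state <- out$state
        lg <- batchLossAndGrad(out$prob, b$masks, weights)
        if (!is.finite(lg$loss))
          stop(sprintf("training diverged at epoch %d (loss = %g)",
                       epoch, lg$loss), call. = FALSE)
        grads <- casnetBwd(params, netcfg, out$cache, lg$dprob)
        stepped <- adamStep(params, grads, opt, lr, config@betas)
        params <- stepped$params
        opt <- stepped$opt
        epochLoss <- epochLoss + lg$loss * length(idx)
        nSeen <- nSeen + length(idx)
      }
      trainLoss <- epochLoss / nSeen
      valLoss <- evalLoss(params, state, netcfg, valSamples, weights,
                          config@batchSize)
      if (!is.finite(valLoss))
        stop(sprintf("training diverged at epoch %d (validation loss = %g)",
                     epoch, valLoss), call. = FALSE)
      if (valLoss < best$val) {
        best <- list(val = valLoss, params = params, state = state)
      }
      sched <- schedulerStep(sched, valLoss, config@lrPatience)
      lr <- sched$lr
      log[[epoch]] <- data.frame(epoch = epoch, trainLoss = trainLoss,
                                 valLoss = valLoss, lr = lr)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2g",
                        epoch, trainLoss, valLoss, lr))
    }
  })
  outModel <- new("CASNetModel", config = netcfg, params = best$params,
                  state = best$state, seed = model@seed)
  if (!is.null(checkpointPath)) saveCheckpoint(outModel, checkpointPath)
  list(model = outModel, log = do.call(rbind, log))
}

#' Predict label masks
#'
#' Evaluation-mode forward pass followed by per-pixel argmax over classes.
#' Batch order is preserved.
#'
#' @param model a [CASNetModel-class].
#' @param images a single matrix, a list of matrices, or a list of
#'   [CardiacSample-class] objects.
#' @param batchSize forward batch size.
#' @return For a single matrix an integer label matrix; otherwise a list of
#'   label matrices.
#' @export
predictMasks <- function(model, images, batchSize = 8L) {
  single <- is.matrix(images)
  if (single) images <- list(images)
  mats <- lapply(images, function(im)
    if (is(im, "CardiacSample")) im@image else im)
  H <- nrow(mats[[1]]); W <- ncol(mats[[1]])
  K <- model@config@numClasses
  out <- vector("list", length(mats))
  for (start in seq(1, length(mats), by = batchSize)) {
    idx <- start:min(start + batchSize - 1, length(mats))
    x <- array(0, dim = c(H, W, 1L, length(idx)))
    for (i in seq_along(idx)) x[, , 1L, i] <- mats[[idx[i]]]
    prob <- casnetFwd(model@params, model@state, model@config, x,
                      train = FALSE, keepCache = FALSE)$prob
    for (i in seq_along(idx)) {
      pm <- prob[, , , i]
      dim(pm) <- c(H * W, K)
      out[[idx[i]]] <- matrix(max.col(pm, ties.method = "first") - 1L, H, W)
    }
  }
  if (single) out[[1]] else out
}

#' Save / load model checkpoints
#'
#' Checkpoints embed the architecture configuration alongside the
#' parameters and batch-norm state, so a loaded model predicts bit-
#' identically to the model that was saved.
#'
#' @param model a [CASNetModel-class].
#' @param path checkpoint file path.
#' @return \code{loadCheckpoint} returns the [CASNetModel-class].
#' @export
saveCheckpoint <- function(model, path) {
  cfg <- model@config
  saveRDS(list(
    config = list(depth = cfg@depth, baseChannels = cfg@baseChannels,
                  numClasses = cfg@numClasses, useMSCB = cfg@useMSCB,
                  useCASC = cfg@useCASC,
                  attentionPoolThreshold = cfg@attentionPoolThreshold),
    params = model@params, state = model@state, seed = model@seed), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  cfg <- do.call(networkConfig, x$config)
  new("CASNetModel", config = cfg, params = x$params, state = x$state,
      seed = as.integer(x$seed))
}
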