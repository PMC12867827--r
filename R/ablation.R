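# Ablation runner: trains on/off combinations of (MSCB, CASC, curvature
# loss) on the same phantom split and reports the seven test-set metrics
# per variant.

ablationGrid <- function() {
  data.frame(
    mscb = c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE),
    casc = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
    curv = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE)
  )
}

# Mean macro-averaged metrics of a model over a list of test samples.
testMetrics <- function(model, testSamples) {
  preds <- predictMasks(model, testSamples)
  rows <- lapply(seq_along(preds), function(i) {
    r <- suppressWarnings(
      evaluateSegmentation(preds[[i]], testSamples[[i]]@mask,
                           spacing = testSamples[[i]]@spacing,
                           numClasses = model@config@numClasses))
    r[r$class == "macro", -1]
  })
  agg <- do.call(rbind, rows)
  colMeans(agg, na.rm = TRUE)
}

#' Run the component ablation study
#'
#' Trains every requested on/off combination of the three contributions
#' (MSCB, CASC, curvature loss term) under identical conditions: the same
#' phantom train/test split, the same initialisation seed and the same
#' schedule. A variant with the curvature term off sets its loss weight to
#' zero, leaving the BCE and Dice weights unchanged. Metrics are the
#' macro averages over foreground classes, averaged over the test set.
#'
#' @param config an [ExperimentConfig-class] used as the base for every
#'   variant (its \code{nTrain}, \code{nTest} and \code{seed} control the
#'   shared split).
#' @param variants data.frame with logical columns \code{mscb, casc, curv};
#'   defaults to all 8 combinations in the conventional order (baseline
#'   first, full model last).
#' @param outCsv optional path; when given the table is also written as CSV
#'   with columns mscb, casc, curv, dsc, recall, acc, precision, jc, hd,
#'   mad.
#' @param verbose print progress to stderr.
#' @return A data.frame with one row per variant: the three switches plus
#'   the seven metrics.
#' @export
runAblation <- function(config, variants = ablationGrid(), outCsv = NULL,
                        verbose = FALSE) {
  validObject(config)
  sd <- childSeeds(config@seed, 2L)
  testSamples <- generateDataset(config@phantom, config@nTest, sd[2])
  rows <- vector("list", nrow(variants))
  for (v in seq_len(nrow(variants))) {
    cfg <- config
    cfg@network@useMSCB <- isTRUE(variants$mscb[v])
    cfg@network@useCASC <- isTRUE(variants$casc[v])
    if (!isTRUE(variants$curv[v]))
      cfg@loss <- lossWeights(config@loss@bce, config@loss@dice, 0)
    if (verbose)
      message(sprintf("ablation variant %d/%d: MSCB=%s CASC=%s curv=%s",
                      v, nrow(variants), variants$mscb[v], variants$casc[v],
                      variants$curv[v]))
    fit <- trainModel(cfg, verbose = verbose)
    m <- testMetrics(fit$model, testSamples)
    rows[[v]] <- cbind(variants[v, , drop = FALSE], as.data.frame(t(m)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(outCsv)) utils::write.csv(out, outCsv, row.names = FALSE)
  out
}
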