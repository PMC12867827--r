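#' Create a phantom specification
#'
#' Defaults describe a 64 x 64 short-axis slice with realistic MRI-like
#' contrast: background 0.20, RV blood pool 0.50, myocardium 0.35, LV blood
#' pool 0.80, additive noise sigma 0.1 and a smooth bias field of amplitude
#' 0.3. Geometric defaults scale linearly with \code{imageSize}.
#'
#' @param imageSize pixels per side (square), >= 32.
#' @param lvRadiusRange (min, max) LV mean radius in pixels.
#' @param myoThicknessRange (min, max) myocardial ring thickness in pixels.
#' @param rvAngularExtent angular width of the RV crescent in radians.
#' @param rotationRange (min, max) in-plane rotation in radians.
#' @param noiseSigma additive Gaussian noise sd on the [0, 1] scale.
#' @param biasFieldAmplitude peak-to-peak bias field amplitude.
#' @param classIntensities named numeric(4): background, RV, MYO, LV mean
#'   intensities, pairwise at least 0.1 apart.
#' @return A [PhantomSpec-class] object.
#' @examples
#' spec <- phantomSpec(imageSize = 64)
#' s <- generatePhantom(spec, seed = 1)
#' table(sampleMask(s))
#' @export
phantomSpec <- function(imageSize = 64L,
                        lvRadiusRange = imageSize * c(0.125, 0.22),
                        myoThicknessRange = imageSize * c(0.05, 0.09),
                        rvAngularExtent = 2.0,
                        rotationRange = c(0, 2 * pi),
                        noiseSigma = 0.1,
                        biasFieldAmplitude = 0.3,
                        classIntensities = c(background = 0.20, RV = 0.50,
                                             MYO = 0.35, LV = 0.80)) {
  new("PhantomSpec",
      imageSize = as.integer(imageSize),
      lvRadiusRange = as.numeric(lvRadiusRange),
      myoThicknessRange = as.numeric(myoThicknessRange),
      rvAngularExtent = as.numeric(rvAngularExtent),
      rotationRange = as.numeric(rotationRange),
      noiseSigma = as.numeric(noiseSigma),
      biasFieldAmplitude = as.numeric(biasFieldAmplitude),
      classIntensities = classIntensities)
}

#' Create a network configuration
#'
#' @param depth number of resolution levels (>= 2); default 4 at full scale,
#'   use 3 for 64 x 64 desk-scale experiments.
#' @param baseChannels channels at the first level, doubled per level.
#' @param numClasses number of output classes.
#' @param useMSCB enable the multi-scale context block at the bottleneck.
#' @param useCASC enable cross-attentive skip connections.
#' @param attentionPoolThreshold max key/value positions attended without
#'   average pooling (queries always stay at full resolution).
#' @return A [NetworkConfig-class] object.
#' @export
networkConfig <- function(depth = 4L, baseChannels = 32L, numClasses = 4L,
                          useMSCB = TRUE, useCASC = TRUE,
                          attentionPoolThreshold = 1024L) {
  new("NetworkConfig",
      depth = as.integer(depth), baseChannels = as.integer(baseChannels),
      numClasses = as.integer(numClasses),
      useMSCB = isTRUE(useMSCB), useCASC = isTRUE(useCASC),
      attentionPoolThreshold = as.integer(attentionPoolThreshold))
}

#' Create composite-loss weights
#'
#' @param bce,dice,curvature nonnegative term weights; defaults
#'   (0.5, 0.4, 0.1).
#' @return A [LossWeights-class] object.
#' @export
lossWeights <- function(bce = 0.5, dice = 0.4, curvature = 0.1) {
  new("LossWeights", bce = as.numeric(bce), dice = as.numeric(dice),
      curvature = as.numeric(curvature))
}

#' Create an experiment configuration
#'
#' Defaults are the desk-scale setup: 64 x 64 phantoms, a depth-3 network
#' with 16 base channels, 15 epochs, 128 training and 64 test phantoms,
#' Adam at learning rate 1e-4 with betas (0.9, 0.999), batch size 8, and
#' learning-rate halving after a 10-epoch validation plateau. Larger
#' configurations (e.g. 256 x 256 inputs, depth 4, 32 base channels, 150
#' epochs) are reachable by argument.
#'
#' @param network a [NetworkConfig-class].
#' @param loss a [LossWeights-class].
#' @param learningRate initial Adam learning rate.
#' @param betas Adam moment decay rates.
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param lrPatience epochs of validation-loss plateau before halving.
#' @param valFraction held-out fraction of the training set.
#' @param augment apply random augmentation to training samples.
#' @param phantom a [PhantomSpec-class]; data source when manifest is "".
#' @param manifest path to a dataset manifest JSON, or "" for phantoms.
#' @param nTrain,nTest phantom counts for the train and test sets.
#' @param seed master seed for the whole run.
#' @return An [ExperimentConfig-class] object.
#' @export
experimentConfig <- function(network = networkConfig(depth = 3L,
                                                     baseChannels = 16L,
                                                     attentionPoolThreshold = 64L),
                             loss = lossWeights(),
                             learningRate = 1e-4,
                             betas = c(0.9, 0.999),
                             epochs = 15L,
                             batchSize = 8L,
                             lrPatience = 10L,
                             valFraction = 0.125,
                             augment = TRUE,
                             phantom = phantomSpec(),
                             manifest = "",
                             nTrain = 128L,
                             nTest = 64L,
                             seed = 1L) {
  new("ExperimentConfig",
      network = network, loss = loss,
      learningRate = as.numeric(learningRate), betas = as.numeric(betas),
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      lrPatience = as.integer(lrPatience),
      valFraction = as.numeric(valFraction), augment = isTRUE(augment),
      phantom = phantom, manifest = as.character(manifest),
      nTrain = as.integer(nTrain), nTest = as.integer(nTest),
      seed = as.integer(seed))
}

#' @describeIn CardiacSample-class construct a sample from image and mask.
#' @param image numeric matrix in [0, 1].
#' @param mask integer matrix of labels 0..3.
#' @param spacing pixel spacing in mm.
#' @param geometry optional generator geometry list.
#' @export
cardiacSample <- function(image, mask, spacing = 1.0, geometry = list()) {
  storage.mode(mask) <- "integer"
  new("CardiacSample", image = image, mask = mask,
      spacing = as.numeric(spacing), geometry = geometry)
}

# ---- accessors ----

#' @rdname CardiacSample-class
#' @param x a CardiacSample.
#' @export
sampleImage <- function(x) x@image

#' @rdname CardiacSample-class
#' @export
sampleMask <- function(x) x@mask

#' @rdname CardiacSample-class
#' @export
pixelSpacing <- function(x) x@spacing

#' @rdname CASNetModel-class
#' @param x a CASNetModel.
#' @export
netConfig <- function(x) x@config

#' @rdname CASNetModel-class
#' @export
modelParams <- function(x) x@params

#' @rdname DatasetManifest-class
#' @param x a DatasetManifest.
#' @export
manifestItems <- function(x) x@items

#' @rdname DatasetManifest-class
#' @export
classTable <- function(x) x@classes

# ---- show methods ----

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d px, LV radius [%.1f, %.1f] px, MYO [%.1f, %.1f] px\n",
              object@imageSize, object@imageSize,
              object@lvRadiusRange[1], object@lvRadiusRange[2],
              object@myoThicknessRange[1], object@myoThicknessRange[2]))
  cat(sprintf("  noise sd %.3f, bias amplitude %.3f, intensities: %s\n",
              object@noiseSigma, object@biasFieldAmplitude,
              paste(sprintf("%s=%.2f", names(object@classIntensities),
                            object@classIntensities), collapse = ", ")))
})

setMethod("show", "CardiacSample", function(object) {
  tab <- table(factor(object@mask, levels = 0:3,
                      labels = c("background", "RV", "MYO", "LV")))
  cat(sprintf("CardiacSample: %d x %d px, spacing %.2f mm\n",
              nrow(object@image), ncol(object@image), object@spacing))
  cat("  pixels:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
      "\n")
})

setMethod("show", "NetworkConfig", function(object) {
  cat(sprintf("NetworkConfig: depth %d, base %d channels, %d classes, MSCB %s, CASC %s\n",
              object@depth, object@baseChannels, object@numClasses,
              if (object@useMSCB) "on" else "off",
              if (object@useCASC) "on" else "off"))
})

setMethod("show", "LossWeights", function(object) {
  cat(sprintf("LossWeights: bce %.3g, dice %.3g, curvature %.3g\n",
              object@bce, object@dice, object@curvature))
})

setMethod("show", "CASNetModel", function(object) {
  show(object@config)
  cat(sprintf("  %d trainable parameters (seed %d)\n",
              parameterCount(object), object@seed))
})

setMethod("show", "ExperimentConfig", function(object) {
  cat("ExperimentConfig:\n  ")
  show(object@network)
  cat(sprintf("  Adam lr %.2g betas (%.3g, %.3g); %d epochs, batch %d, patience %d\n",
              object@learningRate, object@betas[1], object@betas[2],
              object@epochs, object@batchSize, object@lrPatience))
  src <- if (nzchar(object@manifest)) paste("manifest", object@manifest)
         else sprintf("phantoms (%d train / %d test, %d px)",
                      object@nTrain, object@nTest, object@phantom@imageSize)
  cat("  data:", src, "| seed", object@seed, "\n")
})

setMethod("show", "DatasetManifest", function(object) {
  cat(sprintf("DatasetManifest: %d items, classes: %s\n",
              nrow(object@items), paste(object@classes, collapse = ", ")))
  if (nrow(object@items))
    print(table(object@items$split))
})
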