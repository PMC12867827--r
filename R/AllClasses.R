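#' Phantom generation parameters
#'
#' Parameters controlling the synthetic short-axis cardiac phantom
#' generator. A phantom consists of a bright elliptical blood pool (left
#' ventricle, LV), a darker surrounding myocardial ring (MYO) and an
#' attached crescent-shaped right ventricle (RV) on a background, rendered
#' with a smooth multiplicative-style intensity bias field and additive
#' Gaussian noise.
#'
#' @slot imageSize integer, pixels per side of the square image (>= 32).
#' @slot lvRadiusRange numeric(2), min/max LV mean radius in pixels; the
#'   minimum must be >= 3 and the maximum below \code{imageSize / 3}.
#' @slot myoThicknessRange numeric(2), myocardial ring thickness in pixels.
#' @slot rvAngularExtent numeric, angular width of the RV crescent, radians.
#' @slot rotationRange numeric(2), in-plane rotation of the phantom, radians.
#' @slot noiseSigma numeric, standard deviation of the additive Gaussian
#'   noise on the [0, 1] intensity scale (>= 0).
#' @slot biasFieldAmplitude numeric, peak-to-peak amplitude of the smooth
#'   intensity bias field on the [0, 1] scale (>= 0).
#' @slot classIntensities named numeric(4), mean intensity per class
#'   (background, RV, MYO, LV); values must be pairwise >= 0.1 apart.
#' @seealso [phantomSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec",
  representation(
    imageSize = "integer",
    lvRadiusRange = "numeric",
    myoThicknessRange = "numeric",
    rvAngularExtent = "numeric",
    rotationRange = "numeric",
    noiseSigma = "numeric",
    biasFieldAmplitude = "numeric",
    classIntensities = "numeric"
  )
)

setValidity("PhantomSpec", function(object) {
  msgs <- character()
  if (object@imageSize < 32L)
    msgs <- c(msgs, "imageSize must be >= 32 (geometry degenerates below)")
  r <- object@lvRadiusRange
  if (length(r) != 2L || r[1] > r[2])
    msgs <- c(msgs, "lvRadiusRange must be an increasing (min, max) pair")
  else {
    if (r[1] < 3) msgs <- c(msgs, "minimum LV radius must be >= 3 px")
    if (r[2] >= object@imageSize / 3)
      msgs <- c(msgs, "maximum LV radius must be < imageSize / 3")
  }
  t <- object@myoThicknessRange
  if (length(t) != 2L || t[1] > t[2] || t[1] <= 0)
    msgs <- c(msgs, "myoThicknessRange must be a positive (min, max) pair")
  if (object@noiseSigma < 0) msgs <- c(msgs, "noiseSigma must be >= 0")
  if (object@biasFieldAmplitude < 0)
    msgs <- c(msgs, "biasFieldAmplitude must be >= 0")
  ci <- object@classIntensities
  if (length(ci) != 4L || any(ci < 0) || any(ci > 1))
    msgs <- c(msgs, "classIntensities must be 4 values in [0, 1]")
  else if (min(dist(ci)) < 0.1)
    msgs <- c(msgs, "classIntensities must be pairwise >= 0.1 apart")
  if (length(msgs)) msgs else TRUE
})

#' A 2D image/mask pair
#'
#' One grayscale short-axis slice with its integer label mask. Labels are
#' 0 = background, 1 = RV, 2 = MYO, 3 = LV. Phantom samples additionally
#' carry the generating geometry (drawn LV radius, ring thickness, pose) in
#' \code{geometry}, which tests and audits can use as ground truth.
#'
#' @slot image numeric matrix, intensities in [0, 1].
#' @slot mask integer matrix of the same size, values in 0..3.
#' @slot spacing numeric, isotropic pixel spacing in mm (default 1).
#' @slot geometry list, generator geometry (empty for data read from disk).
#' @seealso [generatePhantom()], [readSample()]
#' @export
setClass("CardiacSample",
  representation(
    image = "matrix",
    mask = "matrix",
    spacing = "numeric",
    geometry = "list"
  ),
  prototype(spacing = 1.0, geometry = list())
)

setValidity("CardiacSample", function(object) {
  msgs <- character()
  if (!all(dim(object@image) == dim(object@mask)))
    msgs <- c(msgs, "image and mask dimensions differ")
  if (any(object@image < 0 | object@image > 1))
    msgs <- c(msgs, "image values must lie in [0, 1]")
  labs <- unique(as.vector(object@mask))
  if (!all(labs %in% 0:3))
    msgs <- c(msgs, sprintf("mask contains labels outside 0..3: %s",
                            paste(setdiff(labs, 0:3), collapse = ", ")))
  if (length(object@spacing) != 1L || object@spacing <= 0)
    msgs <- c(msgs, "spacing must be a positive scalar (mm / pixel)")
  if (length(msgs)) msgs else TRUE
})

#' Network architecture configuration
#'
#' Describes a CASNet instance: a U-Net backbone of \code{depth} resolution
#' levels whose first level has \code{baseChannels} channels (doubling per
#' level), with optional Multi-Scale Context Block at the bottleneck
#' (\code{useMSCB}) and Cross-Attentive Skip Connections at every decoder
#' level (\code{useCASC}); with both switches off the model reduces exactly
#' to the plain U-Net baseline. \code{attentionPoolThreshold} is the largest
#' number of key/value positions attended to without average pooling:
#' when a skip level has more spatial positions, keys and values are pooled
#' by the smallest factor bringing them under the threshold while queries
#' stay at full resolution.
#'
#' @slot depth integer >= 2, number of resolution levels.
#' @slot baseChannels integer >= 4, channels at the first level.
#' @slot numClasses integer >= 2, output classes (4 for cardiac phantoms).
#' @slot useMSCB logical, enable the multi-scale context block.
#' @slot useCASC logical, enable cross-attentive skip connections.
#' @slot attentionPoolThreshold integer >= 1, max key positions before
#'   average pooling of keys/values.
#' @seealso [networkConfig()], [initCASNet()]
#' @export
setClass("NetworkConfig",
  representation(
    depth = "integer",
    baseChannels = "integer",
    numClasses = "integer",
    useMSCB = "logical",
    useCASC = "logical",
    attentionPoolThreshold = "integer"
  )
)

setValidity("NetworkConfig", function(object) {
  msgs <- character()
  if (object@depth < 2L) msgs <- c(msgs, "depth must be >= 2")
  if (object@baseChannels < 4L) msgs <- c(msgs, "baseChannels must be >= 4")
  if (object@numClasses < 2L) msgs <- c(msgs, "numClasses must be >= 2")
  if (object@attentionPoolThreshold < 1L)
    msgs <- c(msgs, "attentionPoolThreshold must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Composite loss weights
#'
#' Weights of the three-term training objective
#' \eqn{L = \lambda_1 L_{BCE} + \lambda_2 L_{Dice} + \lambda_3 L_{curv}}.
#' Defaults are (0.5, 0.4, 0.1).
#'
#' @slot bce numeric >= 0, weight of the binary cross-entropy term.
#' @slot dice numeric >= 0, weight of the soft Dice term.
#' @slot curvature numeric >= 0, weight of the Hessian curvature term.
#' @seealso [lossWeights()], [compositeLoss()]
#' @export
setClass("LossWeights",
  representation(bce = "numeric", dice = "numeric", curvature = "numeric"),
  prototype(bce = 0.5, dice = 0.4, curvature = 0.1)
)

setValidity("LossWeights", function(object) {
  w <- c(object@bce, object@dice, object@curvature)
  if (any(w < 0)) "loss weights must be nonnegative" else TRUE
})

#' A CASNet model instance
#'
#' Holds the architecture configuration, the flat list of trainable
#' parameter arrays, and the non-trainable state (batch-normalisation
#' running statistics). Create with [initCASNet()]; run with
#' [casnetForward()] or [predictMasks()].
#'
#' @slot config a [NetworkConfig-class].
#' @slot params named list of numeric arrays (trainable parameters).
#' @slot state named list of numeric vectors (BN running mean/variance).
#' @slot seed integer, the initialisation seed.
#' @export
setClass("CASNetModel",
  representation(
    config = "NetworkConfig",
    params = "list",
    state = "list",
    seed = "integer"
  )
)

#' Experiment configuration
#'
#' Bundles everything one training run needs: the network, the loss
#' weights, the Adam optimiser settings (learning rate 1e-4, betas
#' (0.9, 0.999)), the schedule (epochs, batch size, learning-rate halving
#' after a validation plateau of \code{lrPatience} epochs), the data source
#' (a phantom spec plus train/test sizes, or a dataset manifest path) and
#' the master seed from which the phantom split, weight initialisation and
#' augmentation draws all derive.
#'
#' @slot network a [NetworkConfig-class].
#' @slot loss a [LossWeights-class].
#' @slot learningRate numeric, initial Adam learning rate.
#' @slot betas numeric(2), Adam first/second moment decay rates.
#' @slot epochs integer, training epochs.
#' @slot batchSize integer, minibatch size.
#' @slot lrPatience integer, epochs of validation plateau before halving.
#' @slot valFraction numeric in (0, 1), fraction of the training set held
#'   out for validation-based scheduling and best-checkpoint selection.
#' @slot augment logical, apply random flips/rotation/scaling/elastic
#'   deformation to training samples.
#' @slot phantom a [PhantomSpec-class] (used when \code{manifest} is empty).
#' @slot manifest character, path to a dataset manifest ("" for phantoms).
#' @slot nTrain integer, training samples to generate (phantom source).
#' @slot nTest integer, test samples to generate (phantom source).
#' @slot seed integer, master seed.
#' @seealso [experimentConfig()], [trainModel()], [runAblation()]
#' @export
setClass("ExperimentConfig",
  representation(
    network = "NetworkConfig",
    loss = "LossWeights",
    learningRate = "numeric",
    betas = "numeric",
    epochs = "integer",
    batchSize = "integer",
    lrPatience = "integer",
    valFraction = "numeric",
    augment = "logical",
    phantom = "PhantomSpec",
    manifest = "character",
    nTrain = "integer",
    nTest = "integer",
    seed = "integer"
  )
)

setValidity("ExperimentConfig", function(object) {
  msgs <- character()
  if (object@learningRate <= 0) msgs <- c(msgs, "learningRate must be > 0")
  if (length(object@betas) != 2L || any(object@betas <= 0) ||
      any(object@betas >= 1))
    msgs <- c(msgs, "betas must be two values in (0, 1)")
  if (object@epochs < 1L) msgs <- c(msgs, "epochs must be >= 1")
  if (object@batchSize < 1L) msgs <- c(msgs, "batchSize must be >= 1")
  if (object@valFraction <= 0 || object@valFraction >= 1)
    msgs <- c(msgs, "valFraction must be in (0, 1)")
  if (object@nTrain < 1L) msgs <- c(msgs, "nTrain must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Dataset manifest
#'
#' A table of image/mask file pairs with pixel spacing and split tags, plus
#' the class-name table. Serialised to/from JSON by [saveManifest()] and
#' [loadManifest()].
#'
#' @slot items data.frame with columns \code{image}, \code{mask},
#'   \code{spacing}, \code{split}.
#' @slot classes character vector of class names, index = label value + 1.
#' @export
setClass("DatasetManifest",
  representation(items = "data.frame", classes = "character"),
  prototype(
    items = data.frame(image = character(), mask = character(),
                       spacing = numeric(), split = character(),
                       stringsAsFactors = FALSE),
    classes = c("background", "RV", "MYO", "LV")
  )
)

setValidity("DatasetManifest", function(object) {
  need <- c("image", "mask", "spacing", "split")
  if (!all(need %in% names(object@items)))
    return(paste("manifest items must have columns:",
                 paste(need, collapse = ", ")))
  dup <- object@items$image[duplicated(object@items$image)]
  if (length(dup))
    return(sprintf("splits are not disjoint; duplicated images: %s",
                   paste(unique(dup), collapse = ", ")))
  TRUE
})
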