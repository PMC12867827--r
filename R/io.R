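# Dataset IO: paired PNG (8-bit grayscale image + grayscale label mask) or
# NIfTI files, JSON manifests, and YAML experiment configs. All readers
# return images min-max normalised to [0, 1]; mask resizing is always
# nearest-neighbour so no new labels can appear.

isNifti <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)

# Bilinear (image) / nearest (mask) resize to a square target size.
resizeMatrix <- function(m, target, nearest = FALSE) {
  H <- nrow(m); W <- ncol(m)
  if (H == target && W == target) return(m)
  # align pixel centers: output center c maps to input position
  ri <- (seq_len(target) - 0.5) * H / target + 0.5
  ci <- (seq_len(target) - 0.5) * W / target + 0.5
  rr <- rep(ri, times = target)
  cc <- rep(ci, each = target)
  v <- if (nearest) nearestSample(m, rr, cc) else bilinearSample(m, rr, cc)
  matrix(v, target, target)
}

#' Write an image/mask pair to disk
#'
#' PNG output is 8-bit: the image is scaled to 0..255 and the mask is
#' written as a grayscale label image whose pixel values are the raw class
#' ids. NIfTI output (.nii / .nii.gz) stores the arrays as single 2D slices
#' with the pixel spacing in the header.
#'
#' @param sample a [CardiacSample-class].
#' @param imagePath,maskPath output paths; both must use the same format
#'   (.png, or .nii / .nii.gz).
#' @return Invisibly, c(imagePath, maskPath).
#' @export
writeSample <- function(sample, imagePath, maskPath) {
  if (isNifti(imagePath)) {
    im <- RNifti::asNifti(sample@image)
    RNifti::pixdim(im) <- rep(sample@spacing, 2)
    RNifti::writeNifti(im, imagePath)
    mk <- RNifti::asNifti(sample@mask)
    RNifti::pixdim(mk) <- rep(sample@spacing, 2)
    RNifti::writeNifti(mk, maskPath)
  } else {
    png::writePNG(sample@image, imagePath)
    png::writePNG(sample@mask / 255, maskPath)
  }
  invisible(c(imagePath, maskPath))
}

readGray <- function(path) {
  if (isNifti(path)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[1]
    d <- dim(img)
    list(data = matrix(as.vector(img), d[1], d[2]),
         spacing = if (is.finite(sp) && sp > 0) sp else 1)
  } else {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L) arr <- arr[, , 1]
    list(data = arr, spacing = 1)
  }
}

#' Read an image/mask pair
#'
#' Reads PNG or NIfTI pairs, min-max normalises the image to [0, 1]
#' per slice, and optionally resizes to a square \code{targetSize}
#' (bilinear for the image, nearest-neighbour for the mask). PNG masks are
#' expected to hold raw class ids as 8-bit values; labels outside
#' \code{0..numClasses-1} are an error.
#'
#' @param imagePath,maskPath input paths.
#' @param targetSize optional output size in pixels (square).
#' @param numClasses size of the label alphabet (default 4).
#' @return A [CardiacSample-class].
#' @export
readSample <- function(imagePath, maskPath, targetSize = NULL,
                       numClasses = 4L) {
  for (p in c(imagePath, maskPath))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  im <- readGray(imagePath)
  mk <- readGray(maskPath)
  img <- im$data
  rng <- range(img)
  img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1])
         else img * 0
  mask <- mk$data
  if (!isNifti(maskPath)) mask <- mask * 255
  mask <- round(mask)
  bad <- setdiff(unique(as.vector(mask)), seq_len(numClasses) - 1L)
  if (length(bad))
    stop(sprintf("mask %s contains labels outside the class table: %s",
                 maskPath, paste(bad, collapse = ", ")), call. = FALSE)
  spacing <- im$spacing
  if (!is.null(targetSize)) {
    spacing <- spacing * nrow(img) / targetSize
    img <- clip01(resizeMatrix(img, targetSize))
    mask <- resizeMatrix(mask, targetSize, nearest = TRUE)
  }
  storage.mode(mask) <- "integer"
  cardiacSample(img, mask, spacing = spacing)
}

#' Write a dataset of samples with a JSON manifest
#'
#' @param samples list of [CardiacSample-class] objects.
#' @param dir output directory (created if missing).
#' @param format "png" or "nifti".
#' @param split split tag recorded for every item.
#' @param prefix file-name prefix.
#' @return The [DatasetManifest-class], also written to
#'   \code{dir/manifest.json}.
#' @export
writeDataset <- function(samples, dir, format = c("png", "nifti"),
                         split = "train", prefix = "phantom") {
  format <- match.arg(format)
  ext <- if (format == "png") ".png" else ".nii.gz"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  items <- do.call(rbind, lapply(seq_along(samples), function(i) {
    ip <- file.path(dir, sprintf("%s_%04d_image%s", prefix, i, ext))
    mp <- file.path(dir, sprintf("%s_%04d_mask%s", prefix, i, ext))
    writeSample(samples[[i]], ip, mp)
    data.frame(image = ip, mask = mp, spacing = samples[[i]]@spacing,
               split = split, stringsAsFactors = FALSE)
  }))
  manifest <- new("DatasetManifest", items = items)
  saveManifest(manifest, file.path(dir, "manifest.json"))
  manifest
}

#' Save / load dataset manifests
#'
#' Manifests are JSON files listing image/mask pairs with spacing and split
#' tags plus the class table; the round trip is lossless. Loading verifies
#' that every referenced file exists and reports all missing paths.
#'
#' @param manifest a [DatasetManifest-class].
#' @param path JSON file path.
#' @return \code{loadManifest} returns the [DatasetManifest-class].
#' @export
saveManifest <- function(manifest, path) {
  validObject(manifest)
  jsonlite::write_json(list(classes = manifest@classes,
                            items = manifest@items),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname saveManifest
#' @param checkFiles verify that referenced files exist (default TRUE).
#' @export
loadManifest <- function(path, checkFiles = TRUE) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  items <- as.data.frame(raw$items, stringsAsFactors = FALSE)
  if (nrow(items) == 0) {
    items <- data.frame(image = character(), mask = character(),
                        spacing = numeric(), split = character(),
                        stringsAsFactors = FALSE)
  } else {
    items$image <- as.character(items$image)
    items$mask <- as.character(items$mask)
    items$spacing <- as.numeric(items$spacing)
    items$split <- as.character(items$split)
  }
  m <- new("DatasetManifest", items = items,
           classes = as.character(raw$classes))
  if (checkFiles && nrow(items)) {
    paths <- c(items$image, items$mask)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("manifest references missing files:\n  ",
           paste(missing, collapse = "\n  "), call. = FALSE)
  }
  m
}

#' Load samples listed in a manifest
#'
#' NIfTI volumes with a third dimension are sliced along the last axis into
#' individual 2D samples; PNG pairs load as single slices.
#'
#' @param manifest a [DatasetManifest-class].
#' @param split optional split tag filter.
#' @param targetSize optional square resize.
#' @return A list of [CardiacSample-class] objects.
#' @export
loadSamplesFromManifest <- function(manifest, split = NULL,
                                    targetSize = NULL) {
  items <- manifest@items
  if (!is.null(split)) items <- items[items$split == split, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(items))) {
    ip <- items$image[i]; mp <- items$mask[i]
    if (isNifti(ip)) {
      vol <- RNifti::readNifti(ip)
      if (length(dim(vol)) == 3L) {
        mvol <- RNifti::readNifti(mp)
        for (z in seq_len(dim(vol)[3])) {
          tmpI <- tempfile(fileext = ".nii.gz")
          tmpM <- tempfile(fileext = ".nii.gz")
          sl <- RNifti::asNifti(vol[, , z])
          RNifti::pixdim(sl) <- RNifti::pixdim(vol)[1:2]
          RNifti::writeNifti(sl, tmpI)
          ms <- RNifti::asNifti(mvol[, , z])
          RNifti::pixdim(ms) <- RNifti::pixdim(vol)[1:2]
          RNifti::writeNifti(ms, tmpM)
          out[[length(out) + 1L]] <- readSample(tmpI, tmpM, targetSize)
          unlink(c(tmpI, tmpM))
        }
        next
      }
    }
    out[[length(out) + 1L]] <- readSample(ip, mp, targetSize,
                                          numClasses = length(manifest@classes))
  }
  out
}

# ---- experiment configs as YAML ----

#' Read / write experiment configurations as YAML
#'
#' The YAML layout mirrors the configuration object: a \code{network}
#' section, a \code{loss} section (\code{bce}, \code{dice},
#' \code{curvature}), optimiser/schedule fields, and a \code{data} section
#' (phantom spec or manifest path). The round trip is lossless.
#'
#' @param config an [ExperimentConfig-class].
#' @param path YAML file path.
#' @return \code{readExperimentConfig} returns the
#'   [ExperimentConfig-class].
#' @export
writeExperimentConfig <- function(config, path) {
  net <- config@network
  ph <- config@phantom
  lst <- list(
    network = list(depth = net@depth, base_channels = net@baseChannels,
                   num_classes = net@numClasses, use_mscb = net@useMSCB,
                   use_casc = net@useCASC,
                   attention_pool_threshold = net@attentionPoolThreshold),
    loss = list(bce = config@loss@bce, dice = config@loss@dice,
                curvature = config@loss@curvature),
    optimizer = list(learning_rate = config@learningRate,
                     betas = config@betas),
    schedule = list(epochs = config@epochs, batch_size = config@batchSize,
                    lr_patience = config@lrPatience,
                    val_fraction = config@valFraction,
                    augment = config@augment),
    data = list(manifest = config@manifest,
                n_train = config@nTrain, n_test = config@nTest,
                phantom = list(
                  image_size = ph@imageSize,
                  lv_radius_range = ph@lvRadiusRange,
                  myo_thickness_range = ph@myoThicknessRange,
                  rv_angular_extent = ph@rvAngularExtent,
                  rotation_range = ph@rotationRange,
                  noise_sigma = ph@noiseSigma,
                  bias_field_amplitude = ph@biasFieldAmplitude,
                  class_intensities = as.list(ph@classIntensities))),
    seed = config@seed)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writeExperimentConfig
#' @export
readExperimentConfig <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- y$data$phantom
  spec <- phantomSpec(
    imageSize = ph$image_size,
    lvRadiusRange = unlist(ph$lv_radius_range),
    myoThicknessRange = unlist(ph$myo_thickness_range),
    rvAngularExtent = ph$rv_angular_extent,
    rotationRange = unlist(ph$rotation_range),
    noiseSigma = ph$noise_sigma,
    biasFieldAmplitude = ph$bias_field_amplitude,
    classIntensities = unlist(ph$class_intensities))
  net <- networkConfig(depth = y$network$depth,
                       baseChannels = y$network$base_channels,
                       numClasses = y$network$num_classes,
                       useMSCB = y$network$use_mscb,
                       useCASC = y$network$use_casc,
                       attentionPoolThreshold = y$network$attention_pool_threshold)
  experimentConfig(network = net,
                   loss = lossWeights(y$loss$bce, y$loss$dice,
                                      y$loss$curvature),
                   learningRate = y$optimizer$learning_rate,
                   betas = unlist(y$optimizer$betas),
                   epochs = y$schedule$epochs,
                   batchSize = y$schedule$batch_size,
                   lrPatience = y$schedule$lr_patience,
                   valFraction = y$schedule$val_fraction,
                   augment = y$schedule$augment,
                   phantom = spec,
                   manifest = if (is.null(y$data$manifest)) "" else y$data$manifest,
                   nTrain = y$data$n_train, nTest = y$data$n_test,
                   seed = y$seed)
}
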