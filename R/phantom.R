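# Synthetic short-axis cardiac phantom generator. Geometry is an elliptical
# LV blood pool nested in a myocardial annulus with an attached RV crescent;
# rendering adds a smooth bias field and Gaussian noise. Everything is a
# pure function of (spec, seed).

#' Generate one synthetic cardiac phantom
#'
#' Draws a random geometry (LV radius, myocardial thickness, ellipse aspect,
#' pose, RV position) from `spec`, rasterises the 4-class mask
#' (0 background, 1 RV, 2 MYO, 3 LV), and renders the image as per-class
#' mean intensities plus a smooth bias field plus additive Gaussian noise,
#' clipped to [0, 1]. The LV ellipse has axes r*s and r/s (aspect s), so its
#' area is always pi * r^2 for the drawn radius r. The myocardial ring fully
#' encloses the LV; the RV crescent is an angular sector of an annulus
#' attached to the outer myocardial wall.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed integer seed; output is bitwise-reproducible for a fixed
#'   (spec, seed) pair.
#' @return A [CardiacSample-class] whose \code{geometry} records the drawn
#'   parameters (\code{rLV}, \code{tMYO}, \code{aspect}, \code{phi},
#'   \code{center}, \code{rvAngle}, \code{tRV}).
#' @examples
#' s <- generatePhantom(phantomSpec(), seed = 7)
#' range(sampleImage(s))
#' @export
generatePhantom <- function(spec, seed) {
  validObject(spec)
  n <- spec@imageSize
  withSeed(seed, {
    rLV <- runif(1, spec@lvRadiusRange[1], spec@lvRadiusRange[2])
    tMYO <- runif(1, spec@myoThicknessRange[1], spec@myoThicknessRange[2])
    aspect <- runif(1, 0.85, 1.15)
    phi <- runif(1, spec@rotationRange[1], spec@rotationRange[2])
    center <- n / 2 + 0.5 + runif(2, -0.05 * n, 0.05 * n)
    rvAngle <- runif(1, 0, 2 * pi)
    tRV <- runif(1, 0.35, 0.6) * rLV

    ij <- expand.grid(i = seq_len(n), j = seq_len(n))
    dy <- ij$i - center[1]
    dx <- ij$j - center[2]
    u <- cos(phi) * dx + sin(phi) * dy
    v <- -sin(phi) * dx + cos(phi) * dy
    # elliptical radius in pixel units: q <= rLV is the LV blood pool
    q <- sqrt((u / aspect)^2 + (v * aspect)^2)
    ang <- atan2(v, u)
    dAng <- abs(((ang - rvAngle + pi) %% (2 * pi)) - pi)

    mask <- integer(n * n)
    mask[q > rLV + tMYO & q <= rLV + tMYO + tRV &
           dAng <= spec@rvAngularExtent / 2] <- 1L
    mask[q > rLV & q <= rLV + tMYO] <- 2L
    mask[q <= rLV] <- 3L
    mask <- matrix(mask, n, n)

    img <- matrix(spec@classIntensities[mask + 1L], n, n)
    if (spec@biasFieldAmplitude > 0) {
      grid <- matrix(runif(16, -0.5, 0.5), 4, 4)
      img <- img + spec@biasFieldAmplitude * upsampleGrid(grid, n, n)
    }
    if (spec@noiseSigma > 0)
      img <- img + matrix(rnorm(n * n, 0, spec@noiseSigma), n, n)
    cardiacSample(clip01(img), mask,
                  geometry = list(rLV = rLV, tMYO = tMYO, aspect = aspect,
                                  phi = phi, center = center,
                                  rvAngle = rvAngle, tRV = tRV))
  })
}

#' Generate a reproducible phantom dataset
#'
#' Each sample uses an independent child seed derived from the master seed,
#' so the list is reproducible in content and order and any prefix of it is
#' stable under changes of \code{n}.
#'
#' @param spec a [PhantomSpec-class].
#' @param n number of samples (>= 1).
#' @param seed master seed.
#' @return A list of [CardiacSample-class] objects of length \code{n}.
#' @export
generateDataset <- function(spec, n, seed) {
  stopifnot2(n >= 1, "n must be >= 1")
  seeds <- childSeeds(seed, n)
  lapply(seq_len(n), function(i) generatePhantom(spec, seeds[i]))
}

# Resolve the random transform draws for augmentSample.
drawTransform <- function(seed, imageSize) {
  withSeed(seed, {
    list(flipH = runif(1) < 0.5,
         flipV = runif(1) < 0.5,
         rotation = runif(1, 0, 15) * pi / 180,
         scale = runif(1, 0.9, 1.1),
         elastic = array(runif(2 * 16, -1, 1) * 0.05 * imageSize,
                         dim = c(4, 4, 2)))
  })
}

identityTransform <- function() {
  list(flipH = FALSE, flipV = FALSE, rotation = 0, scale = 1,
       elastic = array(0, dim = c(4, 4, 2)))
}

#' Randomly augment a sample
#'
#' Applies, with independent draws from \code{seed}: horizontal and
#' vertical flips (probability 0.5 each), rotation uniform in 0-15 degrees,
#' isotropic scaling uniform in [0.9, 1.1], and a smooth elastic
#' deformation (4 x 4 random displacement grid, max displacement 5% of the
#' image size, bilinearly upsampled). One geometric map is built and applied
#' to the image with bilinear interpolation and to the mask with
#' nearest-neighbour sampling, so no new labels can appear.
#'
#' @param sample a [CardiacSample-class].
#' @param seed integer seed for the transform draws (ignored when
#'   \code{transform} is given).
#' @param transform optional explicit transform list with elements
#'   \code{flipH}, \code{flipV}, \code{rotation} (radians), \code{scale},
#'   \code{elastic} (4 x 4 x 2 displacement grid in pixels); see
#'   \code{identityTransform} in the sources. Useful for tests.
#' @return The augmented [CardiacSample-class].
#' @export
augmentSample <- function(sample, seed = NULL, transform = NULL) {
  img <- sample@image
  H <- nrow(img); W <- ncol(img)
  if (is.null(transform)) {
    stopifnot2(!is.null(seed), "either seed or transform must be given")
    transform <- drawTransform(seed, max(H, W))
  }
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  out <- expand.grid(i = seq_len(H), j = seq_len(W))
  yo <- out$i - cy; xo <- out$j - cx
  if (transform$flipH) xo <- -xo
  if (transform$flipV) yo <- -yo
  # inverse map of rotate-then-scale: rotate by -theta, scale by 1/s
  th <- -transform$rotation
  s <- 1 / transform$scale
  xi <- s * (cos(th) * xo - sin(th) * yo)
  yi <- s * (sin(th) * xo + cos(th) * yo)
  dyx <- transform$elastic
  dy <- upsampleGrid(dyx[, , 1], H, W)
  dx <- upsampleGrid(dyx[, , 2], H, W)
  ri <- yi + cy + as.vector(dy)
  ci <- xi + cx + as.vector(dx)
  newImg <- matrix(bilinearSample(img, ri, ci), H, W)
  newMask <- matrix(nearestSample(sample@mask, ri, ci), H, W)
  cardiacSample(clip01(newImg), newMask, spacing = sample@spacing,
                geometry = sample@geometry)
}
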