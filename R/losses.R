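# Training losses: per-class binary cross-entropy, soft Dice, and the
# curvature regulariser built on the discrete spatial Hessian of the
# predicted probability maps, combined with weights lambda = (bce, dice,
# curvature). Probability inputs are (H, W, K) arrays whose channels sum to
# 1 per pixel; label masks are integer (H, W) matrices in 0..K-1.

#' Discrete spatial Hessian of a 2D map
#'
#' Central second differences at unit pixel spacing, with x along columns
#' and y along rows: \code{dxx(i,j) = f(i,j+1) - 2 f(i,j) + f(i,j-1)},
#' \code{dyy} analogously along rows, and the mixed partial as central first
#' differences applied twice,
#' \code{dxy(i,j) = (f(i+1,j+1) - f(i+1,j-1) - f(i-1,j+1) + f(i-1,j-1)) / 4}.
#' Borders are handled by replicate padding. Central differences are exact
#' on quadratics, so e.g. \code{f(i,j) = j^2} gives dxx = 2 everywhere on
#' interior pixels.
#'
#' @param map numeric matrix, at least 3 x 3.
#' @return An (H, W, 4) array with slices named \code{dxx}, \code{dxy},
#'   \code{dyx}, \code{dyy} (the two mixed partials are equal by
#'   construction).
#' @examples
#' h <- hessianField(outer(1:5, 1:5, function(i, j) j^2))
#' h[3, 3, ]
#' @export
hessianField <- function(map) {
  stopifnot2(is.matrix(map) && nrow(map) >= 3 && ncol(map) >= 3,
             "map must be a matrix of size at least 3 x 3")
  H <- nrow(map); W <- ncol(map)
  P <- padReplicate(map)
  ctr <- function(di, dj) P[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)]
  dxx <- ctr(0, 1) - 2 * map + ctr(0, -1)
  dyy <- ctr(1, 0) - 2 * map + ctr(-1, 0)
  dxy <- (ctr(1, 1) - ctr(1, -1) - ctr(-1, 1) + ctr(-1, -1)) / 4
  out <- array(c(dxx, dxy, dxy, dyy), dim = c(H, W, 4))
  dimnames(out) <- list(NULL, NULL, c("dxx", "dxy", "dyx", "dyy"))
  out
}

# Adjoint of hessianField composed with weighting fields: given the four
# weight maps g (same shape as the Hessian output), return
# sum_e L_e^T g_e where L_e are the stencil operators with replicate
# padding. Used by the analytic gradient of curvatureLoss.
hessianAdjoint <- function(g) {
  H <- dim(g)[1]; W <- dim(g)[2]
  acc <- matrix(0, H + 2, W + 2)
  scatter <- function(w, di, dj) {
    acc[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)] <<-
      acc[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)] + w
  }
  dxx <- g[, , 1]; dyy <- g[, , 4]
  dmix <- g[, , 2] + g[, , 3]
  scatter(dxx, 0, 1); scatter(-2 * dxx, 0, 0); scatter(dxx, 0, -1)
  scatter(dyy, 1, 0); scatter(-2 * dyy, 0, 0); scatter(dyy, -1, 0)
  scatter(dmix / 4, 1, 1); scatter(-dmix / 4, 1, -1)
  scatter(-dmix / 4, -1, 1); scatter(dmix / 4, -1, -1)
  foldReplicate(acc)
}

# Normalise loss inputs: accept an (H, W, K) probability array or a single
# foreground probability matrix (treated as K = 2 with the map as the one
# foreground class).
probArray <- function(prob) {
  if (is.matrix(prob)) {
    arr <- array(c(1 - prob, prob), dim = c(dim(prob), 2))
    return(arr)
  }
  stopifnot2(length(dim(prob)) == 3L,
             "prob must be a matrix or an (H, W, K) array")
  prob
}

#' Curvature-aware loss
#'
#' For each foreground class k the per-class term is the mean squared
#' Frobenius norm of the spatial Hessian of its probability map,
#' \eqn{L_k = \frac{1}{HW}\sum_{i,j} \lVert \nabla^2 \hat Y_k(i,j)
#' \rVert_F^2}, where the squared Frobenius norm sums the squares of all
#' four Hessian entries (the mixed partial counts twice). The loss is the
#' mean of \eqn{L_k} over foreground classes and is always nonnegative;
#' it is zero exactly when every foreground map is affine (in particular,
#' constant).
#'
#' @param prob an (H, W, K) probability array (classes 2..K are foreground),
#'   or a single foreground probability matrix.
#' @param interiorOnly if TRUE, average only over interior pixels (no
#'   padding effects); useful for analytic checks. Default FALSE uses
#'   replicate padding over the full grid.
#' @return A nonnegative scalar.
#' @examples
#' curvatureLoss(matrix(0.5, 8, 8))        # constant map -> 0
#' @export
curvatureLoss <- function(prob, interiorOnly = FALSE) {
  prob <- probArray(prob)
  K <- dim(prob)[3]
  H <- dim(prob)[1]; W <- dim(prob)[2]
  lk <- vapply(seq_len(K - 1L) + 1L, function(k) {
    h <- hessianField(prob[, , k])
    f2 <- h[, , 1]^2 + h[, , 2]^2 + h[, , 3]^2 + h[, , 4]^2
    if (interiorOnly) mean(f2[2:(H - 1), 2:(W - 1)]) else mean(f2)
  }, numeric(1))
  mean(lk)
}

# dL/dprob of curvatureLoss (replicate-padded variant).
curvatureLossGrad <- function(prob) {
  prob <- probArray(prob)
  d <- dim(prob)
  K <- d[3]
  grad <- array(0, dim = d)
  for (k in seq_len(K - 1L) + 1L) {
    h <- hessianField(prob[, , k])
    grad[, , k] <- 2 * hessianAdjoint(h) / (d[1] * d[2] * (K - 1L))
  }
  grad
}

maskOneHot <- function(mask, K) {
  oh <- array(0, dim = c(dim(mask), K))
  for (k in seq_len(K)) oh[, , k] <- (mask == k - 1L)
  oh
}

checkShapes <- function(prob, mask) {
  stopifnot2(all(dim(prob)[1:2] == dim(mask)),
             sprintf("shape mismatch: prob %s vs mask %s",
                     paste(dim(prob)[1:2], collapse = "x"),
                     paste(dim(mask), collapse = "x")))
}

#' Soft Dice loss
#'
#' Per foreground class k: \eqn{1 - (2\sum \hat y y + s) / (\sum \hat y +
#' \sum y + s)} with smoothing \eqn{s = 1}, averaged over foreground
#' classes. Lies in [0, 1] and equals one minus the (smoothed) Dice
#' coefficient.
#'
#' @param prob (H, W, K) probability array or foreground probability matrix.
#' @param mask integer (H, W) label matrix in 0..K-1.
#' @param smooth smoothing constant s.
#' @return Scalar in [0, 1].
#' @export
diceLoss <- function(prob, mask, smooth = 1) {
  prob <- probArray(prob)
  checkShapes(prob, mask)
  K <- dim(prob)[3]
  lk <- vapply(seq_len(K - 1L) + 1L, function(k) {
    p <- prob[, , k]
    y <- mask == (k - 1L)
    1 - (2 * sum(p[y]) + smooth) / (sum(p) + sum(y) + smooth)
  }, numeric(1))
  mean(lk)
}

diceLossGrad <- function(prob, mask, smooth = 1) {
  prob <- probArray(prob)
  d <- dim(prob)
  K <- d[3]
  grad <- array(0, dim = d)
  for (k in seq_len(K - 1L) + 1L) {
    p <- prob[, , k]
    y <- (mask == (k - 1L)) * 1
    num <- 2 * sum(p * y) + smooth
    den <- sum(p) + sum(y) + smooth
    grad[, , k] <- -(2 * y * den - num) / den^2 / (K - 1L)
  }
  grad
}

#' Binary cross-entropy loss
#'
#' Treats each class map (background included) as an independent binary
#' problem: \eqn{-[y \log \hat y + (1 - y)\log(1 - \hat y)]} averaged over
#' pixels and classes, with probabilities clipped to
#' \eqn{[\epsilon, 1-\epsilon]} before the logarithms.
#'
#' @inheritParams diceLoss
#' @param eps clipping constant (default 1e-7).
#' @return A nonnegative scalar.
#' @export
bceLoss <- function(prob, mask, eps = 1e-7) {
  prob <- probArray(prob)
  checkShapes(prob, mask)
  K <- dim(prob)[3]
  p <- pmin(pmax(prob, eps), 1 - eps)
  y <- maskOneHot(mask, K)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

bceLossGrad <- function(prob, mask, eps = 1e-7) {
  prob <- probArray(prob)
  K <- dim(prob)[3]
  p <- pmin(pmax(prob, eps), 1 - eps)
  y <- maskOneHot(mask, K)
  (-y / p + (1 - y) / (1 - p)) / length(p)
}

#' Composite segmentation loss
#'
#' The weighted training objective \eqn{\lambda_1 L_{BCE} + \lambda_2
#' L_{Dice} + \lambda_3 L_{curv}} with default weights (0.5, 0.4, 0.1). It
#' equals the same weighted combination of [bceLoss()], [diceLoss()] and
#' [curvatureLoss()] exactly, and is linear in each weight.
#'
#' @inheritParams diceLoss
#' @param weights a [LossWeights-class] (or the result of [lossWeights()]).
#' @return A nonnegative scalar.
#' @examples
#' p <- array(0.5, dim = c(8, 8, 2))
#' m <- matrix(rep(0:1, each = 32), 8, 8)
#' compositeLoss(p, m, lossWeights(1, 0, 0))
#' @export
compositeLoss <- function(prob, mask, weights = lossWeights()) {
  validObject(weights)
  prob <- probArray(prob)
  checkShapes(prob, mask)
  weights@bce * bceLoss(prob, mask) +
    weights@dice * diceLoss(prob, mask) +
    weights@curvature * curvatureLoss(prob)
}

# Analytic dL/dprob of compositeLoss; verified against numerical
# differentiation in the test suite.
compositeLossGrad <- function(prob, mask, weights = lossWeights()) {
  prob <- probArray(prob)
  g <- weights@bce * bceLossGrad(prob, mask)
  if (weights@dice != 0) g <- g + weights@dice * diceLossGrad(prob, mask)
  if (weights@curvature != 0)
    g <- g + weights@curvature * curvatureLossGrad(prob)
  g
}
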