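# The two architectural contributions: the Multi-Scale Context Block (MSCB)
# and the Cross-Attentive Skip Connection (CASC). Exported functions operate
# on single feature maps laid out as (height, width, channels) arrays; the
# batched internals used by the training harness work on (H, W, C, N).

asBatch <- function(f) {
  stopifnot2(length(dim(f)) == 3L, "feature map must be an (H, W, C) array")
  dim(f) <- c(dim(f), 1L)
  f
}

fromBatch <- function(f) {
  d <- dim(f)
  dim(f) <- d[1:3]
  f
}

#' Initialise Multi-Scale Context Block parameters
#'
#' The MSCB passes a C-channel map through parallel 1x1, 3x3 and 5x5
#' convolutions (each C to C, ReLU-activated, padded to preserve the spatial
#' size), concatenates the three branch outputs along channels, and fuses
#' them back to C channels with a 1x1 convolution.
#'
#' @param channels number of input (= output) channels C.
#' @param seed integer seed for He-normal initialisation.
#' @return A named list of weight/bias arrays (\code{w1, b1, w3, b3, w5, b5,
#'   wf, bf}).
#' @export
initMSCBParams <- function(channels, seed = 1L) {
  c <- as.integer(channels)
  withSeed(seed, list(
    w1 = heInit(1, 1, c, c), b1 = numeric(c),
    w3 = heInit(3, 3, c, c), b3 = numeric(c),
    w5 = heInit(5, 5, c, c), b5 = numeric(c),
    wf = heInit(1, 1, 3 * c, c), bf = numeric(c)
  ))
}

mscbFwdBatch <- function(x, p) {
  d <- dim(x)
  C <- d[3]
  f1 <- relu(convForward(x, p$w1, p$b1, 0L))
  f3 <- relu(convForward(x, p$w3, p$b3, 1L))
  f5 <- relu(convForward(x, p$w5, p$b5, 2L))
  cat <- array(0, dim = c(d[1], d[2], 3L * C, d[4]))
  cat[, , 1:C, ] <- f1
  cat[, , (C + 1):(2 * C), ] <- f3
  cat[, , (2 * C + 1):(3 * C), ] <- f5
  out <- convForward(cat, p$wf, p$bf, 0L)
  list(out = out, cache = list(x = x, f1 = f1, f3 = f3, f5 = f5, cat = cat))
}

mscbBwdBatch <- function(cache, p, gout) {
  C <- dim(cache$f1)[3]
  fb <- convBackward(cache$cat, p$wf, gout, 0L)
  dcat <- fb$dx
  g1 <- reluBackward(dcat[, , 1:C, , drop = FALSE], cache$f1)
  g3 <- reluBackward(dcat[, , (C + 1):(2 * C), , drop = FALSE], cache$f3)
  g5 <- reluBackward(dcat[, , (2 * C + 1):(3 * C), , drop = FALSE], cache$f5)
  b1 <- convBackward(cache$x, p$w1, g1, 0L)
  b3 <- convBackward(cache$x, p$w3, g3, 1L)
  b5 <- convBackward(cache$x, p$w5, g5, 2L)
  list(dx = b1$dx + b3$dx + b5$dx,
       grads = list(w1 = b1$dw, b1 = b1$db, w3 = b3$dw, b3 = b3$db,
                    w5 = b5$dw, b5 = b5$db, wf = fb$dw, bf = fb$db))
}

#' Multi-Scale Context Block forward pass
#'
#' @param fIn an (H, W, C) feature map.
#' @param params parameters from [initMSCBParams()] for the same C.
#' @return An (H, W, C) feature map: spatial size and channel count are
#'   preserved.
#' @examples
#' p <- initMSCBParams(8, seed = 2)
#' f <- array(rnorm(16 * 16 * 8), dim = c(16, 16, 8))
#' dim(mscbForward(f, p))
#' @export
mscbForward <- function(fIn, params) {
  stopifnot2(length(dim(fIn)) == 3L, "fIn must be an (H, W, C) array")
  if (dim(fIn)[3] != dim(params$w1)[3])
    stop(sprintf("channel mismatch: map has %d channels, params expect %d",
                 dim(fIn)[3], dim(params$w1)[3]), call. = FALSE)
  fromBatch(mscbFwdBatch(asBatch(fIn), params)$out)
}

# Row-softmax of Q K^T / sqrt(Ca) for position-by-channel matrices.
attentionCore <- function(Qm, Km) {
  ca <- ncol(Qm)
  logits <- tcrossprod(Qm, Km) / sqrt(ca)
  logits <- logits - apply(logits, 1, max)
  A <- exp(logits)
  A / rowSums(A)
}

#' Spatial cross-attention map
#'
#' Computes the row-stochastic attention matrix
#' \eqn{A_{ij} = \mathrm{softmax}_j(\langle Q_i, K_j\rangle / \sqrt{C_a})}
#' between N query positions and M key positions in a shared C_a-dimensional
#' embedding.
#'
#' @param q query tensor: an (H, W, C_a) array or an N x C_a matrix of
#'   flattened positions.
#' @param k key tensor: an (H', W', C_a) array or an M x C_a matrix.
#' @return The N x M attention matrix; every row is nonnegative and sums
#'   to 1.
#' @examples
#' q <- matrix(1, 1, 1)
#' k <- matrix(c(0, log(3)), 2, 1)
#' attentionMap(q, k)  # (0.25, 0.75)
#' @export
attentionMap <- function(q, k) {
  toMat <- function(t) {
    if (is.matrix(t)) return(t)
    d <- dim(t)
    stopifnot2(length(d) == 3L, "tensors must be matrices or (H, W, C) arrays")
    dim(t) <- c(d[1] * d[2], d[3])
    t
  }
  Qm <- toMat(q); Km <- toMat(k)
  if (ncol(Qm) != ncol(Km))
    stop(sprintf("embedding dimension mismatch: queries %d, keys %d",
                 ncol(Qm), ncol(Km)), call. = FALSE)
  attentionCore(Qm, Km)
}

# Smallest power-of-two pooling factor bringing H/p * W/p under `threshold`
# (while p divides both dimensions).
poolFactor <- function(H, W, threshold) {
  p <- 1L
  while ((H / p) * (W / p) > threshold &&
         H %% (2L * p) == 0L && W %% (2L * p) == 0L)
    p <- 2L * p
  p
}

#' Initialise Cross-Attentive Skip Connection parameters
#'
#' CASC projects the decoder map (queries) and the encoder map (keys and
#' values) into a shared C_a-dimensional embedding with 1x1 convolutions,
#' computes scaled dot-product attention across spatial positions, and fuses
#' the concatenation of the decoder map with the attended values through a
#' 3x3 convolution back to the decoder width. When the spatial grid exceeds
#' \code{poolThreshold} positions, keys and values are average-pooled by the
#' smallest power-of-two factor that fits; queries always stay at full
#' resolution, so the output grid is unchanged.
#'
#' @param cE encoder channels.
#' @param cD decoder channels (also the output channel count).
#' @param cA attention embedding dimension; defaults to \code{cE / 2}.
#' @param poolThreshold max key positions before average pooling.
#' @param seed integer seed.
#' @return A named list of parameter arrays plus the pooling threshold.
#' @export
initCASCParams <- function(cE, cD, cA = max(1L, cE %/% 2L),
                           poolThreshold = 1024L, seed = 1L) {
  cE <- as.integer(cE); cD <- as.integer(cD); cA <- as.integer(cA)
  withSeed(seed, list(
    wq = heInit(1, 1, cD, cA), bq = numeric(cA),
    wk = heInit(1, 1, cE, cA), bk = numeric(cA),
    wv = heInit(1, 1, cE, cA), bv = numeric(cA),
    wf = heInit(3, 3, cD + cA, cD), bf = numeric(cD),
    poolThreshold = as.integer(poolThreshold)
  ))
}

cascFwdBatch <- function(fe, fd, p) {
  d <- dim(fe)
  H <- d[1]; W <- d[2]; N <- d[4]
  cA <- dim(p$wq)[4]
  cD <- dim(fd)[3]
  q <- convForward(fd, p$wq, p$bq, 0L)
  k <- convForward(fe, p$wk, p$bk, 0L)
  v <- convForward(fe, p$wv, p$bv, 0L)
  pool <- poolFactor(H, W, p$poolThreshold)
  kp <- avgPool(k, pool)
  vp <- avgPool(v, pool)
  at <- .attn_fwd(q, kp, vp, useFp32())
  fatt <- at$fatt
  A <- at$A
  cat <- array(0, dim = c(H, W, cD + cA, N))
  cat[, , 1:cD, ] <- fd
  cat[, , (cD + 1):(cD + cA), ] <- fatt
  out <- convForward(cat, p$wf, p$bf, 1L)
  list(out = out,
       cache = list(fe = fe, fd = fd, q = q, kp = kp, vp = vp, A = A,
                    cat = cat, pool = pool))
}

cascBwdBatch <- function(cache, p, gout) {
  cA <- dim(p$wq)[4]
  cD <- dim(cache$fd)[3]
  pool <- cache$pool
  fb <- convBackward(cache$cat, p$wf, gout, 1L)
  dcat <- fb$dx
  dfd <- dcat[, , 1:cD, , drop = FALSE]
  dfatt <- dcat[, , (cD + 1):(cD + cA), , drop = FALSE]
  db <- .attn_bwd(cache$A, cache$q, cache$kp, cache$vp, dfatt, useFp32())
  dk <- avgUnpool(db$dk, pool)
  dv <- avgUnpool(db$dv, pool)
  dq <- db$dq
  qb <- convBackward(cache$fd, p$wq, dq, 0L)
  kb <- convBackward(cache$fe, p$wk, dk, 0L)
  vb <- convBackward(cache$fe, p$wv, dv, 0L)
  list(dfe = kb$dx + vb$dx,
       dfd = dfd + qb$dx,
       grads = list(wq = qb$dw, bq = qb$db, wk = kb$dw, bk = kb$db,
                    wv = vb$dw, bv = vb$db, wf = fb$dw, bf = fb$db))
}

#' Cross-Attentive Skip Connection forward pass
#'
#' @param fE encoder feature map, (H, W, C_e) array.
#' @param fD decoder feature map, (H, W, C_d) array at the same spatial
#'   size.
#' @param params parameters from [initCASCParams()].
#' @return An (H, W, C_d) fused feature map.
#' @export
cascForward <- function(fE, fD, params) {
  stopifnot2(length(dim(fE)) == 3L && length(dim(fD)) == 3L,
             "feature maps must be (H, W, C) arrays")
  if (!all(dim(fE)[1:2] == dim(fD)[1:2]))
    stop(sprintf("spatial size mismatch: encoder %dx%d vs decoder %dx%d",
                 dim(fE)[1], dim(fE)[2], dim(fD)[1], dim(fD)[2]),
         call. = FALSE)
  fromBatch(cascFwdBatch(asBatch(fE), asBatch(fD), params)$out)
}
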