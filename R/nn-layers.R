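# Internal layer primitives. Feature batches are (H, W, C, N) arrays;
# convolution weights are (kh, kw, Cin, Cout) with bias vectors of length
# Cout. Forward functions return the output plus whatever the backward pass
# needs; backward functions return input gradients and parameter gradients.

# Compute precision of the conv/attention GEMM kernels: float32 by default
# (the standard training precision for convolutional segmentation networks);
# set options(casnet.fp32 = FALSE) for float64, e.g. in finite-difference
# gradient checks.
useFp32 <- function() isTRUE(getOption("casnet.fp32", TRUE))

convForward <- function(x, w, b, pad)
  .conv2d_fwd(x, w, b, as.integer(pad), useFp32())

convBackward <- function(x, w, gout, pad, needDx = TRUE)
  .conv2d_bwd(x, w, gout, as.integer(pad), needDx, useFp32())

convTransForward <- function(x, w, b) .convt2d_fwd(x, w, b)

convTransBackward <- function(x, w, gout) .convt2d_bwd(x, w, gout)

maxPoolForward <- function(x) .maxpool2_fwd(x)

maxPoolBackward <- function(idx, gout, H, W)
  .maxpool2_bwd(idx, gout, as.integer(H), as.integer(W))

relu <- function(x) .relu_fwd(x)

reluBackward <- function(g, y) .relu_bwd(g, y)

# Batch normalisation over (H, W, N) per channel, with running statistics
# for inference. `state` is a list(mean, var) of length-C vectors. With
# reluOut = TRUE the rectifier is fused into the output; the matching
# backward pass then gets the rectified output as `reluY`.
bnForward <- function(x, gamma, beta, state, train, eps = 1e-5,
                      momentum = 0.1, reluOut = FALSE) {
  r <- .bn_fwd(x, gamma, beta, state$mean, state$var, train, eps, momentum,
               reluOut)
  list(y = r$y,
       cache = list(xhat = r$xhat, invstd = r$invstd, gamma = gamma),
       state = list(mean = r$mean, var = r$var))
}

bnBackward <- function(g, cache, reluY = numeric()) {
  .bn_bwd(g, cache$xhat, cache$invstd, cache$gamma, reluY)
}

# Channel-wise softmax on (H, W, K, N); returns probabilities of same shape.
softmaxChannels <- function(x) .softmax_ch(x)

# Gradient through channel softmax: given dL/dprob and prob, return
# dL/dlogits = p * (g - sum_k p_k g_k).
softmaxBackward <- function(g, prob) .softmax_ch_bwd(g, prob)

# He-normal initialiser for conv weights.
heInit <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

newConv <- function(params, name, kh, kw, cin, cout) {
  params[[paste0(name, ".w")]] <- heInit(kh, kw, cin, cout)
  params[[paste0(name, ".b")]] <- numeric(cout)
  params
}

newBN <- function(params, state, name, c) {
  params[[paste0(name, ".gamma")]] <- rep(1, c)
  params[[paste0(name, ".beta")]] <- numeric(c)
  state[[paste0(name, ".mean")]] <- numeric(c)
  state[[paste0(name, ".var")]] <- rep(1, c)
  list(params = params, state = state)
}

# ---- Adam optimiser over a flat named list of parameter arrays ----

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, opt, lr, betas, eps = 1e-8) {
  opt$t <- opt$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
    mhat <- opt$m[[nm]] / corr1
    vhat <- opt$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}
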