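# CASNet assembly: a U-Net backbone of (conv-BN-ReLU) x 2 encoder levels
# with 2x max-pool downsampling, an optional MSCB at the bottleneck,
# transposed-convolution upsampling, and per-level skip fusion that is
# either a CASC (attention) or plain channel concatenation. The final layer
# is a 1x1 convolution followed by a channel softmax.

encChannels <- function(config) {
  config@baseChannels * 2L^(seq_len(config@depth - 1L) - 1L)
}

bottChannels <- function(config) {
  config@baseChannels * 2L^(config@depth - 1L)
}

#' Initialise a CASNet model
#'
#' Builds all trainable parameters (He-normal conv weights, unit-gamma
#' batch-norm) and zeroed running statistics, deterministically from
#' \code{seed}. With \code{useMSCB} and \code{useCASC} both off the
#' parameter set is exactly that of the plain U-Net backbone.
#'
#' @param config a [NetworkConfig-class].
#' @param seed integer initialisation seed.
#' @return A [CASNetModel-class].
#' @examples
#' m <- initCASNet(networkConfig(depth = 2, baseChannels = 4), seed = 1)
#' parameterCount(m)
#' @export
initCASNet <- function(config, seed = 1L) {
  validObject(config)
  ch <- encChannels(config)
  cb <- bottChannels(config)
  nl <- config@depth - 1L
  withSeed(seed, {
    params <- list()
    state <- list()
    addUnit <- function(prefix, cin, cout) {
      params <<- newConv(params, paste0(prefix, ".c1"), 3, 3, cin, cout)
      r <- newBN(params, state, paste0(prefix, ".n1"), cout)
      params <<- r$params; state <<- r$state
      params <<- newConv(params, paste0(prefix, ".c2"), 3, 3, cout, cout)
      r <- newBN(params, state, paste0(prefix, ".n2"), cout)
      params <<- r$params; state <<- r$state
    }
    for (l in seq_len(nl))
      addUnit(paste0("enc", l), if (l == 1L) 1L else ch[l - 1L], ch[l])
    addUnit("bott", ch[nl], cb)
    if (config@useMSCB) {
      params <- newConv(params, "mscb.c1", 1, 1, cb, cb)
      params <- newConv(params, "mscb.c3", 3, 3, cb, cb)
      params <- newConv(params, "mscb.c5", 5, 5, cb, cb)
      params <- newConv(params, "mscb.cf", 1, 1, 3L * cb, cb)
    }
    for (l in rev(seq_len(nl))) {
      cAbove <- if (l == nl) cb else ch[l + 1L]
      params <- newConv(params, paste0("dec", l, ".up"), 2, 2, cAbove, ch[l])
      if (config@useCASC) {
        cA <- max(1L, ch[l] %/% 2L)
        params <- newConv(params, paste0("dec", l, ".att.q"), 1, 1, ch[l], cA)
        params <- newConv(params, paste0("dec", l, ".att.k"), 1, 1, ch[l], cA)
        params <- newConv(params, paste0("dec", l, ".att.v"), 1, 1, ch[l], cA)
        params <- newConv(params, paste0("dec", l, ".att.f"), 3, 3,
                          ch[l] + cA, ch[l])
        cin <- ch[l]
      } else {
        cin <- 2L * ch[l]
      }
      addUnit(paste0("dec", l), cin, ch[l])
    }
    params <- newConv(params, "final", 1, 1, ch[1L], config@numClasses)
    new("CASNetModel", config = config, params = params, state = state,
        seed = as.integer(seed))
  })
}

#' @rdname initCASNet
#' @param model a [CASNetModel-class].
#' @return \code{parameterCount}: the total number of trainable scalars.
#' @export
parameterCount <- function(model) {
  sum(vapply(model@params, length, integer(1)))
}

mscbParamsFromFlat <- function(params) {
  list(w1 = params[["mscb.c1.w"]], b1 = params[["mscb.c1.b"]],
       w3 = params[["mscb.c3.w"]], b3 = params[["mscb.c3.b"]],
       w5 = params[["mscb.c5.w"]], b5 = params[["mscb.c5.b"]],
       wf = params[["mscb.cf.w"]], bf = params[["mscb.cf.b"]])
}

cascParamsFromFlat <- function(params, l, threshold) {
  pre <- paste0("dec", l, ".att.")
  list(wq = params[[paste0(pre, "q.w")]], bq = params[[paste0(pre, "q.b")]],
       wk = params[[paste0(pre, "k.w")]], bk = params[[paste0(pre, "k.b")]],
       wv = params[[paste0(pre, "v.w")]], bv = params[[paste0(pre, "v.b")]],
       wf = params[[paste0(pre, "f.w")]], bf = params[[paste0(pre, "f.b")]],
       poolThreshold = threshold)
}

unitFwd <- function(params, state, prefix, x, train) {
  y1 <- convForward(x, params[[paste0(prefix, ".c1.w")]],
                    params[[paste0(prefix, ".c1.b")]], 1L)
  s1 <- list(mean = state[[paste0(prefix, ".n1.mean")]],
             var = state[[paste0(prefix, ".n1.var")]])
  r1 <- bnForward(y1, params[[paste0(prefix, ".n1.gamma")]],
                  params[[paste0(prefix, ".n1.beta")]], s1, train,
                  reluOut = TRUE)
  a1 <- r1$y
  y2 <- convForward(a1, params[[paste0(prefix, ".c2.w")]],
                    params[[paste0(prefix, ".c2.b")]], 1L)
  s2 <- list(mean = state[[paste0(prefix, ".n2.mean")]],
             var = state[[paste0(prefix, ".n2.var")]])
  r2 <- bnForward(y2, params[[paste0(prefix, ".n2.gamma")]],
                  params[[paste0(prefix, ".n2.beta")]], s2, train,
                  reluOut = TRUE)
  a2 <- r2$y
  state[[paste0(prefix, ".n1.mean")]] <- r1$state$mean
  state[[paste0(prefix, ".n1.var")]] <- r1$state$var
  state[[paste0(prefix, ".n2.mean")]] <- r2$state$mean
  state[[paste0(prefix, ".n2.var")]] <- r2$state$var
  list(out = a2, state = state,
       cache = list(x = x, bn1 = r1$cache, a1 = a1, bn2 = r2$cache, a2 = a2))
}

unitBwd <- function(params, prefix, cache, g, grads, needDx = TRUE) {
  b2 <- bnBackward(g, cache$bn2, reluY = cache$a2)
  grads[[paste0(prefix, ".n2.gamma")]] <- b2$dgamma
  grads[[paste0(prefix, ".n2.beta")]] <- b2$dbeta
  c2 <- convBackward(cache$a1, params[[paste0(prefix, ".c2.w")]], b2$dx, 1L)
  grads[[paste0(prefix, ".c2.w")]] <- c2$dw
  grads[[paste0(prefix, ".c2.b")]] <- c2$db
  b1 <- bnBackward(c2$dx, cache$bn1, reluY = cache$a1)
  grads[[paste0(prefix, ".n1.gamma")]] <- b1$dgamma
  grads[[paste0(prefix, ".n1.beta")]] <- b1$dbeta
  c1 <- convBackward(cache$x, params[[paste0(prefix, ".c1.w")]], b1$dx, 1L,
                     needDx = needDx)
  grads[[paste0(prefix, ".c1.w")]] <- c1$dw
  grads[[paste0(prefix, ".c1.b")]] <- c1$db
  list(dx = if (needDx) c1$dx else NULL, grads = grads)
}

# Full forward pass on an (H, W, 1, N) batch. Returns class probabilities
# (H, W, K, N), the logits, the updated BN state and (if keepCache) all
# intermediates needed by casnetBwd.
casnetFwd <- function(params, state, config, x, train = FALSE,
                      keepCache = train) {
  d <- dim(x)
  nl <- config@depth - 1L
  if (d[1] %% 2L^nl != 0L || d[2] %% 2L^nl != 0L)
    stop(sprintf("spatial size %dx%d not divisible by 2^%d", d[1], d[2], nl),
         call. = FALSE)
  cache <- list(enc = vector("list", nl), pool = vector("list", nl),
                dec = vector("list", nl), skipFuse = vector("list", nl))
  h <- x
  skips <- vector("list", nl)
  for (l in seq_len(nl)) {
    r <- unitFwd(params, state, paste0("enc", l), h, train)
    state <- r$state
    skips[[l]] <- r$out
    if (keepCache) cache$enc[[l]] <- r$cache
    mp <- maxPoolForward(r$out)
    if (keepCache) cache$pool[[l]] <- mp$idx
    h <- mp$y
  }
  r <- unitFwd(params, state, "bott", h, train)
  state <- r$state
  if (keepCache) cache$bott <- r$cache
  h <- r$out
  if (config@useMSCB) {
    mr <- mscbFwdBatch(h, mscbParamsFromFlat(params))
    if (keepCache) cache$mscb <- mr$cache
    h <- mr$out
  }
  for (l in rev(seq_len(nl))) {
    up <- convTransForward(h, params[[paste0("dec", l, ".up.w")]],
                           params[[paste0("dec", l, ".up.b")]])
    if (keepCache) cache$dec[[l]] <- list(upIn = h)
    fe <- skips[[l]]
    if (config@useCASC) {
      cr <- cascFwdBatch(fe, up,
                         cascParamsFromFlat(params, l,
                                            config@attentionPoolThreshold))
      fused <- cr$out
      if (keepCache) cache$skipFuse[[l]] <- cr$cache
    } else {
      dd <- dim(up)
      cd <- dd[3]
      ce <- dim(fe)[3]
      fused <- array(0, dim = c(dd[1], dd[2], cd + ce, dd[4]))
      fused[, , 1:cd, ] <- up
      fused[, , (cd + 1):(cd + ce), ] <- fe
      if (keepCache) cache$skipFuse[[l]] <- list(cd = cd, ce = ce)
    }
    r <- unitFwd(params, state, paste0("dec", l), fused, train)
    state <- r$state
    if (keepCache) cache$dec[[l]]$unit <- r$cache
    h <- r$out
  }
  logits <- convForward(h, params[["final.w"]], params[["final.b"]], 0L)
  prob <- softmaxChannels(logits)
  if (keepCache) {
    cache$lastDec <- h
    cache$prob <- prob
  }
  list(prob = prob, logits = logits, state = state, cache = cache)
}

# Backward pass from dL/dprob; returns the flat gradient list.
casnetBwd <- function(params, config, cache, dprob) {
  nl <- config@depth - 1L
  grads <- list()
  dlogits <- softmaxBackward(dprob, cache$prob)
  fb <- convBackward(cache$lastDec, params[["final.w"]], dlogits, 0L)
  grads[["final.w"]] <- fb$dw
  grads[["final.b"]] <- fb$db
  g <- fb$dx
  dSkips <- vector("list", nl)
  # decoder backward: shallowest level first, gradient flows to the level
  # above through the transposed convolution
  for (l in seq_len(nl)) {
    r <- unitBwd(params, paste0("dec", l), cache$dec[[l]]$unit, g, grads)
    grads <- r$grads
    gFused <- r$dx
    if (config@useCASC) {
      cb <- cascBwdBatch(cache$skipFuse[[l]],
                         cascParamsFromFlat(params, l,
                                            config@attentionPoolThreshold),
                         gFused)
      pre <- paste0("dec", l, ".att.")
      grads[[paste0(pre, "q.w")]] <- cb$grads$wq
      grads[[paste0(pre, "q.b")]] <- cb$grads$bq
      grads[[paste0(pre, "k.w")]] <- cb$grads$wk
      grads[[paste0(pre, "k.b")]] <- cb$grads$bk
      grads[[paste0(pre, "v.w")]] <- cb$grads$wv
      grads[[paste0(pre, "v.b")]] <- cb$grads$bv
      grads[[paste0(pre, "f.w")]] <- cb$grads$wf
      grads[[paste0(pre, "f.b")]] <- cb$grads$bf
      dUp <- cb$dfd
      dSkips[[l]] <- cb$dfe
    } else {
      cd <- cache$skipFuse[[l]]$cd
      ce <- cache$skipFuse[[l]]$ce
      dUp <- gFused[, , 1:cd, , drop = FALSE]
      dSkips[[l]] <- gFused[, , (cd + 1):(cd + ce), , drop = FALSE]
    }
    ub <- convTransBackward(cache$dec[[l]]$upIn,
                            params[[paste0("dec", l, ".up.w")]], dUp)
    grads[[paste0("dec", l, ".up.w")]] <- ub$dw
    grads[[paste0("dec", l, ".up.b")]] <- ub$db
    g <- ub$dx
  }
  if (config@useMSCB) {
    mb <- mscbBwdBatch(cache$mscb, mscbParamsFromFlat(params), g)
    grads[["mscb.c1.w"]] <- mb$grads$w1
    grads[["mscb.c1.b"]] <- mb$grads$b1
    grads[["mscb.c3.w"]] <- mb$grads$w3
    grads[["mscb.c3.b"]] <- mb$grads$b3
    grads[["mscb.c5.w"]] <- mb$grads$w5
    grads[["mscb.c5.b"]] <- mb$grads$b5
    grads[["mscb.cf.w"]] <- mb$grads$wf
    grads[["mscb.cf.b"]] <- mb$grads$bf
    g <- mb$dx
  }
  r <- unitBwd(params, "bott", cache$bott, g, grads)
  grads <- r$grads
  g <- r$dx
  for (l in rev(seq_len(nl))) {
    d <- dim(dSkips[[l]])
    g <- maxPoolBackward(cache$pool[[l]], g, d[1], d[2])
    g <- g + dSkips[[l]]
    r <- unitBwd(params, paste0("enc", l), cache$enc[[l]], g, grads,
                 needDx = l > 1L)
    grads <- r$grads
    g <- r$dx
  }
  grads
}

#' Run the network forward on images
#'
#' Evaluation-mode forward pass (batch-norm running statistics) returning
#' per-class probability maps that sum to 1 at each pixel.
#'
#' @param model a [CASNetModel-class].
#' @param image an (H, W) matrix, an (H, W, 1) array, or an (H, W, 1, N)
#'   batch; H and W must be divisible by \code{2^(depth - 1)}.
#' @return For a single image an (H, W, K) probability array; for a batch
#'   an (H, W, K, N) array.
#' @examples
#' m <- initCASNet(networkConfig(depth = 2, baseChannels = 4), seed = 1)
#' p <- casnetForward(m, matrix(0.5, 16, 16))
#' range(apply(p, c(1, 2), sum))
#' @export
casnetForward <- function(model, image) {
  single <- FALSE
  if (is.matrix(image)) {
    dim(image) <- c(dim(image), 1L, 1L)
    single <- TRUE
  } else if (length(dim(image)) == 3L) {
    dim(image) <- c(dim(image), 1L)
    single <- TRUE
  }
  stopifnot2(length(dim(image)) == 4L && dim(image)[3] == 1L,
             "image must be (H, W), (H, W, 1) or (H, W, 1, N)")
  out <- casnetFwd(model@params, model@state, model@config, image,
                   train = FALSE, keepCache = FALSE)
  if (single) fromBatch(out$prob) else out$prob
}
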