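test_that("forward pass produces pixelwise-normalised probability maps", {
  cfg <- networkConfig(depth = 3, baseChannels = 8, numClasses = 4,
                       attentionPoolThreshold = 64)
  m <- initCASNet(cfg, seed = 1)
  img <- matrix(runif(64 * 64), 64, 64)
  p <- casnetForward(m, img)
  expect_identical(dim(p), c(64L, 64L, 4L))
  expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-5)
  expect_true(all(p >= 0 & p <= 1))
  # indivisible input size is rejected
  expect_error(casnetForward(m, matrix(0.5, 63, 63)), "divisible")
})

test_that("initialisation is deterministic in the seed", {
  cfg <- tinyConfig()
  a <- initCASNet(cfg, seed = 42)
  b <- initCASNet(cfg, seed = 42)
  expect_identical(a@params, b@params)
  c <- initCASNet(cfg, seed = 43)
  expect_false(identical(a@params, c@params))
})

test_that("the double-off variant has exactly the plain backbone's parameters", {
  countFor <- function(useMSCB, useCASC) {
    parameterCount(initCASNet(
      networkConfig(depth = 3, baseChannels = 16, numClasses = 4,
                    useMSCB = useMSCB, useCASC = useCASC), seed = 1))
  }
  # analytic plain U-Net count, depth 3, base 16, 4 classes:
  # conv kh*kw*cin*cout + cout, BN 2 * cout per layer
  convN <- function(k, ci, co) k * k * ci * co + co
  bnN <- function(c) 2 * c
  unitN <- function(ci, co) convN(3, ci, co) + convN(3, co, co) + 2 * bnN(co)
  plain <- unitN(1, 16) + unitN(16, 32) +          # encoder
    unitN(32, 64) +                                # bottleneck
    (2 * 2 * 64 * 32 + 32) + unitN(64, 32) +       # up2 + dec2 (concat)
    (2 * 2 * 32 * 16 + 16) + unitN(32, 16) +       # up1 + dec1 (concat)
    (1 * 1 * 16 * 4 + 4)                           # final
  expect_equal(countFor(FALSE, FALSE), plain)
  # switching modules on only ever adds parameters
  expect_gt(countFor(TRUE, FALSE), plain)
  expect_gt(countFor(FALSE, TRUE), plain)
  expect_gt(countFor(TRUE, TRUE), countFor(TRUE, FALSE))
})

test_that("scaling all logits preserves the per-pixel argmax", {
  set.seed(8)
  logits <- array(rnorm(16 * 16 * 4 * 1), dim = c(16, 16, 4, 1))
  p1 <- casnet:::softmaxChannels(logits)
  p2 <- casnet:::softmaxChannels(2 * logits)
  am <- function(p) apply(p[, , , 1], c(1, 2), which.max)
  expect_identical(am(p1), am(p2))
  # sharper: the winning probability does not decrease
  expect_true(all(apply(p2[, , , 1], c(1, 2), max) >=
                    apply(p1[, , , 1], c(1, 2), max) - 1e-12))
})

test_that("network backward pass matches finite differences", {
  # double-precision kernels for a clean finite-difference comparison
  withr::local_options(casnet.fp32 = FALSE)
  set.seed(11)
  cfg <- tinyConfig(useMSCB = TRUE, useCASC = TRUE)
  model <- initCASNet(cfg, seed = 3)
  H <- 8
  x <- array(runif(H * H * 2), dim = c(H, H, 1, 2))
  masks <- list(randomMask(H, H, 3, seed = 5), randomMask(H, H, 3, seed = 6))
  w <- lossWeights()
  lossOf <- function(params) {
    out <- casnet:::casnetFwd(params, model@state, cfg, x, train = TRUE)
    tot <- 0
    for (i in 1:2) {
      p <- out$prob[, , , i]
      dim(p) <- c(H, H, 3)
      tot <- tot + compositeLoss(p, masks[[i]], w)
    }
    tot / 2
  }
  out <- casnet:::casnetFwd(model@params, model@state, cfg, x, train = TRUE)
  dprob <- array(0, dim = dim(out$prob))
  for (i in 1:2) {
    p <- out$prob[, , , i]
    dim(p) <- c(H, H, 3)
    dprob[, , , i] <- casnet:::compositeLossGrad(p, masks[[i]], w) / 2
  }
  grads <- casnet:::casnetBwd(model@params, cfg, out$cache, dprob)
  eps <- 1e-5
  params <- model@params
  # probe a parameter in every module family
  probes <- c("enc1.c1.w", "enc1.n2.gamma", "bott.c2.w", "mscb.c5.w",
              "mscb.cf.b", "dec1.up.w", "dec1.att.q.w", "dec1.att.v.w",
              "dec1.att.f.w", "dec1.c1.w", "dec1.n1.beta", "final.w")
  for (nm in probes) {
    idx <- which.max(abs(grads[[nm]]))
    pp <- params; pp[[nm]][idx] <- pp[[nm]][idx] + eps
    pm <- params; pm[[nm]][idx] <- pm[[nm]][idx] - eps
    num <- (lossOf(pp) - lossOf(pm)) / (2 * eps)
    expect_equal(grads[[nm]][idx], num, tolerance = 1e-3,
                 label = paste("gradient of", nm))
  }
})

test_that("shape contracts hold through MSCB and CASC inside the network", {
  cfg <- networkConfig(depth = 2, baseChannels = 8, numClasses = 2,
                       useMSCB = TRUE, useCASC = TRUE,
                       attentionPoolThreshold = 9)
  m <- initCASNet(cfg, seed = 2)
  # attention pooling path: 16x16 skip level exceeds the 9-position
  # threshold, so keys/values are pooled while the output stays full size
  p <- casnetForward(m, matrix(runif(16 * 16), 16, 16))
  expect_identical(dim(p), c(16L, 16L, 2L))
  expect_identical(casnet:::poolFactor(16L, 16L, 9L), 8L)
  expect_identical(casnet:::poolFactor(4L, 4L, 16L), 1L)
})
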