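test_that("discrete Hessian has the expected closed forms", {
  # constant map: all four fields zero
  h <- hessianField(matrix(2.5, 6, 6))
  expect_true(all(h == 0))

  # affine map: zero Hessian on interior pixels
  f <- outer(1:8, 1:8, function(i, j) 3 * i - 2 * j + 1)
  h <- hessianField(f)
  expect_true(all(abs(h[2:7, 2:7, ]) < 1e-12))

  # quadratic in the column coordinate: dxx = 2 exactly on the interior
  f <- outer(1:8, 1:8, function(i, j) j^2)
  h <- hessianField(f)
  expect_equal(unname(h[2:7, 2:7, 1]), matrix(2, 6, 6))
  expect_true(all(abs(h[2:7, 2:7, 2:4]) < 1e-12))

  # mixed partials are equal and the map must be at least 3x3
  expect_identical(h[, , 2], h[, , 3])
  expect_error(hessianField(matrix(0, 2, 5)), "3 x 3")
})

test_that("Hessian matches the brute-force oracle on random maps", {
  for (seed in 1:25) {
    set.seed(seed)
    f <- matrix(rnorm(64), 8, 8)
    expect_lt(max(abs(unname(hessianField(f)) - bruteHessian(f))), 1e-6)
  }
})

test_that("Hessian adjoint is the exact transpose of the forward operator", {
  # <H(f), g> == <f, H^T(g)> for random f, g
  for (seed in 1:5) {
    set.seed(seed)
    f <- matrix(rnorm(48), 6, 8)
    g <- array(rnorm(48 * 4), dim = c(6, 8, 4))
    lhs <- sum(hessianField(f) * g)
    rhs <- sum(f * casnet:::hessianAdjoint(g))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("curvature loss closed forms and invariances hold", {
  expect_identical(curvatureLoss(matrix(0.7, 8, 8)), 0)

  # f = j^2 / s: interior-only loss is exactly (2/s)^2
  s <- 100
  f <- outer(1:12, 1:12, function(i, j) j^2 / s)
  expect_equal(curvatureLoss(f, interiorOnly = TRUE), 4 / s^2,
               tolerance = 1e-12)

  # rotation / flip invariance
  set.seed(3)
  disk <- outer(1:16, 1:16, function(i, j)
    as.numeric((i - 8.5)^2 + (j - 8.5)^2 < 25))
  sm <- 0.25 * (disk + disk[c(1, 1:15), ] + disk[, c(1, 1:15)] +
                  disk[c(1, 1:15), c(1, 1:15)])
  base <- curvatureLoss(sm)
  expect_equal(curvatureLoss(t(sm)[, 16:1]), base, tolerance = 1e-5)  # 90 deg
  expect_equal(curvatureLoss(sm[16:1, ]), base, tolerance = 1e-5)    # flip
  expect_equal(curvatureLoss(sm[, 16:1]), base, tolerance = 1e-5)
})

test_that("Gaussian smoothing of a binary disk strictly decreases curvature", {
  n <- 32
  disk <- outer(1:n, 1:n, function(i, j)
    as.numeric((i - n / 2 - 0.5)^2 + (j - n / 2 - 0.5)^2 < 64))
  gaussKernel <- function(sigma) {
    r <- ceiling(3 * sigma)
    k <- outer(-r:r, -r:r, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
    k / sum(k)
  }
  smooth <- function(m, sigma) {
    k <- gaussKernel(sigma)
    r <- (nrow(k) - 1) / 2
    P <- m
    for (rep in seq_len(r)) P <- casnet:::padReplicate(P)
    out <- matrix(0, nrow(m), ncol(m))
    for (a in -r:r) for (b in -r:r)
      out <- out + k[a + r + 1, b + r + 1] *
        P[(1 + r + a):(nrow(m) + r + a), (1 + r + b):(ncol(m) + r + b)]
    out
  }
  losses <- c(curvatureLoss(disk),
              vapply(c(0.5, 1, 1.5, 2, 2.5),
                     function(s) curvatureLoss(smooth(disk, s)), numeric(1)))
  expect_true(all(diff(losses) < 0))
})

test_that("soft Dice loss matches its closed forms", {
  # exact one-hot prediction on a large region: loss ~ 0 (within the
  # smoothing-induced bound)
  m <- matrix(0L, 64, 64)
  m[, 1:32] <- 1L
  prob <- array(0, dim = c(64, 64, 2))
  prob[, , 2] <- (m == 1L)
  prob[, , 1] <- 1 - prob[, , 2]
  expect_lt(diceLoss(prob, m), 1e-3)

  # uniform 0.5 prediction, half-foreground truth: soft Dice coefficient 0.5
  probU <- array(0.5, dim = c(64, 64, 2))
  expect_equal(diceLoss(probU, m), 0.5, tolerance = 1e-3)

  # disjoint prediction and truth: loss -> 1 as regions grow
  probD <- array(0, dim = c(64, 64, 2))
  probD[, , 2] <- (m == 0L)
  probD[, , 1] <- 1 - probD[, , 2]
  expect_gt(diceLoss(probD, m), 0.999)

  expect_error(diceLoss(array(0.5, dim = c(4, 4, 2)), matrix(0L, 8, 8)),
               "mismatch")
})

test_that("binary cross-entropy matches its closed forms", {
  m <- randomMask(16, 16, 2, seed = 1)
  one <- array(0, dim = c(16, 16, 2))
  one[, , 2] <- (m == 1L)
  one[, , 1] <- 1 - one[, , 2]
  expect_lt(bceLoss(one, m), 1e-6)

  half <- array(0.5, dim = c(16, 16, 2))
  expect_equal(bceLoss(half, m), log(2), tolerance = 1e-12)

  worst <- 1 - one
  expect_equal(bceLoss(worst, m), -log(1e-7), tolerance = 1e-3)
})

test_that("composite loss combines its terms linearly", {
  set.seed(4)
  prob <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  norm <- array(rep(apply(prob, c(1, 2), sum), 3), dim = dim(prob))
  prob <- prob / norm
  m <- randomMask(8, 8, 3, seed = 2)

  expect_equal(compositeLoss(prob, m, lossWeights(1, 0, 0)),
               bceLoss(prob, m))
  expect_equal(compositeLoss(prob, m, lossWeights(0, 1, 0)),
               diceLoss(prob, m))
  expect_equal(compositeLoss(prob, m, lossWeights(0, 0, 1)),
               curvatureLoss(prob))
  w <- lossWeights(0.5, 0.4, 0.1)
  expect_equal(compositeLoss(prob, m, w),
               0.5 * bceLoss(prob, m) + 0.4 * diceLoss(prob, m) +
                 0.1 * curvatureLoss(prob))
  # linear in each weight
  expect_equal(compositeLoss(prob, m, lossWeights(1.5, 1.2, 0.3)),
               3 * compositeLoss(prob, m, w))
  # constant probabilities have zero curvature penalty
  expect_identical(compositeLoss(array(0.5, dim = c(8, 8, 2)),
                                 matrix(0L, 8, 8), lossWeights(0, 0, 1)), 0)
  expect_error(compositeLoss(prob, m, lossWeights(-1, 0, 0)), "nonnegative")
})

test_that("analytic composite-loss gradient matches numerical differentiation", {
  set.seed(6)
  H <- 6; W <- 6; K <- 3
  prob <- array(runif(H * W * K, 0.1, 0.9), dim = c(H, W, K))
  m <- randomMask(H, W, K, seed = 3)
  w <- lossWeights()
  g <- casnet:::compositeLossGrad(prob, m, w)
  eps <- 1e-6
  for (trial in 1:30) {
    i <- sample(H, 1); j <- sample(W, 1); k <- sample(K, 1)
    pp <- prob; pp[i, j, k] <- pp[i, j, k] + eps
    pm <- prob; pm[i, j, k] <- pm[i, j, k] - eps
    num <- (compositeLoss(pp, m, w) - compositeLoss(pm, m, w)) / (2 * eps)
    expect_equal(g[i, j, k], num, tolerance = 1e-4)
  }
})
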