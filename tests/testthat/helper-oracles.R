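# Independent brute-force oracles used to check the fast implementations.

# Naive double-loop scaled dot-product attention.
naiveAttention <- function(Qm, Km) {
  n <- nrow(Qm); m <- nrow(Km); ca <- ncol(Qm)
  A <- matrix(0, n, m)
  for (i in seq_len(n)) {
    logits <- numeric(m)
    for (j in seq_len(m))
      logits[j] <- sum(Qm[i, ] * Km[j, ]) / sqrt(ca)
    e <- exp(logits - max(logits))
    A[i, ] <- e / sum(e)
  }
  A
}

# Brute-force central-difference Hessian with replicate padding, computed
# pixel by pixel from first principles.
bruteHessian <- function(f) {
  H <- nrow(f); W <- ncol(f)
  at <- function(i, j) f[min(max(i, 1), H), min(max(j, 1), W)]
  out <- array(0, dim = c(H, W, 4))
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      out[i, j, 1] <- at(i, j + 1) - 2 * at(i, j) + at(i, j - 1)
      out[i, j, 4] <- at(i + 1, j) - 2 * at(i, j) + at(i - 1, j)
      m <- (at(i + 1, j + 1) - at(i + 1, j - 1) -
              at(i - 1, j + 1) + at(i - 1, j - 1)) / 4
      out[i, j, 2] <- m
      out[i, j, 3] <- m
    }
  }
  out
}

# O(|A| * |B|) directed and symmetric contour distances.
bruteDirected <- function(a, b) {
  best <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    d <- Inf
    for (j in seq_len(nrow(b)))
      d <- min(d, sqrt(sum((a[i, ] - b[j, ])^2)))
    best[i] <- d
  }
  best
}

bruteHausdorff <- function(a, b)
  max(max(bruteDirected(a, b)), max(bruteDirected(b, a)))

bruteMAD <- function(a, b) mean(bruteDirected(a, b))

# Tiny deterministic network configuration used by architecture tests.
tinyConfig <- function(...) {
  networkConfig(depth = 2L, baseChannels = 4L, numClasses = 3L,
                attentionPoolThreshold = 16L, ...)
}

# Random label mask with all classes present.
randomMask <- function(H, W, K, seed) {
  withr::with_seed(seed, matrix(sample(0:(K - 1), H * W, replace = TRUE),
                                H, W))
}
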