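# Internal numerical helpers shared by the phantom generator, the network
# and the losses.

# Evaluate expr with the global RNG seeded at `seed`, restoring the caller's
# RNG state afterwards, so all generation is a pure function of its seed.
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive n reproducible child seeds from a master seed (kept below 2^31).
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Bilinear sampling of matrix `m` at fractional (row, col) positions.
# Coordinates are clamped to the image domain (replicate border).
bilinearSample <- function(m, ri, ci) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(ri, 1), H)
  ci <- pmin(pmax(ci, 1), W)
  r0 <- floor(ri); c0 <- floor(ci)
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  fr <- ri - r0; fc <- ci - c0
  m00 <- m[cbind(r0, c0)]; m10 <- m[cbind(r1, c0)]
  m01 <- m[cbind(r0, c1)]; m11 <- m[cbind(r1, c1)]
  (1 - fr) * (1 - fc) * m00 + fr * (1 - fc) * m10 +
    (1 - fr) * fc * m01 + fr * fc * m11
}

# Nearest-neighbour sampling (used for label masks).
nearestSample <- function(m, ri, ci) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(round(ri), 1), H)
  ci <- pmin(pmax(round(ci), 1), W)
  m[cbind(ri, ci)]
}

# Bilinearly upsample a small control grid to H x W (used for bias fields
# and elastic displacement fields). Control points span the full image.
upsampleGrid <- function(grid, H, W) {
  gh <- nrow(grid); gw <- ncol(grid)
  ri <- seq(1, gh, length.out = H)
  ci <- seq(1, gw, length.out = W)
  v <- bilinearSample(grid, rep(ri, times = W), rep(ci, each = H))
  matrix(v, nrow = H, ncol = W)
}

# Average-pool an (H, W, C, N) array by integer factor p in both spatial
# dimensions. p must divide H and W.
avgPool <- function(x, p) {
  if (p == 1L) return(x)
  d <- dim(x)
  H <- d[1]; W <- d[2]; CN <- prod(d[3:4])
  dim(x) <- c(p, H / p, W * CN)
  x <- colSums(x) / p                       # (H/p, W * CN)
  dim(x) <- c(H / p, p, (W / p) * CN)
  x <- aperm(x, c(2, 1, 3))
  x <- colSums(x) / p                       # (H/p, (W/p) * CN)
  dim(x) <- c(H / p, W / p, d[3], d[4])
  x
}

# Adjoint of avgPool: expand gradient back to (H, W, C, N), dividing by p^2.
avgUnpool <- function(g, p) {
  if (p == 1L) return(g)
  d <- dim(g)
  g <- g[rep(seq_len(d[1]), each = p), rep(seq_len(d[2]), each = p), , ,
         drop = FALSE] / (p * p)
  g
}

# Replicate-pad a matrix by one pixel on each side.
padReplicate <- function(m) {
  H <- nrow(m); W <- ncol(m)
  P <- matrix(0, H + 2, W + 2)
  P[2:(H + 1), 2:(W + 1)] <- m
  P[1, ] <- P[2, ]; P[H + 2, ] <- P[H + 1, ]
  P[, 1] <- P[, 2]; P[, W + 2] <- P[, W + 1]
  P
}

# Adjoint of padReplicate: fold the padded border back onto the edge cells.
foldReplicate <- function(P) {
  H <- nrow(P) - 2; W <- ncol(P) - 2
  Q <- P[2:(H + 1), , drop = FALSE]
  Q[1, ] <- Q[1, ] + P[1, ]
  Q[H, ] <- Q[H, ] + P[H + 2, ]
  R <- Q[, 2:(W + 1), drop = FALSE]
  R[, 1] <- R[, 1] + Q[, 1]
  R[, W] <- R[, W] + Q[, W + 2]
  R
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
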