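## Local-linear kernel smoothing on binned data.
##
## Raw observations are binned to the cells of the (equally spaced) output
## grid, but the exact within-cell moments (sums of x, x^2, x*y, ...) are kept,
## so a noiseless linear signal is reproduced exactly: the weighted least
## squares fit is exact for linear functions whatever the weights, as long as
## the moment sums are exact. Only the kernel is evaluated at cell centers,
## which makes the 2D surface smoother a set of small matrix products instead
## of a per-point loop over raw pairs.

epanechnikov <- function(u) ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0)

## kernel matrix between output grid points (rows) and bin centers (cols)
kernelMatrix <- function(grid, bw) epanechnikov(outer(grid, grid, "-") / bw)

binIndex <- function(x, grid) {
  dg <- grid[2L] - grid[1L]
  i <- as.integer(round((x - grid[1L]) / dg)) + 1L
  if (any(i < 1L | i > length(grid)))
    stop("observations outside the smoothing grid")
  i
}

checkEquallySpaced <- function(grid) {
  d <- diff(grid)
  if (max(d) - min(d) > 1e-8 * mean(d))
    stop("smoothing requires an equally spaced grid")
  invisible(grid)
}

## Local-linear smooth of scattered (x, y) evaluated on 'grid'.
## Returns the estimated regression function at each grid point.
locLinear1d <- function(x, y, grid, bw, w = NULL) {
  checkEquallySpaced(grid)
  if (bw <= 0) stop("'bw' must be positive")
  if (is.null(w)) w <- rep(1, length(x))
  b <- binIndex(x, grid)
  agg <- rowsum(cbind(w, w * x, w * x^2, w * y, w * x * y), b)
  M <- matrix(0, length(grid), 5L)
  M[as.integer(rownames(agg)), ] <- agg
  K <- kernelMatrix(grid, bw)
  A0 <- K %*% M[, 1L]; A1 <- K %*% M[, 2L]; A2 <- K %*% M[, 3L]
  B0 <- K %*% M[, 4L]; B1 <- K %*% M[, 5L]
  g <- grid
  S0 <- A0
  S1 <- A1 - g * A0
  S2 <- A2 - 2 * g * A1 + g^2 * A0
  T0 <- B0
  T1 <- B1 - g * B0
  den <- S0 * S2 - S1^2
  bad <- !(S0 > 0) | den <= 1e-10 * pmax(S0, 1)^2 * max(bw, 1)^2 * 1e-6
  if (any(bad))
    stop("no local support at ", sum(bad), " grid point(s); ",
         "increase the bandwidth (current bw = ", bw, ")")
  drop((S2 * T0 - S1 * T1) / den)
}

## Local-linear smooth of scattered surface values v at (s, t), evaluated on
## grid x grid. Product Epanechnikov kernel. Returns an ngrid x ngrid matrix.
locLinear2d <- function(s, t, v, grid, bw, w = NULL) {
  checkEquallySpaced(grid)
  if (bw <= 0) stop("'bw' must be positive")
  if (is.null(w)) w <- rep(1, length(s))
  ng <- length(grid)
  bs <- binIndex(s, grid); bt <- binIndex(t, grid)
  cell <- (bs - 1L) * ng + bt
  agg <- rowsum(cbind(w, w * s, w * t, w * s^2, w * t^2, w * s * t,
                      w * v, w * v * s, w * v * t), cell)
  idx <- as.integer(rownames(agg))
  Ms <- lapply(seq_len(9L), function(k) {
    m <- matrix(0, ng, ng)          # rows: t bins, cols: s bins
    m[idx] <- agg[, k]
    m
  })
  K <- kernelMatrix(grid, bw)
  ## A[i,j] = sum over cells of K(t_c - t_i) K(s_c - s_j) * moment; rows index
  ## the t coordinate of the output point, columns the s coordinate
  A <- lapply(Ms, function(m) K %*% m %*% t(K))
  t0 <- matrix(grid, ng, ng)        # t coordinate varies along rows
  s0 <- t(t0)                       # s coordinate varies along columns
  S00 <- A[[1L]]
  S10 <- A[[2L]] - s0 * A[[1L]]
  S01 <- A[[3L]] - t0 * A[[1L]]
  S20 <- A[[4L]] - 2 * s0 * A[[2L]] + s0^2 * A[[1L]]
  S02 <- A[[5L]] - 2 * t0 * A[[3L]] + t0^2 * A[[1L]]
  S11 <- A[[6L]] - s0 * A[[3L]] - t0 * A[[2L]] + s0 * t0 * A[[1L]]
  T00 <- A[[7L]]
  T10 <- A[[8L]] - s0 * A[[7L]]
  T01 <- A[[9L]] - t0 * A[[7L]]
  det <- S00 * (S20 * S02 - S11^2) - S10 * (S10 * S02 - S11 * S01) +
    S01 * (S10 * S11 - S20 * S01)
  num <- T00 * (S20 * S02 - S11^2) - S10 * (T10 * S02 - S11 * T01) +
    S01 * (T10 * S11 - S20 * T01)
  scale <- pmax(S00, 1)^3 * max(bw, 1)^4
  bad <- !(S00 > 0) | det <= 1e-12 * scale
  if (any(bad))
    stop("no local support at ", sum(bad), " surface point(s); ",
         "increase the bandwidth (current bw = ", bw, ")")
  num / det
}
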