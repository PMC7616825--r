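## Small numeric utilities shared across modules.

#' Trapezoid quadrature weights
#'
#' Weights \code{w} such that \code{sum(w * f(grid))} approximates
#' \code{integrate(f)} over the span of \code{grid}. The weights are positive
#' and sum to \code{diff(range(grid))}.
#'
#' @param grid strictly increasing numeric vector of time points.
#' @return numeric vector of weights, same length as \code{grid}.
#' @export
#' @examples
#' g <- seq(0, 50, length.out = 101)
#' sum(quadWeights(g) * g)  # ~ integral of t over [0,50] = 1250
quadWeights <- function(grid) {
  if (length(grid) < 2L || is.unsorted(grid, strictly = TRUE))
    stop("'grid' must be strictly increasing with at least two points")
  d <- diff(grid)
  c(d[1L], d[-1L] + d[-length(d)], d[length(d)]) / 2
}

## trapezoid integral of f (vector or matrix columns) on grid
trapz <- function(grid, f) {
  w <- quadWeights(grid)
  if (is.matrix(f)) as.vector(crossprod(f, w)) else sum(w * f)
}

#' Equally spaced time grid
#'
#' @param tMin,tMax domain endpoints.
#' @param n number of grid points.
#' @return numeric vector of \code{n} equally spaced points.
#' @export
timeGrid <- function(tMin = 0, tMax = 50, n = 101L) {
  if (tMax <= tMin) stop("'tMax' must exceed 'tMin'")
  if (n < 2L) stop("'n' must be at least 2")
  seq(tMin, tMax, length.out = n)
}

## column-wise cumulative sums without apply() overhead
colCumsum <- function(m) {
  cs <- matrix(cumsum(m), nrow(m), ncol(m))
  if (ncol(m) > 1L) {
    off <- c(0, cs[nrow(m), -ncol(m)])
    cs <- cs - rep(off, each = nrow(m))
  }
  cs
}

## linear interpolation of each column of 'curves' (defined on 'grid') at 'times';
## returns length(times) x ncol(curves)
interpCurves <- function(grid, curves, times) {
  curves <- as.matrix(curves)
  if (any(times < grid[1L] - 1e-9) || any(times > grid[length(grid)] + 1e-9))
    stop("interpolation times outside the curve grid")
  times <- pmin(pmax(times, grid[1L]), grid[length(grid)])
  i <- findInterval(times, grid, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(grid) - 1L)
  h <- (times - grid[i]) / (grid[i + 1L] - grid[i])
  curves[i, , drop = FALSE] * (1 - h) + curves[i + 1L, , drop = FALSE] * h
}

## all ordered within-group observation pairs for groups of sizes 'lens'
## (returns two index vectors into the concatenated records, including i==j pairs)
allPairsWithin <- function(lens) {
  lens <- as.integer(lens)
  offs <- cumsum(lens) - lens
  a <- unlist(lapply(lens, function(k) rep(seq_len(k), each = k)), use.names = FALSE)
  b <- unlist(lapply(lens, function(k) rep.int(seq_len(k), k)), use.names = FALSE)
  off <- rep.int(offs, lens * lens)
  list(i = a + off, j = b + off)
}

## mean-center columns of a matrix, dropping attributes
centerCols <- function(m) {
  m <- as.matrix(m)
  sweep(m, 2L, colMeans(m), check.margin = FALSE)
}

## symmetric inverse square root via eigendecomposition
symInvSqrt <- function(m, tol = 1e-12) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (any(e$values < tol * max(e$values)))
    stop("matrix is numerically singular; cannot form inverse square root")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

## draw integer sub-seeds from a master seed without disturbing the caller RNG
deriveSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
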