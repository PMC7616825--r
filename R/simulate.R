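#' Simulation configuration
#'
#' Parameters of the synthetic study design: \code{nSubjects} individuals,
#' \code{nVariants} independent biallelic variants with allele frequency
#' \code{maf} (dosages Binomial(2, maf)), a sinusoidal ("A") or linear
#' ("B", "C") time-varying genetic effect on the exposure, six outcome
#' scenarios encoding different effect-function shapes, domain
#' \code{[0, tMax]}, \code{nObs} randomly placed exposure measurements per
#' subject, and a dense simulation grid of \code{denseGridSize} points.
#' The default values reproduce the reference study conditions: n = 10000,
#' J = 30, maf = 0.3, 10 observations per subject on [0, 50], and a dense
#' grid of 501 points (0.1 time-unit spacing).
#'
#' The master \code{seed} is expanded into independent sub-seeds for
#' genotypes, genetic-effect coefficients, trajectory noise, observation-time
#' sampling and outcome noise, so each component can be regenerated
#' independently and reproducibly.
#'
#' @param nSubjects number of individuals (>= 2).
#' @param nVariants number of genetic variants J.
#' @param maf minor-allele frequency in (0, 1).
#' @param exposureScenario "A", "B" or "C".
#' @param outcomeScenario integer 1..6.
#' @param tMax domain endpoint T.
#' @param nObs sparse measurements per subject (>= 2).
#' @param denseGridSize dense simulation grid size (>= 50).
#' @param seed integer master seed.
#' @return a \code{SimConfig} list.
#' @export
#' @examples
#' cfg <- simConfig(nSubjects = 100, seed = 1)
simConfig <- function(nSubjects, nVariants = 30L, maf = 0.3,
                      exposureScenario = c("A", "B", "C"),
                      outcomeScenario = 3L, tMax = 50, nObs = 10L,
                      denseGridSize = 501L, seed = 1L) {
  exposureScenario <- match.arg(exposureScenario)
  if (nSubjects < 2L) stop("'nSubjects' must be at least 2")
  if (maf <= 0 || maf >= 1) stop("'maf' must be strictly between 0 and 1")
  if (tMax <= 0) stop("'tMax' must be positive")
  if (nObs < 2L) stop("'nObs' must be at least 2")
  if (denseGridSize < 50L) stop("'denseGridSize' must be at least 50")
  if (!outcomeScenario %in% 1:6) stop("'outcomeScenario' must be in 1..6")
  seeds <- deriveSeeds(as.integer(seed), 5L)
  structure(list(nSubjects = as.integer(nSubjects),
                 nVariants = as.integer(nVariants), maf = maf,
                 exposureScenario = exposureScenario,
                 outcomeScenario = as.integer(outcomeScenario),
                 tMax = tMax, nObs = as.integer(nObs),
                 denseGridSize = as.integer(denseGridSize),
                 seed = as.integer(seed),
                 subSeeds = list(genotypes = seeds[1L], alpha = seeds[2L],
                                 paths = seeds[3L], sampling = seeds[4L],
                                 outcome = seeds[5L])),
            class = "SimConfig")
}

denseGrid <- function(cfg) seq(0, cfg$tMax, length.out = cfg$denseGridSize)

#' Simulate genotype dosages
#'
#' Independent Binomial(2, maf) dosages for each subject and variant.
#'
#' @param cfg a \code{\link{simConfig}} object.
#' @return integer matrix (n x J) with column names \code{g1..gJ}.
#' @export
genGenotypes <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$subSeeds$genotypes)
  G <- matrix(rbinom(cfg$nSubjects * cfg$nVariants, 2L, cfg$maf),
              cfg$nSubjects, cfg$nVariants)
  dimnames(G) <- list(paste0("s", seq_len(cfg$nSubjects)),
                      paste0("g", seq_len(cfg$nVariants)))
  G
}

#' Time-varying genetic effect curves
#'
#' Per-variant coefficient curves \eqn{\alpha_j(t)} evaluated on a grid.
#' Scenario A: \eqn{\alpha_j(t) = 0.05 \sin(a_j t) + b_j} with
#' \eqn{a_j, b_j \sim U(-0.1, 0.1)}. Scenarios B and C:
#' \eqn{\alpha_j(t) = a_j + b_j t} with \eqn{a_j \sim U(-0.1, 0.1)} and slope
#' \eqn{b_j \sim U(-0.004, 0.004)} (B) or \eqn{U(-0.01, 0.01)} (C).
#'
#' @param cfg a \code{\link{simConfig}} object.
#' @param grid evaluation grid (defaults to the dense simulation grid).
#' @return list with \code{curves} (grid x J matrix), \code{a}, \code{b},
#'   \code{scenario}, \code{grid}.
#' @export
genAlpha <- function(cfg, grid = denseGrid(cfg)) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$subSeeds$alpha)
  J <- cfg$nVariants
  a <- runif(J, -0.1, 0.1)
  b <- switch(cfg$exposureScenario,
              A = runif(J, -0.1, 0.1),
              B = runif(J, -0.004, 0.004),
              C = runif(J, -0.01, 0.01))
  curves <- if (cfg$exposureScenario == "A") {
    0.05 * sin(outer(grid, a)) + rep(b, each = length(grid))
  } else {
    rep(a, each = length(grid)) + outer(grid, b)
  }
  list(curves = curves, a = a, b = b, scenario = cfg$exposureScenario,
       grid = grid)
}

## Wiener process matrix: n x length(grid), variance 'varEnd' at grid end,
## starting at 0 at grid[1]
rWiener <- function(n, grid, varEnd = 1) {
  dv <- diff(grid) / (grid[length(grid)] - grid[1L]) * varEnd
  inc <- matrix(rnorm(length(dv) * n, sd = sqrt(rep(dv, n))),
                length(dv), n)
  rbind(0, colCumsum(inc))  # (grid x n)
}

#' Simulate dense exposure and confounder paths
#'
#' Exposure paths
#' \eqn{X_i(t) = \sum_j \alpha_j(t) G_{ij} + U_{0i} + U_i(t) + \epsilon_{X,i}(t)}
#' on the dense grid, where \eqn{U_0 \sim N(0,1)} and \eqn{U(t)},
#' \eqn{\epsilon_X(t)} are independent Wiener processes scaled to have
#' variance 1 at the domain endpoint.
#'
#' @param cfg a \code{\link{simConfig}} object.
#' @param G genotype matrix from \code{\link{genGenotypes}}.
#' @param alpha coefficient curves from \code{\link{genAlpha}}, evaluated on
#'   the dense grid.
#' @return list with matrices \code{X}, \code{U}, \code{epsX} (n x grid),
#'   vector \code{U0}, \code{geneScore} (n x grid), and \code{grid}.
#' @export
genPaths <- function(cfg, G, alpha) {
  stopifnot(inherits(cfg, "SimConfig"))
  grid <- alpha$grid
  if (abs(grid[1L]) > 1e-9 || abs(grid[length(grid)] - cfg$tMax) > 1e-9)
    stop("coefficient curves must be evaluated on a grid covering [0, tMax]")
  n <- cfg$nSubjects
  set.seed(cfg$subSeeds$paths)
  U0 <- rnorm(n)
  U <- t(rWiener(n, grid))      # n x grid
  epsX <- t(rWiener(n, grid))
  geneScore <- G %*% t(alpha$curves)
  X <- geneScore + U0 + U + epsX
  list(X = X, U = U, epsX = epsX, U0 = U0, geneScore = geneScore, grid = grid)
}

#' Sparse observation sampling
#'
#' For each subject, draws \code{cfg$nObs} observation times uniformly at
#' random (without replacement) from the dense grid and reads the exposure
#' path at those times.
#'
#' @param paths dense paths from \code{\link{genPaths}}.
#' @param cfg a \code{\link{simConfig}} object.
#' @return long-format data frame (\code{subject_id}, \code{time},
#'   \code{value}) sorted by subject then time.
#' @export
sparseSample <- function(paths, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  ng <- length(paths$grid)
  if (cfg$nObs > ng) stop("'nObs' exceeds the dense grid size")
  n <- nrow(paths$X)
  set.seed(cfg$subSeeds$sampling)
  idx <- vapply(seq_len(n), function(i) sort(sample.int(ng, cfg$nObs)),
                integer(cfg$nObs))                     # nObs x n
  times <- paths$grid[as.vector(idx)]
  values <- paths$X[cbind(rep(seq_len(n), each = cfg$nObs), as.vector(idx))]
  data.frame(subject_id = paste0("s", rep(seq_len(n), each = cfg$nObs)),
             time = times, value = values, stringsAsFactors = FALSE)
}

#' True effect function of the outcome scenarios
#'
#' Scenario 1: null (0); 2: constant 0.1; 3: increasing \code{0.02 t};
#' 4: sign change \code{0.5 - 0.02 t}; 5: early-age only
#' \code{0.05 (20 - t)} for \code{t < 20}; 6: later-age only
#' \code{0.05 (t - 30)} for \code{t > 30}.
#'
#' @param scenario integer 1..6.
#' @param t times in [0, 50].
#' @return \eqn{\beta(t)} at \code{t}.
#' @export
#' @examples
#' trueBeta(3, 25)  # 0.5
trueBeta <- function(scenario, t) {
  if (!all(scenario %in% 1:6)) stop("'scenario' must be in 1..6")
  if (any(t < 0 | t > 50)) stop("'t' must lie in [0, 50]")
  switch(as.character(scenario),
         "1" = rep(0, length(t)),
         "2" = rep(0.1, length(t)),
         "3" = 0.02 * t,
         "4" = 0.5 - 0.02 * t,
         "5" = 0.05 * (20 - t) * (t < 20),
         "6" = 0.05 * (t - 30) * (t > 30))
}

#' Simulate the outcome
#'
#' \eqn{Y_i = \int_0^T \beta(t) X_i(t) dt + 10 (U_{0i} + U_i(T)) +
#' \epsilon_{Y,i}} with trapezoid quadrature on the dense grid and
#' \eqn{\epsilon_Y \sim N(0, 1)} (an independent Wiener process evaluated at
#' the domain endpoint).
#'
#' @param paths dense paths from \code{\link{genPaths}}.
#' @param cfg a \code{\link{simConfig}} object (supplies the outcome scenario
#'   and noise sub-seed).
#' @return numeric outcome vector, named by subject.
#' @export
genOutcome <- function(paths, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  grid <- paths$grid
  n <- nrow(paths$X)
  bw <- trueBeta(cfg$outcomeScenario, grid) * quadWeights(grid)
  integral <- drop(paths$X %*% bw)
  set.seed(cfg$subSeeds$outcome)
  epsY <- rnorm(n)
  y <- integral + 10 * (paths$U0 + paths$U[, length(grid)]) + epsY
  names(y) <- paste0("s", seq_len(n))
  y
}

#' Simulate a complete dataset
#'
#' Runs the full generator: genotypes, genetic-effect curves, dense paths,
#' sparse exposure records and outcome.
#'
#' @param cfg a \code{\link{simConfig}} object.
#' @param keepPaths keep the dense path matrices (memory-heavy at large n)?
#' @return list with \code{exposure} (long data frame), \code{genotypes}
#'   (n x J), \code{outcome} (named numeric), \code{alpha}, \code{cfg}, and
#'   optionally \code{paths}.
#' @export
simulateDataset <- function(cfg, keepPaths = FALSE) {
  G <- genGenotypes(cfg)
  alpha <- genAlpha(cfg)
  paths <- genPaths(cfg, G, alpha)
  exposure <- sparseSample(paths, cfg)
  y <- genOutcome(paths, cfg)
  out <- list(exposure = exposure, genotypes = G, outcome = y, alpha = alpha,
              cfg = cfg)
  if (keepPaths) out$paths <- paths
  out
}

#' Per-timepoint genetic variance explained
#'
#' At each dense grid point, the R-squared from regressing the exposure
#' \eqn{X(t)} on all genotype dosages; used to verify the design calibration
#' (about 5\% of single-timepoint exposure variance explained by the variants
#' in the sinusoidal and weak-linear scenarios).
#'
#' @param paths dense paths from \code{\link{genPaths}}.
#' @param G genotype matrix.
#' @return numeric vector of R-squared values along the grid.
#' @export
geneticR2 <- function(paths, G) {
  Gc <- centerCols(G)
  Q <- qr.Q(qr(Gc))
  Xc <- centerCols(paths$X)
  fitted2 <- colSums(crossprod(Q, Xc)^2)
  total <- colSums(Xc^2)
  fitted2 / total
}
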