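#' @include utils.R
NULL

#' Sparse functional principal component model
#'
#' Result of \code{\link{fitFpca}}: the estimated mean curve, eigenfunctions,
#' eigenvalues, measurement-noise variance and per-subject PACE scores of a
#' sparsely observed exposure process on a common grid.
#'
#' @slot grid numeric, strictly increasing evaluation grid spanning the domain.
#' @slot mu numeric, mean curve on \code{grid}.
#' @slot phi matrix (grid x K) of eigenfunctions, orthonormal under trapezoid
#'   quadrature.
#' @slot lambda numeric, eigenvalues in strictly decreasing order.
#' @slot sigma2 non-negative scalar measurement-error variance.
#' @slot scores matrix (n x K) of conditional-expectation (PACE) scores.
#' @slot fve numeric, cumulative fraction of variance explained.
#' @slot subjectIds character, subject identifiers aligned with rows of
#'   \code{scores}.
#' @export
setClass("FpcaModel",
  representation(grid = "numeric", mu = "numeric", phi = "matrix",
                 lambda = "numeric", sigma2 = "numeric", scores = "matrix",
                 fve = "numeric", subjectIds = "character"),
  validity = function(object) {
    msg <- character()
    if (is.unsorted(object@grid, strictly = TRUE))
      msg <- c(msg, "grid must be strictly increasing")
    if (length(object@mu) != length(object@grid))
      msg <- c(msg, "mu and grid lengths differ")
    if (nrow(object@phi) != length(object@grid))
      msg <- c(msg, "phi must have one row per grid point")
    if (ncol(object@phi) != length(object@lambda))
      msg <- c(msg, "number of eigenfunctions and eigenvalues differ")
    if (length(object@lambda) > 1L && any(diff(object@lambda) >= 0))
      msg <- c(msg, "eigenvalues must be strictly decreasing")
    if (any(object@lambda < 0)) msg <- c(msg, "eigenvalues must be non-negative")
    if (object@sigma2 < 0) msg <- c(msg, "sigma2 must be non-negative")
    if (ncol(object@scores) != length(object@lambda))
      msg <- c(msg, "scores must have one column per component")
    if (length(object@fve) && (is.unsorted(object@fve) || any(object@fve > 1 + 1e-8)))
      msg <- c(msg, "fve must be non-decreasing and at most 1")
    if (length(msg)) msg else TRUE
  })

#' Basis set for the effect function
#'
#' Basis curves \eqn{b_l(t)} used to parameterise
#' \eqn{\beta(t) = \sum_l \gamma_l b_l(t)}. Polynomial bases are evaluated on
#' the rescaled time \eqn{u = t/T} for conditioning; see
#' \code{\link{makeBasis}}.
#'
#' @slot kind "eigenfunction", "polynomial" or "custom".
#' @slot curves matrix (grid x L) of basis curves.
#' @slot grid numeric evaluation grid.
#' @slot degree integer, polynomial degree (NA otherwise).
#' @export
setClass("EffectBasis",
  representation(kind = "character", curves = "matrix", grid = "numeric",
                 degree = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("eigenfunction", "polynomial", "custom"))
      msg <- c(msg, "unknown basis kind")
    if (nrow(object@curves) != length(object@grid))
      msg <- c(msg, "curves must have one row per grid point")
    if (ncol(object@curves) < 1L) msg <- c(msg, "at least one basis curve required")
    if (!all(is.finite(object@curves))) msg <- c(msg, "basis curves must be finite")
    if (length(msg)) msg else TRUE
  })

#' Instrumental-variable data block
#'
#' Mean-centered instruments, pseudo-exposures and outcome, aligned by subject.
#' Built by \code{\link{buildIvData}}.
#'
#' @slot Z matrix (n x J) of centered instruments.
#' @slot E matrix (n x L) of centered (possibly transformed) pseudo-exposures.
#' @slot y numeric, centered outcome.
#' @export
setClass("IvData",
  representation(Z = "matrix", E = "matrix", y = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@y)
    if (nrow(object@Z) != n || nrow(object@E) != n)
      msg <- c(msg, "Z, E and y must have matching rows")
    if (max(abs(colMeans(object@Z))) > 1e-8 * max(1, max(abs(object@Z))) ||
        max(abs(colMeans(object@E))) > 1e-8 * max(1, max(abs(object@E))))
      msg <- c(msg, "columns must be mean-centered")
    if (ncol(object@Z) < ncol(object@E))
      msg <- c(msg, "need at least as many instruments as exposures")
    if (n <= ncol(object@Z)) msg <- c(msg, "need more subjects than instruments")
    if (length(msg)) msg else TRUE
  })

#' Fitted MPCMR (or association) model
#'
#' Coefficients on the pseudo-exposure scale together with their covariance,
#' the moment Jacobian and the weighting matrix at the fit.
#'
#' @slot estimate numeric, fitted coefficients (\eqn{\beta^*} or \eqn{\gamma}).
#' @slot Sigma covariance matrix of \code{estimate} (estimate scale).
#' @slot Ghat Jacobian of the moment vector, \eqn{-E_n(Z \xi')}.
#' @slot Omega weighting matrix evaluated at the fit.
#' @slot objective continuously-updating GMM objective at the fit
#'   (\code{NA} for association fits).
#' @slot method "cue_gmm" or "association".
#' @slot n sample size.
#' @slot converged logical.
#' @export
setClass("MpcmrFit",
  representation(estimate = "numeric", Sigma = "matrix", Ghat = "matrix",
                 Omega = "matrix", objective = "numeric", method = "character",
                 n = "integer", converged = "logical"),
  validity = function(object) {
    msg <- character()
    L <- length(object@estimate)
    if (!all(dim(object@Sigma) == L)) msg <- c(msg, "Sigma dimension mismatch")
    if (max(abs(object@Sigma - t(object@Sigma))) > 1e-8 * max(1, max(abs(object@Sigma))))
      msg <- c(msg, "Sigma must be symmetric")
    if (any(diag(object@Sigma) < -1e-12)) msg <- c(msg, "Sigma must be psd")
    if (!is.na(object@objective) && object@objective < -1e-8)
      msg <- c(msg, "objective must be non-negative")
    if (!object@method %in% c("cue_gmm", "association"))
      msg <- c(msg, "unknown method")
    if (length(msg)) msg else TRUE
  })

#' Reconstructed effect curve
#'
#' Pointwise effect function estimate \eqn{\hat\beta(t)} with standard errors
#' and 95\% Wald bounds. Coerce with \code{as.data.frame}.
#'
#' @slot grid numeric evaluation grid.
#' @slot beta numeric, \eqn{\hat\beta(t)}.
#' @slot se numeric, pointwise standard errors.
#' @slot lo,hi numeric, pointwise 95\% Wald bounds.
#' @slot basisKind character, basis used for reconstruction.
#' @export
setClass("EffectCurve",
  representation(grid = "numeric", beta = "numeric", se = "numeric",
                 lo = "numeric", hi = "numeric", basisKind = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@grid)
    if (any(lengths(list(object@beta, object@se, object@lo, object@hi)) != n))
      msg <- c(msg, "component lengths differ")
    if (any(object@se < 0)) msg <- c(msg, "se must be non-negative")
    if (any(object@lo > object@beta + 1e-8) || any(object@hi < object@beta - 1e-8))
      msg <- c(msg, "bounds must bracket the estimate")
    if (length(msg)) msg else TRUE
  })

#' LM-test confidence region on a parameter lattice
#'
#' Candidate parameter values with their Kleibergen LM statistics and
#' acceptance indicators at level \code{alpha}. The accepted set may be empty
#' or disconnected; both are representable.
#'
#' @slot candidates matrix (m^L x L) of candidate parameter values.
#' @slot lm numeric, LM statistic at each candidate.
#' @slot accepted logical, LM below the chi-square cutoff.
#' @slot alpha test level.
#' @slot df degrees of freedom of the reference chi-square.
#' @export
setClass("LmRegion",
  representation(candidates = "matrix", lm = "numeric", accepted = "logical",
                 alpha = "numeric", df = "integer"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@candidates) != length(object@lm) ||
        length(object@lm) != length(object@accepted))
      msg <- c(msg, "candidates, lm and accepted lengths differ")
    if (any(object@lm < -1e-10, na.rm = TRUE)) msg <- c(msg, "LM values must be non-negative")
    if (object@alpha <= 0 || object@alpha >= 1) msg <- c(msg, "alpha must be in (0,1)")
    if (length(msg)) msg else TRUE
  })

## ------------------------------------------------------------------ show ----

setMethod("show", "FpcaModel", function(object) {
  K <- length(object@lambda)
  cat("FpcaModel:", K, "component(s),", nrow(object@scores), "subjects\n")
  cat("  domain [", min(object@grid), ",", max(object@grid), "] on",
      length(object@grid), "grid points\n")
  cat("  eigenvalues:", paste(signif(object@lambda, 4), collapse = ", "), "\n")
  cat("  FVE:", paste(sprintf("%.1f%%", 100 * object@fve[seq_len(min(4, length(object@fve)))]),
                      collapse = ", "),
      if (length(object@fve) > 4) "...\n" else "\n")
  cat("  noise variance:", signif(object@sigma2, 4), "\n")
})

setMethod("show", "EffectBasis", function(object) {
  cat("EffectBasis:", object@kind,
      if (!is.na(object@degree)) paste0("(degree ", object@degree, ")"), "with",
      ncol(object@curves), "curve(s) on", length(object@grid), "grid points\n")
})

setMethod("show", "IvData", function(object) {
  cat("IvData:", length(object@y), "subjects,", ncol(object@Z), "instruments,",
      ncol(object@E), "pseudo-exposure(s)\n")
})

setMethod("show", "MpcmrFit", function(object) {
  cat("MpcmrFit (", object@method, "), n = ", object@n, "\n", sep = "")
  est <- object@estimate
  se <- sqrt(pmax(diag(object@Sigma), 0))
  for (l in seq_along(est))
    cat(sprintf("  gamma[%d] = %9.5f  (se %.5f)\n", l, est[l], se[l]))
  if (!is.na(object@objective))
    cat("  CUE objective:", signif(object@objective, 5), "\n")
})

setMethod("show", "EffectCurve", function(object) {
  cat("EffectCurve on [", min(object@grid), ",", max(object@grid), "] (",
      length(object@grid), " points), basis: ", object@basisKind, "\n", sep = "")
  mid <- interpCurves(object@grid, cbind(object@beta, object@se),
                      mean(range(object@grid)))
  cat(sprintf("  beta at domain midpoint: %.4f (se %.4f)\n", mid[1], mid[2]))
})

setMethod("show", "LmRegion", function(object) {
  cat("LmRegion:", nrow(object@candidates), "candidates,",
      sum(object@accepted), "accepted at level", object@alpha,
      "(df =", object@df, ")\n")
})
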