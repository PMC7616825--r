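## Continuously-updating GMM estimation of the pseudo-exposure model, the
## naive association fit, and effect-curve reconstruction.

#' Assemble an instrumental-variable data block
#'
#' Aligns instruments, pseudo-exposures and outcome by subject identifier
#' (row names / names) when available, drops subjects missing from any block,
#' removes zero-variance instrument columns with a warning, and mean-centers
#' every column.
#'
#' @param Z instrument (genotype dosage) matrix, rows named by subject.
#' @param E pseudo-exposure score matrix (\eqn{\xi} or \eqn{\xi^*}).
#' @param y outcome vector, named by subject when alignment is needed.
#' @return an \code{\linkS4class{IvData}}.
#' @export
buildIvData <- function(Z, E, y) {
  Z <- as.matrix(Z); E <- as.matrix(E)
  if (!is.null(rownames(Z)) && !is.null(rownames(E)) && !is.null(names(y))) {
    ## sorted ids: the result is invariant to the input row order
    ids <- sort(intersect(intersect(rownames(Z), rownames(E)), names(y)))
    dropped <- max(nrow(Z), nrow(E), length(y)) - length(ids)
    if (dropped > 0)
      message(dropped, " subject(s) missing from at least one block; dropped")
    Z <- Z[ids, , drop = FALSE]
    E <- E[ids, , drop = FALSE]
    y <- y[ids]
  } else if (nrow(Z) != nrow(E) || nrow(Z) != length(y)) {
    stop("unnamed inputs must already be row-aligned")
  }
  keep <- apply(Z, 2L, function(col) var(col) > 0)
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance instrument column(s) dropped")
    Z <- Z[, keep, drop = FALSE]
  }
  if (ncol(Z) < ncol(E))
    stop("fewer instruments than pseudo-exposures after alignment; ",
         "the model is not identified")
  new("IvData", Z = centerCols(Z), E = centerCols(E),
      y = as.vector(y) - mean(y))
}

#' Continuously-updating GMM fit
#'
#' Minimises the continuously-updating objective
#' \eqn{n\, \hat g(\beta)' \hat\Omega(\beta)^{-1} \hat g(\beta)} with moment
#' vector \eqn{\hat g(\beta) = E_n(Z(Y - \xi'\beta))} and homoskedastic
#' weighting \eqn{\hat\Omega(\beta) = E_n(ZZ') E_n((Y - \xi'\beta)^2)}.
#' Because the weighting factorises into a fixed matrix times a scalar
#' residual variance, the minimisation is performed by iterated linear GMM
#' steps with the scale re-evaluated at each iterate (convergence declared at
#' relative change below 1e-10, maximum 200 iterations); with this weighting
#' the iteration is stationary at the two-stage least squares solution.
#' The reported covariance is
#' \eqn{\hat\Sigma = (\hat G' \hat\Omega(\hat\beta)^{-1} \hat G)^{-1} / n},
#' on the estimate scale.
#'
#' @param data an \code{\linkS4class{IvData}}.
#' @return an \code{\linkS4class{MpcmrFit}} with \code{method = "cue_gmm"}.
#' @export
cueGmm <- function(data) {
  Z <- data@Z; E <- data@E; y <- data@y
  n <- length(y)
  J <- ncol(Z); L <- ncol(E)
  Czz <- crossprod(Z) / n
  Czy <- crossprod(Z, y) / n
  Cze <- crossprod(Z, E) / n
  Ghat <- -Cze
  CzzInv <- tryCatch(solve(Czz), error = function(e)
    stop("instrument second-moment matrix is singular"))
  ## start: 2SLS via the linear GMM step with unit scale
  A <- crossprod(Cze, CzzInv)              # L x J
  M <- A %*% Cze                           # L x L
  if (rcond(M) < 1e-12)
    stop("G'Omega^{-1}G is numerically singular: conditionally weak or ",
         "collinear pseudo-exposures; see the identification-robust tools")
  beta <- drop(solve(M, A %*% Czy))
  sigma2 <- mean((y - E %*% beta)^2)
  converged <- FALSE
  for (iter in seq_len(200L)) {
    ## linear GMM step under Omega = Czz * sigma2 (the scalar cancels in the
    ## minimiser but is part of the continuously-updating objective)
    betaNew <- drop(solve(M, A %*% Czy))
    sigma2New <- mean((y - E %*% betaNew)^2)
    rel <- max(abs(betaNew - beta) / pmax(abs(beta), 1e-8),
               abs(sigma2New - sigma2) / max(sigma2, 1e-12))
    beta <- betaNew; sigma2 <- sigma2New
    if (rel < 1e-10) { converged <- TRUE; break }
  }
  if (!converged)
    warning("continuously-updating iteration did not converge; ",
            "returning the best iterate")
  Omega <- Czz * sigma2
  g <- Czy - Cze %*% beta
  ## a numerically perfect fit makes the objective 0/0; define it as 0
  quad <- drop(n * crossprod(g, CzzInv %*% g))
  objective <- if (sigma2 < 1e-14 * mean(y^2)) 0 else quad / sigma2
  GtOiG <- crossprod(Cze, CzzInv %*% Cze) / sigma2
  Sigma <- solve(GtOiG) / n
  new("MpcmrFit", estimate = setNames(as.vector(beta), colnames(E)),
      Sigma = (Sigma + t(Sigma)) / 2, Ghat = Ghat, Omega = Omega,
      objective = max(objective, 0), method = "cue_gmm", n = as.integer(n),
      converged = converged)
}

#' Naive association fit
#'
#' Ordinary least squares of the centered outcome on the centered
#' pseudo-exposure scores, without instruments. Used as the confounded
#' comparator for the instrumented fit.
#'
#' @param E score matrix (n x L).
#' @param y outcome vector.
#' @return an \code{\linkS4class{MpcmrFit}} with \code{method = "association"}.
#' @export
associationFit <- function(E, y) {
  E <- centerCols(E); y <- as.vector(y) - mean(y)
  n <- length(y)
  if (n <= ncol(E)) stop("need more subjects than pseudo-exposures")
  XtX <- crossprod(E)
  if (rcond(XtX) < 1e-12) stop("rank-deficient score design")
  beta <- drop(solve(XtX, crossprod(E, y)))
  resid <- y - E %*% beta
  s2 <- sum(resid^2) / (n - ncol(E))
  Sigma <- s2 * solve(XtX)
  new("MpcmrFit", estimate = setNames(beta, colnames(E)),
      Sigma = (Sigma + t(Sigma)) / 2, Ghat = -XtX / n, Omega = XtX / n * s2,
      objective = NA_real_, method = "association", n = as.integer(n),
      converged = TRUE)
}

#' Reconstruct the effect curve from fitted coefficients
#'
#' \eqn{\hat\beta(t) = \sum_l b_l(t)\hat\gamma_l} with pointwise standard
#' error \eqn{\hat\sigma(t) = \sqrt{b(t)'\hat\Sigma b(t)}} and 95\% Wald
#' bounds.
#'
#' @param fit an \code{\linkS4class{MpcmrFit}} with L coefficients.
#' @param basis the \code{\linkS4class{EffectBasis}} used in fitting (L
#'   curves).
#' @return an \code{\linkS4class{EffectCurve}}.
#' @export
reconstructEffect <- function(fit, basis) {
  Bm <- basis@curves
  if (ncol(Bm) != length(fit@estimate))
    stop("basis dimension does not match the fitted coefficients")
  beta <- drop(Bm %*% fit@estimate)
  se <- sqrt(pmax(rowSums((Bm %*% fit@Sigma) * Bm), 0))
  z <- qnorm(0.975)
  new("EffectCurve", grid = basis@grid, beta = beta, se = se,
      lo = beta - z * se, hi = beta + z * se, basisKind = basis@kind)
}

#' Effect of a known trajectory intervention
#'
#' For an intervention curve \eqn{a(t)} added to the exposure trajectory, the
#' mean outcome shift is \eqn{\int_0^T \beta(t) a(t) dt}; its standard error
#' follows from the linear functional \eqn{w_l = \int b_l(t) a(t) dt} of the
#' fitted coefficients.
#'
#' @param fit an \code{\linkS4class{MpcmrFit}}.
#' @param basis the basis used in fitting.
#' @param a intervention curve evaluated on the basis grid.
#' @return list with \code{estimate} and \code{se}.
#' @export
interventionEffect <- function(fit, basis, a) {
  if (length(a) != length(basis@grid))
    stop("intervention curve must be evaluated on the basis grid")
  w <- drop(crossprod(basis@curves, quadWeights(basis@grid) * a))
  list(estimate = sum(w * fit@estimate),
       se = sqrt(max(0, drop(crossprod(w, fit@Sigma %*% w)))))
}
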