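## Identification-robust inference: Kleibergen's Lagrange-multiplier
## statistic, lattice inversion to confidence regions, pointwise bands for
## the effect function, and the global causal null test.

## Precompute every moment needed to evaluate the LM statistic at many
## candidate parameter values. All pieces are linear or quadratic in beta0.
lmPrep <- function(data) {
  Z <- data@Z; E <- data@E; y <- data@y
  n <- length(y); L <- ncol(E)
  Czz <- crossprod(Z) / n
  CzzInvSqrt <- symInvSqrt(Czz)
  A0 <- lapply(seq_len(L), function(k) crossprod(Z * (E[, k] * y), Z) / n)
  A1 <- lapply(seq_len(L), function(k)
    lapply(seq_len(L), function(l) crossprod(Z * (E[, k] * E[, l]), Z) / n))
  list(n = n, J = ncol(Z), L = L,
       Czz = Czz, CzzInv = chol2inv(chol(Czz)), CzzInvSqrt = CzzInvSqrt,
       g0 = drop(crossprod(Z, y) / n), G1 = crossprod(Z, E) / n,
       yy = mean(y^2), Ey = drop(crossprod(E, y) / n), EE = crossprod(E) / n,
       A0 = A0, A1 = A1)
}

lmStatCore <- function(prep, beta0) {
  L <- prep$L
  sigma2 <- drop(prep$yy - 2 * sum(prep$Ey * beta0) +
                   crossprod(beta0, prep$EE %*% beta0))
  g <- prep$g0 - drop(prep$G1 %*% beta0)
  OmInvG <- drop(prep$CzzInv %*% g) / sigma2
  D <- matrix(0, prep$J, L)
  for (k in seq_len(L)) {
    Dk <- prep$A0[[k]]
    for (l in seq_len(L)) Dk <- Dk - prep$A1[[k]][[l]] * beta0[l]
    ## Delta_k(beta0) = -Dk; D_k = G_k - Delta_k' Omega^{-1} g
    D[, k] <- -prep$G1[, k] + drop(t(Dk) %*% OmInvG)
  }
  q <- drop(prep$CzzInvSqrt %*% g) / sqrt(sigma2)
  Dt <- prep$CzzInvSqrt %*% D / sqrt(sigma2)
  M <- crossprod(Dt)
  h <- drop(crossprod(Dt, q))
  df <- L
  lm <- tryCatch(drop(prep$n * crossprod(h, solve(M, h))),
                 error = function(e) NA_real_)
  if (is.na(lm)) {
    ## rank-deficient direction matrix: project onto its numerical range
    e <- eigen(M, symmetric = TRUE)
    keep <- e$values > max(e$values, 0) * 1e-10
    df <- sum(keep)
    if (df == 0L) return(list(lm = 0, df = 0L))
    hk <- drop(crossprod(e$vectors[, keep, drop = FALSE], h))
    lm <- drop(prep$n * sum(hk^2 / e$values[keep]))
  }
  list(lm = max(lm, 0), df = as.integer(df))
}

#' Kleibergen LM statistic at a candidate parameter
#'
#' Score-type statistic whose null distribution is chi-square with L degrees
#' of freedom regardless of instrument strength. Construction: the moment
#' vector \eqn{\hat g(\beta_0)} and homoskedastic weighting
#' \eqn{\hat\Omega(\beta_0)}; per-component covariance blocks
#' \eqn{\hat\Delta_k = E_n(-Z\xi_k(Y - \xi'\beta_0)Z')}; orthogonalised
#' Jacobian columns
#' \eqn{\hat D_k = \hat G_k - \hat\Delta_k'\hat\Omega^{-1}\hat g}; and the
#' quadratic form of \eqn{\hat\Omega^{-1/2}\sqrt n\, \hat g} projected onto
#' the span of \eqn{\hat\Omega^{-1/2}\hat D}. When that span is numerically
#' rank-deficient the projection uses its numerical range with
#' correspondingly reduced degrees of freedom (reported in the result).
#'
#' @param data an \code{\linkS4class{IvData}}.
#' @param beta0 candidate coefficient vector (length L).
#' @param alpha level used for the acceptance flag.
#' @return list with \code{lm}, \code{df}, \code{accepted}, \code{pvalue},
#'   \code{beta0}.
#' @export
lmStat <- function(data, beta0, alpha = 0.05) {
  beta0 <- as.numeric(beta0)
  if (length(beta0) != ncol(data@E))
    stop("'beta0' must have one entry per pseudo-exposure")
  prep <- lmPrep(data)
  res <- lmStatCore(prep, beta0)
  cut <- qchisq(1 - alpha, res$df)
  list(lm = res$lm, df = res$df, accepted = res$lm <= cut,
       pvalue = pchisq(res$lm, res$df, lower.tail = FALSE), beta0 = beta0)
}

#' LM confidence region by lattice inversion
#'
#' Evaluates the LM statistic over an \code{m^L} lattice centered at the
#' point estimate, spanning \code{width} standard errors in each coordinate,
#' and collects the candidates not rejected at level \code{alpha}. The
#' accepted set may be empty (a warning is raised: possible misspecification
#' or too-narrow search) or disconnected; it is reported as-is.
#'
#' @param data an \code{\linkS4class{IvData}}.
#' @param fit an \code{\linkS4class{MpcmrFit}} used to center and scale the
#'   lattice.
#' @param m lattice points per parameter (>= 2).
#' @param width half-width of the search region in standard errors.
#' @param alpha test level.
#' @return an \code{\linkS4class{LmRegion}}.
#' @export
lmRegion <- function(data, fit, m = 41L, width = 4, alpha = 0.05) {
  if (m < 2L) stop("'m' must be at least 2")
  est <- fit@estimate
  se <- sqrt(pmax(diag(fit@Sigma), 0))
  if (any(se == 0)) stop("degenerate standard errors; cannot build the lattice")
  axes <- lapply(seq_along(est), function(l)
    seq(est[l] - width * se[l], est[l] + width * se[l], length.out = m))
  cand <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  colnames(cand) <- names(est)
  prep <- lmPrep(data)
  vals <- numeric(nrow(cand))
  dfs <- integer(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- lmStatCore(prep, cand[i, ])
    vals[i] <- r$lm; dfs[i] <- r$df
  }
  df <- as.integer(ncol(data@E))
  accepted <- vals <= qchisq(1 - alpha, dfs) & dfs == df
  if (!any(accepted))
    warning("no lattice point accepted by the LM test; possible model ",
            "misspecification or too-narrow search region")
  new("LmRegion", candidates = cand, lm = vals, accepted = accepted,
      alpha = alpha, df = df)
}

#' Pointwise identification-robust band for the effect function
#'
#' For each time point, the band is the range of \eqn{b(t)'\beta_0} over all
#' accepted candidates of the LM region: the image of the parameter
#' confidence region under the linear curve map.
#'
#' @param region an \code{\linkS4class{LmRegion}} with a non-empty accepted
#'   set.
#' @param basis the \code{\linkS4class{EffectBasis}} used in fitting.
#' @return data frame with columns \code{t}, \code{lo}, \code{hi}.
#' @export
regionToBand <- function(region, basis) {
  acc <- acceptedSet(region)
  if (!nrow(acc))
    stop("LM region is empty; widen the search region before building a band")
  if (ncol(acc) != ncol(basis@curves))
    stop("region and basis dimensions do not match")
  vals <- basis@curves %*% t(acc)        # grid x nAccepted
  data.frame(t = basis@grid,
             lo = apply(vals, 1L, min),
             hi = apply(vals, 1L, max))
}

#' Global test of no causal effect over the whole time domain
#'
#' Evaluates the LM statistic at the zero coefficient vector; under the
#' global null of no effect at any time the statistic is chi-square with L
#' degrees of freedom.
#'
#' @param data an \code{\linkS4class{IvData}}.
#' @param alpha test level.
#' @return list with \code{statistic}, \code{df}, \code{pvalue},
#'   \code{reject}.
#' @export
globalNullTest <- function(data, alpha = 0.05) {
  res <- lmStat(data, rep(0, ncol(data@E)), alpha = alpha)
  list(statistic = res$lm, df = res$df, pvalue = res$pvalue,
       reject = !res$accepted)
}
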