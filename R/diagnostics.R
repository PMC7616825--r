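## Instrument-strength and validity diagnostics.

#' Conditional F-statistics for pseudo-exposures
#'
#' Sanderson-Windmeijer-type conditional instrument strength for each
#' pseudo-exposure in a multivariable IV model. For exposure k, the other
#' exposures are partialled out through their instrument-predicted values
#' (the two-stage least squares regression of \eqn{E_k} on \eqn{E_{-k}} with
#' instruments Z); the conditional F is the F-statistic of the instruments
#' in the regression of the resulting residual on Z, with the
#' degrees-of-freedom correction \eqn{J/(J - L + 1)} applied through the
#' numerator degrees of freedom. With a single exposure this reduces to the
#' ordinary first-stage F-statistic.
#'
#' @param Z instrument matrix (will be centered), or an
#'   \code{\linkS4class{IvData}} holding both blocks.
#' @param E pseudo-exposure matrix (will be centered); ignored when \code{Z}
#'   is an \code{IvData}.
#' @return numeric vector of conditional F-statistics, one per column of
#'   \code{E}.
#' @export
conditionalF <- function(Z, E) {
  if (is(Z, "IvData")) { E <- Z@E; Z <- Z@Z }
  Z <- centerCols(Z); E <- as.matrix(E); E <- centerCols(E)
  n <- nrow(Z); J <- ncol(Z); L <- ncol(E)
  if (J < L) stop("need at least as many instruments as exposures")
  if (n <= J + L) stop("sample too small for the conditional F computation")
  qrZ <- qr(Z)
  Ehat <- qr.fitted(qrZ, E)                     # instrument-predicted exposures
  vapply(seq_len(L), function(k) {
    if (L == 1L) {
      v <- E[, 1L]
    } else {
      others <- Ehat[, -k, drop = FALSE]
      delta <- qr.coef(qr(others), E[, k])      # 2SLS coefficient of E_k on E_-k
      v <- E[, k] - drop(others %*% delta)
    }
    fit <- qr.fitted(qrZ, v)
    ssr <- sum(fit^2)
    rss <- sum(v^2) - ssr
    ## numerator df J-L+1 applies the J/(J-L+1) correction to the plain
    ## J-instrument F; denominator df accounts for centering and the L-1
    ## partialled exposures
    (ssr / (J - L + 1)) / (rss / (n - J - L))
  }, numeric(1L))
}

#' Over-identification (Hansen J / Q) test
#'
#' The continuously-updating GMM objective evaluated at the fit, compared to
#' a chi-square with \eqn{J - L} degrees of freedom. Requires more
#' instruments than exposures; with \eqn{J = L} the test is not defined and
#' a not-applicable result is returned.
#'
#' @param data an \code{\linkS4class{IvData}}.
#' @param fit the corresponding \code{\linkS4class{MpcmrFit}}.
#' @return list with \code{statistic}, \code{df}, \code{pvalue},
#'   \code{applicable}.
#' @export
overidQ <- function(data, fit) {
  J <- ncol(data@Z); L <- ncol(data@E)
  if (J <= L)
    return(list(statistic = NA_real_, df = 0L, pvalue = NA_real_,
                applicable = FALSE))
  stat <- fit@objective
  if (is.na(stat)) stop("over-identification test requires a GMM fit")
  list(statistic = stat, df = as.integer(J - L),
       pvalue = pchisq(stat, J - L, lower.tail = FALSE), applicable = TRUE)
}

#' Time-varying genetic association curves
#'
#' Reconstructs each variant's association with the exposure over time from
#' its associations with the principal component scores:
#' \eqn{\hat\alpha_j(t) = \sum_k \widehat{cov}(Z_j, \xi_k) /
#' \widehat{var}(Z_j)\, \phi_k(t)}.
#'
#' @param Z instrument matrix (n x J), aligned with the score rows.
#' @param model an \code{\linkS4class{FpcaModel}} with scores.
#' @return matrix (grid x J) of association curves; zero-variance variants
#'   are dropped with a warning.
#' @export
alphaCurves <- function(Z, model) {
  Z <- as.matrix(Z)
  xi <- model@scores
  if (nrow(Z) != nrow(xi)) stop("instrument rows must align with the scores")
  v <- apply(Z, 2L, var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance variant(s) excluded")
    Z <- Z[, v > 0, drop = FALSE]
    v <- v[v > 0]
  }
  alphaK <- cov(Z, xi) / v                 # J x K
  out <- model@phi %*% t(alphaK)           # grid x J
  colnames(out) <- colnames(Z)
  out
}

#' Leave-one-out instrument contributions to the Q statistic
#'
#' Per-variant plumbing for heterogeneity assessment: the GMM objective
#' refitted with each instrument left out, and the drop relative to the full
#' fit.
#'
#' @param data an \code{\linkS4class{IvData}}.
#' @return data frame with \code{instrument}, \code{Q_without}, \code{dQ}.
#' @export
looInstrumentQ <- function(data) {
  J <- ncol(data@Z)
  if (J <= ncol(data@E) + 1L)
    stop("leave-one-out contributions need J > L + 1")
  full <- cueGmm(data)@objective
  qs <- vapply(seq_len(J), function(j) {
    d <- new("IvData", Z = data@Z[, -j, drop = FALSE], E = data@E, y = data@y)
    cueGmm(d)@objective
  }, numeric(1L))
  data.frame(instrument = colnames(data@Z) %||% paste0("g", seq_len(J)),
             Q_without = qs, dQ = full - qs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
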