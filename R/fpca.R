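## Sparse functional principal component analysis with PACE scores.

## validate and index long-format exposure records
checkLongData <- function(data) {
  need <- c("subject_id", "time", "value")
  if (!all(need %in% names(data)))
    stop("exposure data must have columns subject_id, time, value")
  if (!nrow(data)) stop("exposure data are empty")
  if (!all(is.finite(data$time)) || !all(is.finite(data$value)))
    stop("exposure times and values must be finite")
  data[order(data$subject_id, data$time), , drop = FALSE]
}

#' Mean-curve estimation for sparse longitudinal data
#'
#' Local-linear Epanechnikov smooth of the pooled (time, value) records,
#' evaluated on \code{grid}.
#'
#' @param data long-format data frame (\code{subject_id}, \code{time},
#'   \code{value}).
#' @param grid equally spaced evaluation grid covering the observation times.
#' @param bandwidth kernel bandwidth in time units.
#' @return numeric mean curve on \code{grid}.
#' @export
estimateMean <- function(data, grid, bandwidth) {
  data <- checkLongData(data)
  locLinear1d(data$time, data$value, grid, bandwidth)
}

#' Covariance-surface estimation
#'
#' Raw cross-products of mean-removed values from distinct observations of
#' the same subject are smoothed to a symmetric surface \eqn{G(s,t)} by 2D
#' local-linear smoothing. The measurement-error variance is estimated as the
#' average, over the central half of the domain, of the difference between
#' the smoothed diagonal of same-observation squared residuals and the
#' surface diagonal, floored at zero.
#'
#' @param data long-format exposure records.
#' @param mu mean curve on \code{grid} (from \code{\link{estimateMean}}).
#' @param grid equally spaced evaluation grid.
#' @param bandwidth kernel bandwidth for the surface smooth.
#' @return list with \code{surface} (grid x grid, symmetric), \code{sigma2},
#'   and \code{diagVar} (smoothed diagonal including the error variance).
#' @export
estimateCov <- function(data, mu, grid, bandwidth) {
  data <- checkLongData(data)
  lens <- as.integer(table(factor(data$subject_id,
                                  levels = unique(data$subject_id))))
  if (!any(lens >= 2L))
    stop("covariance estimation needs at least one subject with 2+ observations")
  resid <- data$value - drop(interpCurves(grid, matrix(mu), data$time))
  pairs <- allPairsWithin(lens)
  off <- pairs$i != pairs$j
  G <- locLinear2d(data$time[pairs$i][off], data$time[pairs$j][off],
                   (resid[pairs$i] * resid[pairs$j])[off], grid, bandwidth)
  G <- (G + t(G)) / 2
  diagVar <- locLinear1d(data$time, resid^2, grid, bandwidth)
  mid <- grid >= min(grid) + diff(range(grid)) / 4 &
    grid <= max(grid) - diff(range(grid)) / 4
  sigma2 <- max(0, mean(diagVar[mid] - diag(G)[mid]))
  list(surface = G, sigma2 = sigma2, diagVar = diagVar)
}

#' Eigen-decomposition of a covariance surface
#'
#' Solves the weighted eigenproblem of the covariance operator under
#' trapezoid quadrature. Eigenfunctions are normalised to unit
#' quadrature norm and sign-fixed so that \eqn{\int \phi_k(t)\, t\, dt \ge 0}
#' (ties broken by \eqn{\int \phi_k \ge 0}); negative eigenvalues are
#' dropped.
#'
#' @param surface symmetric covariance surface on \code{grid x grid}.
#' @param grid evaluation grid.
#' @param maxK maximum number of components returned.
#' @return list with \code{lambda} (decreasing, positive) and \code{phi}
#'   (grid x K).
#' @export
eigenDecompose <- function(surface, grid, maxK = 20L) {
  if (!all(is.finite(surface))) stop("covariance surface contains non-finite values")
  w <- quadWeights(grid)
  sw <- sqrt(w)
  S <- sw * t(sw * t((surface + t(surface)) / 2))
  e <- eigen(S, symmetric = TRUE)
  keep <- which(e$values > max(e$values) * 1e-12 & e$values > 0)
  keep <- head(keep, maxK)
  if (!length(keep)) stop("covariance surface has no positive eigenvalues")
  lambda <- e$values[keep]
  phi <- e$vectors[, keep, drop = FALSE] / sw
  for (k in seq_along(keep)) {
    s1 <- sum(w * phi[, k] * grid)
    s0 <- sum(w * phi[, k])
    if (s1 < 0 || (abs(s1) < 1e-10 && s0 < 0)) phi[, k] <- -phi[, k]
  }
  ## enforce strict ordering in case of exact ties
  ord <- order(lambda, decreasing = TRUE)
  list(lambda = lambda[ord], phi = phi[, ord, drop = FALSE])
}

#' Number of components for a variance-explained threshold
#'
#' @param lambda positive eigenvalues in decreasing order.
#' @param threshold required cumulative fraction of variance in (0, 1].
#' @return smallest K whose cumulative eigenvalue fraction reaches the
#'   threshold.
#' @export
#' @examples
#' selectK(c(3, 1), 0.75)  # 1
selectK <- function(lambda, threshold = 0.95) {
  if (!length(lambda)) stop("empty spectrum")
  if (threshold <= 0 || threshold > 1) stop("'threshold' must be in (0, 1]")
  fve <- cumsum(lambda) / sum(lambda)
  which(fve >= threshold - 1e-12)[1L]
}

#' PACE conditional-expectation scores
#'
#' Best-linear-prediction scores
#' \eqn{\hat\xi_{ik} = \lambda_k \phi_k(t_i)' \Sigma_i^{-1} (x_i - \mu(t_i))}
#' with \eqn{\Sigma_i = \Phi_i \Lambda \Phi_i' + \sigma^2 I} at subject i's
#' observation times (eigenfunctions linearly interpolated from the grid).
#' When \eqn{\Sigma_i} is numerically singular (no measurement noise and
#' duplicated times) a small ridge is added with a warning.
#'
#' @param data long-format exposure records.
#' @param model an \code{FpcaModel} (scores slot may be empty).
#' @return matrix (n x K) of scores, rows named by subject.
#' @export
paceScores <- function(data, model) {
  data <- checkLongData(data)
  grid <- model@grid
  subj <- factor(data$subject_id, levels = unique(data$subject_id))
  phiObs <- interpCurves(grid, model@phi, data$time)
  muObs <- drop(interpCurves(grid, matrix(model@mu), data$time))
  resid <- data$value - muObs
  lambda <- model@lambda
  K <- length(lambda)
  sigma2 <- model@sigma2
  idx <- split(seq_len(nrow(data)), subj)
  ridgeUsed <- FALSE
  xi <- matrix(0, length(idx), K,
               dimnames = list(names(idx), paste0("xi", seq_len(K))))
  Lam <- diag(lambda, K)
  for (i in seq_along(idx)) {
    ii <- idx[[i]]
    Phi <- phiObs[ii, , drop = FALSE]
    Sig <- Phi %*% Lam %*% t(Phi)
    diag(Sig) <- diag(Sig) + sigma2
    sol <- tryCatch(solve(Sig, resid[ii]), error = function(e) NULL)
    if (is.null(sol)) {
      ridgeUsed <- TRUE
      diag(Sig) <- diag(Sig) + 1e-8 * max(diag(Sig), 1)
      sol <- solve(Sig, resid[ii])
    }
    xi[i, ] <- lambda * drop(crossprod(Phi, sol))
  }
  if (ridgeUsed)
    warning("singular conditional covariance for some subjects; ",
            "ridge-stabilised solve used")
  xi
}

#' Sparse FPCA via PACE
#'
#' Full sparse functional principal component analysis: local-linear mean and
#' covariance smoothing, quadrature eigen-decomposition, component selection
#' by fraction of variance explained, and conditional-expectation (PACE)
#' scores.
#'
#' @param data long-format exposure records (\code{subject_id}, \code{time},
#'   \code{value}).
#' @param domain domain \code{c(0, T)}; defaults to the observed time range.
#' @param gridSize output grid size (equally spaced).
#' @param fveThreshold fraction of variance explained used to select K
#'   (ignored when \code{K} is given).
#' @param K fixed number of components, overriding \code{fveThreshold}.
#' @param bwMean mean-smoothing bandwidth; default 10\% of the domain width.
#' @param bwCov covariance-smoothing bandwidth; default 15\% of the domain
#'   width.
#' @return an \code{\linkS4class{FpcaModel}}.
#' @export
fitFpca <- function(data, domain = NULL, gridSize = 101L, fveThreshold = 0.95,
                    K = NULL, bwMean = NULL, bwCov = NULL) {
  data <- checkLongData(data)
  if (is.null(domain)) domain <- range(data$time)
  if (any(data$time < domain[1L] - 1e-9 | data$time > domain[2L] + 1e-9))
    stop("observation times outside the stated domain")
  grid <- seq(domain[1L], domain[2L], length.out = gridSize)
  width <- diff(domain)
  if (is.null(bwMean)) bwMean <- 0.10 * width
  if (is.null(bwCov)) bwCov <- 0.15 * width
  mu <- estimateMean(data, grid, bwMean)
  cv <- estimateCov(data, mu, grid, bwCov)
  ed <- eigenDecompose(cv$surface, grid)
  fveAll <- cumsum(ed$lambda) / sum(ed$lambda)
  Ksel <- if (is.null(K)) selectK(ed$lambda, fveThreshold) else min(K, length(ed$lambda))
  model <- new("FpcaModel", grid = grid, mu = mu,
               phi = ed$phi[, seq_len(Ksel), drop = FALSE],
               lambda = ed$lambda[seq_len(Ksel)], sigma2 = cv$sigma2,
               scores = matrix(0, 0L, Ksel), fve = fveAll,
               subjectIds = character())
  xi <- paceScores(data, model)
  model@scores <- xi
  model@subjectIds <- rownames(xi)
  validObject(model)
  model
}
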