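test_that("IV data assembly centers, aligns by subject id, and flags degenerate instruments", {
  s <- makeIvSim(n = 300, seed = 30)
  rownames(s$Z) <- rownames(s$E) <- names(s$y) <- paste0("id", 1:300)
  iv <- buildIvData(s$Z, s$E, s$y)
  expect_s4_class(iv, "IvData")
  expect_lt(max(abs(colMeans(iv@Z))), 1e-10)
  expect_lt(max(abs(colMeans(iv@E))), 1e-10)
  expect_lt(abs(mean(iv@y)), 1e-10)
  ## permutation invariance: shuffled rows give the same aligned block
  p <- sample(300)
  iv2 <- buildIvData(s$Z[p, ], s$E, s$y)
  expect_equal(iv@Z, iv2@Z)
  expect_equal(iv@y, iv2@y)
  ## already-centered input is unchanged
  iv3 <- buildIvData(iv@Z, iv@E, iv@y)
  expect_equal(iv3@Z, iv@Z)
  ## zero-variance instrument dropped with a warning
  Zbad <- cbind(s$Z, zz = rep(1, 300))
  expect_warning(iv4 <- buildIvData(Zbad, s$E, s$y), "zero-variance")
  expect_equal(ncol(iv4@Z), ncol(s$Z))
  ## under-identification
  expect_error(buildIvData(s$Z[, 1, drop = FALSE], s$E, s$y), "identified")
})

test_that("CUE-GMM with factorized homoskedastic weighting matches the 2SLS closed form", {
  s <- makeIvSim(n = 2000, J = 6, L = 2, seed = 31)
  iv <- buildIvData(s$Z, s$E, s$y)
  fit <- cueGmm(iv)
  expect_true(fit@converged)
  expect_equal(unname(coef(fit)), unname(tsls(s$Z, s$E, s$y)),
               tolerance = 1e-6)
  ## covariance equals the classical homoskedastic 2SLS sandwich
  n <- length(iv@y)
  P <- qr.fitted(qr(iv@Z), iv@E)
  s2 <- mean((iv@y - iv@E %*% coef(fit))^2)
  expect_equal(unname(vcov(fit)), unname(s2 * solve(crossprod(P, iv@E))),
               tolerance = 1e-6)
})

test_that("single instrument, single exposure reduces to the Wald ratio", {
  s <- makeIvSim(n = 1000, J = 1, L = 1, beta0 = 0.7, seed = 32)
  iv <- buildIvData(s$Z, s$E, s$y)
  fit <- cueGmm(iv)
  expect_equal(unname(coef(fit)), cov(s$Z[, 1], s$y) / cov(s$Z[, 1], s$E[, 1]),
               tolerance = 1e-10)
})

test_that("noise-free outcome is fitted exactly with zero objective", {
  s <- makeIvSim(n = 500, seed = 33)
  yExact <- drop(s$E %*% s$beta0)
  iv <- buildIvData(s$Z, s$E, yExact)
  fit <- cueGmm(iv)
  expect_equal(unname(coef(fit)), s$beta0, tolerance = 1e-8)
  expect_lt(fit@objective, 1e-12)
})

test_that("estimates are invariant to rescaling an instrument column", {
  s <- makeIvSim(n = 800, seed = 34)
  Z2 <- s$Z; Z2[, 2] <- Z2[, 2] * 37
  f1 <- cueGmm(buildIvData(s$Z, s$E, s$y))
  f2 <- cueGmm(buildIvData(Z2, s$E, s$y))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  expect_equal(vcov(f1), vcov(f2), tolerance = 1e-8)
})

test_that("objective at the fit is below values at displaced parameters", {
  s <- makeIvSim(n = 2000, seed = 35)
  iv <- buildIvData(s$Z, s$E, s$y)
  fit <- cueGmm(iv)
  obj <- function(b) {
    n <- length(iv@y)
    g <- crossprod(iv@Z, iv@y - iv@E %*% b) / n
    drop(n * crossprod(g, solve(crossprod(iv@Z) / n, g))) /
      mean((iv@y - iv@E %*% b)^2)
  }
  se <- sqrt(diag(vcov(fit)))
  set.seed(35)
  for (i in 1:40) {
    d <- rnorm(2); d <- d / sqrt(sum(d^2))
    for (step in c(2, 5))
      expect_lt(fit@objective, obj(coef(fit) + step * se * d))
  }
})

test_that("association fit is OLS and coincides with GMM when instruments equal exposures", {
  set.seed(36)
  ## orthonormal-column design: coefficients are inner products
  n <- 400
  Q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  Q <- scale(Q, scale = FALSE)
  y <- drop(Q %*% c(1, -2, 0.5)) + rnorm(n, sd = 0.1)
  fit <- associationFit(Q, y)
  expect_equal(unname(coef(fit)),
               drop(solve(crossprod(Q), crossprod(Q, y - mean(y)))),
               tolerance = 1e-10)
  ## self-instrumenting limit: GMM with Z = E is OLS
  s <- makeIvSim(n = 600, seed = 37)
  ivSelf <- buildIvData(s$E, s$E, s$y)
  expect_equal(coef(cueGmm(ivSelf)), coef(associationFit(s$E, s$y)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("effect-curve reconstruction round-trips through the eigenfunction basis", {
  kl <- denseKlData(n = 200)
  fpca <- fitFpca(kl$long, domain = c(0, 10), gridSize = 51, K = 2)
  basis <- makeBasis("eigenfunction", model = fpca)
  fit <- new("MpcmrFit", estimate = c(0.8, -0.4),
             Sigma = diag(c(0.04, 0.09)), Ghat = matrix(0, 2, 2),
             Omega = diag(2), objective = 0, method = "cue_gmm",
             n = 200L, converged = TRUE)
  curve <- reconstructEffect(fit, basis)
  w <- quadWeights(timePoints(fpca))
  backOut <- drop(crossprod(eigenFunctions(fpca), w * curve@beta))
  expect_equal(backOut, c(0.8, -0.4), tolerance = 1e-6)
  ## pointwise variance is the quadratic form b(t)' Sigma b(t)
  seHand <- sqrt(basisCurves(basis)[, 1]^2 * 0.04 +
                   basisCurves(basis)[, 2]^2 * 0.09)
  expect_equal(curve@se, seHand, tolerance = 1e-10)
  expect_true(all(curve@lo <= curve@beta & curve@beta <= curve@hi))

  ## constant-only basis gives a flat curve with constant uncertainty
  b0 <- makeBasis("polynomial", 0, grid = timePoints(fpca))
  fit0 <- new("MpcmrFit", estimate = 0.3, Sigma = matrix(0.01),
              Ghat = matrix(0), Omega = matrix(1), objective = 0,
              method = "cue_gmm", n = 200L, converged = TRUE)
  c0 <- reconstructEffect(fit0, b0)
  expect_equal(unique(c0@beta), 0.3)
  expect_equal(unique(c0@se), 0.1)
})

test_that("intervention contrasts integrate the effect curve against the intervention", {
  g <- seq(0, 50, length.out = 101)
  b <- makeBasis("polynomial", 0, grid = g)
  fit <- new("MpcmrFit", estimate = 0.1, Sigma = matrix(4e-4),
             Ghat = matrix(0), Omega = matrix(1), objective = 0,
             method = "cue_gmm", n = 100L, converged = TRUE)
  ## constant unit intervention under a constant effect 0.1 over 50 units
  eff <- interventionEffect(fit, b, rep(1, 101))
  expect_equal(eff$estimate, 5)
  expect_equal(eff$se, sqrt(50^2 * 4e-4))
  ## null intervention
  eff0 <- interventionEffect(fit, b, rep(0, 101))
  expect_equal(eff0$estimate, 0)
  expect_equal(eff0$se, 0)
  ## intervention along a basis curve picks out gamma_l * ||b_l||^2
  kl <- denseKlData(n = 150)
  fpca <- fitFpca(kl$long, domain = c(0, 10), gridSize = 51, K = 2)
  be <- makeBasis("eigenfunction", model = fpca)
  fit2 <- new("MpcmrFit", estimate = c(1.5, 0), Sigma = diag(2) * 0.01,
              Ghat = matrix(0, 2, 2), Omega = diag(2), objective = 0,
              method = "cue_gmm", n = 150L, converged = TRUE)
  a <- basisCurves(be)[, 1]
  eff2 <- interventionEffect(fit2, be, a)
  expect_equal(eff2$estimate, 1.5, tolerance = 1e-6)  # ||phi_1||^2 = 1
})
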