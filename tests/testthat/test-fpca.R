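test_that("mean smoother is exact on constant and linear signals", {
  d <- smallSparseData(noise = 0)
  grid <- seq(0, 10, length.out = 41)
  constData <- d; constData$value <- 7
  expect_equal(estimateMean(constData, grid, bandwidth = 2),
               rep(7, 41), tolerance = 1e-10)
  ## noiseless a + b t is reproduced exactly by local-linear smoothing
  expect_equal(estimateMean(d, grid, bandwidth = 2), 1 + 0.5 * grid,
               tolerance = 1e-8)
  expect_error(estimateMean(d, grid, bandwidth = 0.01), "bandwidth")
})

test_that("mean smoother agrees with pointwise averages on a dense balanced design", {
  set.seed(5)
  grid <- seq(0, 10, length.out = 41)
  n <- 400
  mu <- sin(grid / 10 * 2 * pi)
  vals <- rep(mu, n) + rnorm(41 * n, sd = 0.3)
  d <- data.frame(subject_id = rep(sprintf("s%03d", 1:n), each = 41),
                  time = rep(grid, n), value = vals)
  muHat <- estimateMean(d, grid, bandwidth = 1)
  ptwise <- tapply(d$value, d$time, mean)
  expect_lt(max(abs(muHat - ptwise)), 0.12)
})

test_that("covariance surface is symmetric, nearly noise-free for dense noiseless data, and recovers a known spectrum", {
  kl <- denseKlData()
  mu <- estimateMean(kl$long, kl$grid, bandwidth = 1.5)
  cv <- estimateCov(kl$long, mu, kl$grid, bandwidth = 2)
  expect_identical(cv$surface, t(cv$surface))
  expect_lt(cv$sigma2, 0.05 * max(diag(cv$surface)))

  ## sparse noisy draws from a 2-component KL model: top-2 eigenvalues
  ## within 15% of the truth
  set.seed(6)
  n <- 2000; nObs <- 6
  grid <- seq(0, 10, length.out = 51)
  Tn <- 10
  phi <- cbind(rep(1 / sqrt(Tn), 51), sqrt(3 / Tn) * (2 * grid / Tn - 1))
  lam <- c(3, 1); sig <- 0.5
  long <- do.call(rbind, lapply(1:n, function(i) {
    idx <- sort(sample.int(51, nObs))
    xi <- rnorm(2, sd = sqrt(lam))
    data.frame(subject_id = sprintf("s%04d", i), time = grid[idx],
               value = drop(phi[idx, ] %*% xi) + rnorm(nObs, sd = sig))
  }))
  fit <- fitFpca(long, domain = c(0, 10), gridSize = 51, K = 2)
  expect_equal(eigenValues(fit), lam, tolerance = 0.15)
  expect_equal(noiseVariance(fit), sig^2, tolerance = 0.4)
})

test_that("eigen-decomposition returns quadrature-orthonormal, sign-fixed, descending components", {
  grid <- seq(0, 10, length.out = 101)
  w <- quadWeights(grid)
  ## rank-1 surface G = phi phi' with unit-norm phi
  phi <- sin(grid) + 0.5
  phi <- phi / sqrt(sum(w * phi^2))
  ed <- eigenDecompose(outer(phi, phi), grid)
  expect_equal(length(ed$lambda), 1L)
  expect_equal(ed$lambda, 1, tolerance = 1e-8)
  expect_equal(abs(ed$phi[, 1]), abs(phi), tolerance = 1e-6)
  ## sign convention: positive inner product with t
  expect_gte(sum(w * ed$phi[, 1] * grid), 0)

  ## a general smooth symmetric surface: orthonormality and ordering
  S <- outer(grid, grid, function(s, t) 2 * exp(-(s - t)^2 / 8) + 0.5)
  ed2 <- eigenDecompose(S, grid, maxK = 6)
  gram <- crossprod(ed2$phi, w * ed2$phi)
  expect_equal(gram, diag(ncol(ed2$phi)), tolerance = 1e-6)
  expect_true(all(diff(ed2$lambda) < 0))
})

test_that("dense-limit eigen-decomposition matches classical PCA", {
  kl <- denseKlData(n = 300)
  ## narrow bandwidths: with fully observed curves every covariance cell is
  ## populated, so barely any smoothing is needed for the comparison
  fit <- fitFpca(kl$long, domain = c(0, 10), gridSize = 51, K = 2,
                 bwMean = 0.5, bwCov = 0.5)
  ## classical-PCA oracle on the quadrature-weighted curve matrix: the
  ## discretised covariance operator and weighted PCA share spectrum and
  ## scores
  w <- quadWeights(kl$grid)
  pca <- prcomp(kl$X %*% diag(sqrt(w)), center = TRUE)
  expect_equal(eigenValues(fit), pca$sdev[1:2]^2 * (300 - 1) / 300,
               tolerance = 0.01)
  ## eigenfunctions proportional to rescaled loadings (up to sign)
  for (k in 1:2) {
    al <- abs(cor(eigenFunctions(fit)[, k], pca$rotation[, k] / sqrt(w)))
    expect_gt(al, 0.999)
  }
  ## PACE scores match classical PCA scores within 1%
  sc <- scores(fit)[sprintf("s%03d", 1:300), ]
  for (k in 1:2) {
    r <- lm(pca$x[, k] ~ sc[, k])
    expect_equal(abs(unname(coef(r)[2])), 1, tolerance = 0.01)
    expect_gt(summary(r)$r.squared, 0.999)
  }
})

test_that("PACE scores equal quadrature projections for dense noiseless curves and vanish at the mean", {
  kl <- denseKlData(n = 120)
  fit <- fitFpca(kl$long, domain = c(0, 10), gridSize = 51, K = 2)
  w <- quadWeights(timePoints(fit))
  centered <- t(kl$X) - meanCurve(fit)           # grid x n
  proj <- t(crossprod(centered * w, eigenFunctions(fit)))  # n: projections
  sc <- scores(fit)[sprintf("s%03d", 1:120), ]
  expect_equal(unname(sc), unname(t(proj)), tolerance = 1e-3)

  ## a subject observed exactly at the mean gets zero scores
  d2 <- data.frame(subject_id = "x", time = timePoints(fit),
                   value = meanCurve(fit))
  both <- rbind(kl$long, d2)
  fit2 <- fitFpca(both, domain = c(0, 10), gridSize = 51, K = 2)
  expect_equal(unname(scores(fit2)["x", ]), c(0, 0), tolerance = 1e-8)
})

test_that("PACE scores are shrunk: score variance does not exceed the eigenvalue", {
  set.seed(8)
  n <- 1500
  grid <- seq(0, 10, length.out = 51)
  phi <- cbind(rep(1 / sqrt(10), 51), sqrt(3 / 10) * (2 * grid / 10 - 1))
  lam <- c(2, 0.7)
  long <- do.call(rbind, lapply(1:n, function(i) {
    idx <- sort(sample.int(51, 4))
    xi <- rnorm(2, sd = sqrt(lam))
    data.frame(subject_id = sprintf("s%04d", i), time = grid[idx],
               value = drop(phi[idx, ] %*% xi) + rnorm(4, sd = 0.6))
  }))
  fit <- fitFpca(long, domain = c(0, 10), gridSize = 51, K = 2)
  v <- apply(scores(fit), 2, var)
  expect_true(all(v <= eigenValues(fit) * 1.05))
})

test_that("component selection honours the variance-explained threshold", {
  expect_equal(selectK(c(3, 1), 0.75), 1L)
  expect_equal(selectK(c(3, 1), 0.76), 2L)
  expect_equal(selectK(5, 1), 1L)
  expect_error(selectK(numeric(0), 0.9), "empty")
  expect_error(selectK(c(3, 1), 0), "threshold")
})

test_that("simulated sparse trajectories yield two near-linear leading eigenfunctions", {
  ## the simulation design's confounder structure (random level + Brownian
  ## motion) concentrates variance on a rising first component and a
  ## contrast-like second component, both close to linear in t
  cfg <- simConfig(nSubjects = 10000, exposureScenario = "B", seed = 21)
  sim <- simulateDataset(cfg)
  fit <- fitFpca(sim$exposure, domain = c(0, 50))
  expect_gte(length(eigenValues(fit)), 2L)
  g <- timePoints(fit)
  r2 <- vapply(1:2, function(k)
    summary(lm(eigenFunctions(fit)[, k] ~ g))$r.squared, numeric(1))
  ## both leading components are close to linear; their average tracks the
  ## nominal level tightly while individual components fluctuate a little
  ## across realisations
  expect_gte(mean(r2), 0.95)
  expect_true(all(r2 >= 0.90))
  expect_true(all(diff(eigenValues(fit)) < 0))
  expect_gte(fve(fit)[2], 0.95)
})
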