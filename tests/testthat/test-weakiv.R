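## independent scalar (L = 1) implementation of the three-step LM
## construction, used as a brute-force oracle
scalarLmOracle <- function(Z, e, y, b0) {
  Zc <- scale(Z, scale = FALSE)
  ec <- e - mean(e); yc <- y - mean(y)
  n <- length(yc)
  r <- yc - ec * b0
  g <- colMeans(Zc * r)
  Om <- crossprod(Zc) / n * mean(r^2)
  Gk <- -colMeans(Zc * ec)
  Dl <- -crossprod(Zc * (ec * r), Zc) / n         # Delta_1(b0)
  ed <- eigen(Om, symmetric = TRUE)
  OmIS <- ed$vectors %*% (t(ed$vectors) / sqrt(ed$values))
  D <- Gk - drop(t(Dl) %*% solve(Om, g))
  q <- drop(OmIS %*% g)
  Dt <- drop(OmIS %*% D)
  n * sum(q * Dt)^2 / sum(Dt^2)
}

test_that("LM statistic matches an independent scalar implementation and is non-negative", {
  s <- makeIvSim(n = 800, J = 5, L = 1, beta0 = 0.4, seed = 40)
  iv <- buildIvData(s$Z, s$E, s$y)
  set.seed(41)
  for (b0 in c(0.4, 0, -1, 2.7, rnorm(3))) {
    got <- lmStat(iv, b0)
    want <- scalarLmOracle(s$Z, s$E[, 1], s$y, b0)
    expect_equal(got$lm, want, tolerance = 1e-8)
    expect_gte(got$lm, 0)
    expect_equal(got$df, 1L)
  }
})

test_that("LM statistic is invariant to instrument rescaling", {
  s <- makeIvSim(n = 600, J = 6, L = 2, seed = 42)
  iv1 <- buildIvData(s$Z, s$E, s$y)
  Z2 <- s$Z; Z2[, 1] <- Z2[, 1] * 0.01; Z2[, 4] <- Z2[, 4] * 250
  iv2 <- buildIvData(Z2, s$E, s$y)
  for (b0 in list(c(0, 0), s$beta0, c(1, 1))) {
    expect_equal(lmStat(iv1, b0)$lm, lmStat(iv2, b0)$lm, tolerance = 1e-7)
  }
})

test_that("lattice inversion accepts the point estimate under strong instruments and matches lmStat", {
  s <- makeIvSim(n = 4000, J = 8, L = 2, strength = 0.5, seed = 43)
  iv <- buildIvData(s$Z, s$E, s$y)
  fit <- cueGmm(iv)
  reg <- lmRegion(iv, fit, m = 11, width = 4)
  expect_s4_class(reg, "LmRegion")
  expect_equal(nrow(reg@candidates), 121L)
  expect_true(any(reg@accepted))
  ## the candidate closest to the point estimate is accepted
  d2 <- colSums((t(reg@candidates) - coef(fit))^2)
  expect_true(reg@accepted[which.min(d2)])
  ## lattice values agree with one-at-a-time evaluation
  for (i in c(1L, 61L, 121L)) {
    expect_equal(reg@lm[i], lmStat(iv, reg@candidates[i, ])$lm,
                 tolerance = 1e-10)
  }
  ## true parameter inside the band region
  expect_equal(lmStat(iv, s$beta0)$accepted, TRUE)
})

test_that("strongly identified LM region endpoints approach the Wald interval", {
  s <- makeIvSim(n = 20000, J = 8, L = 2, strength = 0.6, seed = 44)
  iv <- buildIvData(s$Z, s$E, s$y)
  fit <- cueGmm(iv)
  reg <- lmRegion(iv, fit, m = 161, width = 4)
  acc <- acceptedSet(reg)
  se <- sqrt(diag(vcov(fit)))
  ## the LM region is a joint 95% region for both coordinates; its
  ## per-coordinate projection corresponds to a Wald interval inflated by
  ## the two- versus one-degree-of-freedom chi-square cutoff ratio
  infl <- sqrt(qchisq(0.95, 2) / qchisq(0.95, 1))
  for (l in 1:2) {
    lmWidth <- max(acc[, l]) - min(acc[, l])
    waldWidth <- 2 * qnorm(0.975) * se[l] * infl
    expect_equal(unname(lmWidth), unname(waldWidth), tolerance = 0.10)
  }
})

test_that("bands are the image of the accepted set under the basis map", {
  g <- seq(0, 10, length.out = 21)
  bas <- makeBasis("polynomial", 1, grid = g)
  ## hand-built region: symmetric accepted set around (1, 0)
  cand <- as.matrix(expand.grid(seq(0.5, 1.5, 0.25), seq(-0.5, 0.5, 0.25)))
  lmv <- rep(10, nrow(cand))
  acc <- abs(cand[, 1] - 1) + abs(cand[, 2]) <= 0.5
  lmv[acc] <- 1
  reg <- new("LmRegion", candidates = cand, lm = lmv, accepted = acc,
             alpha = 0.05, df = 2L)
  band <- regionToBand(reg, bas)
  mid <- drop(basisCurves(bas) %*% c(1, 0))
  expect_equal((band$lo + band$hi) / 2, mid, tolerance = 1e-10)
  expect_true(all(band$lo <= mid & mid <= band$hi))
  ## single accepted point collapses the band to that curve
  reg1 <- new("LmRegion", candidates = cand, lm = lmv,
              accepted = seq_len(nrow(cand)) == which(acc)[1],
              alpha = 0.05, df = 2L)
  band1 <- regionToBand(reg1, bas)
  curve1 <- drop(basisCurves(bas) %*% cand[which(acc)[1], ])
  expect_equal(band1$lo, curve1)
  expect_equal(band1$hi, curve1)
  ## empty region errors
  regE <- new("LmRegion", candidates = cand, lm = rep(10, nrow(cand)),
              accepted = rep(FALSE, nrow(cand)), alpha = 0.05, df = 2L)
  expect_error(regionToBand(regE, bas), "empty")
})

test_that("the global null test evaluates the LM statistic at zero", {
  s <- makeIvSim(n = 3000, J = 8, L = 2, strength = 0.5, seed = 45)
  iv <- buildIvData(s$Z, s$E, s$y)
  gn <- globalNullTest(iv)
  direct <- lmStat(iv, c(0, 0))
  expect_equal(gn$statistic, direct$lm)
  expect_equal(gn$pvalue, direct$pvalue)
  ## a clearly non-null effect is rejected
  expect_true(gn$reject)
  ## under a simulated null the test does not reject at this sample size
  s0 <- makeIvSim(n = 3000, J = 8, L = 2, beta0 = c(0, 0), strength = 0.5,
                  seed = 46)
  iv0 <- buildIvData(s0$Z, s0$E, s0$y)
  expect_false(globalNullTest(iv0)$reject)
})

test_that("weak-instrument robust bands are wider than Wald bands at most timepoints", {
  cfg <- simConfig(nSubjects = 1200, exposureScenario = "A",
                   outcomeScenario = 3, seed = 47)
  sim <- simulateDataset(cfg)
  m <- fitFpca(sim$exposure, domain = c(0, 50), K = 2)
  iv <- buildIvData(sim$genotypes, scores(m), sim$outcome)
  fit <- cueGmm(iv)
  basis <- makeBasis("eigenfunction", model = m)
  wald <- reconstructEffect(fit, basis)
  reg <- lmRegion(iv, fit, m = 21, width = 4)
  band <- regionToBand(reg, basis)
  wider <- (band$hi - band$lo) >= (wald@hi - wald@lo) * 0.999
  expect_gt(mean(wider), 0.6)
})
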