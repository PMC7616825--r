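## Shared fixtures, all generated in code.

## Direct linear IV data (no FPCA involved): E = Z pi + V + confounder,
## y = E beta0 + confounder + noise. Used to test the GMM and LM machinery
## against closed forms.
makeIvSim <- function(n = 2000, J = 6, L = 2, beta0 = c(0.5, -0.3),
                      strength = 0.25, confound = 2, seed = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(n * J), n, J, dimnames = list(NULL, paste0("z", 1:J)))
  pi <- matrix(runif(J * L, strength / 2, strength), J, L)
  u <- rnorm(n)
  E <- Z %*% pi + matrix(rnorm(n * L), n, L) + u
  colnames(E) <- paste0("e", 1:L)
  y <- drop(E %*% beta0) + confound * u + rnorm(n)
  list(Z = Z, E = E, y = y, beta0 = beta0)
}

## 2SLS closed form on centered data
tsls <- function(Z, E, y) {
  Zc <- scale(Z, scale = FALSE); Ec <- scale(E, scale = FALSE)
  yc <- y - mean(y)
  P <- qr.fitted(qr(Zc), Ec)
  drop(solve(crossprod(P, Ec), crossprod(P, yc)))
}

## tiny long-format exposure table
smallSparseData <- function(n = 30, nObs = 5, seed = 2, noise = 0.3) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    t <- sort(runif(nObs, 0, 10))
    data.frame(subject_id = sprintf("s%02d", i), time = t,
               value = 1 + 0.5 * t + rnorm(nObs, sd = noise))
  }))
}

## dense noiseless curves lying in a known 2-function eigenspace
denseKlData <- function(n = 80, ngrid = 51, lam = c(3, 1), seed = 4) {
  set.seed(seed)
  grid <- seq(0, 10, length.out = ngrid)
  Tn <- max(grid)
  phi1 <- rep(1 / sqrt(Tn), ngrid)
  phi2 <- sqrt(3 / Tn) * (2 * grid / Tn - 1)
  xi <- cbind(rnorm(n, sd = sqrt(lam[1])), rnorm(n, sd = sqrt(lam[2])))
  X <- xi %*% rbind(phi1, phi2)              # n x ngrid
  long <- data.frame(subject_id = rep(sprintf("s%03d", 1:n), each = ngrid),
                     time = rep(grid, n), value = as.vector(t(X)))
  list(long = long, grid = grid, phi = cbind(phi1, phi2), xi = xi, X = X)
}
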