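smallCfg <- function(seed = 1, nIter = 400, burn = 100, thin = 2,
                     chains = 2) {
  mcmcConfig(nChains = chains, nIterations = nIter, burnIn = burn,
             thin = thin, seed = seed)
}

test_that("identical seed and config give bit-identical draws", {
  spec <- scenarioSpec(nAges = 8, nYears = 14, seed = 3)
  g <- genROMIFromModel(spec, "linear")
  a <- runSampler(g$rho, "linear", smallCfg(seed = 11))
  b <- runSampler(g$rho, "linear", smallCfg(seed = 11))
  expect_identical(a@draws, b@draws)
  c <- runSampler(g$rho, "linear", smallCfg(seed = 12))
  expect_false(identical(a@draws, c@draws))
  ## exponential model too
  ge <- genROMIFromModel(spec, "exponential")
  d1 <- runSampler(ge$rho, "exponential", smallCfg(seed = 5))
  d2 <- runSampler(ge$rho, "exponential", smallCfg(seed = 5))
  expect_identical(d1@draws, d2@draws)
})

test_that("retention, thinning and support invariants hold", {
  spec <- scenarioSpec(nAges = 6, nYears = 12, seed = 9)
  g <- genROMIFromModel(spec, "linear")
  cfg <- smallCfg(seed = 2, nIter = 505, thin = 5)
  pd <- runSampler(g$rho, "linear", cfg)
  expect_identical(nrow(parameterDraws(pd, "sigma")),
                   2L * (505L %/% 5L))
  sig <- parameterDraws(pd, "sigma")[, 1]
  expect_true(all(sig > 0 & sig < 1))
  expect_true(all(abs(parameterDraws(pd, "mu1")[, 1]) < 0.1))
  expect_true(all(abs(parameterDraws(pd, "rhoCorr")[, 1]) < 1))
  om <- cbind(parameterDraws(pd, "omega1"), parameterDraws(pd, "omega2"))
  expect_true(all(om > 0 & om < 1))
})

test_that("conjugate toy posterior matches the closed form", {
  ## single age, sigma and all hyper-parameters pinned: the beta posterior
  ## is exactly N((X'X/s^2 + Q)^-1 X'y/s^2, (X'X/s^2 + Q)^-1) with prior
  ## mean zero and a wide coefficient prior
  set.seed(99)
  Tn <- 18
  sigma <- 0.004
  y <- 0.02 + 6e-4 * (1:Tn) + rnorm(Tn, 0, sigma)
  rho <- ROMISurface(rbind(y), 0, 2000 + 1:Tn - 1)
  priors <- list(
    sigma = priorSpec("fixed", c(0, 1), value = sigma),
    mu1 = priorSpec("fixed", c(-0.1, 0.1), value = 0),
    mu2 = priorSpec("fixed", c(-0.1, 0.1), value = 0),
    omega1 = priorSpec("fixed", c(0, 1), value = 0.9),
    omega2 = priorSpec("fixed", c(0, 1), value = 0.9),
    rhoCorr = priorSpec("fixed", c(-1, 1), value = 0)
  )
  pd <- runSampler(rho, "linear",
                   mcmcConfig(nChains = 2, nIterations = 3000, burnIn = 50,
                              thin = 1, seed = 4),
                   priors = priors)
  X <- cbind(1, 1:Tn)
  Q <- diag(1 / 0.9^2, 2)
  P <- crossprod(X) / sigma^2 + Q
  postMean <- solve(P, crossprod(X, y) / sigma^2)
  b1 <- parameterDraws(pd, "beta1")[, 1]
  b2 <- parameterDraws(pd, "beta2")[, 1]
  n <- length(b1)
  expect_lt(abs(mean(b1) - postMean[1]), 3 * sd(b1) / sqrt(n) * 3)
  expect_lt(abs(mean(b2) - postMean[2]), 3 * sd(b2) / sqrt(n) * 3)
  ## posterior spread matches the closed form too (rough check)
  S <- solve(P)
  expect_equal(sd(b1), sqrt(S[1, 1]), tolerance = 0.1)
  expect_equal(sd(b2), sqrt(S[2, 2]), tolerance = 0.1)
})

test_that("Raftery-Lewis diagnostic hits the closed-form minimum", {
  set.seed(123)
  ch <- rnorm(20000)
  rl <- rafteryLewis(ch)
  expect_identical(rl$Nmin, ceiling(0.025 * 0.975 * (qnorm(0.975) / 0.005)^2))
  expect_identical(rl$Nmin, 3746)
  expect_gt(rl$I, 0.9)
  expect_lt(rl$I, 1.2)
  ## deterministic
  expect_identical(rafteryLewis(ch), rl)
  ## autocorrelation inflates the dependence factor
  ar <- as.numeric(arima.sim(list(ar = 0.9), 20000, sd = 1))
  expect_gt(rafteryLewis(ar)$I, rl$I)
  expect_error(rafteryLewis(rep(1, 100)), "constant")
})

test_that("Raftery-Lewis agrees with an independent implementation", {
  set.seed(77)
  ch <- rnorm(8000)
  rl <- rafteryLewis(ch)
  cd <- coda::raftery.diag(coda::mcmc(ch), q = 0.025, r = 0.005, s = 0.95)
  res <- cd$resmatrix
  expect_equal(rl$N, unname(res[1, "M"] + res[1, "N"]), tolerance = 0.15)
  expect_equal(rl$I, unname(res[1, "I"]), tolerance = 0.15)
})

test_that("chain diagnostics flag convergence on well-behaved draws", {
  spec <- scenarioSpec(nAges = 6, nYears = 14, seed = 31)
  g <- genROMIFromModel(spec, "linear")
  pd <- runSampler(g$rho, "linear", smallCfg(seed = 8, nIter = 600))
  d <- chainDiagnostics(pd)
  expect_true(all(c("trace", "acf", "rhat") %in% names(d)))
  expect_true(all(d$rhat$rhat < 1.2))
  ## ACF equals a direct-summation oracle on one chain
  x <- parameterDraws(pd, "sigma")[pd@chain == 1L, 1]
  xc <- x - mean(x)
  denom <- sum(xc^2)
  oracleACF <- vapply(0:5, function(l) {
    sum(xc[seq_len(length(x) - l)] * xc[seq_len(length(x) - l) + l]) / denom
  }, numeric(1))
  oneChain <- pd
  ## restrict to chain 1 by rebuilding a single-chain object
  keep <- pd@chain == 1L
  oneChain@draws <- lapply(pd@draws, function(m) m[keep, , drop = FALSE])
  oneChain@chain <- pd@chain[keep]
  expect_warning(d1 <- chainDiagnostics(oneChain, maxLag = 5),
                 "scale reduction omitted")
  got <- d1$acf[d1$acf$parameter == "sigma", "acf"]
  expect_equal(got, oracleACF, tolerance = 1e-10)
})

test_that("white-noise pseudo-chains give scale reduction near 1", {
  set.seed(55)
  n <- 800
  pd <- makeDraws(beta1 = 0.02, beta2 = 1e-4, sigma = 0.005, nRep = 2 * n)
  pd@chain <- rep(1:2, each = n)
  pd@draws$sigma[, 1] <- 0.005 + rnorm(2 * n, 0, 1e-4)
  d <- chainDiagnostics(pd, parameters = "sigma")
  expect_lt(d$rhat$rhat[d$rhat$parameter == "sigma"], 1.05)
  acf1 <- d$acf[d$acf$parameter == "sigma" & d$acf$lag >= 1, "acf"]
  expect_true(all(abs(acf1) < 3 / sqrt(n)))
})
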