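test_that("noise-free prediction reproduces the model mean path", {
  pd <- makeDraws(beta1 = c(0.01, 0.02), beta2 = c(0.001, -0.0005),
                  sigma = 0.005, baseT = 10L)
  dr <- posteriorPredictROMI(pd, 3, clipBounds(-Inf, Inf),
                             includeNoise = FALSE)
  for (h in 1:3) {
    expect_equal(dr[1, , h], c(0.01, 0.02) + c(0.001, -0.0005) * (10 + h),
                 ignore_attr = TRUE)
  }
  ## forecast-year labels continue the base period
  expect_identical(dimnames(dr)$year, as.character(2011:2013))
})

test_that("the clip ceiling binds when mean improvement is implausible", {
  pd <- makeDraws(beta1 = 0.10, beta2 = 0, sigma = 0.001, nRep = 50)
  set.seed(3)
  dr <- posteriorPredictROMI(pd, 4, clipBounds(), includeNoise = TRUE)
  expect_true(all(dr == 0.035))
})

test_that("predictive noise has the parameter draw's spread", {
  pd <- makeDraws(beta1 = 0.02, beta2 = 0, sigma = 0.006, nRep = 4000)
  set.seed(9)
  dr <- posteriorPredictROMI(pd, 1, clipBounds(-Inf, Inf),
                             includeNoise = TRUE)
  expect_equal(sd(dr[, 1, 1]), 0.006, tolerance = 0.05)
  expect_equal(mean(dr[, 1, 1]), 0.02, tolerance = 0.01)
})

test_that("reference-country mean honours the missing policy", {
  yrs <- 2000:2002
  r1 <- ROMISurface(rbind(c(0.01, 0.01, 0.01)), 0, yrs)
  r2 <- ROMISurface(rbind(c(0.03, 0.03, NA)), 0, yrs)
  r3 <- ROMISurface(rbind(c(0.02, NA, NA)), 0, yrs)
  expect_identical(surfaceValues(referenceMeanROMI(list(r1))),
                   surfaceValues(r1))
  m <- referenceMeanROMI(list(r1, r2, r3))
  expect_equal(surfaceValues(m)[1, ], c(0.02, 0.02, 0.01),
               ignore_attr = TRUE)
  expect_error(referenceMeanROMI(list()), "at least one")
})

test_that("blending contracts hold exactly", {
  set.seed(14)
  coi <- array(runif(2 * 3 * 4, 0, 0.03), c(2, 3, 4))
  rc <- array(runif(2 * 3 * 4, 0, 0.03), c(2, 3, 4))
  expect_identical(blendWithReference(coi, rc, rep(0, 4)), coi)
  expect_identical(blendWithReference(coi, rc, rep(1, 4)), rc)
  half <- blendWithReference(array(0.01, c(1, 1, 1)),
                             array(0.03, c(1, 1, 1)), 0.5)
  expect_equal(half[1, 1, 1], 0.02)
  ## blending is linear: equal inputs are a fixed point for any weight
  same <- blendWithReference(coi, coi, runif(4))
  expect_equal(same, coi, tolerance = 1e-15)
  expect_error(blendWithReference(coi, rc, rep(0.5, 3)), "schedule length")
})

test_that("convergence schedules have the declared shapes", {
  expect_identical(convergenceSchedule("off", 5), rep(0, 5))
  expect_equal(convergenceSchedule("linear", 4), (1:4) / 4)
  w <- convergenceSchedule("delayed", 6, startYear = 4)
  expect_equal(w, c(0, 0, 0, 1 / 3, 2 / 3, 1))
  expect_true(all(diff(w) >= 0))
})

test_that("rate propagation is the geometric recursion", {
  dr <- array(0.03, c(5, 1, 3))
  rq <- propagateRates(0.02, dr, 0.5)
  expect_equal(surfaceValues(rq[[1]])[1, ], 0.02 * 0.97^(1:3),
               tolerance = 1e-14, ignore_attr = TRUE)
  ## degenerate posterior: both modes coincide
  rqT <- propagateRates(0.02, dr, c(0.1, 0.9), mode = "trajectory")
  rqQ <- propagateRates(0.02, dr, c(0.1, 0.9), mode = "quantile-path")
  expect_equal(surfaceValues(rqT[[1]]), surfaceValues(rqQ[[1]]),
               tolerance = 1e-14)
  expect_equal(surfaceValues(rqT[[2]]), surfaceValues(rqQ[[2]]),
               tolerance = 1e-14)
  expect_error(propagateRates(0.02, array(1.5, c(1, 1, 1)), 0.5), ">= 1")
  expect_error(propagateRates(-0.1, dr, 0.5), "positive")
})

test_that("quantile surfaces never cross and e0 is monotone in the level", {
  pd <- makeDraws(beta1 = rep(0.015, 101), beta2 = rep(2e-4, 101),
                  sigma = 0.005, nRep = 300)
  set.seed(4)
  dr <- posteriorPredictROMI(pd, 6, clipBounds(-Inf, Inf),
                             includeNoise = TRUE)
  jump <- 5e-5 * exp(0.09 * (0:100)) + 5e-4
  lv <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  for (mode in c("quantile-path", "trajectory")) {
    rq <- propagateRates(jump, dr, lv, mode = mode)
    ## death rates non-increasing in the level, cell-wise
    for (i in seq_len(length(lv) - 1)) {
      expect_true(all(surfaceValues(rq[[i + 1]]) <=
                        surfaceValues(rq[[i]]) + 1e-12))
    }
    e0 <- summarizeE0(rq)
    expect_true(all(apply(e0, 2, function(col) all(diff(col) >= -1e-9))))
  }
})

test_that("uncertainty widens with the forecast horizon", {
  pd <- makeDraws(beta1 = rep(0.015, 101), beta2 = rep(1e-4, 101),
                  sigma = 0.006, nRep = 400)
  ## perturb the coefficient draws so parameter uncertainty is present
  set.seed(8)
  pd@draws$beta1 <- pd@draws$beta1 + rnorm(400 * 101, 0, 0.002)
  pd@draws$beta2 <- pd@draws$beta2 + rnorm(400 * 101, 0, 1e-4)
  dr <- posteriorPredictROMI(pd, 10, clipBounds(-Inf, Inf),
                             includeNoise = TRUE)
  jump <- 5e-5 * exp(0.09 * (0:100)) + 5e-4
  rq <- propagateRates(jump, dr, c(0.1, 0.9))
  e0 <- summarizeE0(rq)
  width <- e0[2, ] - e0[1, ]
  expect_gt(cor(width, seq_along(width)), 0.9)
  expect_gt(width[10], width[1])
})

test_that("the forecast wrapper assembles a coherent result object", {
  spec <- scenarioSpec(nAges = 30, nYears = 12, horizon = 4, seed = 17,
                       sigma = 0.004)
  g <- genROMIFromModel(spec, "linear")
  pd <- runSampler(g$rho, "linear",
                   mcmcConfig(nChains = 2, nIterations = 300, burnIn = 100,
                              thin = 2, seed = 2))
  jump <- rep(0.01, 30)
  set.seed(5)
  fr <- forecastMortality(pd, jump, horizon = 4,
                          bounds = clipBounds(-Inf, Inf), exAge = 20L)
  expect_s4_class(fr, "ForecastResult")
  expect_identical(dim(fr@romiDraws)[3], 4L)
  expect_identical(nrow(fr@e0Quantiles), length(fr@quantileLevels))
  expect_identical(nrow(fr@exQuantiles), length(fr@quantileLevels))
  tabs <- forecastTables(fr)
  expect_identical(nrow(tabs$e0), length(fr@quantileLevels) * 4L)
  expect_identical(nrow(tabs$rates), length(fr@quantileLevels) * 30L * 4L)
})

test_that("per-draw life-expectancy trajectories match the single-draw case", {
  pd <- makeDraws(beta1 = rep(0.02, 21), beta2 = rep(0, 21), sigma = 0.005)
  dr <- posteriorPredictROMI(pd, 3, clipBounds(-Inf, Inf),
                             includeNoise = FALSE)
  jump <- rep(0.01, 21)
  e0d <- e0FromDraws(jump, dr)
  rq <- propagateRates(jump, dr, 0.5)
  expect_equal(as.numeric(e0d[1, ]), as.numeric(summarizeE0(rq)[1, ]),
               tolerance = 1e-12)
})
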