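test_that("noiseless generation is exact and deterministic", {
  spec <- scenarioSpec(nAges = 10, nYears = 12, sigma = 0, seed = 4)
  g1 <- genROMIFromModel(spec, "linear")
  g2 <- genROMIFromModel(spec, "linear")
  expect_identical(surfaceValues(g1$rho), surfaceValues(g2$rho))
  ## sigma = 0: surface equals beta1 + beta2 t exactly
  tt <- seq_len(ncol(surfaceValues(g1$rho)))
  expected <- outer(g1$truth$beta1, rep(1, length(tt))) +
    outer(g1$truth$beta2, tt)
  expect_equal(surfaceValues(g1$rho), expected, tolerance = 1e-15,
               ignore_attr = TRUE)
  ## different seed differs
  g3 <- genROMIFromModel(scenarioSpec(nAges = 10, nYears = 12, sigma = 0,
                                      seed = 5), "linear")
  expect_false(identical(surfaceValues(g1$rho), surfaceValues(g3$rho)))
})

test_that("observation noise has the specified variance", {
  spec <- scenarioSpec(nAges = 40, nYears = 26, sigma = 0.005, seed = 8)
  g <- genROMIFromModel(spec, "linear")
  resid <- surfaceValues(g$rho) - g$truth$mean
  ## 1000 cells: the empirical sd estimates sigma well
  expect_equal(sd(as.vector(resid)), 0.005, tolerance = 0.1)
})

test_that("mortality surfaces invert to the generating schedule", {
  spec <- scenarioSpec(nAges = 15, nYears = 10, horizon = 5, sigma = 0,
                       seed = 2)
  sim <- genMortalitySurface(spec)
  r <- computeROMI(sim$truth)
  expect_equal(surfaceValues(r), sim$schedule, tolerance = 1e-12,
               ignore_attr = TRUE)
  ## with observation noise the realized improvements are what the surface
  ## encodes, and they scatter around the schedule with s.d. sigma
  specN <- scenarioSpec(nAges = 40, nYears = 20, horizon = 0, sigma = 0.005,
                        seed = 2)
  simN <- genMortalitySurface(specN)
  rN <- computeROMI(simN$truth)
  expect_equal(surfaceValues(rN), simN$rhoRealized, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sd(simN$rhoRealized - simN$schedule), 0.005,
               tolerance = 0.1)
  ## Gompertz baseline: log m linear in age when c = 0
  spec0 <- scenarioSpec(nAges = 20, nYears = 5, horizon = 0,
                        gompertz = c(1e-4, 0.1, 0), schedule = "constant",
                        seed = 1)
  sim0 <- genMortalitySurface(spec0)
  lm0 <- log(surfaceValues(sim0$truth)[, 1])
  fits <- lm(lm0 ~ I(0:19))
  expect_equal(unname(coef(fits)), c(log(1e-4), 0.1), tolerance = 1e-10)
  expect_lt(max(abs(residuals(fits))), 1e-10)
})

test_that("Poisson mode concentrates on the truth at large exposure", {
  spec <- scenarioSpec(nAges = 50, nYears = 6, horizon = 0,
                       exposure = 1e7, seed = 13)
  sim <- genMortalitySurface(spec)
  expect_s4_class(sim$observed, "MortalitySurface")
  central <- 30:50  # adult ages, rates around 1e-3 and above
  rel <- abs(surfaceValues(sim$observed)[central, ] -
               surfaceValues(sim$truth)[central, ]) /
    surfaceValues(sim$truth)[central, ]
  expect_lt(median(rel, na.rm = TRUE), 0.01)
  expect_lt(max(rel, na.rm = TRUE), 0.05)
})

test_that("the convergent pair encodes stagnation and faster reference", {
  spec <- scenarioSpec(nAges = 60, nYears = 20, horizon = 5, seed = 21,
                       stagnationWindow = c(6L, 12L))
  pair <- genConvergentPair(spec)
  win <- 6:12
  ## inside the window the COI improves at the stagnation level only
  expect_true(all(pair$truth$coiSchedule[, win] ==
                    spec@hyper$stagnationLevel))
  expect_true(all(pair$truth$rcSchedule[, win] >
                    pair$truth$coiSchedule[, win]))
  ## COI life expectancy grows more slowly than the RC's during stagnation
  e0 <- function(s, yr) lifeExpectancy(surfaceValues(s)[, yr],
                                       ages = ages(s))
  coiGain <- e0(pair$coi$truth, 13) - e0(pair$coi$truth, 6)
  rcGain <- e0(pair$rc$truth, 13) - e0(pair$rc$truth, 6)
  expect_lt(coiGain, rcGain)
  ## zero-length window: schedules differ only by the reference boost
  spec0 <- scenarioSpec(nAges = 10, nYears = 8, horizon = 0, seed = 3,
                        stagnationWindow = c(0L, 0L))
  p0 <- genConvergentPair(spec0)
  expect_equal(p0$truth$rcSchedule - p0$truth$coiSchedule,
               matrix(spec0@hyper$rcBoost, 10, 7), tolerance = 1e-15,
               ignore_attr = TRUE)
  ## determinism
  p1 <- genConvergentPair(spec)
  expect_identical(surfaceValues(p1$coi$truth),
                   surfaceValues(pair$coi$truth))
})
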