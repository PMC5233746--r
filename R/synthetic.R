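#' @include forecast.R
NULL

## Synthetic mortality worlds with known structure, so every pipeline stage
## is testable without external data. A Gompertz-Makeham baseline
## m[x, 0] = a e^(b x) + c evolves under an age-specific improvement
## schedule rho_x(t); observation noise enters either as Gaussian noise on
## the ROMI scale or as Poisson death counts given an exposure level.

#' Create a synthetic-scenario specification
#'
#' The defaults emulate the forecasting set-up the package targets: 101
#' single ages 0-100, a 26-year base period (so 25 base transitions) and a
#' 21-year horizon — the shape of a validating forecast with at least as
#' many reference years as forecast years. The baseline is a
#' Gompertz-Makeham law with adult doubling time around 7 years
#' (`b = 0.1`); the default improvement schedule is the linear hierarchy
#' with overall mean improvement near 1.5% a year, between-age spread well
#' inside the 0.5-3.5% band of plausible sustained decline, and
#' observation noise `sigma = 0.005` on the ROMI scale.
#'
#' @param nAges number of single ages (ages 0..nAges-1, last open-ended).
#' @param nYears base-period years (transitions: nYears - 1).
#' @param horizon future years the truth extends over.
#' @param gompertz baseline coefficients `c(a, b, c)`.
#' @param schedule `"constant"`, `"linear"` (per-age intercept+slope drawn
#'   from the bivariate hierarchy) or `"loglinear"`
#'   (`exp(theta1 + theta2 log t)`).
#' @param hyper named list of schedule parameters. Used fields by schedule:
#'   constant — `level`; linear — `mu1, mu2, omega1, omega2, rhoCorr`;
#'   loglinear — `theta1, theta2` (scalars or per-age vectors). Optional
#'   for any schedule: `peakAmp, peakAge, peakWidth, peakDrift` add a
#'   Gaussian-in-age bump of extra improvement whose centre drifts upward
#'   with time (the aging of mortality decline).
#' @param sigma s.d. of Gaussian observation noise on generated ROMIs.
#' @param exposure person-years per cell for Poisson death counts
#'   (0 disables Poisson mode).
#' @param stagnationWindow `c(first, last)` transition indices of a
#'   near-zero-improvement episode for the convergent-pair generator;
#'   `c(0, 0)` for none.
#' @param seed RNG seed; the generators are deterministic given the spec.
#' @return a [ScenarioSpec-class].
#' @examples
#' scenarioSpec(nAges = 21, nYears = 16)
#' @export
scenarioSpec <- function(nAges = 101L, nYears = 26L, horizon = 21L,
                         gompertz = c(5e-5, 0.1, 5e-4),
                         schedule = c("linear", "constant", "loglinear"),
                         hyper = list(), sigma = 0.005, exposure = 0,
                         stagnationWindow = c(0L, 0L), seed = 1L) {
  schedule <- match.arg(schedule)
  defaults <- list(
    level = 0.015,
    mu1 = 0.012, mu2 = 2e-4, omega1 = 0.004, omega2 = 1.5e-4,
    rhoCorr = -0.4,
    theta1 = log(0.025), theta2 = -0.15,
    peakAmp = 0, peakAge = 70, peakWidth = 12, peakDrift = 0,
    stagnationLevel = 0.002, rcBoost = 0.006
  )
  defaults[names(hyper)] <- hyper
  new("ScenarioSpec", nAges = as.integer(nAges), nYears = as.integer(nYears),
      horizon = as.integer(horizon), gompertz = as.numeric(gompertz),
      schedule = schedule, hyper = defaults, sigma = as.numeric(sigma),
      exposure = as.numeric(exposure),
      stagnationWindow = as.integer(stagnationWindow),
      seed = as.integer(seed))
}

setMethod("show", "ScenarioSpec", function(object) {
  cat(sprintf(
    "ScenarioSpec: %d ages x %d base years + %d horizon, %s schedule, sigma=%g%s\n",
    object@nAges, object@nYears, object@horizon, object@schedule,
    object@sigma,
    if (object@exposure > 0) sprintf(", Poisson exposure %g", object@exposure)
    else ""
  ))
  invisible(NULL)
})

## deterministic part of the improvement schedule (and per-age parameters
## drawn from the hierarchy for the linear schedule); tTotal transitions
.trueSchedule <- function(spec, tTotal) {
  h <- spec@hyper
  A <- spec@nAges
  tSeq <- seq_len(tTotal)
  drawn <- list()
  base <- switch(spec@schedule,
    constant = matrix(rep(h$level, length.out = A), A, tTotal),
    linear = {
      ## per-age (beta1, beta2) from the bivariate hierarchy
      z1 <- stats::rnorm(A)
      z2 <- stats::rnorm(A)
      b1 <- h$mu1 + h$omega1 * z1
      b2 <- h$mu2 + h$omega2 * (h$rhoCorr * z1 + sqrt(1 - h$rhoCorr^2) * z2)
      drawn <- list(beta1 = b1, beta2 = b2)
      outer(b1, rep(1, tTotal)) + outer(b2, tSeq)
    },
    loglinear = {
      th1 <- rep(h$theta1, length.out = A)
      th2 <- rep(h$theta2, length.out = A)
      drawn <- list(theta1 = th1, theta2 = th2)
      exp(outer(th1, rep(1, tTotal)) + outer(th2, log(tSeq)))
    }
  )
  if (h$peakAmp > 0) {
    x <- seq_len(A) - 1L
    for (tt in tSeq) {
      ctr <- h$peakAge + h$peakDrift * tt
      base[, tt] <- base[, tt] +
        h$peakAmp * exp(-(x - ctr)^2 / (2 * h$peakWidth^2))
    }
  }
  attr(base, "drawn") <- drawn
  base
}

#' Generate an improvement-rate surface from a core model
#'
#' Draws per-age coefficients from the linear hierarchy (or sets them to
#' the log-linear schedule's coefficients), then adds independent
#' N(0, sigma^2) observation noise per cell. The returned truth record
#' contains everything needed to score parameter recovery.
#'
#' @param spec a [scenarioSpec()].
#' @param model `"linear"` or `"exponential"` (maps to the linear /
#'   loglinear schedule regardless of `spec`'s schedule field).
#' @param startYear calendar label of the first transition.
#' @return list with `rho` ([ROMISurface-class], base transitions only) and
#'   `truth` (named list of generating parameters).
#' @export
genROMIFromModel <- function(spec, model = c("linear", "exponential"),
                             startYear = 1965L) {
  model <- match.arg(model)
  set.seed(spec@seed)
  specUse <- spec
  specUse@schedule <- if (model == "linear") "linear" else "loglinear"
  Tn <- spec@nYears - 1L
  mean <- .trueSchedule(specUse, Tn)
  rho <- mean + matrix(stats::rnorm(length(mean), 0, spec@sigma),
                       nrow(mean))
  yrs <- startYear + seq_len(Tn) - 1L
  truth <- c(attr(mean, "drawn"),
             list(sigma = spec@sigma, hyper = spec@hyper, mean = mean))
  list(rho = ROMISurface(rho, seq_len(spec@nAges) - 1L, yrs,
                         list(kind = "synthetic", model = model)),
       truth = truth)
}

#' Generate a full synthetic mortality surface
#'
#' Builds the baseline from the Gompertz-Makeham law, evolves
#' m\[x, t+1\] = m\[x, t\] (1 - rho_x(t)) over base period plus horizon,
#' and optionally draws death counts D ~ Poisson(E m) to produce a noisy
#' observed surface (cells with zero simulated deaths become missing, as a
#' zero rate cannot feed the improvement-rate transform). When `sigma > 0`
#' the realized improvements carry Gaussian noise, so the surface is one
#' draw from the stochastic world the core models assume; the noise-free
#' schedule and the realized improvements are both returned.
#'
#' @param spec a [scenarioSpec()].
#' @param startYear calendar label of the first rate year.
#' @return list with `truth` ([MortalitySurface-class] over all years),
#'   `observed` (Poisson-noise surface or NULL), `deaths` and `exposures`
#'   ([ExposureSurface-class] or NULL), `schedule` (the noise-free
#'   improvement matrix), `rhoRealized` (the noisy improvements actually
#'   applied) and `params` (drawn schedule parameters).
#' @export
genMortalitySurface <- function(spec, startYear = 1965L) {
  set.seed(spec@seed)
  A <- spec@nAges
  x <- seq_len(A) - 1L
  g <- spec@gompertz
  m0 <- g[1] * exp(g[2] * x) + g[3]
  tTotal <- spec@nYears + spec@horizon - 1L
  sched <- .trueSchedule(spec, tTotal)
  if (any(sched >= 1)) stop("improvement schedule reaches 1: rates would",
                            " become non-positive")
  ## realized improvements carry the Gaussian observation noise, so the
  ## evolved rates are one draw from the world the core models assume
  rhoReal <- sched
  if (spec@sigma > 0) {
    rhoReal <- sched + matrix(stats::rnorm(length(sched), 0, spec@sigma),
                              nrow(sched))
  }
  m <- matrix(NA_real_, A, tTotal + 1L)
  m[, 1L] <- m0
  for (tt in seq_len(tTotal)) m[, tt + 1L] <- m[, tt] * (1 - rhoReal[, tt])
  yrs <- startYear + 0:tTotal
  truth <- MortalitySurface(m, x, yrs, list(kind = "synthetic-truth"))
  out <- list(truth = truth, observed = NULL, deaths = NULL,
              exposures = NULL, schedule = sched, rhoRealized = rhoReal,
              params = attr(sched, "drawn"))
  if (spec@exposure > 0) {
    E <- matrix(spec@exposure, A, tTotal + 1L)
    D <- matrix(stats::rpois(length(m), E * m), A)
    deaths <- ExposureSurface(D, x, yrs, list(kind = "synthetic-deaths"))
    expo <- ExposureSurface(E, x, yrs, list(kind = "synthetic-exposures"))
    out$deaths <- deaths
    out$exposures <- expo
    out$observed <- ratesFromCounts(deaths, expo)
  }
  out
}

#' Generate a convergent country pair
#'
#' The country of interest (COI) follows the scenario's schedule but with a
#' stagnation episode — improvement pinned near zero inside
#' `stagnationWindow` — after which it resumes by converging to the trend
#' of the reference country (RC), which improves steadily faster (schedule
#' plus `hyper$rcBoost`) throughout. This is the canonical turning-point
#' situation for blending the COI forecast toward the RC trend.
#'
#' @param spec a [scenarioSpec()]; set `stagnationWindow` to a mid-period
#'   index window, e.g. `c(8, 15)`.
#' @param startYear calendar label of the first rate year.
#' @return list with elements `coi` and `rc` (each as returned by
#'   [genMortalitySurface()]) and `truth` holding both schedules.
#' @export
genConvergentPair <- function(spec, startYear = 1965L) {
  set.seed(spec@seed)
  h <- spec@hyper
  tTotal <- spec@nYears + spec@horizon - 1L
  sched <- .trueSchedule(spec, tTotal)
  win <- spec@stagnationWindow
  coiSched <- sched
  rcSched <- sched + h$rcBoost
  if (win[2] >= win[1] && win[1] >= 1L) {
    idx <- win[1]:min(win[2], tTotal)
    coiSched[, idx] <- h$stagnationLevel
    ## after the episode the COI resumes by converging to the reference
    ## trend — the canonical turning-point narrative the blend targets
    if (win[2] < tTotal) {
      post <- (win[2] + 1L):tTotal
      coiSched[, post] <- rcSched[, post]
    }
  }

  evolve <- function(schedule, label) {
    A <- spec@nAges
    x <- seq_len(A) - 1L
    g <- spec@gompertz
    rhoReal <- schedule
    if (spec@sigma > 0) {
      rhoReal <- schedule +
        matrix(stats::rnorm(length(schedule), 0, spec@sigma), A)
    }
    m <- matrix(NA_real_, A, tTotal + 1L)
    m[, 1L] <- g[1] * exp(g[2] * x) + g[3]
    for (tt in seq_len(tTotal)) m[, tt + 1L] <- m[, tt] * (1 - rhoReal[, tt])
    ms <- MortalitySurface(m, x, startYear + 0:tTotal,
                           list(kind = "synthetic-truth", population = label))
    out <- list(truth = ms, observed = NULL, deaths = NULL,
                exposures = NULL, schedule = schedule, rhoRealized = rhoReal)
    if (spec@exposure > 0) {
      E <- matrix(spec@exposure, A, tTotal + 1L)
      D <- matrix(stats::rpois(length(m), E * m), A)
      out$deaths <- ExposureSurface(D, x, startYear + 0:tTotal,
                                    list(population = label))
      out$exposures <- ExposureSurface(E, x, startYear + 0:tTotal,
                                       list(population = label))
      out$observed <- ratesFromCounts(out$deaths, out$exposures)
    }
    out
  }
  list(coi = evolve(coiSched, "COI"), rc = evolve(rcSched, "RC"),
       truth = list(coiSchedule = coiSched, rcSchedule = rcSched,
                    window = win))
}
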