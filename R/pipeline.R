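#' @include synthetic.R validation.R smoothing.R diagnostics.R
NULL

## End-to-end runs driven by a configuration list (optionally loaded from
## YAML): smooth -> ROMI -> fit -> predict -> (blend) -> propagate ->
## summarize, plus a validating variant that scores a held-out period and
## a scenario writer. Every run is reproducible from its manifest.

#' Default run configuration
#'
#' Returns the full configuration list with the package defaults: clip
#' bounds \[0.005, 0.035\], five chains of 5200 iterations after a burn-in
#' of 200 with thinning 5, the exponential core model, smoothing off, and
#' convergence off. Any subset can be overridden via `...` (nested lists
#' are merged field-wise).
#'
#' @param ... named overrides, e.g. `model = "linear"`,
#'   `mcmc = list(nChains = 2)`.
#' @return a named configuration list.
#' @examples
#' cfg <- runConfig(horizon = 10, mcmc = list(nIterations = 500))
#' cfg$mcmc$nChains
#' @export
runConfig <- function(...) {
  base <- list(
    seed = 1L,
    model = "exponential",
    horizon = 21L,
    basePeriod = NULL,           # c(firstYear, lastYear) or NULL = all
    input = list(kind = "scenario", scenario = list(), rates = NULL,
                 deaths = NULL, exposures = NULL, sex = "Female",
                 openAge = 100L),
    smoothing = list(enabled = FALSE, penaltyOrder = 2L,
                     lambdaGrid = 10^seq(-2, 6, by = 1),
                     mode = "time-per-age"),
    clip = list(low = 0.005, high = 0.035),
    convergence = list(shape = "off", startYear = 1L, rc = NULL),
    mcmc = list(nChains = 5L, nIterations = 5200L, burnIn = 200L,
                thin = 5L),
    quantiles = c(0.025, 0.10, 0.165, 0.25, 0.5, 0.75, 0.835, 0.90, 0.975),
    intervals = c(0.50, 0.67, 0.80, 0.95),
    jumpoff = "smoothed",        # or "observed"
    includeNoise = TRUE,
    exAge = 65L,
    sex = "female",
    floor = 1e-4,
    outDir = NULL,
    logLevel = "info"
  )
  .mergeConfig(base, list(...))
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file and merges it onto [runConfig()]'s defaults.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
loadRunConfig <- function(path) {
  do.call(runConfig, yaml::read_yaml(path))
}

.logMsg <- function(cfg, ...) {
  if (!identical(cfg$logLevel, "quiet")) message("[romicast] ", ...)
}

## resolve the input block into (rates, deaths, exposures) surfaces
.loadInput <- function(cfg) {
  inp <- cfg$input
  if (inp$kind == "scenario") {
    spec <- do.call(scenarioSpec, inp$scenario)
    ## a stagnation window marks a convergent-pair scenario: the country of
    ## interest is the stagnating member of the pair
    sim <- if (spec@stagnationWindow[1] > 0L) {
      genConvergentPair(spec)$coi
    } else {
      genMortalitySurface(spec)
    }
    rates <- if (!is.null(sim$observed)) sim$observed else sim$truth
    list(rates = rates, deaths = sim$deaths, exposures = sim$exposures,
         truth = sim)
  } else if (inp$kind == "csv") {
    list(rates = readSurfaceCSV(inp$rates, "rates"), deaths = NULL,
         exposures = NULL, truth = NULL)
  } else if (inp$kind == "hmd") {
    if (!is.null(inp$deaths) && !is.null(inp$exposures)) {
      d <- readHMDTable(inp$deaths, "deaths", inp$sex, inp$openAge)
      e <- readHMDTable(inp$exposures, "exposures", inp$sex, inp$openAge)
      list(rates = ratesFromCounts(d, e), deaths = d, exposures = e,
           truth = NULL)
    } else {
      list(rates = readHMDTable(inp$rates, "rates", inp$sex, inp$openAge),
           deaths = NULL, exposures = NULL, truth = NULL)
    }
  } else {
    stop("unknown input kind '", inp$kind, "'")
  }
}

.subsetBase <- function(surface, basePeriod) {
  if (is.null(basePeriod)) return(surface)
  yrs <- surface@years
  keep <- yrs[yrs >= basePeriod[1] & yrs <= basePeriod[2]]
  if (!length(keep)) stop("base period outside the data's year range")
  surface[, keep]
}

.loadRC <- function(cfg, baseSurface) {
  rcSpec <- cfg$convergence$rc
  if (is.null(rcSpec)) stop("convergence enabled but no reference countries")
  if (identical(rcSpec, "scenario")) {
    spec <- do.call(scenarioSpec, cfg$input$scenario)
    pair <- genConvergentPair(spec)
    rates <- if (!is.null(pair$rc$observed)) pair$rc$observed
             else pair$rc$truth
    list(.subsetBase(rates, cfg$basePeriod))
  } else {
    lapply(rcSpec, function(p) {
      .subsetBase(readSurfaceCSV(p, "rates"), cfg$basePeriod)
    })
  }
}

.writeManifest <- function(cfg, outDir, stage) {
  cfgPath <- file.path(outDir, "config.json")
  jsonlite::write_json(cfg, cfgPath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(
    stage = stage,
    seed = cfg$seed,
    configHash = unname(tools::md5sum(cfgPath)),
    package = "romicast",
    version = as.character(utils::packageVersion("romicast")),
    rVersion = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

## shared front half of forecast/validation runs; returns the fitted model,
## the forecast result and the (possibly smoothed) base surface
.fitAndForecast <- function(cfg, rates, deaths, exposures) {
  stage <- "input"
  withCallingHandlers({
    stage <- "smoothing"
    baseRates <- .subsetBase(rates, cfg$basePeriod)
    if (isTRUE(cfg$smoothing$enabled)) {
      if (is.null(deaths) || is.null(exposures)) {
        stop("smoothing requires death counts and exposures")
      }
      smCfg <- smoothingConfig(cfg$smoothing$penaltyOrder,
                               cfg$smoothing$lambdaGrid,
                               mode = cfg$smoothing$mode)
      baseRates <- smoothRates(.subsetBase(deaths, cfg$basePeriod),
                               .subsetBase(exposures, cfg$basePeriod),
                               smCfg)
    }
    nBase <- length(baseRates@years)
    if (cfg$horizon > nBase) {
      warning("horizon (", cfg$horizon, ") exceeds the base period length (",
              nBase, " years); at least as many reference years as forecast",
              " years are recommended", call. = FALSE)
    }

    stage <- "romi"
    rho <- computeROMI(baseRates)

    stage <- "fit"
    mc <- mcmcConfig(cfg$mcmc$nChains, cfg$mcmc$nIterations, cfg$mcmc$burnIn,
                     cfg$mcmc$thin, seed = cfg$seed)
    pd <- runSampler(rho, cfg$model, mc, floor = cfg$floor)

    stage <- "predict"
    bounds <- clipBounds(cfg$clip$low, cfg$clip$high)
    set.seed(cfg$seed + 1L)
    rc <- NULL
    weights <- NULL
    if (!identical(cfg$convergence$shape, "off")) {
      stage <- "blend"
      rcSurfaces <- .loadRC(cfg, baseRates)
      rcRho <- referenceMeanROMI(lapply(rcSurfaces, computeROMI))
      rcFit <- runSampler(rcRho, cfg$model, mc, floor = cfg$floor)
      rc <- posteriorPredictROMI(rcFit, cfg$horizon, bounds,
                                 cfg$includeNoise)
      weights <- convergenceSchedule(cfg$convergence$shape, cfg$horizon,
                                     cfg$convergence$startYear)
    }

    stage <- "propagate"
    jump <- if (identical(cfg$jumpoff, "observed")) {
      .subsetBase(rates, cfg$basePeriod)
    } else {
      baseRates
    }
    fr <- forecastMortality(pd, jump, cfg$horizon, bounds, cfg$includeNoise,
                            cfg$quantiles, rc = rc, weights = weights,
                            exAge = cfg$exAge, sex = cfg$sex)
    list(pd = pd, fr = fr, baseRates = baseRates)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run a full mortality forecast
#'
#' Executes smooth -> ROMI -> fit -> predict -> (blend) -> propagate ->
#' summarize according to the configuration and, if `outDir` is set,
#' writes the forecast tables, diagnostics and a machine-readable run
#' manifest (config hash, seed, versions).
#'
#' @param cfg configuration list from [runConfig()] or [loadRunConfig()].
#' @return a list with `forecast` (a [ForecastResult-class]), `fit`
#'   (a [ParameterDraws-class]) and `baseRates`, invisibly when writing.
#' @export
runForecast <- function(cfg = runConfig()) {
  lo <- .loadInput(cfg)
  res <- .fitAndForecast(cfg, lo$rates, lo$deaths, lo$exposures)
  out <- list(forecast = res$fr, fit = res$pd, baseRates = res$baseRates)
  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    tabs <- forecastTables(res$fr)
    utils::write.csv(tabs$rates, file.path(cfg$outDir, "rate_quantiles.csv"),
                     row.names = FALSE)
    utils::write.csv(tabs$e0, file.path(cfg$outDir, "e0_quantiles.csv"),
                     row.names = FALSE)
    diag <- chainDiagnostics(res$pd)
    utils::write.csv(diag$acf, file.path(cfg$outDir, "diagnostics_acf.csv"),
                     row.names = FALSE)
    if (!is.null(diag$rhat)) {
      utils::write.csv(diag$rhat,
                       file.path(cfg$outDir, "diagnostics_rhat.csv"),
                       row.names = FALSE)
    }
    .writeManifest(cfg, cfg$outDir, "forecast")
    .logMsg(cfg, "forecast written to ", cfg$outDir)
    return(invisible(out))
  }
  out
}

#' Run a validating forecast against a held-out period
#'
#' Fits on the configured base period, forecasts over the held-out years
#' still present in the data, and scores the median life-expectancy
#' forecast (errors, MAE) and the empirical coverage of each configured
#' central prediction interval. Requires observed data covering base +
#' holdout.
#'
#' @param cfg configuration list; `basePeriod` must end before the last
#'   observed year, and `horizon` years after it must be observed.
#' @return list with `errors`, `mae`, `coverage` (data frame: level,
#'   coverage percent), `e0Observed`, `e0Quantiles`, and the fitted
#'   objects.
#' @export
runValidation <- function(cfg = runConfig()) {
  lo <- .loadInput(cfg)
  rates <- lo$rates
  if (is.null(cfg$basePeriod)) {
    stop("validation requires an explicit basePeriod")
  }
  lastBase <- cfg$basePeriod[2]
  holdoutYears <- (lastBase + 1L):(lastBase + cfg$horizon)
  if (!all(holdoutYears %in% rates@years)) {
    stop("holdout years ", min(holdoutYears), "-", max(holdoutYears),
         " extend beyond the observed data")
  }
  res <- .fitAndForecast(cfg, rates, lo$deaths, lo$exposures)
  fr <- res$fr

  obs <- rates[, holdoutYears]
  e0Obs <- vapply(seq_along(holdoutYears), function(j) {
    mx <- obs@values[, j]
    if (anyNA(mx)) stop("missing observed rates in the holdout period")
    lifeExpectancy(mx, ages = obs@ages, sex = cfg$sex)
  }, numeric(1))
  names(e0Obs) <- holdoutYears

  lv <- fr@quantileLevels
  medRow <- which.min(abs(lv - 0.5))
  e0Med <- fr@e0Quantiles[medRow, ]
  fe <- forecastErrors(stats::setNames(e0Med, fr@years), e0Obs)
  cov <- do.call(rbind, lapply(cfg$intervals, function(ci) {
    loLv <- (1 - ci) / 2
    hiLv <- 1 - loLv
    iLo <- which.min(abs(lv - loLv))
    iHi <- which.min(abs(lv - hiLv))
    data.frame(level = ci,
               coverage = empiricalCoverage(fr@e0Quantiles[iLo, ],
                                            fr@e0Quantiles[iHi, ], e0Obs))
  }))
  out <- list(errors = fe$errors, mae = fe$mae, coverage = cov,
              e0Observed = e0Obs, e0Quantiles = fr@e0Quantiles,
              forecast = fr, fit = res$pd)
  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(
      data.frame(year = as.integer(names(fe$errors)), error = fe$errors,
                 row.names = NULL),
      file.path(cfg$outDir, "validation_errors.csv"), row.names = FALSE
    )
    utils::write.csv(cov, file.path(cfg$outDir, "validation_coverage.csv"),
                     row.names = FALSE)
    txt <- c(
      sprintf("Validation %d-%d (base %d-%d)", min(holdoutYears),
              max(holdoutYears), cfg$basePeriod[1], cfg$basePeriod[2]),
      sprintf("Mean absolute error of median e0 forecast: %.3f years",
              fe$mae),
      sprintf("Coverage of %d%% interval: %.1f%%", round(100 * cov$level),
              cov$coverage)
    )
    writeLines(txt, file.path(cfg$outDir, "validation_summary.txt"))
    .writeManifest(cfg, cfg$outDir, "validate")
    .logMsg(cfg, "validation written to ", cfg$outDir)
    return(invisible(out))
  }
  out
}

#' Write a synthetic scenario to disk
#'
#' Generates the scenario (a single population, or a convergent COI/RC
#' pair when the stagnation window is set) and writes the surfaces as
#' surface CSVs plus a truth record as JSON.
#'
#' @param spec a [scenarioSpec()] or path to a YAML file of its arguments.
#' @param outDir output directory.
#' @param pair force generation of the convergent COI/RC pair.
#' @return invisible list of written paths.
#' @export
simulateScenario <- function(spec, outDir, pair = NULL) {
  if (is.character(spec)) spec <- do.call(scenarioSpec, yaml::read_yaml(spec))
  stopifnot(is(spec, "ScenarioSpec"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(pair)) pair <- spec@stagnationWindow[1] > 0L
  paths <- list()
  writeOne <- function(sim, prefix) {
    p <- file.path(outDir, paste0(prefix, "_truth_rates.csv"))
    writeSurfaceCSV(sim$truth, p)
    paths[[paste0(prefix, "Truth")]] <<- p
    if (!is.null(sim$observed)) {
      p2 <- file.path(outDir, paste0(prefix, "_observed_rates.csv"))
      writeSurfaceCSV(sim$observed, p2)
      paths[[paste0(prefix, "Observed")]] <<- p2
    }
    sim
  }
  if (pair) {
    sims <- genConvergentPair(spec)
    writeOne(sims$coi, "coi")
    writeOne(sims$rc, "rc")
    truth <- list(kind = "convergent-pair",
                  coiSchedule = sims$truth$coiSchedule,
                  rcSchedule = sims$truth$rcSchedule,
                  window = sims$truth$window)
  } else {
    sim <- writeOne(genMortalitySurface(spec), "coi")
    truth <- list(kind = "single", schedule = sim$schedule,
                  params = sim$params)
  }
  tp <- file.path(outDir, "truth.json")
  jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA)
  paths$truth <- tp
  invisible(paths)
}
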