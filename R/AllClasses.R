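#' @import methods
NULL

## Central data containers. A Lexis surface is a rectangular grid of a
## demographic quantity by single age (rows) and calendar year (columns);
## missing cells are NA, never silently zero.

#' Virtual parent of all age-by-year grids
#'
#' A `LexisSurface` holds a numeric matrix `values` indexed by integer
#' `ages` (rows) and integer `years` (columns), plus free-form `metadata`
#' (population label, sex, source, smoothing record, ...). Missing cells are
#' `NA`. Both axes must be contiguous and strictly increasing by 1.
#'
#' @slot values numeric matrix, `length(ages)` x `length(years)`.
#' @slot ages integer vector of single ages, last one open-ended by
#'   convention.
#' @slot years integer vector of calendar years.
#' @slot metadata named list.
#' @keywords classes
setClass("LexisSurface",
  representation("VIRTUAL",
    values = "matrix",
    ages = "integer",
    years = "integer",
    metadata = "list"
  )
)

.validLexis <- function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "'values' must be a numeric matrix")
  if (nrow(v) != length(object@ages) || ncol(v) != length(object@years)) {
    msg <- c(msg, sprintf(
      "values is %d x %d but there are %d ages and %d years",
      nrow(v), ncol(v), length(object@ages), length(object@years)
    ))
  }
  if (length(object@ages) == 0L || length(object@years) == 0L) {
    msg <- c(msg, "surface must have at least one age and one year")
  }
  if (length(object@ages) > 1L && !all(diff(object@ages) == 1L)) {
    msg <- c(msg, "ages must be contiguous and strictly increasing by 1")
  }
  if (length(object@years) > 1L && !all(diff(object@years) == 1L)) {
    msg <- c(msg, "years must be contiguous and strictly increasing by 1")
  }
  if (any(is.infinite(v))) msg <- c(msg, "values must be finite or NA")
  if (length(msg)) msg else TRUE
}

setValidity("LexisSurface", .validLexis)

#' Death-rate surface
#'
#' Central death rates m\[x, t\] (deaths per person-year) on a Lexis grid.
#' Non-missing cells must be strictly positive: a zero rate cannot enter the
#' improvement-rate transform, which divides by m\[x, t\], so zeros are
#' flagged missing at construction time by [ratesFromCounts()] and the
#' readers.
#'
#' @seealso [MortalitySurface()], [computeROMI()], [ratesFromCounts()]
#' @keywords classes
#' @export
setClass("MortalitySurface", contains = "LexisSurface")

setValidity("MortalitySurface", function(object) {
  v <- object@values
  if (any(v <= 0, na.rm = TRUE)) {
    "death rates must be strictly positive where not missing"
  } else {
    TRUE
  }
})

#' Exposure or death-count surface
#'
#' Person-years of exposure E\[x, t\] (or death counts D\[x, t\]) on a Lexis
#' grid; values must be non-negative where not missing.
#'
#' @keywords classes
#' @export
setClass("ExposureSurface", contains = "LexisSurface")

setValidity("ExposureSurface", function(object) {
  v <- object@values
  if (any(v < 0, na.rm = TRUE)) {
    "exposures/counts must be non-negative where not missing"
  } else {
    TRUE
  }
})

#' Rate-of-mortality-improvement surface
#'
#' Annual proportional improvement rho\[x, t\] = -(m\[x, t+1\]/m\[x, t\] - 1),
#' positive when mortality falls. The year label of each column is the
#' EARLIER year of the transition it describes: the column labelled t holds
#' the m\[x, t\] -> m\[x, t+1\] improvement.
#'
#' @seealso [computeROMI()], [invertROMI()], [clipROMI()]
#' @keywords classes
#' @export
setClass("ROMISurface", contains = "LexisSurface")

#' Posterior draws of core-model parameters
#'
#' Retained MCMC draws for one core model, pooled across chains. Each element
#' of `draws` is a matrix with one row per retained draw (all chains stacked)
#' and one column per scalar component (per-age vectors such as `beta1` have
#' one column per age). `chain` tags every row with its chain index.
#'
#' @slot model `"linear"` or `"exponential"`.
#' @slot draws named list of draw matrices.
#' @slot chain integer vector, chain index of each row.
#' @slot ages integer vector of the fitted ages.
#' @slot config the [mcmcConfig()] list used.
#' @slot priors the prior specification used.
#' @slot acceptance named numeric vector of Metropolis acceptance rates.
#' @slot prefit named list; for the exponential model the OLS anchors
#'   `theta1Hat`, `theta2Hat`.
#' @keywords classes
#' @export
setClass("ParameterDraws",
  representation(
    model = "character",
    draws = "list",
    chain = "integer",
    ages = "integer",
    config = "list",
    priors = "list",
    acceptance = "numeric",
    prefit = "list"
  )
)

setValidity("ParameterDraws", function(object) {
  msg <- character()
  if (!object@model %in% c("linear", "exponential")) {
    msg <- c(msg, "model must be 'linear' or 'exponential'")
  }
  n <- length(object@chain)
  bad <- vapply(object@draws, function(m) nrow(m) != n, logical(1))
  if (any(bad)) {
    msg <- c(msg, "all draw matrices must have one row per retained draw")
  }
  if (length(msg)) msg else TRUE
})

#' Forecast output container
#'
#' Posterior-predictive ROMI draws together with the quantile surfaces of
#' future death rates and the life-expectancy trajectories derived from them.
#'
#' @slot romiDraws numeric array (draw, age, forecast year) of
#'   posterior-predictive improvement rates, after any clipping/blending.
#' @slot rateQuantiles named list of [MortalitySurface-class] objects, one per
#'   quantile level, over the forecast years.
#' @slot e0Quantiles numeric matrix (quantile level x forecast year) of life
#'   expectancy at birth.
#' @slot exQuantiles numeric matrix as `e0Quantiles` but for the remaining
#'   life expectancy at `exAge`.
#' @slot exAge integer, age for `exQuantiles` (default 65).
#' @slot quantileLevels numeric vector of requested levels.
#' @slot jumpoff numeric vector of jump-off rates (last base-year column).
#' @slot ages,years integer axes of the forecast grid.
#' @keywords classes
#' @export
setClass("ForecastResult",
  representation(
    romiDraws = "array",
    rateQuantiles = "list",
    e0Quantiles = "matrix",
    exQuantiles = "matrix",
    exAge = "integer",
    quantileLevels = "numeric",
    jumpoff = "numeric",
    ages = "integer",
    years = "integer"
  )
)

#' Synthetic-scenario specification
#'
#' Describes a synthetic mortality world: a Gompertz-Makeham baseline
#' m\[x, 0\] = a e^(b x) + c, an age-specific improvement schedule rho_x(t),
#' optional observation noise (Gaussian on the ROMI scale and/or Poisson
#' death counts given an exposure level), and an optional faster-improving
#' reference population toward which the population of interest converges
#' after a stagnation episode.
#'
#' @slot nAges integer number of single ages (ages run 0 .. nAges-1).
#' @slot nYears integer number of base-period years.
#' @slot horizon integer number of future years the truth extends over.
#' @slot gompertz numeric `c(a, b, c)` baseline coefficients.
#' @slot schedule character, one of `"constant"`, `"linear"`, `"loglinear"`.
#' @slot hyper named list of schedule parameters (see [scenarioSpec()]).
#' @slot sigma numeric, s.d. of Gaussian noise on observed ROMIs.
#' @slot exposure numeric, person-years per cell for Poisson mode (0 = off).
#' @slot stagnationWindow integer length-2 year-index window of near-zero
#'   improvement for the convergent-pair generator (c(0, 0) = none).
#' @slot seed integer RNG seed.
#' @keywords classes
#' @export
setClass("ScenarioSpec",
  representation(
    nAges = "integer",
    nYears = "integer",
    horizon = "integer",
    gompertz = "numeric",
    schedule = "character",
    hyper = "list",
    sigma = "numeric",
    exposure = "numeric",
    stagnationWindow = "integer",
    seed = "integer"
  )
)

setValidity("ScenarioSpec", function(object) {
  msg <- character()
  if (object@nAges < 2L) msg <- c(msg, "nAges must be >= 2")
  if (object@nYears < 3L) msg <- c(msg, "nYears must be >= 3")
  if (object@horizon < 0L) msg <- c(msg, "horizon must be >= 0")
  if (length(object@gompertz) != 3L || any(object@gompertz < 0)) {
    msg <- c(msg, "gompertz must be c(a, b, c) with non-negative entries")
  }
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (object@exposure < 0) msg <- c(msg, "exposure must be >= 0")
  if (!object@schedule %in% c("constant", "linear", "loglinear")) {
    msg <- c(msg, "schedule must be constant, linear or loglinear")
  }
  if (length(msg)) msg else TRUE
})
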