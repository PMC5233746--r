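#' @include forecast.R
NULL

#' Forecast errors against held-out observations
#'
#' E_t = e0_forecast(t) - e0_observed(t): an overestimate of life
#' expectancy gives a positive error. The mean absolute error summarizes
#' the series.
#'
#' @param forecast numeric vector of forecast life expectancies (by
#'   convention the median trajectory), optionally named by year.
#' @param observed numeric vector of observed values, same years.
#' @return list with `errors` (named numeric) and `mae`.
#' @examples
#' forecastErrors(c(`1991` = 85.0), c(`1991` = 84.5))  # E = +0.5
#' @export
forecastErrors <- function(forecast, observed) {
  if (length(forecast) != length(observed)) {
    stop("forecast and observed series have different lengths")
  }
  if (!is.null(names(forecast)) && !is.null(names(observed)) &&
      !identical(names(forecast), names(observed))) {
    stop("forecast and observed years do not match")
  }
  e <- forecast - observed
  list(errors = e, mae = mean(abs(e)))
}

#' Empirical coverage of a prediction interval
#'
#' Percentage of held-out years whose observed value falls inside
#' `[lower, upper]`; values exactly on a bound count as inside.
#'
#' @param lower,upper interval bound trajectories (`lower <= upper`
#'   everywhere).
#' @param observed observed trajectory, same years.
#' @return coverage in percent.
#' @examples
#' empiricalCoverage(c(1, 1), c(3, 3), c(2, 4))  # 50
#' @export
empiricalCoverage <- function(lower, upper, observed) {
  if (length(lower) != length(upper) || length(lower) != length(observed)) {
    stop("trajectories have different lengths")
  }
  if (any(lower > upper)) stop("crossing interval bounds")
  100 * mean(observed >= lower & observed <= upper)
}

#' Prior-sensitivity harness
#'
#' Refits a core model once per prior family (same data, same MCMC
#' configuration and seed) and tabulates the posterior medians of the
#' hyper-parameters; optionally also the median life-expectancy forecast
#' path per family and its deviation from the first family.
#'
#' @param rho base-period [ROMISurface-class].
#' @param model `"linear"` or `"exponential"`.
#' @param priorFamilies named list of prior overrides, one element per
#'   family (each a (partial) named list of [priorSpec()] objects);
#'   e.g. uniform / beta / normal specifications for sigma.
#' @param config an [mcmcConfig()].
#' @param jumpoff optional jump-off rates; with `horizon`, median e0 paths
#'   are compared across families.
#' @param horizon optional forecast length for the e0 comparison.
#' @param bounds clip bounds for the e0 comparison.
#' @return list with `table` (data frame: family, parameter, median) and,
#'   when `jumpoff` is given, `e0Median` (family x year matrix) and
#'   `e0Delta` (max abs deviation from the first family, per family).
#' @export
priorSensitivityDefaults <- function() {
  list(
    uniform = list(sigma = priorSpec("uniform", c(0, 1))),
    beta = list(sigma = priorSpec("beta", c(0, 1), shape1 = 2, shape2 = 2)),
    normal = list(sigma = priorSpec("normal", c(0, 1), mean = 0.05,
                                    sd = 0.1))
  )
}

#' @rdname priorSensitivityDefaults
#' @export
priorSensitivity <- function(rho, model = c("linear", "exponential"),
                             priorFamilies = priorSensitivityDefaults(),
                             config = mcmcConfig(), jumpoff = NULL,
                             horizon = NULL, bounds = clipBounds()) {
  model <- match.arg(model)
  if (length(priorFamilies) < 2L) stop("need at least two prior families")
  fits <- lapply(priorFamilies, function(pf) {
    runSampler(rho, model, config, priors = pf)
  })
  rows <- list()
  for (fam in names(fits)) {
    d <- fits[[fam]]@draws
    for (p in names(d)) {
      if (ncol(d[[p]]) != 1L) next
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, parameter = p, median = stats::median(d[[p]][, 1L])
      )
    }
  }
  out <- list(table = do.call(rbind, rows))
  if (!is.null(jumpoff) && !is.null(horizon)) {
    e0 <- sapply(fits, function(f) {
      ## common random numbers across families: differences reflect the
      ## priors, not the predictive noise stream
      set.seed(config$seed)
      draws <- posteriorPredictROMI(f, horizon, bounds, includeNoise = TRUE)
      rq <- propagateRates(jumpoff, draws, 0.5)
      summarizeE0(rq)[1L, ]
    })
    e0 <- t(e0)
    out$e0Median <- e0
    out$e0Delta <- apply(abs(sweep(e0, 2L, e0[1L, ])), 1L, max)
  }
  out
}
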