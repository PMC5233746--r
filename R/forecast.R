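#' @include mcmc.R lifetable.R
NULL

.defaultQuantiles <- c(0.025, 0.10, 0.165, 0.25, 0.5, 0.75, 0.835, 0.90,
                       0.975)

#' Posterior-predictive draws of future improvement rates
#'
#' For every retained parameter draw the model-mean ROMI path over the
#' forecast times T+1..T+H is computed; if `includeNoise` an independent
#' N(0, sigma^2) innovation is added per cell (the draw's own sigma); the
#' result is clamped to `bounds`. Uses the current R RNG stream — seed
#' before calling for reproducibility.
#'
#' @param pd a [ParameterDraws-class] from [runSampler()].
#' @param horizon number of forecast years H >= 1.
#' @param bounds a [clipBounds()]; `clipBounds(-Inf, Inf)` disables
#'   clamping.
#' @param includeNoise add the observation-level innovation (default TRUE).
#' @return numeric array (draw, age, forecast year).
#' @export
posteriorPredictROMI <- function(pd, horizon, bounds = clipBounds(),
                                 includeNoise = TRUE) {
  stopifnot(is(pd, "ParameterDraws"), horizon >= 1L)
  baseT <- pd@config$baseT
  if (is.null(baseT)) {
    stop("ParameterDraws carries no base-period length; refit with ",
         "runSampler()")
  }
  tSeq <- baseT + seq_len(horizon)
  b1 <- pd@draws$beta1
  b2 <- pd@draws$beta2
  nD <- nrow(b1)
  A <- ncol(b1)
  out <- array(NA_real_, c(nD, A, horizon))
  for (h in seq_len(horizon)) {
    out[, , h] <- if (pd@model == "linear") b1 + b2 * tSeq[h]
                  else exp(b1 + b2 * log(tSeq[h]))
  }
  if (includeNoise) {
    out <- out + array(stats::rnorm(length(out)), dim(out)) *
      as.vector(pd@draws$sigma)
  }
  out <- pmin(pmax(out, bounds$low), bounds$high)
  lastYear <- pd@config$lastYear
  yearLab <- if (is.null(lastYear)) tSeq else lastYear + seq_len(horizon)
  dimnames(out) <- list(NULL, age = as.character(pd@ages),
                        year = as.character(yearLab))
  out
}

#' Mean improvement-rate surface of reference countries
#'
#' Unweighted cell-wise arithmetic mean of the reference countries' ROMI
#' surfaces, skipping missing cells.
#'
#' @param rcSurfaces non-empty list of aligned [ROMISurface-class] objects.
#' @return a [ROMISurface-class].
#' @export
referenceMeanROMI <- function(rcSurfaces) {
  if (!length(rcSurfaces)) stop("need at least one reference-country surface")
  ref <- rcSurfaces[[1]]
  for (s in rcSurfaces[-1]) .checkAligned(ref, s, "reference surfaces")
  vals <- lapply(rcSurfaces, function(s) s@values)
  sumV <- Reduce(`+`, lapply(vals, function(v) ifelse(is.na(v), 0, v)))
  cnt <- Reduce(`+`, lapply(vals, function(v) !is.na(v)))
  m <- ifelse(cnt > 0, sumV / cnt, NA_real_)
  ROMISurface(m, ref@ages, ref@years,
              list(kind = "reference-mean", n = length(rcSurfaces)))
}

#' Convergence weight schedule
#'
#' Per-forecast-year weights w_t of the reference-country trend; the
#' country of interest keeps weight 1 - w_t. `"linear"` ramps w_t = t/H to
#' one over the horizon; `"delayed"` stays at zero until `startYear` (an
#' index into the horizon) and then ramps; `"off"` keeps all weight on the
#' country of interest.
#'
#' @param shape `"off"`, `"linear"` or `"delayed"`.
#' @param horizon number of forecast years.
#' @param startYear first horizon index with positive weight (shape
#'   `"delayed"`).
#' @return numeric vector of length `horizon`, non-decreasing in `[0, 1]`.
#' @examples
#' convergenceSchedule("linear", 5)
#' @export
convergenceSchedule <- function(shape = c("off", "linear", "delayed"),
                                horizon, startYear = 1L) {
  shape <- match.arg(shape)
  stopifnot(horizon >= 1L)
  switch(shape,
    off = rep(0, horizon),
    linear = seq_len(horizon) / horizon,
    delayed = {
      stopifnot(startYear >= 1L, startYear <= horizon)
      w <- rep(0, horizon)
      ramp <- startYear:horizon
      w[ramp] <- (ramp - startYear + 1) / (horizon - startYear + 1)
      w
    }
  )
}

#' Blend forecast draws with a reference-country trend
#'
#' Cell-wise (1 - w_t) rho_COI + w_t rho_RC per draw, the mortality-
#' convergence device applied outside the core models.
#'
#' @param coiDraws array (draw, age, year) of the country of interest's
#'   forecast ROMI draws.
#' @param rc reference trend: an array of the same shape, or an age x year
#'   matrix / [ROMISurface-class] recycled over draws.
#' @param weights numeric vector of per-year weights in `[0, 1]`, length
#'   equal to the horizon (see [convergenceSchedule()]).
#' @return array like `coiDraws`.
#' @export
blendWithReference <- function(coiDraws, rc, weights) {
  d <- dim(coiDraws)
  if (length(weights) != d[3]) {
    stop("schedule length ", length(weights), " differs from horizon ", d[3])
  }
  if (is(rc, "ROMISurface")) rc <- rc@values
  out <- coiDraws
  if (is.matrix(rc)) {
    if (!all(dim(rc) == d[2:3])) stop("reference grid misaligned")
    for (h in seq_len(d[3])) {
      out[, , h] <- (1 - weights[h]) * coiDraws[, , h] +
        weights[h] * matrix(rc[, h], d[1], d[2], byrow = TRUE)
    }
  } else {
    if (!all(dim(rc) == d)) stop("reference draw array misaligned")
    for (h in seq_len(d[3])) {
      out[, , h] <- (1 - weights[h]) * coiDraws[, , h] +
        weights[h] * rc[, , h]
    }
  }
  out
}

#' Propagate ROMI draws to death-rate quantile surfaces
#'
#' Quantile levels always refer to the survival orientation: a higher level
#' means stronger improvement, hence lower death rates and higher life
#' expectancy. In `"quantile-path"` mode (the default) the per-cell
#' quantiles of the ROMI draws are taken first and each quantile path is
#' propagated through m\[x, t\] = m\[x, t-1\] (1 - rho\[x, t\]); in
#' `"trajectory"` mode every draw is propagated and the per-cell rate
#' quantile at level 1 - p is reported for level p (so the orientation
#' matches). Both modes coincide when all draws are identical.
#'
#' @param jumpoff numeric vector of jump-off death rates (last base-year
#'   column, one per age), or a single-year [MortalitySurface-class].
#' @param romiDraws array (draw, age, year) from
#'   [posteriorPredictROMI()] (possibly blended).
#' @param quantileLevels levels in (0, 1).
#' @param mode `"quantile-path"` or `"trajectory"`.
#' @param jumpoffYear calendar year of the jump-off rates (for labels).
#' @return named list of [MortalitySurface-class] objects over the forecast
#'   years, one per level.
#' @export
propagateRates <- function(jumpoff, romiDraws,
                           quantileLevels = .defaultQuantiles,
                           mode = c("quantile-path", "trajectory"),
                           jumpoffYear = NULL) {
  mode <- match.arg(mode)
  if (is(jumpoff, "MortalitySurface")) {
    if (is.null(jumpoffYear)) jumpoffYear <- max(jumpoff@years)
    jumpoff <- jumpoff@values[, ncol(jumpoff@values)]
  }
  jumpoff <- as.numeric(jumpoff)
  if (any(jumpoff <= 0)) stop("jump-off rates must be strictly positive")
  d <- dim(romiDraws)
  if (length(jumpoff) != d[2]) stop("jump-off ages misaligned with draws")
  if (any(romiDraws >= 1)) {
    stop("improvement rates >= 1 would drive death rates non-positive")
  }
  yrLab <- dimnames(romiDraws)$year
  yrs <- if (!is.null(yrLab)) as.integer(yrLab)
         else if (!is.null(jumpoffYear)) jumpoffYear + seq_len(d[3])
         else seq_len(d[3])
  agesOut <- dimnames(romiDraws)$age
  agesOut <- if (!is.null(agesOut)) as.integer(agesOut) else seq_len(d[2]) - 1L

  recurse <- function(rhoMat) {
    m <- matrix(NA_real_, d[2], d[3])
    prev <- jumpoff
    for (h in seq_len(d[3])) {
      prev <- prev * (1 - rhoMat[, h])
      m[, h] <- prev
    }
    m
  }

  out <- vector("list", length(quantileLevels))
  names(out) <- format(quantileLevels)
  if (mode == "quantile-path") {
    for (i in seq_along(quantileLevels)) {
      qs <- apply(romiDraws, c(2, 3), stats::quantile,
                  probs = quantileLevels[i], names = FALSE)
      out[[i]] <- MortalitySurface(recurse(qs), agesOut, yrs,
                                   list(quantile = quantileLevels[i]))
    }
  } else {
    nD <- d[1]
    rates <- array(NA_real_, d)
    for (s in seq_len(nD)) {
      rates[s, , ] <- recurse(matrix(romiDraws[s, , ], d[2], d[3]))
    }
    for (i in seq_along(quantileLevels)) {
      qs <- apply(rates, c(2, 3), stats::quantile,
                  probs = 1 - quantileLevels[i], names = FALSE)
      out[[i]] <- MortalitySurface(qs, agesOut, yrs,
                                   list(quantile = quantileLevels[i]))
    }
  }
  out
}

#' Life-expectancy trajectories from rate-quantile surfaces
#'
#' Applies [buildLifeTable()] to every forecast year's age column of every
#' quantile surface and reports life expectancy at the requested age.
#'
#' @param rateQuantiles list of [MortalitySurface-class] from
#'   [propagateRates()].
#' @param atAge age at which remaining life expectancy is computed (0 for
#'   life expectancy at birth).
#' @param ... passed to [buildLifeTable()] (a0 rule, sex, ...).
#' @return numeric matrix, quantile levels (rows, named) x forecast years.
#' @export
summarizeE0 <- function(rateQuantiles, atAge = 0L, ...) {
  yrs <- rateQuantiles[[1]]@years
  out <- matrix(NA_real_, length(rateQuantiles), length(yrs),
                dimnames = list(names(rateQuantiles), yrs))
  for (i in seq_along(rateQuantiles)) {
    s <- rateQuantiles[[i]]
    out[i, ] <- vapply(seq_along(yrs), function(j) {
      lifeExpectancy(s@values[, j], atAge = atAge, ages = s@ages, ...)
    }, numeric(1))
  }
  out
}

#' Full forecast: draws to quantile surfaces to life expectancy
#'
#' Convenience wrapper running [posteriorPredictROMI()], optional blending
#' with a reference trend, [propagateRates()] and [summarizeE0()], returning
#' a [ForecastResult-class].
#'
#' @inheritParams posteriorPredictROMI
#' @inheritParams propagateRates
#' @param rc optional reference trend (see [blendWithReference()]).
#' @param weights optional convergence weights (required with `rc`).
#' @param exAge age for the secondary life-expectancy summary (default 65).
#' @param sex sex for the life-table infant separation factor.
#' @return a [ForecastResult-class].
#' @export
forecastMortality <- function(pd, jumpoff, horizon, bounds = clipBounds(),
                              includeNoise = TRUE,
                              quantileLevels = .defaultQuantiles,
                              mode = c("quantile-path", "trajectory"),
                              rc = NULL, weights = NULL, exAge = 65L,
                              sex = c("female", "male"),
                              jumpoffYear = NULL) {
  mode <- match.arg(mode)
  sex <- match.arg(sex)
  draws <- posteriorPredictROMI(pd, horizon, bounds, includeNoise)
  if (!is.null(rc)) {
    if (is.null(weights)) weights <- convergenceSchedule("linear", horizon)
    draws <- blendWithReference(draws, rc, weights)
  }
  rq <- propagateRates(jumpoff, draws, quantileLevels, mode,
                       jumpoffYear = jumpoffYear)
  e0 <- summarizeE0(rq, atAge = 0L, sex = sex)
  agesOut <- rq[[1]]@ages
  ex <- if (exAge %in% agesOut) summarizeE0(rq, atAge = exAge, sex = sex)
        else matrix(numeric(0), 0, 0)
  new("ForecastResult", romiDraws = draws, rateQuantiles = rq,
      e0Quantiles = e0, exQuantiles = ex, exAge = as.integer(exAge),
      quantileLevels = quantileLevels,
      jumpoff = if (is(jumpoff, "MortalitySurface"))
        jumpoff@values[, ncol(jumpoff@values)] else as.numeric(jumpoff),
      ages = agesOut, years = rq[[1]]@years)
}

setMethod("show", "ForecastResult", function(object) {
  cat(sprintf(
    "ForecastResult: %d draws, %d ages, forecast years %d-%d\n",
    dim(object@romiDraws)[1], length(object@ages), min(object@years),
    max(object@years)
  ))
  if (nrow(object@e0Quantiles)) {
    med <- which.min(abs(object@quantileLevels - 0.5))
    lastCol <- ncol(object@e0Quantiles)
    cat(sprintf("  median e0 in %d: %.2f years\n", max(object@years),
                object@e0Quantiles[med, lastCol]))
  }
  invisible(NULL)
})

#' Export forecast quantiles as long data frames
#'
#' @param fr a [ForecastResult-class].
#' @return list of data frames `rates` (quantile, age, year, rate) and
#'   `e0` (quantile, year, e0).
#' @export
forecastTables <- function(fr) {
  stopifnot(is(fr, "ForecastResult"))
  rates <- do.call(rbind, lapply(seq_along(fr@quantileLevels), function(i) {
    s <- fr@rateQuantiles[[i]]
    data.frame(
      quantile = fr@quantileLevels[i],
      age = rep(s@ages, times = length(s@years)),
      year = rep(s@years, each = length(s@ages)),
      rate = as.vector(s@values)
    )
  }))
  e0 <- do.call(rbind, lapply(seq_along(fr@quantileLevels), function(i) {
    data.frame(quantile = fr@quantileLevels[i], year = fr@years,
               e0 = fr@e0Quantiles[i, ])
  }))
  list(rates = rates, e0 = e0)
}

#' Per-draw life-expectancy trajectories
#'
#' Propagates every posterior-predictive ROMI draw through the death-rate
#' recursion and computes life expectancy per forecast year, giving the
#' marginal posterior-predictive distribution of e0 (or ex) per year —
#' the right object for calibration checks, where the quantile-path
#' surfaces (which move all ages and years together) would overstate the
#' per-year spread.
#'
#' @inheritParams propagateRates
#' @param atAge age for the life expectancy (default 0).
#' @param ... passed to [buildLifeTable()].
#' @return numeric matrix, draws x forecast years.
#' @export
e0FromDraws <- function(jumpoff, romiDraws, atAge = 0L, ...) {
  if (is(jumpoff, "MortalitySurface")) {
    jumpoff <- jumpoff@values[, ncol(jumpoff@values)]
  }
  jumpoff <- as.numeric(jumpoff)
  d <- dim(romiDraws)
  stopifnot(length(jumpoff) == d[2])
  agesOut <- dimnames(romiDraws)$age
  agesOut <- if (!is.null(agesOut)) as.integer(agesOut) else seq_len(d[2]) - 1L
  out <- matrix(NA_real_, d[1], d[3])
  colnames(out) <- dimnames(romiDraws)$year
  for (s in seq_len(d[1])) {
    prev <- jumpoff
    for (h in seq_len(d[3])) {
      prev <- prev * (1 - romiDraws[s, , h])
      out[s, h] <- lifeExpectancy(prev, atAge = atAge, ages = agesOut, ...)
    }
  }
  out
}
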