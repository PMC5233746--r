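#' @include surfaces.R
NULL

#' Clipping bounds for forecast improvement rates
#'
#' Forecast ROMI draws are clamped to `[low, high]` to exclude implausibly
#' weak or strong mortality decline; the defaults (0.5% and 3.5% annual
#' improvement) reflect the range observed on smoothed Lexis surfaces of
#' developed-country female mortality. Clipping applies to FORECAST draws
#' only, never to observed improvement rates.
#'
#' @param low,high admissible range, `low < high`. Use `c(-Inf, Inf)` to
#'   disable clipping.
#' @return a named list of class `ClipBounds`.
#' @examples
#' clipBounds()
#' clipBounds(-Inf, Inf)  # clipping off
#' @export
clipBounds <- function(low = 0.005, high = 0.035) {
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1L,
            length(high) == 1L, low < high)
  structure(list(low = low, high = high), class = "ClipBounds")
}

#' Rates of mortality improvement from a death-rate surface
#'
#' rho\[x, t\] = -(m\[x, t+1\] / m\[x, t\] - 1): the annual proportional
#' decline of the age-specific death rate, positive when mortality falls.
#' The result has one column fewer than the input; column t (earlier-year
#' label) describes the m\[x, t\] -> m\[x, t+1\] transition. Cells with
#' either parent rate missing are missing.
#'
#' @param m a [MortalitySurface-class] with at least two years.
#' @return a [ROMISurface-class].
#' @examples
#' m <- MortalitySurface(rbind(c(0.0100, 0.0097)), 0, 2000:2001)
#' surfaceValues(computeROMI(m))  # 0.03
#' @export
computeROMI <- function(m) {
  stopifnot(is(m, "MortalitySurface"))
  Tn <- length(m@years)
  if (Tn < 2L) stop("cannot compute improvement rates from a single year")
  v <- m@values
  rho <- -(v[, -1L, drop = FALSE] / v[, -Tn, drop = FALSE] - 1)
  ROMISurface(rho, m@ages, m@years[-Tn], m@metadata)
}

#' Reconstruct death rates from a jump-off column and improvement rates
#'
#' Applies the recursion m\[x, t\] = m\[x, t-1\] (1 - rho\[x, t\]) starting
#' from the jump-off rates, the inverse of [computeROMI()].
#'
#' @param mStart numeric vector of jump-off rates (one per age), belonging
#'   to the year immediately before the first ROMI column's transition, i.e.
#'   to `years(rho)[1]`.
#' @param rho a [ROMISurface-class].
#' @return a [MortalitySurface-class] over `length(years(rho)) + 1` years,
#'   the first being the jump-off year.
#' @examples
#' rho <- ROMISurface(matrix(0.05, 1, 2), 0, 2000:2001)
#' surfaceValues(invertROMI(0.02, rho))  # 0.02, 0.019, 0.01805
#' @export
invertROMI <- function(mStart, rho) {
  stopifnot(is(rho, "ROMISurface"))
  mStart <- as.numeric(mStart)
  A <- length(rho@ages)
  if (length(mStart) != A) {
    stop("jump-off vector has ", length(mStart), " ages but the ROMI surface ",
         "has ", A)
  }
  if (any(rho@values >= 1, na.rm = TRUE)) {
    stop("improvement rates >= 1 would drive death rates non-positive")
  }
  H <- length(rho@years)
  out <- matrix(NA_real_, A, H + 1L)
  out[, 1L] <- mStart
  for (h in seq_len(H)) {
    out[, h + 1L] <- out[, h] * (1 - rho@values[, h])
  }
  yrs <- c(rho@years[1L], rho@years + 1L)
  MortalitySurface(out, rho@ages, yrs, rho@metadata)
}

#' Clamp improvement rates to admissible bounds
#'
#' Element-wise clamp to `[low, high]`; intended for forecast draws only.
#' The number of clamped cells is reported with `message()`.
#'
#' @param rho a [ROMISurface-class] or numeric array of forecast draws.
#' @param bounds a [clipBounds()] object.
#' @param quiet suppress the clamp-count message.
#' @return same type as `rho`.
#' @examples
#' r <- ROMISurface(rbind(c(-0.01, 0.02, 0.05)), 0, 2000:2002)
#' surfaceValues(clipROMI(r, quiet = TRUE))  # 0.005 0.020 0.035
#' @export
clipROMI <- function(rho, bounds = clipBounds(), quiet = FALSE) {
  stopifnot(inherits(bounds, "ClipBounds"))
  clampArr <- function(v) pmin(pmax(v, bounds$low), bounds$high)
  if (is(rho, "ROMISurface")) {
    old <- rho@values
    rho@values[] <- clampArr(old)
    n <- sum(rho@values != old, na.rm = TRUE)
  } else {
    old <- rho
    rho[] <- clampArr(old)
    n <- sum(rho != old, na.rm = TRUE)
  }
  if (!quiet) message("clipROMI: clamped ", n, " cell(s)")
  rho
}

#' Floor improvement rates at a small positive value
#'
#' Replaces values below `floor` by `floor`; used before the log transform
#' of the exponential pre-fit, where non-positive improvement rates would
#' make the logarithm undefined.
#'
#' @param rho a [ROMISurface-class] or numeric array.
#' @param floor strictly positive replacement value (default 1e-4, well
#'   below the default clip minimum of 0.005).
#' @return same type as `rho`.
#' @export
floorPositive <- function(rho, floor = 1e-4) {
  stopifnot(is.numeric(floor), length(floor) == 1L)
  if (floor <= 0) stop("floor must be strictly positive")
  if (is(rho, "ROMISurface")) {
    rho@values[] <- pmax(rho@values, floor)
  } else {
    rho[] <- pmax(rho, floor)
  }
  rho
}

#' Years to halve mortality under a constant improvement rate
#'
#' With a constant annual improvement rho, death rates decay geometrically
#' and halve after log(0.5) / log(1 - rho) years. At the default clip
#' ceiling of 3.5% a year this is about 19.5 years — an extraordinarily fast
#' decline, which is why stronger forecast improvements are clamped.
#'
#' @param rho annual improvement rate(s) in (0, 1).
#' @return halving time in years.
#' @examples
#' halvingTime(0.035)  # < 20
#' @export
halvingTime <- function(rho) {
  stopifnot(all(rho > 0), all(rho < 1))
  log(0.5) / log(1 - rho)
}
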