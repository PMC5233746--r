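#' @include surfaces.R
NULL

## Standard single-age period life table. q_x = m_x / (1 + (1 - a_x) m_x)
## for closed intervals with a_x = 0.5 for x >= 1; the open age group is
## closed with L_A = l_A / m_A, e_A = 1 / m_A. The infant separation factor
## a_0 follows the Andreev-Kingkade piecewise-linear function of m_0 (the
## HMD-protocol convention) or a fixed value.

.a0AndreevKingkade <- function(m0, sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (sex == "female") {
    if (m0 < 0.01724) 0.14903 - 2.05527 * m0
    else if (m0 < 0.06891) 0.04667 + 3.88089 * m0
    else 0.31411
  } else {
    if (m0 < 0.02300) 0.14929 - 1.99545 * m0
    else if (m0 < 0.08307) 0.02832 + 3.26021 * m0
    else 0.29915
  }
}

#' Build a period life table from age-specific death rates
#'
#' @param mx numeric vector of central death rates for single ages
#'   `0..A`, the last age open-ended; all strictly positive.
#' @param ages integer ages (default `0:(length(mx) - 1)`).
#' @param a0Rule infant separation factor rule: `"andreev-kingkade"`
#'   (piecewise-linear in `m0`, default) or `"fixed"`.
#' @param sex sex for the Andreev-Kingkade coefficients.
#' @param a0Fixed value used when `a0Rule = "fixed"`.
#' @param radix starting cohort size `l0` (default 100000).
#' @return a `data.frame` with columns `age, mx, ax, qx, lx, dx, Lx, Tx, ex`.
#' @examples
#' lt <- buildLifeTable(rep(0.01, 101))
#' lt$ex[1]  # e0 under constant hazard
#' @export
buildLifeTable <- function(mx, ages = seq_along(mx) - 1L,
                           a0Rule = c("andreev-kingkade", "fixed"),
                           sex = c("female", "male"), a0Fixed = 0.14,
                           radix = 1e5) {
  a0Rule <- match.arg(a0Rule)
  sex <- match.arg(sex)
  mx <- as.numeric(mx)
  n <- length(mx)
  if (n < 2L) stop("need at least two ages")
  if (any(!is.finite(mx)) || any(mx <= 0)) {
    stop("all death rates must be finite and strictly positive")
  }
  ax <- rep(0.5, n)
  ax[1L] <- if (ages[1L] == 0L) {
    if (a0Rule == "fixed") a0Fixed else .a0AndreevKingkade(mx[1L], sex)
  } else 0.5
  qx <- mx / (1 + (1 - ax) * mx)
  if (any(qx[-n] > 1)) {
    warning("death probabilities above 1 clamped to 1")
    qx <- pmin(qx, 1)
  }
  qx[n] <- 1
  lx <- numeric(n)
  lx[1L] <- radix
  for (i in seq_len(n - 1L)) lx[i + 1L] <- lx[i] * (1 - qx[i])
  dx <- lx * qx
  Lx <- numeric(n)
  Lx[seq_len(n - 1L)] <- lx[-1L] + ax[-n] * dx[-n]
  Lx[n] <- lx[n] / mx[n]
  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(lx > 0, Tx / lx, 0)
  data.frame(age = as.integer(ages), mx = mx, ax = ax, qx = qx, lx = lx,
             dx = dx, Lx = Lx, Tx = Tx, ex = ex)
}

#' Remaining life expectancy at an age
#'
#' @inheritParams buildLifeTable
#' @param atAge integer age at which remaining life expectancy is wanted
#'   (0 gives life expectancy at birth; the open age `A` gives `1/m_A`).
#' @param ... passed to [buildLifeTable()].
#' @return remaining life expectancy in years.
#' @examples
#' lifeExpectancy(rep(0.01, 101), atAge = 65)
#' @export
lifeExpectancy <- function(mx, atAge = 0L, ages = seq_along(mx) - 1L, ...) {
  if (!atAge %in% ages) stop("age ", atAge, " outside the table's range")
  lt <- buildLifeTable(mx, ages = ages, ...)
  lt$ex[match(atAge, lt$age)]
}
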