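#' @include hmd_io.R
NULL

## Penalized-spline (P-spline) smoothing of death rates prior to the
## improvement-rate transform: penalized Poisson regression of death counts
## with a log-exposure offset on a cubic B-spline basis, a difference
## penalty on adjacent coefficients, and the smoothing parameter lambda
## chosen by minimizing BIC = deviance + log(n) * effective dimension over
## a grid. The default mode smooths each age's time series independently;
## an age-by-time 2D smoother (Kronecker basis, shared lambda) is optional.

#' Smoothing configuration
#'
#' @param penaltyOrder order of the difference penalty (1, 2 or 3; order 2,
#'   the default, shrinks toward log-rates linear in time).
#' @param lambdaGrid positive candidate smoothing parameters searched by
#'   BIC.
#' @param knotSpacing grid points per B-spline knot interval (default 5,
#'   standard over-parameterized P-spline practice).
#' @param mode `"time-per-age"` (default) or `"age-time-2D"`.
#' @return a list of class `SmoothingConfig`.
#' @export
smoothingConfig <- function(penaltyOrder = 2L,
                            lambdaGrid = 10^seq(-2, 6, by = 0.5),
                            knotSpacing = 5L,
                            mode = c("time-per-age", "age-time-2D")) {
  mode <- match.arg(mode)
  stopifnot(penaltyOrder %in% 1:3, length(lambdaGrid) >= 1L,
            all(lambdaGrid > 0), knotSpacing >= 1L)
  structure(list(penaltyOrder = as.integer(penaltyOrder),
                 lambdaGrid = as.numeric(lambdaGrid),
                 knotSpacing = as.integer(knotSpacing), mode = mode),
            class = "SmoothingConfig")
}

#' Equally spaced cubic B-spline basis
#'
#' @param x evaluation points.
#' @param ndx number of knot intervals spanning the range of `x`.
#' @param deg spline degree.
#' @return basis matrix, `length(x)` x `(ndx + deg)`.
#' @keywords internal
bsplineBasis <- function(x, ndx, deg = 3L) {
  xl <- min(x)
  xr <- max(x)
  h <- (xr - xl) / ndx
  knots <- seq(xl - deg * h, xr + deg * h, by = h)
  splines::splineDesign(knots, x, ord = deg + 1L, outer.ok = TRUE)
}

## Penalized Poisson IRLS: y ~ Poisson(E * exp(B %*% a)), penalty
## lambda * t(D) D on the coefficients. Returns fit at one lambda.
.pirls <- function(y, E, B, P, lambda, tol = 1e-8, maxit = 50L) {
  a <- rep(0, ncol(B))
  eta <- log((y + mean(y) * 0.1 + 1e-8) / E)
  ## initialize coefficients by a penalized LS fit to the crude log-rate
  a <- tryCatch(
    solve(crossprod(B) + lambda * P + 1e-10 * diag(ncol(B)),
          crossprod(B, eta)),
    error = function(e) rep(0, ncol(B))
  )
  eta <- as.vector(B %*% a)
  for (it in seq_len(maxit)) {
    mu <- E * exp(eta)
    W <- mu
    z <- eta + (y - mu) / mu
    BW <- B * W
    M <- crossprod(BW, B) + lambda * P
    aNew <- tryCatch(solve(M, crossprod(BW, z)), error = function(e) NULL)
    if (is.null(aNew) || any(!is.finite(aNew))) {
      stop("penalized Poisson fit failed to converge at lambda = ", lambda)
    }
    etaNew <- as.vector(B %*% aNew)
    done <- max(abs(etaNew - eta)) < tol
    a <- aNew
    eta <- etaNew
    if (done) break
    if (it == maxit) {
      stop("penalized Poisson fit failed to converge at lambda = ", lambda)
    }
  }
  mu <- E * exp(eta)
  BW <- B * mu
  BtWB <- crossprod(BW, B)
  H <- solve(BtWB + lambda * P, BtWB)
  ed <- sum(diag(H))
  devTerms <- ifelse(y > 0, y * log(y / mu), 0)
  dev <- 2 * sum(devTerms - (y - mu))
  list(coef = a, eta = eta, fitted = mu, ed = ed, dev = dev,
       bic = dev + log(length(y)) * ed)
}

## grid search over lambda for one series/surface
.pirlsGrid <- function(y, E, B, P, lambdaGrid) {
  fits <- lapply(lambdaGrid, function(l) .pirls(y, E, B, P, l))
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  best <- which.min(bics)
  c(fits[[best]], list(lambda = lambdaGrid[best], bicGrid = bics))
}

#' P-spline smoothing of a death-rate surface
#'
#' Smooths observed death counts given exposures and returns strictly
#' positive fitted rates on the same grid. The chosen lambda (per age in
#' the default per-age mode) and the effective dimension are recorded in
#' the result's metadata.
#'
#' @param deaths death counts: [ExposureSurface-class] or matrix.
#' @param exposures person-years at risk, same grid, all positive.
#' @param config a [smoothingConfig()].
#' @return a [MortalitySurface-class] of smoothed rates; metadata fields
#'   `lambda`, `ed`, `bic`.
#' @examples
#' E <- matrix(1e5, 3, 20)
#' m <- outer(c(0.01, 0.02, 0.04), exp(-0.02 * (0:19)))
#' sm <- smoothRates(m * E, E, smoothingConfig(lambdaGrid = 10^(0:4)))
#' @export
smoothRates <- function(deaths, exposures, config = smoothingConfig()) {
  stopifnot(inherits(config, "SmoothingConfig"))
  agesOut <- NULL; yrs <- NULL; md <- list()
  if (is(deaths, "LexisSurface")) {
    if (is(exposures, "LexisSurface")) .checkAligned(deaths, exposures)
    agesOut <- deaths@ages; yrs <- deaths@years; md <- deaths@metadata
    deaths <- deaths@values
  }
  if (is(exposures, "LexisSurface")) {
    if (is.null(agesOut)) { agesOut <- exposures@ages; yrs <- exposures@years }
    exposures <- exposures@values
  }
  deaths <- as.matrix(deaths); exposures <- as.matrix(exposures)
  if (!all(dim(deaths) == dim(exposures))) stop("misaligned grids")
  if (all(is.na(deaths))) stop("all cells missing")
  if (any(exposures <= 0 | is.na(exposures))) {
    stop("exposures must be positive everywhere for smoothing")
  }
  A <- nrow(deaths); Tn <- ncol(deaths)
  if (is.null(agesOut)) agesOut <- seq_len(A) - 1L
  if (is.null(yrs)) yrs <- seq_len(Tn)

  if (config$mode == "time-per-age") {
    ndx <- max(ceiling(Tn / config$knotSpacing), 3L)
    B <- bsplineBasis(seq_len(Tn), ndx)
    D <- diff(diag(ncol(B)), differences = config$penaltyOrder)
    P <- crossprod(D)
    fitted <- matrix(NA_real_, A, Tn)
    lambda <- ed <- bic <- numeric(A)
    for (a in seq_len(A)) {
      obs <- which(!is.na(deaths[a, ]))
      if (length(obs) < config$penaltyOrder + 1L) {
        stop("too few observed years at age ", agesOut[a], " to smooth")
      }
      f <- .pirlsGrid(deaths[a, obs], exposures[a, obs],
                      B[obs, , drop = FALSE], P, config$lambdaGrid)
      fitted[a, ] <- exp(as.vector(B %*% f$coef))
      lambda[a] <- f$lambda; ed[a] <- f$ed; bic[a] <- f$bic
    }
  } else {
    ndxA <- max(ceiling(A / config$knotSpacing), 3L)
    ndxT <- max(ceiling(Tn / config$knotSpacing), 3L)
    Ba <- bsplineBasis(seq_len(A), ndxA)
    Bt <- bsplineBasis(seq_len(Tn), ndxT)
    B <- kronecker(Bt, Ba)  # column-major vec: ages vary fastest
    Da <- diff(diag(ncol(Ba)), differences = config$penaltyOrder)
    Dt <- diff(diag(ncol(Bt)), differences = config$penaltyOrder)
    P <- kronecker(diag(ncol(Bt)), crossprod(Da)) +
      kronecker(crossprod(Dt), diag(ncol(Ba)))
    y <- as.vector(deaths)
    E <- as.vector(exposures)
    obs <- which(!is.na(y))
    f <- .pirlsGrid(y[obs], E[obs], B[obs, , drop = FALSE], P,
                    config$lambdaGrid)
    fitted <- matrix(exp(as.vector(B %*% f$coef)), A, Tn)
    lambda <- f$lambda; ed <- f$ed; bic <- f$bic
  }
  md$lambda <- lambda; md$ed <- ed; md$bic <- bic
  md$smoothing <- config$mode
  MortalitySurface(fitted, agesOut, yrs, md)
}
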