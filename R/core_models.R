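#' @include priors.R romi.R
NULL

## The two Bayesian core models for age-specific rates of mortality
## improvement rho[x, t], with model time t = 1, 2, ... at the first
## base-period transition year (so log(t) is defined; forecast years
## continue T+1, T+2, ...).
##
## Linear model:      rho[x, t] ~ N(beta1[x] + beta2[x] * t, sigma^2)
##                    (beta1[x], beta2[x]) ~ BVN((mu1, mu2), Omega)
##                    Omega = [[omega1^2, rc*omega1*omega2],
##                             [rc*omega1*omega2, omega2^2]]
## Exponential model: rho[x, t] ~ N(exp(beta1[x] + beta2[x]*log t), sigma^2)
##                    beta1[x] ~ N(theta1Hat[x], sigma1^2)
##                    beta2[x] ~ N(theta2Hat[x], sigma2^2)
## with the thetaHat anchors from a per-age OLS of log rho on log t.

#' Model time index for a ROMI surface
#'
#' Maps the surface's transition years to model time t = 1..T. Forecast
#' years continue the sequence at T+1.
#'
#' @param rho a [ROMISurface-class] (or integer vector of years).
#' @return named integer vector of model times.
#' @export
romiTimeIndex <- function(rho) {
  yrs <- if (is(rho, "ROMISurface")) rho@years else as.integer(rho)
  stats::setNames(seq_along(yrs), yrs)
}

#' Linear core-model parameter set
#'
#' @param beta1,beta2 per-age intercepts and slopes.
#' @param sigma within-age residual s.d.
#' @param mu1,mu2 overall means of the intercepts and slopes.
#' @param omega1,omega2 between-age s.d. of intercepts and slopes.
#' @param rhoCorr intercept-slope correlation (named to avoid collision with
#'   the improvement rate rho).
#' @return a list of class `LinearModelParams`.
#' @export
linearModelParams <- function(beta1, beta2, sigma, mu1, mu2,
                              omega1, omega2, rhoCorr) {
  stopifnot(length(beta1) == length(beta2))
  structure(list(beta1 = as.numeric(beta1), beta2 = as.numeric(beta2),
                 sigma = sigma, mu1 = mu1, mu2 = mu2, omega1 = omega1,
                 omega2 = omega2, rhoCorr = rhoCorr),
            class = c("LinearModelParams", "CoreModelParams"))
}

#' Exponential core-model parameter set
#'
#' @param beta1,beta2 per-age coefficients of the log-linear mean.
#' @param sigma residual s.d.
#' @param sigma1,sigma2 prior s.d. of `beta1` and `beta2` around the OLS
#'   anchors.
#' @param theta1Hat,theta2Hat the OLS anchors from [prefitTheta()].
#' @return a list of class `ExpModelParams`.
#' @export
expModelParams <- function(beta1, beta2, sigma, sigma1, sigma2,
                           theta1Hat, theta2Hat) {
  stopifnot(length(beta1) == length(beta2),
            length(theta1Hat) == length(beta1),
            length(theta2Hat) == length(beta1))
  structure(list(beta1 = as.numeric(beta1), beta2 = as.numeric(beta2),
                 sigma = sigma, sigma1 = sigma1, sigma2 = sigma2,
                 theta1Hat = as.numeric(theta1Hat),
                 theta2Hat = as.numeric(theta2Hat)),
            class = c("ExpModelParams", "CoreModelParams"))
}

#' Intercept-slope covariance matrix of the linear model
#'
#' @param omega1,omega2 marginal s.d.s; `rhoCorr` the correlation.
#' @param rhoCorr correlation in (-1, 1).
#' @return 2x2 covariance matrix.
#' @export
omegaMatrix <- function(omega1, omega2, rhoCorr) {
  matrix(c(omega1^2, rhoCorr * omega1 * omega2,
           rhoCorr * omega1 * omega2, omega2^2), 2L, 2L)
}

## log of the bivariate normal density at (b1, b2), vectorized over ages
.dbvnormLog <- function(b1, b2, mu1, mu2, omega1, omega2, rhoCorr) {
  z1 <- (b1 - mu1) / omega1
  z2 <- (b2 - mu2) / omega2
  om <- 1 - rhoCorr^2
  -log(2 * pi) - log(omega1) - log(omega2) - 0.5 * log(om) -
    (z1^2 - 2 * rhoCorr * z1 * z2 + z2^2) / (2 * om)
}

.romiMatrix <- function(rho) {
  if (is(rho, "ROMISurface")) rho@values else as.matrix(rho)
}

#' OLS pre-fit of the exponential model's anchors
#'
#' Per age x, ordinary least squares of log(max(rho\[x, t\], floor)) on
#' (1, log t) over the base period gives the anchors theta1Hat (intercept)
#' and theta2Hat (slope) for the exponential model's coefficient priors.
#' Negative or zero improvement rates are floored first so the logarithm is
#' defined.
#'
#' @param rho a [ROMISurface-class] (or matrix, ages x years).
#' @param floor positive floor applied before the log transform.
#' @return list with numeric vectors `theta1Hat` and `theta2Hat`.
#' @examples
#' tt <- 1:12
#' r <- ROMISurface(rbind(exp(-3 + 0.2 * log(tt))), 0, 2000 + tt - 1)
#' prefitTheta(r)  # theta1Hat = -3, theta2Hat = 0.2
#' @export
prefitTheta <- function(rho, floor = 1e-4) {
  v <- .romiMatrix(rho)
  if (floor <= 0) stop("floor must be strictly positive")
  tSeq <- seq_len(ncol(v))
  lt <- log(tSeq)
  A <- nrow(v)
  th1 <- th2 <- numeric(A)
  for (a in seq_len(A)) {
    obs <- which(!is.na(v[a, ]))
    if (length(obs) < 3L) {
      stop("fewer than 3 usable time points at age index ", a,
           if (is(rho, "ROMISurface")) paste0(" (age ", rho@ages[a], ")"))
    }
    y <- log(pmax(v[a, obs], floor))
    fit <- stats::lm.fit(cbind(1, lt[obs]), y)
    th1[a] <- fit$coefficients[1]
    th2[a] <- fit$coefficients[2]
  }
  list(theta1Hat = th1, theta2Hat = th2)
}

#' Model-mean improvement-rate surface
#'
#' The deterministic mean path of either core model at the supplied model
#' times: beta1\[x\] + beta2\[x\] t (linear) or
#' exp(beta1\[x\] + beta2\[x\] log t) (exponential).
#'
#' @param params a `LinearModelParams` or `ExpModelParams` list.
#' @param tSeq integer model times (t >= 1), e.g. forecast times T+1..T+H.
#' @return numeric matrix, ages x length(tSeq).
#' @examples
#' p <- linearModelParams(0.01, 0.001, 0.005, 0, 0, 0.01, 0.001, 0)
#' meanROMI(p, 10)  # 0.02
#' @export
meanROMI <- function(params, tSeq) {
  stopifnot(all(tSeq >= 1))
  if (inherits(params, "LinearModelParams")) {
    outer(params$beta1, rep(1, length(tSeq))) + outer(params$beta2, tSeq)
  } else if (inherits(params, "ExpModelParams")) {
    exp(outer(params$beta1, rep(1, length(tSeq))) +
          outer(params$beta2, log(tSeq)))
  } else {
    stop("params must be LinearModelParams or ExpModelParams")
  }
}

#' Log-posterior density of the linear core model
#'
#' Sum of the Gaussian likelihood of the observed improvement rates around
#' their age-specific linear trends, the bivariate-normal hierarchy of the
#' per-age coefficients, and the hyper-parameter log priors; `-Inf` outside
#' any prior support. Missing cells are skipped.
#'
#' @param params a [linearModelParams()] list.
#' @param rho a [ROMISurface-class] or matrix (ages x model times 1..T).
#' @param tSeq optional model times (default `1:ncol`).
#' @param priors optional partial override of [defaultPriors()]`("linear")`.
#' @return scalar log density (up to the flat-prior constant).
#' @export
linearLogPosterior <- function(params, rho, tSeq = NULL, priors = NULL) {
  v <- .romiMatrix(rho)
  if (length(params$beta1) != nrow(v)) {
    stop("params have ", length(params$beta1), " ages but the surface has ",
         nrow(v))
  }
  if (is.null(tSeq)) tSeq <- seq_len(ncol(v))
  if (length(tSeq) != ncol(v)) stop("tSeq length must match the year count")
  pr <- .mergePriors("linear", priors)
  lp <- logPriorDensity(pr$sigma, params$sigma) +
    logPriorDensity(pr$mu1, params$mu1) +
    logPriorDensity(pr$mu2, params$mu2) +
    logPriorDensity(pr$omega1, params$omega1) +
    logPriorDensity(pr$omega2, params$omega2) +
    logPriorDensity(pr$rhoCorr, params$rhoCorr)
  if (!is.finite(lp)) return(-Inf)
  mu <- meanROMI(params, tSeq)
  ll <- sum(stats::dnorm(v, mu, params$sigma, log = TRUE), na.rm = TRUE)
  lh <- sum(.dbvnormLog(params$beta1, params$beta2, params$mu1, params$mu2,
                        params$omega1, params$omega2, params$rhoCorr))
  ll + lh + lp
}

#' Log-posterior density of the exponential core model
#'
#' Gaussian likelihood around exp(beta1 + beta2 log t), independent normal
#' priors of the coefficients around their OLS anchors, and the s.d. log
#' priors; `-Inf` outside any prior support.
#'
#' @inheritParams linearLogPosterior
#' @param params an [expModelParams()] list.
#' @param priors optional partial override of
#'   [defaultPriors()]`("exponential")`.
#' @return scalar log density.
#' @export
expLogPosterior <- function(params, rho, tSeq = NULL, priors = NULL) {
  v <- .romiMatrix(rho)
  if (length(params$beta1) != nrow(v)) {
    stop("params have ", length(params$beta1), " ages but the surface has ",
         nrow(v))
  }
  if (is.null(tSeq)) tSeq <- seq_len(ncol(v))
  if (length(tSeq) != ncol(v)) stop("tSeq length must match the year count")
  pr <- .mergePriors("exponential", priors)
  lp <- logPriorDensity(pr$sigma, params$sigma) +
    logPriorDensity(pr$sigma1, params$sigma1) +
    logPriorDensity(pr$sigma2, params$sigma2)
  if (!is.finite(lp)) return(-Inf)
  mu <- meanROMI(params, tSeq)
  ll <- sum(stats::dnorm(v, mu, params$sigma, log = TRUE), na.rm = TRUE)
  lh <- sum(stats::dnorm(params$beta1, params$theta1Hat, params$sigma1,
                         log = TRUE)) +
    sum(stats::dnorm(params$beta2, params$theta2Hat, params$sigma2,
                     log = TRUE))
  ll + lh + lp
}
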