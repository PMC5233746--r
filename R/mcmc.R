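#' @include core_models.R
NULL

## Adaptive Metropolis-within-Gibbs for the two core models.
##
## Linear model blocks: per-age (beta1, beta2) are conjugate bivariate
## normal given the hypers; (mu1, mu2) given the betas is normal truncated
## to its uniform-prior box; sigma, omega1, omega2 and rhoCorr move by
## random-walk Metropolis on an interval-logit scale (with Jacobian).
## Exponential model blocks: per-age (beta1, beta2) are non-conjugate
## (nonlinear mean) and move by per-age random-walk Metropolis; sigma,
## sigma1 and sigma2 by interval-logit random walks.
##
## Proposal scales adapt toward 20-45% acceptance during burn-in only and
## are frozen afterwards, preserving detailed balance for the retained
## draws.

#' MCMC run configuration
#'
#' Defaults follow the forecasting set-up used throughout the package: five
#' parallel chains, 5200 post-burn-in iterations each, a burn-in of 200 and
#' thinning of 5, so 1040 draws are retained per chain (5200 pooled).
#'
#' @param nChains number of chains.
#' @param nIterations post-burn-in iterations per chain.
#' @param burnIn discarded initial iterations per chain.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param seed integer RNG seed; identical seed + config gives bit-identical
#'   draws.
#' @param adaptInterval iterations between proposal-scale adaptations
#'   (burn-in only).
#' @param targetAcceptance acceptance rate the adaptation aims for.
#' @return a named list of class `MCMCConfig`.
#' @export
mcmcConfig <- function(nChains = 5L, nIterations = 5200L, burnIn = 200L,
                       thin = 5L, seed = 1L, adaptInterval = 50L,
                       targetAcceptance = 0.3) {
  stopifnot(nChains >= 1L, nIterations >= 1L, burnIn >= 0L, thin >= 1L,
            adaptInterval >= 1L, targetAcceptance > 0, targetAcceptance < 1)
  structure(list(nChains = as.integer(nChains),
                 nIterations = as.integer(nIterations),
                 burnIn = as.integer(burnIn), thin = as.integer(thin),
                 seed = as.integer(seed),
                 adaptInterval = as.integer(adaptInterval),
                 targetAcceptance = targetAcceptance),
            class = "MCMCConfig")
}

.isFixed <- function(spec) spec$family == "fixed"

## interval-logit transform helpers for a parameter with support (lo, hi)
.toZ <- function(x, lo, hi) stats::qlogis((x - lo) / (hi - lo))
.fromZ <- function(z, lo, hi) lo + (hi - lo) * stats::plogis(z)
.logJacobianZ <- function(z, lo, hi) {
  ## d x / d z = (hi - lo) * s(z) (1 - s(z))
  p <- stats::plogis(z)
  log(hi - lo) + log(p) + log1p(-p)
}

.sampleTruncNorm1 <- function(mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (phi - plo < 1e-12) {
    ## numerically degenerate: the mass sits on one side of the box
    return(min(max(mean, lo + 1e-12), hi - 1e-12))
  }
  stats::qnorm(stats::runif(1L, plo, phi), mean, sd)
}

## one scalar random-walk Metropolis step on the interval-logit scale.
## logTarget(x) must include the log prior; returns list(x, accepted).
.rwStep <- function(x, scale, lo, hi, logTarget) {
  z <- .toZ(x, lo, hi)
  zp <- z + scale * stats::rnorm(1L)
  xp <- .fromZ(zp, lo, hi)
  num <- logTarget(xp) + .logJacobianZ(zp, lo, hi)
  den <- logTarget(x) + .logJacobianZ(z, lo, hi)
  if (is.nan(num) || is.nan(den)) stop("NaN in log-posterior evaluation")
  if (log(stats::runif(1L)) < num - den) list(x = xp, accepted = TRUE)
  else list(x = x, accepted = FALSE)
}

.adaptScale <- function(scale, rate, target) {
  ## Robbins-Monro style multiplicative update, clamped for safety
  pmin(pmax(scale * exp(rate - target), 1e-4), 50)
}

.chainSeeds <- function(seed, nChains) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, nChains)
}

## ---- linear-model chain ---------------------------------------------------

.initLinear <- function(v, tSeq, priors, jitterSd = 0.05) {
  A <- nrow(v)
  b1 <- b2 <- numeric(A)
  X <- cbind(1, tSeq)
  for (a in seq_len(A)) {
    obs <- which(!is.na(v[a, ]))
    fit <- stats::lm.fit(X[obs, , drop = FALSE], v[a, obs])
    b1[a] <- fit$coefficients[1]
    b2[a] <- fit$coefficients[2]
  }
  clampIn <- function(x, spec, pad = 1e-3) {
    lo <- spec$support[1]; hi <- spec$support[2]
    if (.isFixed(spec)) spec$value else min(max(x, lo + pad), hi - pad)
  }
  resid <- v - (outer(b1, rep(1, length(tSeq))) + outer(b2, tSeq))
  sig <- stats::sd(resid, na.rm = TRUE)
  jit <- function(x, s) x * exp(stats::rnorm(1L, 0, jitterSd))
  sdOr <- function(x, fallback) {
    s <- if (length(x) > 1L) stats::sd(x) else NA_real_
    if (is.finite(s) && s > 0) s else fallback
  }
  corInit <- if (A > 1L) stats::cor(b1, b2) else 0
  if (!is.finite(corInit)) corInit <- 0
  list(
    beta1 = b1 + stats::rnorm(A, 0, jitterSd * sdOr(b1, 1e-4)),
    beta2 = b2 + stats::rnorm(A, 0, jitterSd * sdOr(b2, 1e-5)),
    sigma = clampIn(jit(max(sig, 1e-4)), priors$sigma),
    mu1 = clampIn(mean(b1), priors$mu1),
    mu2 = clampIn(mean(b2), priors$mu2),
    omega1 = clampIn(jit(sdOr(b1, 1e-3)), priors$omega1),
    omega2 = clampIn(jit(sdOr(b2, 1e-4)), priors$omega2),
    rhoCorr = clampIn(min(max(corInit, -0.9), 0.9), priors$rhoCorr)
  )
}

.runChainLinear <- function(v, tSeq, priors, cfg, chainSeed) {
  set.seed(chainSeed)
  A <- nrow(v)
  W <- !is.na(v)
  Y <- ifelse(W, v, 0)
  nx <- rowSums(W)
  St <- as.vector(W %*% tSeq)
  Stt <- as.vector(W %*% tSeq^2)
  Sy <- rowSums(Y)
  Sty <- as.vector(Y %*% tSeq)
  Nobs <- sum(nx)

  st <- .initLinear(v, tSeq, priors)
  scaleNames <- c("sigma", "omega1", "omega2", "rhoCorr")
  scales <- stats::setNames(rep(0.5, 4L), scaleNames)
  accWin <- accTot <- stats::setNames(numeric(4L), scaleNames)
  nTot <- stats::setNames(numeric(4L), scaleNames)

  nIterTotal <- cfg$burnIn + cfg$nIterations
  nKeep <- cfg$nIterations %/% cfg$thin
  keep <- list(
    beta1 = matrix(NA_real_, nKeep, A), beta2 = matrix(NA_real_, nKeep, A),
    sigma = matrix(NA_real_, nKeep, 1L), mu1 = matrix(NA_real_, nKeep, 1L),
    mu2 = matrix(NA_real_, nKeep, 1L), omega1 = matrix(NA_real_, nKeep, 1L),
    omega2 = matrix(NA_real_, nKeep, 1L),
    rhoCorr = matrix(NA_real_, nKeep, 1L)
  )
  kept <- 0L

  ssr <- function() {
    mu <- outer(st$beta1, rep(1, length(tSeq))) + outer(st$beta2, tSeq)
    sum((Y - ifelse(W, mu, 0))^2)
  }
  bvnSum <- function(om1, om2, rc) {
    sum(.dbvnormLog(st$beta1, st$beta2, st$mu1, st$mu2, om1, om2, rc))
  }

  for (it in seq_len(nIterTotal)) {
    ## (beta1, beta2) | rest : conjugate bivariate normal, vectorized over
    ## ages (shared 2x2 algebra in closed form)
    Om <- omegaMatrix(st$omega1, st$omega2, st$rhoCorr)
    Q <- solve(Om)
    s2 <- st$sigma^2
    P11 <- nx / s2 + Q[1, 1]
    P12 <- St / s2 + Q[1, 2]
    P22 <- Stt / s2 + Q[2, 2]
    qm <- Q %*% c(st$mu1, st$mu2)
    b1v <- Sy / s2 + qm[1]
    b2v <- Sty / s2 + qm[2]
    det <- P11 * P22 - P12^2
    m1 <- (P22 * b1v - P12 * b2v) / det
    m2 <- (P11 * b2v - P12 * b1v) / det
    ## covariance = P^{-1}; its Cholesky factor, per age
    S11 <- P22 / det
    S12 <- -P12 / det
    S22 <- P11 / det
    L11 <- sqrt(S11)
    L21 <- S12 / L11
    L22 <- sqrt(pmax(S22 - L21^2, 0))
    z1 <- stats::rnorm(A)
    z2 <- stats::rnorm(A)
    st$beta1 <- m1 + L11 * z1
    st$beta2 <- m2 + L21 * z1 + L22 * z2

    ## (mu1, mu2) | beta : normal truncated to the uniform-prior box,
    ## sampled by alternating univariate truncated conditionals
    bb1 <- mean(st$beta1)
    bb2 <- mean(st$beta2)
    sd1 <- st$omega1 * sqrt((1 - st$rhoCorr^2) / A)
    sd2 <- st$omega2 * sqrt((1 - st$rhoCorr^2) / A)
    if (!.isFixed(priors$mu1)) {
      mcond <- bb1 + st$rhoCorr * (st$omega1 / st$omega2) * (st$mu2 - bb2)
      st$mu1 <- .sampleTruncNorm1(mcond, sd1, priors$mu1$support[1],
                                  priors$mu1$support[2])
    } else st$mu1 <- priors$mu1$value
    if (!.isFixed(priors$mu2)) {
      mcond <- bb2 + st$rhoCorr * (st$omega2 / st$omega1) * (st$mu1 - bb1)
      st$mu2 <- .sampleTruncNorm1(mcond, sd2, priors$mu2$support[1],
                                  priors$mu2$support[2])
    } else st$mu2 <- priors$mu2$value

    ## sigma | beta : random walk on interval-logit scale
    if (!.isFixed(priors$sigma)) {
      SSR <- ssr()
      tgt <- function(s) {
        -Nobs * log(s) - SSR / (2 * s^2) + logPriorDensity(priors$sigma, s)
      }
      stp <- .rwStep(st$sigma, scales["sigma"], priors$sigma$support[1],
                     priors$sigma$support[2], tgt)
      st$sigma <- stp$x
      accWin["sigma"] <- accWin["sigma"] + stp$accepted
      if (it > cfg$burnIn) {
        accTot["sigma"] <- accTot["sigma"] + stp$accepted
        nTot["sigma"] <- nTot["sigma"] + 1
      }
    }

    ## omega1, omega2, rhoCorr | beta, mu : random walks
    for (nm in c("omega1", "omega2", "rhoCorr")) {
      spec <- priors[[nm]]
      if (.isFixed(spec)) { st[[nm]] <- spec$value; next }
      tgt <- function(x) {
        om1 <- if (nm == "omega1") x else st$omega1
        om2 <- if (nm == "omega2") x else st$omega2
        rc <- if (nm == "rhoCorr") x else st$rhoCorr
        bvnSum(om1, om2, rc) + logPriorDensity(spec, x)
      }
      stp <- .rwStep(st[[nm]], scales[nm], spec$support[1], spec$support[2],
                     tgt)
      st[[nm]] <- stp$x
      accWin[nm] <- accWin[nm] + stp$accepted
      if (it > cfg$burnIn) {
        accTot[nm] <- accTot[nm] + stp$accepted
        nTot[nm] <- nTot[nm] + 1
      }
    }

    ## adapt proposal scales during burn-in only
    if (it <= cfg$burnIn && it %% cfg$adaptInterval == 0L) {
      rates <- accWin / cfg$adaptInterval
      scales <- .adaptScale(scales, rates, cfg$targetAcceptance)
      accWin[] <- 0
    }

    if (it > cfg$burnIn && (it - cfg$burnIn) %% cfg$thin == 0L &&
        kept < nKeep) {
      kept <- kept + 1L
      keep$beta1[kept, ] <- st$beta1
      keep$beta2[kept, ] <- st$beta2
      keep$sigma[kept, 1L] <- st$sigma
      keep$mu1[kept, 1L] <- st$mu1
      keep$mu2[kept, 1L] <- st$mu2
      keep$omega1[kept, 1L] <- st$omega1
      keep$omega2[kept, 1L] <- st$omega2
      keep$rhoCorr[kept, 1L] <- st$rhoCorr
    }
  }
  list(draws = keep, acceptance = ifelse(nTot > 0, accTot / nTot, NA_real_))
}

## ---- exponential-model chain ----------------------------------------------

.initExp <- function(v, tSeq, priors, theta, jitterSd = 0.05) {
  clampIn <- function(x, spec, pad = 1e-3) {
    lo <- spec$support[1]; hi <- spec$support[2]
    if (.isFixed(spec)) spec$value else min(max(x, lo + pad), hi - pad)
  }
  mu <- exp(outer(theta$theta1Hat, rep(1, length(tSeq))) +
              outer(theta$theta2Hat, log(tSeq)))
  sig <- stats::sd(v - mu, na.rm = TRUE)
  A <- length(theta$theta1Hat)
  list(
    beta1 = theta$theta1Hat + stats::rnorm(A, 0, jitterSd),
    beta2 = theta$theta2Hat + stats::rnorm(A, 0, jitterSd / 5),
    sigma = clampIn(sig * exp(stats::rnorm(1L, 0, jitterSd)), priors$sigma),
    sigma1 = clampIn(0.1 * exp(stats::rnorm(1L, 0, jitterSd)),
                     priors$sigma1),
    sigma2 = clampIn(0.05 * exp(stats::rnorm(1L, 0, jitterSd)),
                     priors$sigma2)
  )
}

.runChainExp <- function(v, tSeq, priors, cfg, chainSeed, theta) {
  set.seed(chainSeed)
  A <- nrow(v)
  W <- !is.na(v)
  Y <- ifelse(W, v, 0)
  nx <- rowSums(W)
  Nobs <- sum(nx)
  lt <- log(tSeq)
  one <- rep(1, length(tSeq))

  st <- .initExp(v, tSeq, priors, theta)
  betaScale <- rep(0.1, A)
  betaAccWin <- betaAccTot <- numeric(A)
  betaNTot <- 0
  scaleNames <- c("sigma", "sigma1", "sigma2")
  scales <- stats::setNames(rep(0.5, 3L), scaleNames)
  accWin <- accTot <- stats::setNames(numeric(3L), scaleNames)
  nTot <- stats::setNames(numeric(3L), scaleNames)

  rowSSR <- function(b1, b2) {
    mu <- exp(outer(b1, one) + outer(b2, lt))
    rowSums(ifelse(W, (Y - mu)^2, 0))
  }

  nIterTotal <- cfg$burnIn + cfg$nIterations
  nKeep <- cfg$nIterations %/% cfg$thin
  keep <- list(
    beta1 = matrix(NA_real_, nKeep, A), beta2 = matrix(NA_real_, nKeep, A),
    sigma = matrix(NA_real_, nKeep, 1L), sigma1 = matrix(NA_real_, nKeep, 1L),
    sigma2 = matrix(NA_real_, nKeep, 1L)
  )
  kept <- 0L
  curSSR <- rowSSR(st$beta1, st$beta2)

  for (it in seq_len(nIterTotal)) {
    ## per-age (beta1, beta2) joint random-walk Metropolis, vectorized
    p1 <- st$beta1 + betaScale * stats::rnorm(A)
    p2 <- st$beta2 + betaScale * stats::rnorm(A) / 5
    propSSR <- rowSSR(p1, p2)
    s2 <- st$sigma^2
    logRatio <- (curSSR - propSSR) / (2 * s2) +
      stats::dnorm(p1, theta$theta1Hat, st$sigma1, log = TRUE) -
      stats::dnorm(st$beta1, theta$theta1Hat, st$sigma1, log = TRUE) +
      stats::dnorm(p2, theta$theta2Hat, st$sigma2, log = TRUE) -
      stats::dnorm(st$beta2, theta$theta2Hat, st$sigma2, log = TRUE)
    if (anyNA(logRatio)) stop("NaN in log-posterior evaluation")
    acc <- log(stats::runif(A)) < logRatio
    st$beta1[acc] <- p1[acc]
    st$beta2[acc] <- p2[acc]
    curSSR[acc] <- propSSR[acc]
    betaAccWin <- betaAccWin + acc
    if (it > cfg$burnIn) {
      betaAccTot <- betaAccTot + acc
      betaNTot <- betaNTot + 1
    }

    ## sigma | beta
    if (!.isFixed(priors$sigma)) {
      SSR <- sum(curSSR)
      tgt <- function(s) {
        -Nobs * log(s) - SSR / (2 * s^2) + logPriorDensity(priors$sigma, s)
      }
      stp <- .rwStep(st$sigma, scales["sigma"], priors$sigma$support[1],
                     priors$sigma$support[2], tgt)
      st$sigma <- stp$x
      accWin["sigma"] <- accWin["sigma"] + stp$accepted
      if (it > cfg$burnIn) {
        accTot["sigma"] <- accTot["sigma"] + stp$accepted
        nTot["sigma"] <- nTot["sigma"] + 1
      }
    }

    ## sigma1, sigma2 | beta : Gaussian "likelihood" of the coefficients
    ## around their OLS anchors
    for (j in 1:2) {
      nm <- paste0("sigma", j)
      spec <- priors[[nm]]
      if (.isFixed(spec)) { st[[nm]] <- spec$value; next }
      dev2 <- if (j == 1L) sum((st$beta1 - theta$theta1Hat)^2)
              else sum((st$beta2 - theta$theta2Hat)^2)
      tgt <- function(s) {
        -A * log(s) - dev2 / (2 * s^2) + logPriorDensity(spec, s)
      }
      stp <- .rwStep(st[[nm]], scales[nm], spec$support[1], spec$support[2],
                     tgt)
      st[[nm]] <- stp$x
      accWin[nm] <- accWin[nm] + stp$accepted
      if (it > cfg$burnIn) {
        accTot[nm] <- accTot[nm] + stp$accepted
        nTot[nm] <- nTot[nm] + 1
      }
    }

    if (it <= cfg$burnIn && it %% cfg$adaptInterval == 0L) {
      betaScale <- .adaptScale(betaScale, betaAccWin / cfg$adaptInterval,
                               cfg$targetAcceptance)
      betaAccWin[] <- 0
      scales <- .adaptScale(scales, accWin / cfg$adaptInterval,
                            cfg$targetAcceptance)
      accWin[] <- 0
    }

    if (it > cfg$burnIn && (it - cfg$burnIn) %% cfg$thin == 0L &&
        kept < nKeep) {
      kept <- kept + 1L
      keep$beta1[kept, ] <- st$beta1
      keep$beta2[kept, ] <- st$beta2
      keep$sigma[kept, 1L] <- st$sigma
      keep$sigma1[kept, 1L] <- st$sigma1
      keep$sigma2[kept, 1L] <- st$sigma2
    }
  }
  accAll <- c(ifelse(nTot > 0, accTot / nTot, NA_real_),
              beta = if (betaNTot > 0) mean(betaAccTot / betaNTot) else NA)
  list(draws = keep, acceptance = accAll)
}

## ---- public sampler --------------------------------------------------------

#' Sample the posterior of a core model
#'
#' Runs `nChains` independent Metropolis-within-Gibbs chains on the
#' base-period improvement-rate surface, discards the burn-in, thins, and
#' pools the retained draws. For the exponential model the OLS anchors are
#' pre-fitted with [prefitTheta()] (after flooring at `floor`).
#'
#' @param rho a [ROMISurface-class] (or ages x years matrix) of observed
#'   improvement rates, model time 1..T along the columns.
#' @param model `"linear"` or `"exponential"`.
#' @param config an [mcmcConfig()].
#' @param priors optional partial override of [defaultPriors()]; a
#'   [priorSpec()] with family `"fixed"` pins a hyper-parameter.
#' @param floor positive floor used by the exponential pre-fit.
#' @return a [ParameterDraws-class] object.
#' @examples
#' rho <- ROMISurface(matrix(rnorm(5 * 12, 0.02, 0.005), 5, 12),
#'                    ages = 0:4, years = 1989:2000)
#' pd <- runSampler(rho, "linear",
#'                  mcmcConfig(nChains = 2, nIterations = 200, burnIn = 50,
#'                             thin = 2, seed = 7))
#' pd
#' @export
runSampler <- function(rho, model = c("linear", "exponential"),
                       config = mcmcConfig(), priors = NULL, floor = 1e-4) {
  model <- match.arg(model)
  stopifnot(inherits(config, "MCMCConfig"))
  v <- .romiMatrix(rho)
  agesOut <- if (is(rho, "ROMISurface")) rho@ages else seq_len(nrow(v)) - 1L
  if (all(is.na(v))) stop("all improvement rates are missing")
  tSeq <- seq_len(ncol(v))
  pr <- .mergePriors(model, priors)
  seeds <- .chainSeeds(config$seed, config$nChains)

  theta <- if (model == "exponential") prefitTheta(v, floor) else list()
  runs <- vector("list", config$nChains)
  for (ch in seq_len(config$nChains)) {
    runs[[ch]] <- if (model == "linear") {
      .runChainLinear(v, tSeq, pr, config, seeds[ch])
    } else {
      .runChainExp(v, tSeq, pr, config, seeds[ch], theta)
    }
  }

  parNames <- names(runs[[1]]$draws)
  draws <- lapply(stats::setNames(parNames, parNames), function(nm) {
    do.call(rbind, lapply(runs, function(r) r$draws[[nm]]))
  })
  nKeep <- config$nIterations %/% config$thin
  chain <- rep(seq_len(config$nChains), each = nKeep)
  accM <- do.call(rbind, lapply(runs, function(r) r$acceptance))
  acceptance <- colMeans(accM)
  low <- acceptance[!is.na(acceptance) & acceptance < 0.01]
  if (length(low)) {
    warning("Metropolis acceptance below 1% after adaptation for: ",
            paste(names(low), collapse = ", "))
  }
  cfgList <- unclass(config)
  cfgList$baseT <- ncol(v)
  ## last base-period RATE year = last transition label + 1
  cfgList$lastYear <- if (is(rho, "ROMISurface")) max(rho@years) + 1L else NULL
  new("ParameterDraws", model = model, draws = draws,
      chain = as.integer(chain), ages = as.integer(agesOut),
      config = cfgList, priors = pr, acceptance = acceptance,
      prefit = theta)
}

#' @rdname parameterDraws
#' @export
setMethod("parameterDraws", "ParameterDraws", function(x, name) {
  if (!name %in% names(x@draws)) {
    stop("no parameter '", name, "'; available: ",
         paste(names(x@draws), collapse = ", "))
  }
  x@draws[[name]]
})

setMethod("show", "ParameterDraws", function(object) {
  cat(sprintf(
    "ParameterDraws: %s core model, %d draws (%d chains x %d), %d ages\n",
    object@model, length(object@chain), max(object@chain),
    sum(object@chain == 1L), length(object@ages)
  ))
  acc <- object@acceptance[!is.na(object@acceptance)]
  if (length(acc)) {
    cat("  Metropolis acceptance:",
        paste(sprintf("%s=%.2f", names(acc), acc), collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' Reconstruct the parameter list of one retained draw
#'
#' @param x a [ParameterDraws-class].
#' @param i draw index (row of the pooled draw matrices).
#' @return a `LinearModelParams` or `ExpModelParams` list.
#' @export
drawParams <- function(x, i) {
  stopifnot(is(x, "ParameterDraws"))
  d <- x@draws
  if (x@model == "linear") {
    linearModelParams(d$beta1[i, ], d$beta2[i, ], d$sigma[i, 1L],
                      d$mu1[i, 1L], d$mu2[i, 1L], d$omega1[i, 1L],
                      d$omega2[i, 1L], d$rhoCorr[i, 1L])
  } else {
    expModelParams(d$beta1[i, ], d$beta2[i, ], d$sigma[i, 1L],
                   d$sigma1[i, 1L], d$sigma2[i, 1L],
                   x@prefit$theta1Hat, x@prefit$theta2Hat)
  }
}
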