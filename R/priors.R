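#' @include surfaces.R
NULL

## Hyper-parameter priors. The default specification is weakly informative
## uniforms: sigma, omega1, omega2, sigma1, sigma2 ~ U(0, 1);
## mu1, mu2 ~ U(-0.1, 0.1); rhoCorr ~ U(-1, 1). Alternative families on the
## same support (rescaled Beta, truncated Normal) support the
## prior-sensitivity harness; a "fixed" family pins a parameter.

#' Specify one hyper-parameter prior
#'
#' @param family `"uniform"`, `"beta"`, `"normal"` or `"fixed"`.
#' @param support length-2 numeric: the admissible open interval. Draws and
#'   Metropolis proposals never leave it; `"beta"` is rescaled onto it and
#'   `"normal"` truncated to it.
#' @param shape1,shape2 Beta shapes (family `"beta"`).
#' @param mean,sd location and spread (family `"normal"`).
#' @param value the pinned value (family `"fixed"`).
#' @return a list of class `PriorSpec`.
#' @examples
#' priorSpec("uniform", c(0, 1))
#' priorSpec("beta", c(0, 1), shape1 = 2, shape2 = 2)
#' priorSpec("fixed", value = 0.005)
#' @export
priorSpec <- function(family = c("uniform", "beta", "normal", "fixed"),
                      support = c(0, 1), shape1 = 2, shape2 = 2,
                      mean = NULL, sd = NULL, value = NULL) {
  family <- match.arg(family)
  stopifnot(length(support) == 2L, support[1] < support[2])
  if (family == "fixed") {
    stopifnot(!is.null(value), value > support[1], value < support[2])
  }
  if (family == "normal") {
    if (is.null(mean)) mean <- sum(support) / 2
    if (is.null(sd)) sd <- diff(support) / 4
  }
  structure(list(family = family, support = support, shape1 = shape1,
                 shape2 = shape2, mean = mean, sd = sd, value = value),
            class = "PriorSpec")
}

#' Log prior density (up to a constant), -Inf outside the support
#'
#' @param spec a [priorSpec()].
#' @param x parameter value(s).
#' @return numeric log density.
#' @keywords internal
#' @export
logPriorDensity <- function(spec, x) {
  lo <- spec$support[1]
  hi <- spec$support[2]
  out <- rep(-Inf, length(x))
  ok <- x > lo & x < hi
  if (any(ok)) {
    out[ok] <- switch(spec$family,
      uniform = 0,
      beta = stats::dbeta((x[ok] - lo) / (hi - lo), spec$shape1, spec$shape2,
                          log = TRUE),
      normal = stats::dnorm(x[ok], spec$mean, spec$sd, log = TRUE),
      fixed = ifelse(x[ok] == spec$value, 0, -Inf)
    )
  }
  out
}

#' Default prior sets for the core models
#'
#' Linear model: sigma, omega1, omega2 ~ U(0,1); mu1, mu2 ~ U(-0.1, 0.1);
#' rhoCorr ~ U(-1, 1). Exponential model: sigma, sigma1, sigma2 ~ U(0,1).
#'
#' @param model `"linear"` or `"exponential"`.
#' @return named list of [priorSpec()] objects.
#' @examples
#' names(defaultPriors("linear"))
#' @export
defaultPriors <- function(model = c("linear", "exponential")) {
  model <- match.arg(model)
  if (model == "linear") {
    list(
      sigma = priorSpec("uniform", c(0, 1)),
      mu1 = priorSpec("uniform", c(-0.1, 0.1)),
      mu2 = priorSpec("uniform", c(-0.1, 0.1)),
      omega1 = priorSpec("uniform", c(0, 1)),
      omega2 = priorSpec("uniform", c(0, 1)),
      rhoCorr = priorSpec("uniform", c(-1, 1))
    )
  } else {
    list(
      sigma = priorSpec("uniform", c(0, 1)),
      sigma1 = priorSpec("uniform", c(0, 1)),
      sigma2 = priorSpec("uniform", c(0, 1))
    )
  }
}

.mergePriors <- function(model, priors) {
  out <- defaultPriors(model)
  if (!is.null(priors)) {
    stopifnot(all(names(priors) %in% names(out)))
    out[names(priors)] <- priors
  }
  out
}
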