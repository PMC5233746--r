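#' @include mcmc.R
NULL

#' Raftery-Lewis run-length diagnostic
#'
#' Estimates how many MCMC iterations are needed to estimate the posterior
#' quantile `q` to within `+/- r` with probability `s`. The draw sequence is
#' dichotomized at its empirical `q`-quantile; the minimal thinning `k` that
#' makes the binary chain first-order Markov is found by BIC comparison of
#' first- versus second-order transition counts; burn-in and the required
#' run length then follow from the two-state transition matrix. The minimum
#' run length for an independence chain is
#' `Nmin = ceiling(q (1-q) (z_(1+s)/2 / r)^2)` and the dependence factor
#' `I = N / Nmin` measures the autocorrelation penalty.
#'
#' @param chain numeric vector of draws of one scalar parameter.
#' @param q quantile of interest (default 0.025).
#' @param r required accuracy (default 0.005).
#' @param s probability of achieving it (default 0.95).
#' @param eps burn-in convergence tolerance (default 0.001).
#' @return list with `N` (required iterations, burn-in included), `Nmin`,
#'   `I` (dependence factor), `burnIn`, and the selected thinning `k`.
#' @examples
#' set.seed(1)
#' rafteryLewis(rnorm(10000))
#' @export
rafteryLewis <- function(chain, q = 0.025, r = 0.005, s = 0.95,
                         eps = 0.001) {
  chain <- as.numeric(chain)
  n <- length(chain)
  if (stats::var(chain) == 0) stop("constant chain: diagnostic undefined")
  zq <- stats::qnorm(0.5 * (1 + s))
  nMin <- ceiling(q * (1 - q) * (zq / r)^2)
  if (n < 3L * 2L) stop("chain too short for the diagnostic")
  cutoff <- stats::quantile(chain, q, names = FALSE)
  zt <- as.integer(chain <= cutoff)

  ## minimal thinning k making the binary chain first-order Markov (BIC)
  k <- 0L
  repeat {
    k <- k + 1L
    zk <- zt[seq(1L, n, by = k)]
    nk <- length(zk)
    if (nk < 3L) stop("chain too short for the diagnostic's thinning search")
    tri <- table(factor(zk[1:(nk - 2L)], 0:1),
                 factor(zk[2:(nk - 1L)], 0:1),
                 factor(zk[3:nk], 0:1))
    g2 <- 0
    for (i1 in 1:2) for (i2 in 1:2) for (i3 in 1:2) {
      if (tri[i1, i2, i3] == 0) next
      fitted <- sum(tri[i1, i2, ]) * sum(tri[, i2, i3]) / sum(tri[, i2, ])
      g2 <- g2 + 2 * tri[i1, i2, i3] * log(tri[i1, i2, i3] / fitted)
    }
    bic <- g2 - log(nk - 2L) * 2
    if (bic < 0 || k > n / 6) break
  }

  zk <- zt[seq(1L, n, by = k)]
  nk <- length(zk)
  from <- zk[1:(nk - 1L)]
  to <- zk[2:nk]
  alpha <- sum(from == 0L & to == 1L) / max(sum(from == 0L), 1L)
  beta <- sum(from == 1L & to == 0L) / max(sum(from == 1L), 1L)
  if (alpha == 0 || beta == 0) {
    stop("degenerate transition matrix: chain does not cross the quantile")
  }
  apb <- alpha + beta
  mStar <- log(eps * apb / max(alpha, beta)) / log(abs(1 - apb))
  burn <- ceiling(max(mStar, 0)) * k
  nStar <- ceiling(alpha * beta * (2 - apb) / apb^3 * (zq / r)^2)
  nReq <- burn + nStar * k
  list(N = nReq, Nmin = nMin, I = nReq / nMin, burnIn = burn, k = k)
}

.scalarComponents <- function(pd, parameters = NULL) {
  nms <- names(pd@draws)
  if (!is.null(parameters)) nms <- intersect(nms, parameters)
  out <- list()
  for (nm in nms) {
    m <- pd@draws[[nm]]
    if (ncol(m) == 1L) {
      out[[nm]] <- m[, 1L]
    } else {
      for (j in seq_len(ncol(m))) {
        out[[sprintf("%s[%d]", nm, pd@ages[j])]] <- m[, j]
      }
    }
  }
  out
}

#' Convergence diagnostics for posterior draws
#'
#' Per scalar parameter component: the trace (draw sequence per chain), the
#' autocorrelation function by lag, and the split-chain potential scale
#' reduction factor (values near 1 indicate convergence). Everything is
#' returned as plotting-ready data frames.
#'
#' @param pd a [ParameterDraws-class] object.
#' @param parameters optional character vector restricting to some parameter
#'   names (default: the scalar hyper-parameters only, to keep the tables
#'   small).
#' @param maxLag largest ACF lag.
#' @return list of data frames `trace`, `acf`, `rhat`.
#' @export
chainDiagnostics <- function(pd, parameters = c("sigma", "mu1", "mu2",
                                                "omega1", "omega2",
                                                "rhoCorr", "sigma1",
                                                "sigma2"),
                             maxLag = 20L) {
  stopifnot(is(pd, "ParameterDraws"))
  comps <- .scalarComponents(pd, parameters)
  chains <- sort(unique(pd@chain))
  nPer <- sum(pd@chain == chains[1])

  traceDf <- do.call(rbind, lapply(names(comps), function(nm) {
    data.frame(parameter = nm, chain = pd@chain,
               iteration = stats::ave(seq_along(pd@chain), pd@chain,
                                      FUN = seq_along),
               value = comps[[nm]])
  }))

  acfDf <- do.call(rbind, lapply(names(comps), function(nm) {
    perChain <- sapply(chains, function(ch) {
      x <- comps[[nm]][pd@chain == ch]
      stats::acf(x, lag.max = maxLag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
    })
    data.frame(parameter = nm, lag = 0:maxLag, acf = rowMeans(perChain))
  }))

  rhatDf <- NULL
  if (length(chains) >= 2L && nPer >= 4L) {
    rhat <- vapply(comps, function(x) {
      half <- nPer %/% 2L
      seqs <- unlist(lapply(chains, function(ch) {
        xs <- x[pd@chain == ch]
        list(xs[seq_len(half)], xs[(half + 1L):(2L * half)])
      }), recursive = FALSE)
      m <- length(seqs)
      nn <- half
      means <- vapply(seqs, mean, numeric(1))
      vars <- vapply(seqs, stats::var, numeric(1))
      W <- mean(vars)
      B <- nn * stats::var(means)
      if (W == 0) return(1)
      sqrt(((nn - 1) / nn * W + B / nn) / W)
    }, numeric(1))
    rhatDf <- data.frame(parameter = names(comps), rhat = as.numeric(rhat))
  } else {
    warning("fewer than 2 chains (or chains too short): ",
            "potential scale reduction omitted")
  }
  list(trace = traceDf, acf = acfDf, rhat = rhatDf)
}
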