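## shared fixtures, built in code

## random positive death-rate surface with ratios near 1 (realistic
## year-on-year changes)
randomRateSurface <- function(nAges = 6, nYears = 12, seed = 1) {
  set.seed(seed)
  m0 <- runif(nAges, 1e-4, 0.2)
  v <- matrix(NA_real_, nAges, nYears)
  v[, 1] <- m0
  for (j in 2:nYears) v[, j] <- v[, j - 1] * runif(nAges, 0.9, 1.1)
  MortalitySurface(v, seq_len(nAges) - 1L, 2000L + seq_len(nYears) - 1L)
}

## write a minimal HMD-style 1x1 file; `rows` is a data.frame with columns
## Year, Age (character), Female, Male, Total (character, "." = missing)
writeHMDFixture <- function(rows, path = tempfile(fileext = ".txt")) {
  fmt <- function(r) {
    sprintf("  %-6s %-6s %14s %14s %14s", r[1], r[2], r[3], r[4], r[5])
  }
  lines <- c(
    "Fixture, Death rates (period 1x1),\tLast modified: test",
    "",
    "  Year          Age             Female            Male           Total",
    apply(rows, 1, fmt)
  )
  writeLines(lines, path)
  path
}

## tiny ParameterDraws with hand-set draws (for forecast-layer tests)
makeDraws <- function(beta1, beta2, sigma, model = "linear", baseT = 10L,
                      nRep = 1L) {
  A <- length(beta1)
  rep1 <- function(x) matrix(rep(x, each = nRep), nRep, length(x))
  draws <- list(beta1 = rep1(beta1), beta2 = rep1(beta2),
                sigma = matrix(sigma, nRep, 1L))
  if (model == "linear") {
    draws <- c(draws, list(mu1 = matrix(0, nRep, 1), mu2 = matrix(0, nRep, 1),
                           omega1 = matrix(0.01, nRep, 1),
                           omega2 = matrix(0.01, nRep, 1),
                           rhoCorr = matrix(0, nRep, 1)))
  } else {
    draws <- c(draws, list(sigma1 = matrix(0.1, nRep, 1),
                           sigma2 = matrix(0.1, nRep, 1)))
  }
  new("ParameterDraws", model = model, draws = draws,
      chain = rep(1L, nRep), ages = seq_len(A) - 1L,
      config = list(baseT = baseT, lastYear = 2000L + baseT),
      priors = defaultPriors(model), acceptance = numeric(0),
      prefit = if (model == "exponential")
        list(theta1Hat = beta1, theta2Hat = beta2) else list())
}
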