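test_that("the exponential pre-fit recovers noiseless coefficients", {
  tt <- 1:15
  r <- ROMISurface(rbind(exp(-3 + 0.2 * log(tt)),
                         rep(0.02, 15)),
                   0:1, 2000 + tt - 1)
  th <- prefitTheta(r)
  expect_equal(th$theta1Hat, c(-3, log(0.02)), tolerance = 1e-10)
  expect_equal(th$theta2Hat, c(0.2, 0), tolerance = 1e-10)
})

test_that("pre-fit floors negatives and matches an independent OLS oracle", {
  set.seed(5)
  tt <- 1:10
  vals <- c(0.02, -0.01, 0.015, 0.03, -0.002, 0.01, 0.02, 0.025, 0.018,
            0.022)
  r <- ROMISurface(rbind(vals), 0, 2000 + tt - 1)
  th <- prefitTheta(r, floor = 1e-4)
  oracle <- stats::lm(log(pmax(vals, 1e-4)) ~ log(tt))
  expect_equal(th$theta1Hat, unname(coef(oracle)[1]), tolerance = 1e-10)
  expect_equal(th$theta2Hat, unname(coef(oracle)[2]), tolerance = 1e-10)
  short <- ROMISurface(rbind(c(0.01, 0.02, NA, NA, NA, NA, NA, NA, NA, NA)),
                       0, 2000 + tt - 1)
  expect_error(prefitTheta(short), "fewer than 3")
})

## independent term-by-term density oracles, written against the model
## definitions rather than the implementation
oracleLinearLP <- function(p, v, tSeq) {
  if (p$sigma <= 0 || p$sigma >= 1) return(-Inf)
  if (abs(p$mu1) >= 0.1 || abs(p$mu2) >= 0.1) return(-Inf)
  if (p$omega1 <= 0 || p$omega1 >= 1 || p$omega2 <= 0 || p$omega2 >= 1) {
    return(-Inf)
  }
  if (abs(p$rhoCorr) >= 1) return(-Inf)
  total <- 0
  for (a in seq_len(nrow(v))) {
    for (j in seq_len(ncol(v))) {
      if (is.na(v[a, j])) next
      mu <- p$beta1[a] + p$beta2[a] * tSeq[j]
      total <- total + dnorm(v[a, j], mu, p$sigma, log = TRUE)
    }
    Om <- matrix(c(p$omega1^2, p$rhoCorr * p$omega1 * p$omega2,
                   p$rhoCorr * p$omega1 * p$omega2, p$omega2^2), 2)
    b <- c(p$beta1[a], p$beta2[a]) - c(p$mu1, p$mu2)
    total <- total - log(2 * pi) - 0.5 * determinant(Om)$modulus[1] -
      0.5 * drop(t(b) %*% solve(Om) %*% b)
  }
  total
}

oracleExpLP <- function(p, v, tSeq) {
  if (p$sigma <= 0 || p$sigma >= 1) return(-Inf)
  if (p$sigma1 <= 0 || p$sigma1 >= 1 || p$sigma2 <= 0 || p$sigma2 >= 1) {
    return(-Inf)
  }
  total <- 0
  for (a in seq_len(nrow(v))) {
    for (j in seq_len(ncol(v))) {
      if (is.na(v[a, j])) next
      mu <- exp(p$beta1[a] + p$beta2[a] * log(tSeq[j]))
      total <- total + dnorm(v[a, j], mu, p$sigma, log = TRUE)
    }
    total <- total + dnorm(p$beta1[a], p$theta1Hat[a], p$sigma1, log = TRUE) +
      dnorm(p$beta2[a], p$theta2Hat[a], p$sigma2, log = TRUE)
  }
  total
}

test_that("linear log-posterior matches the density-sum oracle", {
  set.seed(21)
  v <- matrix(rnorm(6, 0.02, 0.004), 2, 3)
  p <- linearModelParams(beta1 = c(0.018, 0.022), beta2 = c(3e-4, -2e-4),
                         sigma = 0.005, mu1 = 0.02, mu2 = 0, omega1 = 0.01,
                         omega2 = 0.001, rhoCorr = -0.3)
  expect_equal(linearLogPosterior(p, v), oracleLinearLP(p, v, 1:3),
               tolerance = 1e-10)
  ## missing cells are skipped consistently
  v[1, 2] <- NA
  expect_equal(linearLogPosterior(p, v), oracleLinearLP(p, v, 1:3),
               tolerance = 1e-10)
  ## outside prior support
  pBad <- p; pBad$sigma <- 1.5
  expect_identical(linearLogPosterior(pBad, v), -Inf)
  pBad2 <- p; pBad2$mu1 <- 0.2
  expect_identical(linearLogPosterior(pBad2, v), -Inf)
})

test_that("exponential log-posterior matches the density-sum oracle", {
  set.seed(22)
  v <- matrix(rnorm(6, 0.02, 0.004), 2, 3)
  p <- expModelParams(beta1 = c(-3.9, -4.1), beta2 = c(-0.1, 0.05),
                      sigma = 0.005, sigma1 = 0.2, sigma2 = 0.1,
                      theta1Hat = c(-4, -4), theta2Hat = c(0, 0))
  expect_equal(expLogPosterior(p, v), oracleExpLP(p, v, 1:3),
               tolerance = 1e-10)
  pBad <- p; pBad$sigma1 <- -0.1
  expect_identical(expLogPosterior(pBad, v), -Inf)
})

test_that("the hierarchy is exchangeable over ages", {
  set.seed(23)
  v <- matrix(rnorm(12, 0.02, 0.004), 4, 3)
  p <- linearModelParams(beta1 = c(0.01, 0.02, 0.015, 0.025),
                         beta2 = c(1e-4, 2e-4, -1e-4, 0), sigma = 0.005,
                         mu1 = 0.02, mu2 = 0, omega1 = 0.01,
                         omega2 = 0.001, rhoCorr = 0.2)
  perm <- c(3, 1, 4, 2)
  pPerm <- p
  pPerm$beta1 <- p$beta1[perm]
  pPerm$beta2 <- p$beta2[perm]
  expect_equal(linearLogPosterior(pPerm, v[perm, ]),
               linearLogPosterior(p, v), tolerance = 1e-12)
})

test_that("model means evaluate and behave monotonically", {
  pLin <- linearModelParams(0.01, 0.001, 0.005, 0, 0, 0.01, 0.001, 0)
  expect_equal(meanROMI(pLin, 10)[1, 1], 0.02)
  pExpFlat <- expModelParams(log(0.02), 0, 0.005, 0.1, 0.1, log(0.02), 0)
  expect_equal(meanROMI(pExpFlat, c(1, 7, 30))[1, ], rep(0.02, 3))
  pExpDec <- expModelParams(log(0.03), -0.2, 0.005, 0.1, 0.1, log(0.03),
                            -0.2)
  path <- meanROMI(pExpDec, 1:20)[1, ]
  expect_true(all(diff(path) < 0))
})
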