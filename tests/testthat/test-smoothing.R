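## independent brute-force penalized-IRLS oracle: plain loop, no shared
## code with the implementation
oraclePIRLS <- function(y, E, B, D2, lambda) {
  a <- rep(0, ncol(B))
  for (it in 1:200) {
    eta <- as.vector(B %*% a)
    mu <- E * exp(eta)
    W <- diag(mu)
    z <- eta + (y - mu) / mu
    aNew <- solve(t(B) %*% W %*% B + lambda * t(D2) %*% D2,
                  t(B) %*% W %*% z)
    if (max(abs(aNew - a)) < 1e-11) { a <- aNew; break }
    a <- aNew
  }
  eta <- as.vector(B %*% a)
  mu <- E * exp(eta)
  H <- solve(t(B) %*% diag(mu) %*% B + lambda * t(D2) %*% D2,
             t(B) %*% diag(mu) %*% B)
  ed <- sum(diag(H))
  dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  list(bic = dev + log(length(y)) * ed, ed = ed, fitted = mu)
}

test_that("order-2 penalty with huge lambda recovers a log-linear trend", {
  Tn <- 25
  E <- matrix(1e6, 1, Tn)
  m <- matrix(exp(-4 - 0.03 * (seq_len(Tn) - 1)), 1, Tn)
  sm <- smoothRates(m * E, E,
                    smoothingConfig(penaltyOrder = 2, lambdaGrid = 1e9))
  expect_equal(log(surfaceValues(sm)[1, ]), log(m[1, ]),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(surfaceValues(sm) > 0))
})

test_that("order-1 penalty with huge lambda flattens a noisy constant", {
  set.seed(42)
  Tn <- 30
  E <- matrix(1e5, 1, Tn)
  D <- matrix(rpois(Tn, 1e5 * 0.02), 1, Tn)
  sm <- smoothRates(D, E, smoothingConfig(penaltyOrder = 1,
                                          lambdaGrid = 1e9))
  fit <- surfaceValues(sm)[1, ]
  expect_lt(diff(range(fit)) / mean(fit), 1e-4)
  expect_equal(mean(fit), 0.02, tolerance = 0.01)
})

test_that("BIC-selected lambda matches the brute-force oracle on a toy", {
  set.seed(7)
  Tn <- 12
  E <- rep(2e4, Tn)
  truth <- 0.03 * exp(-0.05 * (seq_len(Tn) - 1)) *
    exp(rnorm(Tn, 0, 0.08))
  D <- rpois(Tn, E * truth)
  grid <- c(0.1, 10, 1000)
  sm <- smoothRates(matrix(D, 1), matrix(E, 1),
                    smoothingConfig(penaltyOrder = 2, lambdaGrid = grid))
  ## oracle with the same basis construction
  B <- romicast:::bsplineBasis(seq_len(Tn), max(ceiling(Tn / 5), 3))
  D2 <- diff(diag(ncol(B)), differences = 2)
  bics <- vapply(grid, function(l) oraclePIRLS(D, E, B, D2, l)$bic,
                 numeric(1))
  expect_equal(surfaceMetadata(sm)$lambda, grid[which.min(bics)])
  expect_equal(surfaceMetadata(sm)$bic, min(bics), tolerance = 1e-6)
  ## shrinkage is monotone: effective dimension non-increasing in lambda
  eds <- vapply(grid, function(l) oraclePIRLS(D, E, B, D2, l)$ed, numeric(1))
  expect_true(all(diff(eds) <= 1e-8))
  implEds <- vapply(grid, function(l) {
    romicast:::.pirls(D, E, B, crossprod(D2), l)$ed
  }, numeric(1))
  expect_equal(implEds, eds, tolerance = 1e-6)
})

test_that("the 2D age-time smoother reproduces a smooth surface", {
  A <- 12; Tn <- 14
  x <- seq_len(A) - 1
  m <- outer(exp(-6 + 0.08 * x), exp(-0.02 * (seq_len(Tn) - 1)))
  E <- matrix(1e6, A, Tn)
  sm <- smoothRates(m * E, E,
                    smoothingConfig(lambdaGrid = 10^(0:3),
                                    mode = "age-time-2D"))
  expect_equal(surfaceValues(sm), m, tolerance = 0.02, ignore_attr = TRUE)
  expect_true(all(surfaceValues(sm) > 0))
})

test_that("degenerate smoothing inputs are refused", {
  E <- matrix(1e5, 1, 10)
  expect_error(smoothRates(matrix(NA_real_, 1, 10), E), "missing")
  E0 <- E; E0[1, 3] <- 0
  expect_error(smoothRates(matrix(10, 1, 10), E0), "positive")
})
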