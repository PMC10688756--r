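sim_spatial <- function(n, beta, rho, sigma = 1, seed = 1) {
  set.seed(seed)
  coords <- cbind(lon = runif(n, -55, -35), lat = runif(n, -30, -5))
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  d <- as.matrix(dist(coords))
  e <- if (rho > 0) {
    drop(t(chol(exp(-d / rho) + diag(1e-10, n))) %*% rnorm(n)) * sigma
  } else rnorm(n, sd = sigma)
  list(data = data.frame(y = beta[1] + beta[2] * x1 + beta[3] * x2 + e,
                         x1 = x1, x2 = x2),
       coords = coords)
}

test_that("standardize produces exact z-scores", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  df <- data.frame(a = rnorm(20, 5, 3), b = runif(20))
  z <- standardize(df)
  expect_equal(colMeans(z), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(vapply(z, sd, 1), c(a = 1, b = 1), tolerance = 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(data.frame(a = rep(2, 5))), "constant")
})

test_that("the zero-range limit reproduces ordinary least squares", {
  s <- sim_spatial(60, c(1, 2, -1), rho = 0, seed = 2)
  # with a fixed, vanishing range the correlation matrix is the identity
  fit <- gls_exponential(y ~ x1 + x2, s$data, s$coords, rho = 1e-8)
  ols <- lm(y ~ x1 + x2, s$data)
  expect_equal(coef(fit), coef(ols), tolerance = 1e-6)
  fit0 <- gls_exponential(y ~ x1 + x2, s$data, correlation = "none")
  expect_equal(coef(fit0), coef(ols), tolerance = 1e-10)
  # intercept-only model with V = I estimates the arithmetic mean
  m <- gls_exponential(y ~ 1, s$data, correlation = "none")
  expect_equal(unname(coef(m)), mean(s$data$y), tolerance = 1e-10)
})

test_that("ML estimates agree with the nlme oracle", {
  skip_if_not_installed("nlme")
  s <- sim_spatial(120, c(0.5, 1.5, -0.8), rho = 3, seed = 3)
  fit <- gls_exponential(y ~ x1 + x2, s$data, s$coords)
  df <- cbind(s$data, lon = s$coords[, 1], lat = s$coords[, 2])
  ofit <- nlme::gls(y ~ x1 + x2, df, method = "ML",
                    correlation = nlme::corExp(form = ~ lon + lat))
  expect_equal(coef(fit), coef(ofit), tolerance = 1e-3)
  expect_equal(fit$logLik, as.numeric(stats::logLik(ofit)),
               tolerance = 1e-4)
  expect_equal(fit$rho,
               as.numeric(coef(ofit$modelStruct$corStruct,
                               unconstrained = FALSE)),
               tolerance = 0.02)
  # the optimum dominates every grid evaluation
  expect_gte(fit$logLik, fit$grid_logLik_max - 1e-9)
})

test_that("range and coefficients are recovered from simulation", {
  hits_beta <- 0
  hits_rho <- 0
  n_rep <- 12
  for (r in seq_len(n_rep)) {
    s <- sim_spatial(150, c(0, 1, -0.5), rho = 2, sigma = 1, seed = 100 + r)
    fit <- gls_exponential(y ~ x1 + x2, s$data, s$coords)
    ct <- fit$coef_table
    ok_b <- abs(ct["x1", "Estimate"] - 1) < 2.5 * ct["x1", "Std. Error"] &&
      abs(ct["x2", "Estimate"] + 0.5) < 2.5 * ct["x2", "Std. Error"]
    hits_beta <- hits_beta + ok_b
    hits_rho <- hits_rho + (fit$rho > 1 && fit$rho < 4)
  }
  expect_gte(hits_beta, n_rep - 2)
  expect_gte(hits_rho, n_rep - 3)
})

test_that("scaling the response leaves standardized structure intact", {
  s <- sim_spatial(80, c(0, 1, -0.5), rho = 2, seed = 7)
  f1 <- gls_exponential(y ~ x1 + x2, s$data, s$coords)
  d2 <- s$data
  d2$y <- 10 * d2$y
  f2 <- gls_exponential(y ~ x1 + x2, d2, s$coords)
  expect_equal(coef(f2), 10 * coef(f1), tolerance = 1e-4)
  # logLik shifts by exactly -n log(c)
  expect_equal(f2$logLik, f1$logLik - 80 * log(10), tolerance = 1e-4)
  expect_equal(f2$rho, f1$rho, tolerance = 1e-3)
})

test_that("duplicate coordinates are handled with a ridge", {
  s <- sim_spatial(40, c(0, 1, 0), rho = 2, seed = 8)
  coords <- s$coords
  coords[2, ] <- coords[1, ]
  fit <- gls_exponential(y ~ x1, s$data, coords)
  expect_true(is.finite(fit$logLik))
  expect_error(gls_exponential(y ~ x1 + I(2 * x1), s$data, s$coords),
               "singular")
})

test_that("Moran's I matches expectation for iid data and flags gradients", {
  skip_if_not_installed("ape")
  set.seed(9)
  coords <- cbind(runif(40, -55, -35), runif(40, -30, -5))
  z <- rnorm(40)
  m <- morans_i(z, coords, n_perm = 999, seed = 10)
  expect_equal(m$expected, -1 / 39)
  expect_lt(abs(m$observed - m$expected), 0.15)
  expect_gt(m$p_value, 0.01)
  # the statistic agrees with the ape implementation
  w <- 1 / as.matrix(dist(coords))
  diag(w) <- 0
  expect_equal(m$observed, ape::Moran.I(z, w)$observed, tolerance = 1e-10)
  expect_equal(m$expected, ape::Moran.I(z, w)$expected)
  # a smooth spatial gradient is detected
  g <- coords[, 1] + 0.1 * rnorm(40)
  mg <- morans_i(g, coords, n_perm = 999, seed = 11)
  expect_gt(mg$observed, 0.1)
  expect_lt(mg$p_value, 0.01)
  expect_error(morans_i(rnorm(2), coords[1:2, ]), "at least 10")
})

test_that("AIC tables rank, weight and guard the response", {
  s <- sim_spatial(60, c(0, 1, 0), rho = 0, seed = 12)
  f1 <- gls_exponential(y ~ x1, s$data, correlation = "none")
  f2 <- gls_exponential(y ~ x1 + x2, s$data, correlation = "none")
  tab <- aic_table(list(with = f2, without = f1))
  expect_equal(sum(tab$weight), 1)
  expect_equal(min(tab$dAIC), 0)
  expect_equal(tab$AIC, sort(tab$AIC))
  # two identical fits split the weight evenly
  tab2 <- aic_table(list(a = f1, b = f1))
  expect_equal(tab2$weight, c(0.5, 0.5))
  d3 <- s$data
  d3$y <- rev(d3$y)
  f3 <- gls_exponential(y ~ x1, d3, correlation = "none")
  expect_error(aic_table(list(f1, f3)), "same response")
})
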