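test_that("Poisson pmf is a normalized count distribution with mean = var = lambda", {
  expect_equal(poisson_pmf(0, 1), exp(-1), tolerance = 1e-12)
  ks <- 0:200
  expect_lt(abs(sum(poisson_pmf(ks, 3)) - 1), 1e-12)
  p7 <- poisson_pmf(ks, 7)
  expect_lt(abs(sum(ks * p7) - 7), 1e-9)
  expect_lt(abs(sum(ks^2 * p7) - sum(ks * p7)^2 - 7), 1e-9)
  expect_error(poisson_pmf(-1, 2), "non-negative")
  expect_error(poisson_pmf(2, 0), "positive")
})

test_that("log posterior equals likelihood + prior up to a constant", {
  set.seed(12)
  X <- cbind(1, matrix(rnorm(40), 20, 2))
  y <- rpois(20, 3)
  flat <- poisson_prior(0.5, 0, q = 3)
  # flat prior: difference to the dpois log-likelihood is constant in B
  diffs <- vapply(1:5, function(i) {
    B <- rnorm(3, sd = 0.3)
    poisson_log_posterior(B, X, y, flat) -
      sum(dpois(y, exp(drop(X %*% B)), log = TRUE))
  }, numeric(1))
  expect_lt(diff(range(diffs)), 1e-8)
  # B = 0 under a flat prior: alpha and quadratic terms vanish, exp term is -n
  expect_equal(poisson_log_posterior(rep(0, 3), X, y, flat), -nrow(X))
  # informative prior adds exactly the quadratic penalty (+ alpha shift)
  pr <- poisson_prior(0.5, 2, q = 3)
  B <- rnorm(3)
  expect_equal(poisson_log_posterior(B, X, y, pr) -
                 poisson_log_posterior(B, X, y, flat),
               sum(0.5 * 2 * B) - sum(2 * B^2) / 2, tolerance = 1e-10)
  # overflow returns -Inf, never NaN
  expect_identical(poisson_log_posterior(c(800, 0, 0), X, y, flat), -Inf)
})

test_that("posterior normalizes under quadrature for an intercept model", {
  X <- matrix(1, 2, 1)
  y <- c(2, 3)
  grid <- seq(-5, 5, length.out = 4001)
  lp <- vapply(grid, function(b) poisson_log_posterior(b, X, y,
                                                       poisson_prior(0, 0, 1)),
               numeric(1))
  dens <- exp(lp)
  Z <- sum(dens) * diff(grid[1:2])
  expect_lt(abs(sum(dens / Z) * diff(grid[1:2]) - 1), 1e-6)
})

test_that("zero proposal scale freezes the chain at the MLE start", {
  set.seed(13)
  X <- cbind(1, rnorm(100))
  y <- rpois(100, exp(1 + 0.5 * X[, 2]))
  fit <- fit_poisson_mcmc(X, y, poisson_prior(q = 2), n_iter = 500,
                          burn_in = 100, thin = 5, seed = 1,
                          proposal_scale = 0, adapt = FALSE)
  mle <- suppressWarnings(glm.fit(X, y, family = poisson()))$coefficients
  expect_true(all(abs(sweep(fit$draws, 2, mle)) < 1e-12))
})

test_that("Metropolis posterior agrees with the quadrature oracle", {
  set.seed(14)
  n <- 200
  y <- rpois(n, 4)
  X <- matrix(1, n, 1)
  fit <- fit_poisson_mcmc(X, y, poisson_prior(0.5, 0, 1), n_iter = 30000,
                          burn_in = 2000, thin = 5, seed = 2)
  qa <- quadrature_poisson_posterior(X, y)
  diag <- ergodic_diagnostics(fit$draws, n_batches = 40)
  expect_lt(abs(mean(fit$draws) - qa$mean), 2 * diag$se + 1e-4)
  expect_lt(abs(sd(fit$draws) - qa$sd), 0.2 * qa$sd)
  # posterior mean of exp(beta0) near the observed mean rate
  expect_lt(abs(mean(exp(fit$draws)) - mean(y)), 3 * sd(exp(fit$draws)))
})

test_that("flat-prior posterior mean sits near the GLM estimate", {
  set.seed(15)
  n <- 600
  X <- cbind(1, runif(n), runif(n))
  B_true <- c(1, 0.8, -0.5)
  y <- simulate_counts(X, B_true, seed = 3)
  fit <- fit_poisson_mcmc(X, y, poisson_prior(q = 3), n_iter = 20000,
                          burn_in = 2000, thin = 5, seed = 4)
  mle <- suppressWarnings(glm.fit(X, y, family = poisson()))$coefficients
  post_mean <- colMeans(fit$draws)
  post_sd <- apply(fit$draws, 2, sd)
  expect_true(all(abs(post_mean - mle) < 2 * post_sd))
  expect_gt(fit$acceptance_rate, 0.05)
  expect_lt(fit$acceptance_rate, 0.6)
  # seed determinism
  fit2 <- fit_poisson_mcmc(X, y, poisson_prior(q = 3), n_iter = 20000,
                           burn_in = 2000, thin = 5, seed = 4)
  expect_identical(fit$draws, fit2$draws)
})

test_that("flat-prior log posterior is concave", {
  set.seed(16)
  X <- cbind(1, matrix(rnorm(60), 30, 2))
  y <- rpois(30, 2)
  flat <- poisson_prior(0, 0, 3)
  for (i in 1:20) {
    B1 <- rnorm(3); B2 <- rnorm(3)
    f_mid <- poisson_log_posterior((B1 + B2) / 2, X, y, flat)
    expect_gte(f_mid, min(poisson_log_posterior(B1, X, y, flat),
                          poisson_log_posterior(B2, X, y, flat)) - 1e-10)
  }
})

test_that("chain histogram matches the quadrature density (detailed balance)", {
  set.seed(17)
  y <- rpois(50, 3)
  X <- matrix(1, 50, 1)
  fit <- fit_poisson_mcmc(X, y, poisson_prior(0, 0, 1), n_iter = 101000,
                          burn_in = 1000, thin = 1, seed = 5)
  qa <- quadrature_poisson_posterior(X, y, half_width = 8, n_grid = 2001)
  cdf <- cumsum(qa$weights)
  ks <- max(abs(ecdf(fit$draws)(qa$grid) - cdf))
  expect_lt(ks, 0.03)
})

test_that("posterior-predictive counts respect the Poisson mean surface", {
  # posterior collapsed at B = 0: lambda = 1, 95% interval within {0..4}
  fake <- structure(list(draws = matrix(0, 200, 2)), class = "poisson_fit")
  X_new <- matrix(rnorm(20), 10, 2)
  pr <- predict_counts(fake, X_new, seed = 6)
  expect_true(all(pr$lambda_draws == 1))
  expect_true(all(pr$upper <= 4) && all(pr$lower == 0))
  # law of total expectation: mean of count draws tracks mean of lambda
  set.seed(18)
  fake2 <- structure(list(draws = matrix(rnorm(2000 * 2, sd = 0.2), 2000)),
                     class = "poisson_fit")
  pr2 <- predict_counts(fake2, X_new, seed = 7)
  lam_mean <- colMeans(pr2$lambda_draws)
  cnt_mean <- colMeans(pr2$count_draws)
  expect_true(all(abs(cnt_mean - lam_mean) <
                    3 * sqrt(lam_mean / nrow(fake2$draws)) + 0.05))
  expect_error(predict_counts(fake, matrix(0, 2, 5)), "basis mismatch")
})

test_that("held-out counts fall inside 95% predictive intervals", {
  set.seed(19)
  n <- 600; n_test <- 200
  X <- cbind(1, runif(n + n_test), runif(n + n_test))
  B_true <- c(1.2, 0.7, -0.6)
  y <- simulate_counts(X, B_true, seed = 8)
  fit <- fit_poisson_mcmc(X[1:n, ], y[1:n], poisson_prior(q = 3),
                          n_iter = 20000, burn_in = 2000, thin = 10,
                          seed = 9)
  pr <- predict_counts(fit, X[n + 1:n_test, ], seed = 10)
  covered <- mean(y[n + 1:n_test] >= pr$lower & y[n + 1:n_test] <= pr$upper)
  expect_gte(covered, 0.90)
})

test_that("batch-mean diagnostics summarize the chain correctly", {
  const <- rep(2.5, 500)
  d <- ergodic_diagnostics(const, n_batches = 10)
  expect_true(all(d$running_mean == 2.5))
  expect_equal(unname(d$se), 0)
  set.seed(20)
  z <- rnorm(1e4)
  dz <- ergodic_diagnostics(z, n_batches = 100)
  expect_gt(dz$se, 0.005)
  expect_lt(dz$se, 0.02)
  expect_equal(dz$running_mean[length(z), 1], mean(z))
  expect_error(ergodic_diagnostics(rnorm(10), n_batches = 10), "too short")
})
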