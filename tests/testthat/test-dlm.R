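test_that("Kalman filter matches dense joint-Gaussian conditioning", {
  for (s in 1:8) {
    dims <- list(c(2, 2, 3), c(3, 2, 4), c(1, 1, 4), c(4, 3, 2))[[
      (s - 1) %% 4 + 1]]
    inst <- random_dlm_instance(dims[1], dims[2], dims[3], seed = 100 + s)
    kf <- kalman_filter(inst$spec, inst$params, inst$Y)
    or <- dense_gaussian_oracle(inst$spec, inst$params, inst$Y)
    for (t in seq_len(ncol(inst$Y))) {
      expect_lt(max(abs(kf$m[[t]] - or$steps[[t]]$filt$mean)), 1e-8)
      expect_lt(max(abs(kf$C[[t]] - or$steps[[t]]$filt$cov)), 1e-8)
      expect_lt(max(abs(kf$f[[t]] - or$steps[[t]]$pred$mean)), 1e-8)
      expect_lt(max(abs(kf$Q[[t]] - or$steps[[t]]$pred$cov)), 1e-8)
      # filtering never inflates uncertainty: C_t <= R_t
      ev <- eigen(kf$R[[t]] - kf$C[[t]], symmetric = TRUE,
                  only.values = TRUE)$values
      expect_gte(min(ev), -1e-10)
    }
  }
})

test_that("predictive log-density equals the sum of per-step Gaussian terms", {
  inst <- random_dlm_instance(3, 2, 5, seed = 200)
  kf <- kalman_filter(inst$spec, inst$params, inst$Y)
  ll <- 0
  for (t in 1:5) {
    e <- inst$Y[, t] - kf$f[[t]]
    Q <- kf$Q[[t]]
    ll <- ll - 0.5 * (3 * log(2 * pi) +
                        as.numeric(determinant(Q)$modulus) +
                        drop(t(e) %*% solve(Q, e)))
  }
  expect_equal(kf$log_likelihood, ll, tolerance = 1e-10)
})

test_that("static-model limit reproduces Bayesian linear regression", {
  # G = I, W = 0: the DLM is a static regression; the filtered posterior
  # after T steps equals the conjugate posterior on the stacked data
  set.seed(201)
  m <- 4; p <- 2; T_len <- 6
  F_mat <- matrix(runif(m * p), m, p)
  sigma2 <- 0.3
  spec <- dlm_spec(F_mat, m0 = rep(0, p), C0 = diag(p))
  beta_true <- c(1, -0.5)
  Y <- sapply(1:T_len, function(t) F_mat %*% beta_true +
                rnorm(m, 0, sqrt(sigma2)))
  params <- list(psi = rep(1, p), phi_y = rep(1 / sigma2, m),
                 phi_beta = rep(1e12, p))   # W ~ 0
  kf <- kalman_filter(spec, params, Y)
  X_stack <- do.call(rbind, replicate(T_len, F_mat, simplify = FALSE))
  y_stack <- as.numeric(Y)
  post_prec <- diag(p) + crossprod(X_stack) / sigma2
  post_mean <- solve(post_prec, crossprod(X_stack, y_stack) / sigma2)
  expect_equal(kf$m[[T_len]], drop(post_mean), tolerance = 1e-4)
  expect_equal(kf$C[[T_len]], solve(post_prec), tolerance = 1e-4)
})

test_that("uninformative observations leave the prior untouched", {
  inst <- random_dlm_instance(3, 2, 4, seed = 202)
  params <- inst$params
  params$phi_y <- rep(1e-12, 3)          # V ~ 1e12
  kf <- kalman_filter(inst$spec, params, inst$Y)
  for (t in 1:4) {
    expect_equal(kf$m[[t]], kf$a[[t]], tolerance = 1e-4)
    expect_equal(kf$C[[t]], kf$R[[t]], tolerance = 1e-4)
  }
})

test_that("FFBS freezes the state path when the evolution is degenerate", {
  set.seed(203)
  m <- 3; p <- 2
  F_mat <- matrix(runif(m * p), m, p)
  spec <- dlm_spec(F_mat)
  Y <- matrix(rnorm(m * 5), m, 5)
  params <- list(psi = rep(1, p), phi_y = rep(2, m),
                 phi_beta = rep(1e14, p))
  beta <- ffbs_sample_states(spec, params, Y, seed = 1)
  expect_lt(max(apply(beta, 1, function(r) diff(range(r)))), 1e-5)
})

test_that("FFBS draws have the smoother's moments", {
  inst <- random_dlm_instance(3, 2, 10, seed = 204)
  or <- dense_gaussian_oracle(inst$spec, inst$params, inst$Y)
  kf <- kalman_filter(inst$spec, inst$params, inst$Y)
  n_draw <- 5000
  set.seed(205)
  draws <- array(0, c(n_draw, 2, 11))
  for (s in seq_len(n_draw)) {
    draws[s, , ] <- ffbs_sample_states(inst$spec, inst$params, inst$Y,
                                       filter = kf)
  }
  for (t in 0:10) {
    sm <- or$smooth[[t + 1]]
    mc_mean <- apply(draws[, , t + 1], 2, mean)
    mc_se <- apply(draws[, , t + 1], 2, sd) / sqrt(n_draw)
    expect_true(all(abs(mc_mean - sm$mean) < 3 * mc_se + 1e-8))
  }
  # terminal draws follow the exact filtered law N(m_T, C_T)
  emp_cov <- cov(draws[, , 11])
  expect_lt(max(abs(emp_cov - kf$C[[10]])) / max(abs(kf$C[[10]])), 0.1)
})

test_that("evolution-diagonal update has its conjugate normal conditional", {
  # dogmatic prior returns psi0 exactly
  beta <- matrix(rnorm(40), 2, 20)
  expect_equal(gibbs_update_G(beta, c(1, 1), psi0 = 0.3, tau0 = 0),
               c(0.3, 0.3))
  # simulated AR(1) states: posterior mean recovers psi
  set.seed(206)
  T_len <- 500
  b <- matrix(0, 1, T_len + 1)
  for (t in seq_len(T_len)) b[1, t + 1] <- 0.9 * b[1, t] + rnorm(1, 0, 0.5)
  phi_b <- 1 / 0.25
  draws <- replicate(400, gibbs_update_G(b, phi_b, 0, 1))
  expect_lt(abs(mean(draws) - 0.9), 0.05)
  # flat-ish prior: conditional mean equals the least-squares AR coefficient
  ls <- sum(b[1, -1] * b[1, -(T_len + 1)]) / sum(b[1, -(T_len + 1)]^2)
  many <- replicate(4000, gibbs_update_G(b, phi_b, 0, 1e6))
  se <- sd(many) / sqrt(4000)
  expect_lt(abs(mean(many) - ls), 3 * se + 1e-6)
})

test_that("precision updates follow their gamma full conditionals", {
  set.seed(207)
  m <- 3; p <- 2; T_len <- 8
  F_mat <- matrix(runif(m * p), m, p)
  spec <- dlm_spec(F_mat)
  # zero residuals: draw from Gamma(alpha + T/2, b); check the mean by MC
  beta <- matrix(rnorm(p * (T_len + 1)), p)
  Y_exact <- F_mat %*% beta[, -1]
  draws <- replicate(4000, gibbs_update_variances(spec, Y_exact, beta,
                                                  psi = rep(0, p))$phi_y[1])
  expect_lt(abs(mean(draws) - (3 + T_len / 2) / 0.01),
            3 * sd(draws) / sqrt(4000))
  # huge residuals: posterior mean precision collapses towards (a+T/2)/(SS/2)
  Y_noisy <- Y_exact + 100
  ph <- replicate(200, gibbs_update_variances(spec, Y_noisy, beta,
                                              rep(0, p))$phi_y[1])
  expect_lt(mean(ph), 1e-2)
})

test_that("observation precision is recovered from simulated panels", {
  set.seed(208)
  errs <- vapply(1:50, function(r) {
    T_len <- 200
    F_mat <- matrix(runif(2), 1, 2)
    beta <- matrix(rnorm(2 * (T_len + 1), sd = 1), 2)
    Y <- F_mat %*% beta[, -1] + rnorm(T_len, 0, sqrt(1 / 100))
    spec <- dlm_spec(F_mat)
    mean(replicate(40, gibbs_update_variances(spec, Y, beta,
                                              rep(0, 2))$phi_y[1]))
  }, numeric(1))
  expect_lt(abs(mean(errs) - 100) / 100, 0.2)
})

test_that("Gibbs chains mix and agree across seeds on synthetic panels", {
  set.seed(209)
  m <- 12; p <- 3; T_len <- 20
  F_mat <- matrix(runif(m * p), m, p)
  psi_true <- c(0.9, 0.7, 0.5)
  sim <- simulate_volumes(F_mat, psi_true, V = 1 / 100, W = 1 / 4, T_len,
                          m0 = 0, C0 = 1, seed = 210)
  spec <- dlm_spec(F_mat)
  f1 <- gibbs_sample(spec, sim$Y, n_iter = 1500, burn_in = 300, thin = 2,
                     seed = 1)
  f2 <- gibbs_sample(spec, sim$Y, n_iter = 1500, burn_in = 300, thin = 2,
                     seed = 2)
  # split-chain potential scale reduction on each psi_j
  for (j in seq_len(p)) {
    ch <- cbind(f1$psi[, j], f2$psi[, j])
    W <- mean(apply(ch, 2, var))
    B <- nrow(ch) * var(colMeans(ch))
    rhat <- sqrt((1 - 1 / nrow(ch)) + B / (W * nrow(ch)))
    expect_lt(rhat, 1.05)
  }
  # determinism under identical seeds
  f1b <- gibbs_sample(spec, sim$Y, n_iter = 1500, burn_in = 300, thin = 2,
                      seed = 1)
  expect_identical(f1$psi, f1b$psi)
})

test_that("single-step panel reduces to the conjugate one-step posterior", {
  set.seed(211)
  m <- 4; p <- 2
  F_mat <- matrix(runif(m * p), m, p)
  spec <- dlm_spec(F_mat, m0 = c(0.5, -0.5), C0 = diag(2, p))
  params <- list(psi = c(0.8, 0.6), phi_y = rep(4, m), phi_beta = c(2, 3))
  Y1 <- matrix(rnorm(m), m, 1)
  kf <- kalman_filter(spec, params, Y1)
  # closed-form conditioning of beta_1 ~ N(G m0, G C0 G' + W) on Y_1
  a1 <- params$psi * spec$m0
  R1 <- diag(params$psi) %*% spec$C0 %*% diag(params$psi) +
    diag(1 / params$phi_beta)
  Q1 <- F_mat %*% R1 %*% t(F_mat) + diag(1 / params$phi_y, m)
  K1 <- R1 %*% t(F_mat) %*% solve(Q1)
  expect_equal(kf$m[[1]], drop(a1 + K1 %*% (Y1 - F_mat %*% a1)),
               tolerance = 1e-10)
  expect_equal(kf$C[[1]], R1 - K1 %*% F_mat %*% R1, tolerance = 1e-10)
})

test_that("volume predictions are consistent in-sample and track the noe input", {
  set.seed(212)
  m <- 10; p <- 3; T_len <- 12
  F_mat <- matrix(runif(m * p), m, p)
  colnames(F_mat) <- c("a", "b", "noe")
  beta_true <- matrix(rep(c(0.5, -0.3, 1.5), T_len + 1), p)
  sim <- simulate_volumes(F_mat, 1, V = 0.01, W = 0, T_len,
                          m0 = beta_true[, 1], C0 = 0, seed = 213)
  spec <- dlm_spec(F_mat)
  fit <- gibbs_sample(spec, sim$Y, n_iter = 1200, burn_in = 200, thin = 2,
                      seed = 3)
  # in-sample: predictive mean for a training row stays inside its band
  pred <- predict_volumes(fit, F_mat[1, , drop = FALSE], seed = 4)
  expect_true(all(sim$Y[1, ] >= pred$lower[1, ] - 0.5 &
                    sim$Y[1, ] <= pred$upper[1, ] + 0.5))
  expect_true(mean(sim$Y[1, ] >= pred$lower[1, ] &
                     sim$Y[1, ] <= pred$upper[1, ]) >= 0.8)
  # noe effect: raising the noe input moves predictions with the positive
  # generative coefficient
  F_lo <- F_hi <- F_mat[1, , drop = FALSE]
  F_lo[, "noe"] <- 0; F_hi[, "noe"] <- 1
  p_lo <- predict_volumes(fit, F_lo, seed = 5)
  p_hi <- predict_volumes(fit, F_hi, seed = 5)
  expect_gt(mean(p_hi$mean - p_lo$mean), 0)
  # un-normalized inputs trigger a warning
  expect_warning(predict_volumes(fit, F_mat[1, , drop = FALSE] * 30,
                                 seed = 6), "un-normalized")
})

test_that("spec and parameter validation reject degenerate inputs", {
  F_mat <- matrix(runif(6), 3, 2)
  expect_error(dlm_spec(F_mat, b_y = -1), "gamma hyperparameters")
  spec <- dlm_spec(F_mat)
  expect_error(kalman_filter(spec, list(psi = c(1, 1), phi_y = rep(1, 3),
                                        phi_beta = c(1, 1)),
                             matrix(NA_real_, 3, 2)), "finite")
  expect_error(gibbs_sample(spec, matrix(rnorm(6), 3, 2), n_iter = 10,
                            burn_in = 20), "exceed")
})
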