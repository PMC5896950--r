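# Bayesian dynamic linear model for the panel of log detached-cluster
# volumes: Y_t = F beta_t + v_t, beta_t = G beta_{t-1} + w_t, with diagonal
# time-invariant G = diag(psi), V = diag(1/phi_y), W = diag(1/phi_beta).
# Kalman filtering, forward-filtering backward-sampling, and conjugate Gibbs
# updates for psi and the precisions.

#' Dynamic linear model specification
#'
#' Fixes the regression matrix, initial-state prior and the hyperparameters
#' of the parameter priors: `psi_j ~ N(psi0, tau0)` for the diagonal of the
#' evolution matrix G, and shape-rate gamma priors `phi_y,i ~ Ga(alpha_y,
#' b_y)`, `phi_beta,j ~ Ga(alpha_beta, b_beta)` on the observation and
#' evolution precisions.
#'
#' @param F_mat m x p regression matrix (rows = training runs; columns =
#'   the min-max-normalized inputs, e.g. the seven simulator parameters
#'   plus the shear-event count).
#' @param m0,C0 Prior mean and covariance of the initial state `beta_0`
#'   (scalars and vectors are expanded to length/diagonal p).
#' @param psi0,tau0 Normal prior mean and variance for each `psi_j`.
#' @param alpha_y,b_y Gamma shape and rate for each observation precision.
#' @param alpha_beta,b_beta Gamma shape and rate for each evolution
#'   precision.
#' @return List of class `dlm_spec`.
#' @export
dlm_spec <- function(F_mat, m0 = 0, C0 = 1, psi0 = 0, tau0 = 1,
                     alpha_y = 3, b_y = 0.01, alpha_beta = 3, b_beta = 1) {
  F_mat <- as.matrix(F_mat)
  p <- ncol(F_mat)
  m0 <- rep_len(m0, p)
  C0 <- if (is.matrix(C0)) C0 else diag(rep_len(C0, p), p)
  if (any(eigen(C0, symmetric = TRUE, only.values = TRUE)$values < 0)) {
    stop("'C0' must be positive semidefinite", call. = FALSE)
  }
  assert_positive(c(alpha_y, b_y, alpha_beta, b_beta), "gamma hyperparameters")
  if (tau0 < 0) stop("'tau0' must be non-negative", call. = FALSE)
  structure(list(F_mat = F_mat, m = nrow(F_mat), p = p, m0 = m0, C0 = C0,
                 psi0 = psi0, tau0 = tau0, alpha_y = alpha_y, b_y = b_y,
                 alpha_beta = alpha_beta, b_beta = b_beta),
            class = "dlm_spec")
}

#' @keywords internal
dlm_params <- function(psi, phi_y, phi_beta, spec) {
  list(psi = rep_len(psi, spec$p), phi_y = rep_len(phi_y, spec$m),
       phi_beta = rep_len(phi_beta, spec$p))
}

#' Kalman filter for the detached-volume panel
#'
#' Standard recursions for `Y_t = F beta_t + v_t`, `beta_t = G beta_{t-1} +
#' w_t`: prior `a_t = G m_{t-1}`, `R_t = G C_{t-1} G' + W`; one-step
#' predictive `f_t = F a_t`, `Q_t = F R_t F' + V`; filtered `m_t = a_t +
#' K_t (Y_t - f_t)`, `C_t = R_t - K_t F R_t` with gain `K_t = R_t F'
#' Q_t^{-1}`.  Also accumulates the one-step-ahead predictive log density
#' `sum_t log N(Y_t; f_t, Q_t)`.
#'
#' @param spec A [dlm_spec()].
#' @param params List with `psi` (length p), `phi_y` (length m), `phi_beta`
#'   (length p): G = diag(psi), V = diag(1/phi_y), W = diag(1/phi_beta).
#' @param Y m x T observation panel (log volumes).
#' @return List of class `kalman_result` with per-step lists `a`, `R`, `f`,
#'   `Q`, `m`, `C` and scalar `log_likelihood`.
#' @export
kalman_filter <- function(spec, params, Y) {
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == spec$m)
  if (any(!is.finite(Y))) stop("'Y' must be finite", call. = FALSE)
  params <- dlm_params(params$psi, params$phi_y, params$phi_beta, spec)
  Fm <- spec$F_mat
  g <- params$psi
  V <- diag(1 / params$phi_y, spec$m)
  W <- diag(1 / params$phi_beta, spec$p)
  T_len <- ncol(Y)
  a <- R <- f <- Q <- m <- C <- vector("list", T_len)
  m_prev <- spec$m0
  C_prev <- spec$C0
  ll <- 0
  for (t in seq_len(T_len)) {
    a[[t]] <- g * m_prev
    Rt <- t(g * t(g * C_prev)) + W
    R[[t]] <- (Rt + t(Rt)) / 2
    f[[t]] <- drop(Fm %*% a[[t]])
    Qt <- Fm %*% R[[t]] %*% t(Fm) + V
    Qt <- (Qt + t(Qt)) / 2
    ch <- tryCatch(chol(Qt), error = function(e) NULL)
    if (is.null(ch)) {
      stop(sprintf(
        "singular one-step predictive covariance at t = %d (rcond ~ %.2e); ",
        t, rcond(Qt)), "check for zero observation variance with ",
        "collinear F rows", call. = FALSE)
    }
    e_t <- Y[, t] - f[[t]]
    # K_t = R F' Q^{-1} via the Cholesky factor of Q
    RFt <- R[[t]] %*% t(Fm)
    Kt <- t(backsolve(ch, forwardsolve(t(ch), t(RFt))))
    m[[t]] <- a[[t]] + drop(Kt %*% e_t)
    Ct <- R[[t]] - Kt %*% Fm %*% R[[t]]
    C[[t]] <- (Ct + t(Ct)) / 2
    z <- forwardsolve(t(ch), e_t)
    ll <- ll - 0.5 * (spec$m * log(2 * pi) + 2 * sum(log(diag(ch))) +
                        sum(z^2))
    Q[[t]] <- Qt
    m_prev <- m[[t]]
    C_prev <- C[[t]]
  }
  structure(list(a = a, R = R, f = f, Q = Q, m = m, C = C,
                 log_likelihood = ll, params = params),
            class = "kalman_result")
}

#' Forward-filtering backward-sampling draw of the state trajectory
#'
#' Samples `beta_{0:T}` from its joint posterior given the panel and the
#' current parameters: `beta_T ~ N(m_T, C_T)`, then backwards
#' `beta_t | beta_{t+1} ~ N(m_t + J_t (beta_{t+1} - a_{t+1}), C_t - J_t
#' R_{t+1} J_t')` with `J_t = C_t G' R_{t+1}^{-1}`.  The initial state
#' `beta_0` is sampled from its smoothing conditional under the prior
#' `N(m0, C0)`.
#'
#' @param spec A [dlm_spec()].
#' @param params Parameter list as in [kalman_filter()].
#' @param Y m x T panel.
#' @param seed Integer seed, or `NULL` to use the current RNG state (as
#'   inside a Gibbs sweep).
#' @param filter Optional precomputed [kalman_filter()] result.
#' @return p x (T+1) matrix of sampled states; column 1 is `beta_0`.
#' @export
ffbs_sample_states <- function(spec, params, Y, seed = NULL, filter = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(filter)) filter <- kalman_filter(spec, params, Y)
  params <- filter$params
  g <- params$psi
  T_len <- length(filter$m)
  p <- spec$p
  beta <- matrix(0, p, T_len + 1L)
  beta[, T_len + 1L] <- rmvnorm_one(filter$m[[T_len]], filter$C[[T_len]])
  for (t in rev(seq_len(T_len))) {
    m_t <- if (t > 1L) filter$m[[t - 1L]] else spec$m0
    C_t <- if (t > 1L) filter$C[[t - 1L]] else spec$C0
    R_next <- filter$R[[t]]
    a_next <- filter$a[[t]]
    # J = C G' R^{-1}; R is PSD-projected, may still be singular (W = 0)
    CG <- t(g * t(C_t))                       # C_t %*% diag(g)
    Rinv_CG <- tryCatch(solve(R_next, t(CG)),
                        error = function(e) {
                          MASS_ginv(R_next) %*% t(CG)
                        })
    J <- t(Rinv_CG)
    mean_t <- m_t + drop(J %*% (beta[, t + 1L] - a_next))
    cov_t <- C_t - J %*% R_next %*% t(J)   # symmetrized/clipped in sampler
    beta[, t] <- rmvnorm_one(mean_t, cov_t)
  }
  beta
}

# Moore-Penrose pseudoinverse via eigendecomposition (symmetric PSD input);
# used only when an evolution covariance is exactly singular.
#' @keywords internal
MASS_ginv <- function(S, tol = 1e-12) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  if (!any(keep)) return(matrix(0, nrow(S), ncol(S)))
  e$vectors[, keep, drop = FALSE] %*%
    ((1 / e$values[keep]) * t(e$vectors[, keep, drop = FALSE]))
}

#' Gibbs update of the evolution-matrix diagonal
#'
#' Each `psi_j` has a normal full conditional combining the `N(psi0, tau0)`
#' prior with the AR(1) likelihood of its state track: precision
#' `1/tau0 + phi_beta_j sum_t beta_{j,t-1}^2`, mean `(psi0/tau0 +
#' phi_beta_j sum_t beta_{j,t-1} beta_{j,t}) / precision`.
#'
#' @param beta p x (T+1) state path (column 1 = initial state).
#' @param phi_beta Evolution precisions (length p).
#' @param psi0,tau0 Prior mean and variance; `tau0 = 0` returns `psi0`
#'   exactly (dogmatic prior).
#' @return Vector of p sampled `psi_j`.
#' @export
gibbs_update_G <- function(beta, phi_beta, psi0 = 0, tau0 = 1) {
  p <- nrow(beta)
  T1 <- ncol(beta)
  phi_beta <- rep_len(phi_beta, p)
  if (tau0 == 0) return(rep(psi0, p))
  prev <- beta[, -T1, drop = FALSE]
  cur <- beta[, -1L, drop = FALSE]
  prec <- 1 / tau0 + phi_beta * rowSums(prev^2)
  mean <- (psi0 / tau0 + phi_beta * rowSums(prev * cur)) / prec
  stats::rnorm(p, mean, sqrt(1 / prec))
}

#' Gibbs update of the observation and evolution precisions
#'
#' Conjugate shape-rate gamma full conditionals:
#' `phi_y,i ~ Ga(alpha_y + T/2, b_y + SSE_i / 2)` with per-run residuals
#' `Y_{i,t} - F_i beta_t`, and `phi_beta,j ~ Ga(alpha_beta + T/2,
#' b_beta + SSW_j / 2)` with evolution residuals
#' `beta_{j,t} - psi_j beta_{j,t-1}`.
#'
#' @param spec A [dlm_spec()].
#' @param Y m x T panel.
#' @param beta p x (T+1) state path.
#' @param psi Current evolution diagonal.
#' @return List with `phi_y` (length m) and `phi_beta` (length p).
#' @export
gibbs_update_variances <- function(spec, Y, beta, psi) {
  T_len <- ncol(Y)
  fitted <- spec$F_mat %*% beta[, -1L, drop = FALSE]   # m x T
  sse <- rowSums((Y - fitted)^2)
  stopifnot(all(sse >= 0))
  phi_y <- stats::rgamma(spec$m, spec$alpha_y + T_len / 2,
                         rate = spec$b_y + sse / 2)
  prev <- beta[, -ncol(beta), drop = FALSE]
  cur <- beta[, -1L, drop = FALSE]
  ssw <- rowSums((cur - rep_len(psi, spec$p) * prev)^2)
  phi_beta <- stats::rgamma(spec$p, spec$alpha_beta + T_len / 2,
                            rate = spec$b_beta + ssw / 2)
  list(phi_y = phi_y, phi_beta = phi_beta)
}

#' Gibbs sampler for the dynamic linear model
#'
#' Systematic scan: a full FFBS draw of the state trajectory given the
#' parameters, then the normal update of the evolution diagonal `psi` and
#' the gamma updates of the observation and evolution precisions given the
#' states.
#'
#' @param spec A [dlm_spec()].
#' @param Y m x T panel of log detached volumes.
#' @param n_iter,burn_in,thin Chain settings; `(n_iter - burn_in) / thin`
#'   draws are retained.
#' @param seed Integer seed.
#' @param init Optional list with starting `psi`, `phi_y`, `phi_beta`.
#' @return Object of class `dlm_fit` with `psi` (S x p), `phi_y` (S x m),
#'   `phi_beta` (S x p), `beta` (S x p x (T+1)) and `settings`.
#' @export
gibbs_sample <- function(spec, Y, n_iter = 20000, burn_in = 1000,
                         thin = 10, seed = 1L, init = NULL) {
  Y <- as.matrix(Y)
  if (n_iter <= burn_in) stop("'n_iter' must exceed 'burn_in'", call. = FALSE)
  T_len <- ncol(Y)
  set.seed(seed)
  psi <- init$psi %||% rep(0.5, spec$p)
  phi_y <- init$phi_y %||% rep(spec$alpha_y / spec$b_y, spec$m)
  phi_beta <- init$phi_beta %||% rep(spec$alpha_beta / spec$b_beta, spec$p)
  S <- (n_iter - burn_in) %/% thin
  out_psi <- matrix(NA_real_, S, spec$p)
  out_phiy <- matrix(NA_real_, S, spec$m)
  out_phib <- matrix(NA_real_, S, spec$p)
  out_beta <- array(NA_real_, c(S, spec$p, T_len + 1L))
  kept <- 0L
  for (it in seq_len(n_iter)) {
    params <- list(psi = psi, phi_y = phi_y, phi_beta = phi_beta)
    beta <- ffbs_sample_states(spec, params, Y)
    psi <- gibbs_update_G(beta, phi_beta, spec$psi0, spec$tau0)
    upd <- gibbs_update_variances(spec, Y, beta, psi)
    phi_y <- upd$phi_y
    phi_beta <- upd$phi_beta
    if (any(c(phi_y, phi_beta) > 1e12)) {
      stop("divergent precision draw (> 1e12): the configuration is not ",
           "identifiable for this panel", call. = FALSE)
    }
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      out_psi[kept, ] <- psi
      out_phiy[kept, ] <- phi_y
      out_phib[kept, ] <- phi_beta
      out_beta[kept, , ] <- beta
    }
  }
  structure(list(psi = out_psi[seq_len(kept), , drop = FALSE],
                 phi_y = out_phiy[seq_len(kept), , drop = FALSE],
                 phi_beta = out_phib[seq_len(kept), , drop = FALSE],
                 beta = out_beta[seq_len(kept), , , drop = FALSE],
                 spec = spec,
                 settings = list(n_iter = n_iter, burn_in = burn_in,
                                 thin = thin, seed = seed)),
            class = "dlm_fit")
}

#' @export
print.dlm_fit <- function(x, ...) {
  cat("Bayesian dynamic linear model (Gibbs with FFBS)\n")
  cat(sprintf("  %d retained draws; p = %d states, m = %d runs, T = %d\n",
              nrow(x$psi), x$spec$p, x$spec$m, dim(x$beta)[3] - 1L))
  invisible(x)
}

#' Predictive log detached volume for new runs
#'
#' For each retained posterior draw, `Y*_t = F* beta_t + v*` with
#' `v* ~ N(0, 1/phi_bar)` where `phi_bar` is the harmonic mean of that
#' draw's training observation precisions (`new_unit = "harmonic"`), or a
#' fresh draw from the gamma prior (`new_unit = "prior"`).
#'
#' @param fit A [gibbs_sample()] result.
#' @param F_new n_new x p matrix of normalized test inputs (same columns
#'   and normalization as training; values far outside \[0, 1\] trigger a
#'   warning).
#' @param seed Integer seed.
#' @param new_unit Observation-variance policy for unseen runs.
#' @return List of class `dlm_predictive` with `mean`, `lower`, `upper`
#'   (n_new x T) and the draw array `Y_draws` (S x n_new x T).
#' @export
predict_volumes <- function(fit, F_new, seed = 1L,
                            new_unit = c("harmonic", "prior")) {
  new_unit <- match.arg(new_unit)
  F_new <- as.matrix(F_new)
  if (ncol(F_new) != fit$spec$p) stop("F_new column mismatch", call. = FALSE)
  if (any(F_new < -0.5 | F_new > 1.5)) {
    warning("F_new values outside [-0.5, 1.5]: inputs look un-normalized")
  }
  S <- nrow(fit$psi)
  T_len <- dim(fit$beta)[3] - 1L
  n_new <- nrow(F_new)
  set.seed(seed)
  Y_draws <- array(NA_real_, c(S, n_new, T_len))
  for (s in seq_len(S)) {
    sd_new <- if (new_unit == "harmonic") {
      sqrt(mean(1 / fit$phi_y[s, ]))
    } else {
      sqrt(1 / stats::rgamma(1, fit$spec$alpha_y, rate = fit$spec$b_y))
    }
    mu <- F_new %*% matrix(fit$beta[s, , -1L], nrow = fit$spec$p)  # n_new x T
    Y_draws[s, , ] <- mu + stats::rnorm(n_new * T_len, 0, sd_new)
  }
  mean_mat <- apply(Y_draws, c(2, 3), mean)
  lo <- apply(Y_draws, c(2, 3), stats::quantile, probs = 0.025)
  hi <- apply(Y_draws, c(2, 3), stats::quantile, probs = 0.975)
  structure(list(mean = mean_mat, lower = lo, upper = hi,
                 Y_draws = Y_draws),
            class = "dlm_predictive")
}
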