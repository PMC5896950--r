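# Bayesian Poisson log-linear emulator for the expected number of shear
# events: exact log-posterior, Metropolis random-walk sampler initialized at
# the maximum-likelihood estimate, posterior-predictive counts and batch-mean
# ergodic diagnostics.

#' Independent normal prior on the Poisson regression coefficients
#'
#' Each coefficient has prior `N(mean_i, 1 / precision_i)`; a precision of
#' zero gives a flat prior for that coefficient (its mean is then inert).
#'
#' @param mean Prior means (recycled to q).
#' @param precision Prior precisions, >= 0 (recycled to q).
#' @param q Number of coefficients.
#' @return List of class `poisson_prior`.
#' @export
poisson_prior <- function(mean = 0.5, precision = 0, q = 28L) {
  precision <- rep_len(precision, q)
  assert_non_negative(precision, "precision")
  structure(list(mean = rep_len(mean, q), precision = precision, q = q),
            class = "poisson_prior")
}

#' Poisson probability mass function
#'
#' `f(k; lambda) = lambda^k exp(-lambda) / k!`, evaluated in log space for
#' stability.  Thin wrapper with the domain checks of the count model.
#'
#' @param k Non-negative integer count(s).
#' @param lambda Positive Poisson mean.
#' @return Probability in (0, 1\].
#' @export
poisson_pmf <- function(k, lambda) {
  if (any(k < 0) || any(k != round(k))) {
    stop("'k' must be a non-negative integer", call. = FALSE)
  }
  if (any(lambda <= 0)) stop("'lambda' must be positive", call. = FALSE)
  stats::dpois(k, lambda)
}

#' Log posterior of the Poisson regression coefficients
#'
#' Up to an additive constant (the -sum log y! term),
#' `sum_i alpha_i beta_i - sum_i precision_i beta_i^2 / 2 - sum_k exp(x_k . B)`
#' with `alpha_i = m_i precision_i + sum_k x_ik y_k`: the product of the
#' Poisson likelihood and the independent normal prior.  Coefficients with
#' prior precision zero contribute no quadratic penalty.  An overflowing
#' exponential returns `-Inf` (the proposal is rejected), never `NaN`.
#'
#' @param B Coefficient vector.
#' @param X Basis matrix (n x q), e.g. from [build_quadratic_features()].
#' @param y Non-negative integer counts of length n.
#' @param prior A [poisson_prior()].
#' @param alpha Optional precomputed `alpha` vector (cached by the sampler).
#' @return Scalar log density (unnormalized).
#' @export
poisson_log_posterior <- function(B, X, y, prior = poisson_prior(q = ncol(X)),
                                  alpha = NULL) {
  if (length(B) != ncol(X)) stop("length(B) must equal ncol(X)",
                                 call. = FALSE)
  if (any(y < 0) || any(y != round(y))) {
    stop("'y' must be non-negative integer counts", call. = FALSE)
  }
  if (is.null(alpha)) alpha <- prior$mean * prior$precision + drop(crossprod(X, y))
  eta <- drop(X %*% B)
  if (any(eta > 700)) return(-Inf)
  sum(alpha * B) - sum(prior$precision * B^2) / 2 - sum(exp(eta))
}

# Maximum-likelihood start and Fisher information for the proposal.
#' @keywords internal
poisson_mle <- function(X, y) {
  if (all(y == 0)) {
    # all-zero counts: intercept floored, no curvature information beyond it
    B <- numeric(ncol(X))
    B[1] <- log(1e-8)
    return(list(coef = B, fisher = crossprod(X) * 1e-8))
  }
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson()))
  B <- fit$coefficients
  if (any(is.na(B))) {
    stop("collinear basis columns at the MLE stage; drop redundant inputs ",
         "or add prior precision", call. = FALSE)
  }
  w <- fit$fitted.values
  list(coef = B, fisher = crossprod(X * sqrt(w), X * sqrt(w)))
}

#' Metropolis sampler for the Poisson regression posterior
#'
#' Symmetric Gaussian random-walk Metropolis on the exact posterior of the
#' count model.  The chain starts at the maximum-likelihood estimate; the
#' proposal covariance is the inverse Fisher information at the MLE times a
#' global scale that is adapted towards a 23 percent acceptance rate during
#' burn-in only and frozen afterwards.
#'
#' @param X Basis matrix (n x q).
#' @param y Non-negative integer counts.
#' @param prior A [poisson_prior()]; default flat.
#' @param n_iter,burn_in,thin Chain length, discarded prefix and thinning
#'   interval; `(n_iter - burn_in) / thin` draws are retained.
#' @param seed Integer seed.
#' @param proposal_scale Initial global proposal scale (default
#'   `2.38 / sqrt(q)`); 0 freezes the chain at its start.
#' @param adapt Adapt the scale during burn-in.
#' @return Object of class `poisson_fit` with elements `draws` (S x q),
#'   `acceptance_rate`, `mle`, `alpha`, `settings` and the training basis
#'   attributes.
#' @export
fit_poisson_mcmc <- function(X, y, prior = poisson_prior(q = ncol(X)),
                             n_iter = 60000, burn_in = 1000, thin = 10,
                             seed = 1L, proposal_scale = NULL,
                             adapt = TRUE) {
  X <- as.matrix(X)
  if (n_iter <= burn_in) stop("'n_iter' must exceed 'burn_in'", call. = FALSE)
  if (thin < 1) stop("'thin' must be >= 1", call. = FALSE)
  q <- ncol(X)
  alpha <- prior$mean * prior$precision + drop(crossprod(X, y))
  mle <- poisson_mle(X, y)
  # proposal: scaled Cholesky factor of the inverse Fisher information
  prop_chol <- tryCatch(chol(solve(mle$fisher + prior$precision * diag(q))),
                        error = function(e) {
    stop("collinear basis columns at the MLE stage; drop redundant inputs ",
         "or add prior precision", call. = FALSE)
  })
  scale <- proposal_scale %||% (2.38 / sqrt(q))
  set.seed(seed)
  B <- mle$coef
  lp <- poisson_log_posterior(B, X, y, prior, alpha)
  S <- (n_iter - burn_in) %/% thin
  draws <- matrix(NA_real_, S, q, dimnames = list(NULL, colnames(X)))
  n_acc <- 0L; kept <- 0L
  acc_window <- 0; win <- 0L
  for (it in seq_len(n_iter)) {
    prop <- B + scale * drop(stats::rnorm(q) %*% prop_chol)
    lp_prop <- poisson_log_posterior(prop, X, y, prior, alpha)
    if (is.finite(lp_prop) &&
        log(stats::runif(1)) < lp_prop - lp) {
      B <- prop; lp <- lp_prop
      acc_window <- acc_window + 1
      if (it > burn_in) n_acc <- n_acc + 1L
    }
    win <- win + 1L
    if (adapt && it <= burn_in && scale > 0 && win == 50L) {
      # Robbins-Monro step towards 23% acceptance, burn-in only
      scale <- scale * exp((acc_window / win - 0.23) / sqrt(it / 50))
      acc_window <- 0; win <- 0L
    }
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- B
    }
  }
  structure(list(draws = draws[seq_len(kept), , drop = FALSE],
                 acceptance_rate = n_acc / (n_iter - burn_in),
                 mle = mle$coef, alpha = alpha, prior = prior,
                 proposal_scale = scale,
                 settings = list(n_iter = n_iter, burn_in = burn_in,
                                 thin = thin, seed = seed)),
            class = "poisson_fit")
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat("Bayesian Poisson regression (Metropolis)\n")
  cat(sprintf("  %d retained draws over %d coefficients; acceptance %.2f\n",
              nrow(x$draws), ncol(x$draws), x$acceptance_rate))
  invisible(x)
}

#' Posterior-predictive shear-event counts
#'
#' For each retained draw `B_s` and new point `k`, the mean surface
#' `lambda = exp(basis_k . B_s)` and one Poisson draw; central 95 percent
#' intervals are empirical 2.5/97.5 percentiles of the count draws.
#'
#' @param fit A [fit_poisson_mcmc()] result.
#' @param X_new Basis matrix of the new points (same columns as training).
#' @param seed Integer seed for the Poisson draws.
#' @return List of class `count_predictive` with `lambda_draws`,
#'   `count_draws` (both S x n_new), `mean`, `lower`, `median`, `upper`.
#' @export
predict_counts <- function(fit, X_new, seed = 1L) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != ncol(fit$draws)) {
    stop("basis mismatch: X_new has ", ncol(X_new), " columns, posterior has ",
         ncol(fit$draws), call. = FALSE)
  }
  lambda <- exp(fit$draws %*% t(X_new))           # S x n_new
  set.seed(seed)
  counts <- matrix(stats::rpois(length(lambda), lambda), nrow(lambda))
  qs <- apply(counts, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  structure(list(lambda_draws = lambda, count_draws = counts,
                 mean = colMeans(lambda), lower = qs[1, ],
                 median = qs[2, ], upper = qs[3, ]),
            class = "count_predictive")
}

#' Batch-mean ergodic diagnostics for an MCMC chain
#'
#' Running (cumulative) means per coefficient, plus the batch-means standard
#' error: the chain is split into consecutive batches and the Monte-Carlo
#' standard error of the overall mean is `sd(batch means) / sqrt(n_batches)`.
#'
#' @param draws Numeric vector or S x q matrix of retained draws.
#' @param n_batches Number of equal batches (>= 2).
#' @return List with `running_mean` (same shape as `draws`), `batch_means`,
#'   `se` (per coefficient) and `mean`.
#' @export
ergodic_diagnostics <- function(draws, n_batches = 50L) {
  draws <- as.matrix(draws)
  S <- nrow(draws)
  if (S < 2L * n_batches) {
    stop("chain too short: need at least 2 draws per batch", call. = FALSE)
  }
  width <- S %/% n_batches
  use <- seq_len(width * n_batches)
  g <- rep(seq_len(n_batches), each = width)
  running <- apply(draws, 2, function(v) cumsum(v) / seq_len(S))
  bm <- apply(draws[use, , drop = FALSE], 2,
              function(v) tapply(v, g, mean))
  se <- apply(as.matrix(bm), 2, stats::sd) / sqrt(n_batches)
  list(running_mean = running, batch_means = bm, se = se,
       mean = colMeans(draws))
}
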