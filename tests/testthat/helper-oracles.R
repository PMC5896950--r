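# Independent oracles used to check the package's own implementations.
# Each one is a direct, brute-force computation that shares no code with
# the path it verifies.

# Joint-Gaussian oracle for the linear state-space model: builds the exact
# joint distribution of (beta_0, ..., beta_T, Y_1, ..., Y_T) as a linear
# map of independent Gaussians and conditions it densely.  Returns, per t,
# the filtered mean/cov of beta_t given Y_{1:t} and the one-step predictive
# mean/cov of Y_t given Y_{1:(t-1)}.
dense_gaussian_oracle <- function(spec, params, Y) {
  p <- spec$p; m <- spec$m; T_len <- ncol(Y)
  g <- rep_len(params$psi, p)
  Wd <- rep_len(1 / params$phi_beta, p)
  Vd <- rep_len(1 / params$phi_y, m)
  nz <- p + T_len * p + T_len * m
  mean_z <- c(spec$m0, rep(0, T_len * (p + m)))
  cov_z <- diag(c(diag(as.matrix(spec$C0)), rep(Wd, T_len),
                  rep(Vd, T_len)), nz)
  cov_z[seq_len(p), seq_len(p)] <- as.matrix(spec$C0)
  # linear maps from z to each beta_t and Y_t
  L <- matrix(0, p, nz); L[, seq_len(p)] <- diag(p)
  maps_b <- vector("list", T_len + 1); maps_b[[1]] <- L
  maps_y <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    L <- g * L
    wcols <- p + (t - 1) * p + seq_len(p)
    L[cbind(seq_len(p), wcols)] <- L[cbind(seq_len(p), wcols)] + 1
    maps_b[[t + 1]] <- L
    My <- spec$F_mat %*% L
    vcols <- p + T_len * p + (t - 1) * m + seq_len(m)
    My[cbind(seq_len(m), vcols)] <- My[cbind(seq_len(m), vcols)] + 1
    maps_y[[t]] <- My
  }
  A <- do.call(rbind, c(maps_b, maps_y))
  mu <- drop(A %*% mean_z)
  Sig <- A %*% cov_z %*% t(A)
  b_idx <- function(t) t * p + seq_len(p)            # beta_t rows (t >= 0)
  y_idx <- function(t) (T_len + 1) * p + (t - 1) * m + seq_len(m)
  cond <- function(target, given, obs) {
    if (length(given) == 0) {
      return(list(mean = mu[target],
                  cov = Sig[target, target, drop = FALSE]))
    }
    S12 <- Sig[target, given, drop = FALSE]
    S22 <- Sig[given, given, drop = FALSE]
    K <- S12 %*% solve(S22)
    list(mean = mu[target] + drop(K %*% (obs - mu[given])),
         cov = Sig[target, target, drop = FALSE] -
           K %*% t(S12))
  }
  out <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    given_prev <- if (t > 1) unlist(lapply(seq_len(t - 1), y_idx)) else
      integer(0)
    obs_prev <- if (t > 1) as.numeric(Y[, seq_len(t - 1)]) else numeric(0)
    given_now <- unlist(lapply(seq_len(t), y_idx))
    obs_now <- as.numeric(Y[, seq_len(t)])
    out[[t]] <- list(
      pred = cond(y_idx(t), given_prev, obs_prev),
      filt = cond(b_idx(t), given_now, obs_now))
  }
  # smoothing means of every beta_t given all data (for FFBS moment checks)
  all_y <- unlist(lapply(seq_len(T_len), y_idx))
  smooth <- lapply(0:T_len, function(t) {
    cond(b_idx(t), all_y, as.numeric(Y))
  })
  list(steps = out, smooth = smooth)
}

# Grid-quadrature oracle for the Poisson-regression posterior with 1 or 2
# coefficients: independent likelihood evaluation via dpois.
quadrature_poisson_posterior <- function(X, y, prior_mean = 0,
                                         prior_prec = 0, half_width = 6,
                                         n_grid = 401) {
  X <- as.matrix(X)
  q <- ncol(X)
  prior_mean <- rep_len(prior_mean, q)
  prior_prec <- rep_len(prior_prec, q)
  loglik <- function(b) {
    lam <- exp(drop(X %*% b))
    sum(stats::dpois(y, lam, log = TRUE)) +
      sum(ifelse(prior_prec > 0,
                 stats::dnorm(b, prior_mean, 1 / sqrt(pmax(prior_prec,
                                                           1e-300)),
                              log = TRUE), 0))
  }
  mle <- suppressWarnings(stats::glm.fit(X, y,
                                         family = stats::poisson()))
  ctr <- mle$coefficients
  grids <- lapply(seq_len(q), function(j) {
    seq(ctr[j] - half_width, ctr[j] + half_width, length.out = n_grid)
  })
  if (q == 1L) {
    lp <- vapply(grids[[1]], function(b) loglik(b), numeric(1))
    w <- exp(lp - max(lp))
    w <- w / sum(w)
    mean <- sum(w * grids[[1]])
    sd <- sqrt(sum(w * (grids[[1]] - mean)^2))
    return(list(mean = mean, sd = sd, grid = grids[[1]], weights = w))
  }
  gg <- as.matrix(expand.grid(grids[[1]], grids[[2]]))
  lp <- apply(gg, 1, loglik)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  mean <- colSums(w * gg)
  sd <- sqrt(colSums(w * sweep(gg, 2, mean)^2))
  list(mean = mean, sd = sd)
}

# Brute-force biofilm height: explicit double loop over base columns.
brute_force_height <- function(snapshot, grid) {
  Nx <- grid$N[["x"]]; Ny <- grid$N[["y"]]
  dx <- grid$L[["x"]] / Nx; dy <- grid$L[["y"]] / Ny
  total <- 0
  for (ix in seq_len(Nx) - 1) {
    for (iy in seq_len(Ny) - 1) {
      inb <- snapshot$x_um >= ix * dx & (snapshot$x_um < (ix + 1) * dx |
              (ix == Nx - 1 & snapshot$x_um <= grid$L[["x"]])) &
             snapshot$y_um >= iy * dy & (snapshot$y_um < (iy + 1) * dy |
              (iy == Ny - 1 & snapshot$y_um <= grid$L[["y"]]))
      if (any(inb)) total <- total + max(snapshot$z_um[inb])
    }
  }
  total / (Nx * Ny)
}

# Alternative Sobol estimators (Sobol 1993 / Homma-Saltelli product form)
# on the same sample matrices; independent of the package estimators.
# f(B) . f(AB_i) shares only column i, so its covariance estimates V_i;
# f(A) . f(AB_i) shares every column except i, so it estimates Var - VT_i.
sobol_alt <- function(model, design) {
  fA <- as.numeric(model(design$A))
  fB <- as.numeric(model(design$B))
  f0sq <- mean(fA) * mean(fB)
  var_y <- stats::var(c(fA, fB))
  S <- ST <- numeric(length(design$AB))
  for (i in seq_along(design$AB)) {
    fABi <- as.numeric(model(design$AB[[i]]))
    S[i] <- (mean(fB * fABi) - f0sq) / var_y
    ST[i] <- 1 - (mean(fA * fABi) - f0sq) / var_y
  }
  list(S_first = S, S_total = ST)
}

# Random small DLM instance shared by filter/FFBS tests.
random_dlm_instance <- function(m, p, T_len, seed) {
  set.seed(seed)
  F_mat <- matrix(runif(m * p), m, p)
  spec <- dlm_spec(F_mat, m0 = rnorm(p), C0 = diag(runif(p, 0.5, 2), p))
  params <- list(psi = runif(p, -0.5, 1), phi_y = runif(m, 0.5, 5),
                 phi_beta = runif(p, 0.5, 5))
  sim <- simulate_volumes(F_mat, params$psi, 1 / params$phi_y,
                          1 / params$phi_beta, T_len,
                          m0 = spec$m0, C0 = spec$C0,
                          seed = seed + 1000L)
  list(spec = spec, params = params, Y = sim$Y, beta = sim$beta)
}
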