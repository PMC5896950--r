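# Synthetic stand-in for individual-based biofilm simulation output: designs,
# morphology time series, shear-event counts and detached-cluster volumes with
# exactly the statistical structure the two emulators assume.

#' Configuration of the synthetic detachment study
#'
#' Fixed coefficients of the closed-form covariate trajectory family, the
#' reference ranges used to normalize Poisson-model inputs, the true
#' quadratic Poisson coefficients, and the true dynamic-linear-model
#' parameters used to generate log detached volumes.  These defaults define
#' the study conditions; they are documented in the methods vignette.
#'
#' @param growth_s Duration of the initial no-flow growth phase (s).
#' @param shear_s Duration of the shear period (s).
#' @param slice_dt Recording interval (s).
#' @return Named list with components `trajectory`, `norm_ranges`,
#'   `poisson_B`, `dlm`, `growth_s`, `shear_s`, `slice_dt`.
#' @export
study_config <- function(growth_s = 40000, shear_s = 200000,
                         slice_dt = 2000) {
  # Quadratic-basis coefficient order: intercept; linear in (time, particles,
  # gamma, eps, height, mass); then squares/interactions (i,j), i <= j.
  B <- numeric(28)
  names(B) <- quadratic_basis_labels()
  B["(0,0)"] <- 1.6          # baseline log-rate per 2000 s slice
  B["(0,1)"] <- 2.0          # events rise with time ...
  B["(1,1)"] <- -2.2         # ... then decline (peak mid-window)
  B["(0,3)"] <- 0.9          # higher shear rate, more events
  B["(1,3)"] <- 0.4
  B["(0,2)"] <- 0.3          # more particles, slightly more events
  list(
    growth_s = growth_s, shear_s = shear_s, slice_dt = slice_dt,
    trajectory = list(
      H0 = 40, height_rise = 1e-5, height_decay0 = 8e-6,
      M0 = 50, E0 = 600, P0 = 2000,
      decay0 = c(mass = 6e-5, eps = 7e-5, particles = 6e-5),
      t_mid = 60000, gamma_ref = 0.25, noise_sd = 0.05),
    norm_ranges = rbind(
      time      = c(0, shear_s),
      particles = c(0, 3000),
      gamma     = c(0.125, 0.375),
      eps       = c(0, 900),
      height    = c(0, 80),
      mass      = c(0, 75),
      noe       = c(0, 40)),
    poisson_B = B,
    dlm = list(
      psi = rep(0.99, 8),
      phi_y = 100,         # observation sd 0.1 on the log scale
      phi_beta = 1000,     # slow state drift: evolution sd ~0.03 per bin
      m0 = c(0.4, -0.4, 1.6, 2.0, 0.2, -0.2, 1.4, 2.4),
      C0 = 1e-4,
      volume_jitter_sd = 0.1))
}

#' Noise-free covariate trajectory means
#'
#' Closed-form family: biofilm height rises during early growth and decays
#' under shear, `H0 (1 + a t) exp(-b(gamma) t_shear)`; mass, EPS count and
#' particle count follow a logistic decline in time-under-shear with decay
#' rate proportional to the shear rate, `X0 plogis((t_mid - t_shear) r(gamma))`.
#'
#' @param params Named vector or list with at least `gamma` (s^-1, > 0).
#' @param times Absolute times (s) from the start of the run; shear is
#'   applied after `config$growth_s`.
#' @param config [study_config()].
#' @return Data frame with columns `time_s`, `height`, `mass`, `eps`,
#'   `particles`.
#' @export
covariate_trajectory_mean <- function(params, times,
                                      config = study_config()) {
  gamma <- params[["gamma"]]
  if (!is.finite(gamma) || gamma <= 0) {
    stop("shear rate 'gamma' must be strictly positive", call. = FALSE)
  }
  tr <- config$trajectory
  scale <- gamma / tr$gamma_ref
  t_shear <- pmax(times - config$growth_s, 0)
  height <- tr$H0 * (1 + tr$height_rise * times) *
    exp(-tr$height_decay0 * scale * t_shear)
  logis <- function(x0, rate) {
    x0 * stats::plogis((tr$t_mid - t_shear) * rate * scale)
  }
  data.frame(time_s = times,
             height = height,
             mass = logis(tr$M0, tr$decay0[["mass"]]),
             eps = logis(tr$E0, tr$decay0[["eps"]]),
             particles = logis(tr$P0, tr$decay0[["particles"]]))
}

#' Simulate one replicate of the morphology covariate trajectories
#'
#' Noise-free means from [covariate_trajectory_mean()] times i.i.d.
#' mean-one lognormal replicate noise, so all series stay positive.
#'
#' @inheritParams covariate_trajectory_mean
#' @param T_slices Number of recording slices (>= 2).
#' @param seed Integer seed.
#' @param noise_sd Lognormal sigma of the replicate noise (0 for exact
#'   curves).
#' @return Data frame with columns `time_s`, `height`, `mass`, `eps`,
#'   `particles`.
#' @export
simulate_covariate_trajectories <- function(params, T_slices = 120,
                                            seed = 1L, noise_sd = NULL,
                                            config = study_config()) {
  if (T_slices < 2) stop("'T_slices' must be at least 2", call. = FALSE)
  noise_sd <- noise_sd %||% config$trajectory$noise_sd
  times <- config$slice_dt * seq_len(T_slices)
  mu <- covariate_trajectory_mean(params, times, config)
  set.seed(seed)
  for (v in c("height", "mass", "eps", "particles")) {
    mu[[v]] <- mu[[v]] *
      exp(stats::rnorm(T_slices, -noise_sd^2 / 2, noise_sd))
  }
  mu
}

#' Simulate Poisson shear-event counts
#'
#' Draws independent counts `noe_t ~ Poisson(exp(basis_t . B))`.  When
#' `covariates` has the six raw input columns (time, particles, gamma, eps,
#' height, mass) and `true_B` has 28 entries, the quadratic basis is built
#' with [build_quadratic_features()]; otherwise `covariates` is used as the
#' basis matrix directly and must have `length(true_B)` columns.
#'
#' @param covariates Matrix or data frame of inputs or a prebuilt basis.
#' @param true_B Coefficient vector on the scale of the supplied inputs.
#' @param seed Integer seed.
#' @return Integer vector of counts, with the mean vector as attribute
#'   `lambda`.
#' @export
simulate_counts <- function(covariates, true_B, seed = 1L) {
  X <- as.matrix(covariates)
  if (ncol(X) == 6L && length(true_B) == 28L) {
    X <- build_quadratic_features(X)
  } else if (ncol(X) != length(true_B)) {
    stop("'true_B' length must match the quadratic basis built from the ",
         "six covariates, or the column count of a prebuilt basis",
         call. = FALSE)
  }
  eta <- drop(X %*% true_B)
  if (any(eta > log(1e9))) {
    stop("Poisson mean exp(basis . B) overflows; rescale coefficients",
         call. = FALSE)
  }
  lambda <- exp(eta)
  set.seed(seed)
  y <- stats::rpois(length(lambda), lambda)
  attr(y, "lambda") <- lambda
  y
}

#' Forward-simulate the dynamic-linear-model state-space pair
#'
#' Exact simulation of `Y_t = F beta_t + v_t`, `beta_t = G beta_{t-1} + w_t`
#' with `beta_0 ~ N(m0, C0)`; `v_t ~ N(0, V)`, `w_t ~ N(0, W)`.
#'
#' @param F_mat m x p regression matrix.
#' @param G,V,W Diagonal matrices or the vectors of their diagonals
#'   (lengths p, m, p); variance entries must be non-negative.
#' @param T_len Number of time steps.
#' @param m0,C0 Prior mean vector and covariance (scalar, vector diagonal
#'   or matrix) of the initial state.
#' @param seed Integer seed.
#' @return List with `Y` (m x T) and `beta` (p x (T+1), first column the
#'   initial state).
#' @export
simulate_volumes <- function(F_mat, G, V, W, T_len, m0 = 0, C0 = 1,
                             seed = 1L) {
  F_mat <- as.matrix(F_mat)
  m <- nrow(F_mat); p <- ncol(F_mat)
  g <- if (is.matrix(G)) diag(G) else rep_len(G, p)
  v <- if (is.matrix(V)) diag(V) else rep_len(V, m)
  w <- if (is.matrix(W)) diag(W) else rep_len(W, p)
  if (any(v < 0) || any(w < 0)) {
    stop("variance entries of V and W must be non-negative", call. = FALSE)
  }
  m0 <- rep_len(m0, p)
  C0d <- if (is.matrix(C0)) diag(C0) else rep_len(C0, p)
  assert_non_negative(C0d, "C0")
  set.seed(seed)
  beta <- matrix(0, p, T_len + 1L)
  beta[, 1L] <- stats::rnorm(p, m0, sqrt(C0d))
  Y <- matrix(0, m, T_len)
  for (t in seq_len(T_len)) {
    beta[, t + 1L] <- g * beta[, t] + stats::rnorm(p, 0, sqrt(w))
    Y[, t] <- drop(F_mat %*% beta[, t + 1L]) + stats::rnorm(m, 0, sqrt(v))
  }
  list(Y = Y, beta = beta)
}

#' Bin a recording-interval series into coarser averaging windows
#'
#' Condenses a series recorded every `slice_dt` seconds into windows of
#' `bin_dt` seconds: continuous channels are averaged, count channels are
#' summed (events per window, preserving integrality).
#'
#' @param x Numeric vector.
#' @param slice_dt,bin_dt Recording and averaging intervals (s); `bin_dt`
#'   must be an integer multiple of `slice_dt`.
#' @param channel `"mean"` for continuous series, `"sum"` for counts.
#' @param allow_ragged Drop a trailing partial window instead of erroring.
#' @return Numeric vector of length `length(x) * slice_dt / bin_dt`.
#' @examples
#' average_slices(1:10, slice_dt = 2000, bin_dt = 10000)  # 3, 8
#' @export
average_slices <- function(x, slice_dt = 2000, bin_dt = 10000,
                           channel = c("mean", "sum"),
                           allow_ragged = FALSE) {
  channel <- match.arg(channel)
  ratio <- bin_dt / slice_dt
  if (ratio < 1 || abs(ratio - round(ratio)) > 1e-9) {
    stop("'bin_dt' must be a positive integer multiple of 'slice_dt'",
         call. = FALSE)
  }
  ratio <- as.integer(round(ratio))
  rem <- length(x) %% ratio
  if (rem != 0L) {
    if (!allow_ragged) {
      stop("series length ", length(x), " is not divisible by the ",
           "slice-to-bin ratio ", ratio,
           "; set allow_ragged = TRUE to truncate the trailing partial bin",
           call. = FALSE)
    }
    x <- x[seq_len(length(x) - rem)]
  }
  g <- rep(seq_len(length(x) %/% ratio), each = ratio)
  out <- if (channel == "mean") tapply(x, g, mean) else tapply(x, g, sum)
  as.numeric(out)
}

#' Generate a complete synthetic detachment study
#'
#' Emulates the output of the individual-based biofilm simulator: a Latin
#' hypercube design over the seven simulator parameters, per-design-point
#' replicate time series of shear-event counts (Poisson with a log-quadratic
#' mean in normalized time, particle count, shear rate, EPS count, height
#' and mass), detached-cluster volumes driven by a shared dynamic linear
#' model on the 10,000 s bin scale, and monotone-trend morphology
#' covariates.  The ground truth used for generation is returned for
#' parameter-recovery testing.
#'
#' @param n_design Number of design points.
#' @param n_reps Replicates per design point.
#' @param n_bins Number of 10,000 s averaging windows over the shear
#'   period.
#' @param seed Global seed; fanned out to independent child streams for
#'   the design, trajectories, counts and volumes.
#' @param config [study_config()].
#' @return List of class `detachment_study` with components `design`,
#'   `runs` (list of data frames, one per design point and replicate, with
#'   columns `time_s, noe, volume, height, mass, eps, particles`), `truth`
#'   and `config`.
#' @export
simulate_detachment_study <- function(n_design = 140, n_reps = 5,
                                      n_bins = 20, seed = 1L,
                                      config = study_config()) {
  slice_dt <- config$slice_dt
  T_slices <- as.integer((config$growth_s + config$shear_s) / slice_dt)
  shear_slices <- as.integer(config$shear_s / slice_dt)
  ratio <- as.integer(config$shear_s / (n_bins * slice_dt))
  design <- latin_hypercube_design(n_design,
                                   seed = child_seed(seed, "design"))
  nr <- config$norm_ranges
  norm01 <- function(x, key) {
    (x - nr[key, 1]) / (nr[key, 2] - nr[key, 1])
  }
  times <- slice_dt * seq_len(T_slices)
  in_shear <- times > config$growth_s

  # Per-slice Poisson means and covariates, replicate by replicate.
  runs <- vector("list", n_design * n_reps)
  mean_lambda <- numeric(n_design)
  k <- 0L
  for (i in seq_len(n_design)) {
    params <- as.list(design[i, ])
    lam_acc <- 0
    for (r in seq_len(n_reps)) {
      s_tr <- child_seed(seed, sprintf("traj_%d_%d", i, r))
      cov <- simulate_covariate_trajectories(params, T_slices, seed = s_tr,
                                             config = config)
      Xn <- cbind(time = norm01(pmax(times - config$growth_s, 0), "time"),
                  particles = norm01(cov$particles, "particles"),
                  gamma = norm01(params$gamma, "gamma"),
                  eps = norm01(cov$eps, "eps"),
                  height = norm01(cov$height, "height"),
                  mass = norm01(cov$mass, "mass"))
      noe <- simulate_counts(Xn, config$poisson_B,
                             seed = child_seed(seed,
                                               sprintf("noe_%d_%d", i, r)))
      lambda <- attr(noe, "lambda") * in_shear
      noe <- as.integer(noe * in_shear)  # shear off during growth phase
      lam_acc <- lam_acc + mean(lambda[in_shear])
      k <- k + 1L
      runs[[k]] <- data.frame(design_id = i, rep = r, time_s = times,
                              noe = noe, volume = NA_real_, gamma =
                                params$gamma, height = cov$height,
                              mass = cov$mass, eps = cov$eps,
                              particles = cov$particles)
    }
    mean_lambda[i] <- lam_acc / n_reps
  }

  # Shared DLM truth on the bin scale drives all detached volumes.  Inputs
  # enter the true surface min-max normalized over the realized design, the
  # same convention the emulator applies to its training inputs.
  F_true <- normalize_inputs(cbind(
    as.matrix(design[, c("mu_m_HET", "K_s_HET", "Y_HET", "gamma", "K_n",
                         "gamma_n", "K_e")]),
    noe = mean_lambda))
  dl <- config$dlm
  vol <- simulate_volumes(F_true, dl$psi, 1 / dl$phi_y, 1 / dl$phi_beta,
                          n_bins, m0 = dl$m0, C0 = dl$C0,
                          seed = child_seed(seed, "volumes"))

  # Disaggregate bin volumes to slices with mean-one lognormal jitter.
  sdv <- dl$volume_jitter_sd
  slice_bin <- rep(seq_len(n_bins), each = ratio)
  k <- 0L
  for (i in seq_len(n_design)) {
    for (r in seq_len(n_reps)) {
      k <- k + 1L
      set.seed(child_seed(seed, sprintf("vol_%d_%d", i, r)))
      jit <- exp(stats::rnorm(shear_slices, -sdv^2 / 2, sdv))
      v_slice <- exp(vol$Y[i, slice_bin]) / ratio * jit
      volume <- c(rep(1e-8, T_slices - shear_slices), v_slice)
      runs[[k]]$volume <- volume
    }
  }

  truth <- list(poisson_B = config$poisson_B, dlm_psi = dl$psi,
                dlm_phi_y = dl$phi_y, dlm_phi_beta = dl$phi_beta,
                dlm_beta_path = vol$beta, F_true = F_true,
                Y_bins = vol$Y, mean_lambda = mean_lambda, seed = seed)
  structure(list(design = design, runs = runs, truth = truth,
                 config = config, n_bins = n_bins, n_reps = n_reps),
            class = "detachment_study")
}

#' @export
print.detachment_study <- function(x, ...) {
  cat("Synthetic biofilm detachment study\n")
  cat("  design points:", nrow(x$design), " replicates:", x$n_reps, "\n")
  cat("  slices per run:", nrow(x$runs[[1]]),
      " shear-window bins:", x$n_bins, "\n")
  invisible(x)
}

#' Write a detachment study to plain-text files
#'
#' Writes `design.csv` (7 named parameter columns), one
#' `run_<i>_rep_<r>.csv` per replicate (columns `time_s, noe, volume,
#' height, mass, eps, particles`) and `truth.json`.
#'
#' @param study A [simulate_detachment_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(study$design),
                   file.path(dir, "design.csv"), row.names = FALSE)
  for (run in study$runs) {
    f <- sprintf("run_%d_rep_%d.csv", run$design_id[1], run$rep[1])
    utils::write.csv(run[, c("time_s", "noe", "volume", "height", "mass",
                             "eps", "particles")],
                     file.path(dir, f), row.names = FALSE)
  }
  truth <- study$truth
  truth$F_true <- unclass(truth$F_true)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(dir)
}

#' Write a particle snapshot with its grid sidecar
#'
#' @param snapshot Data frame with columns `x_um`, `y_um`, `z_um`.
#' @param path CSV path; a `.yaml` sidecar with the grid spec is written
#'   alongside.
#' @param grid A [grid_spec()].
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(snapshot, path, grid = grid_spec()) {
  utils::write.csv(snapshot, path, row.names = FALSE)
  yaml::write_yaml(list(L = as.list(grid$L), N = as.list(grid$N)),
                   sub("\\.csv$", ".yaml", path))
  invisible(path)
}
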