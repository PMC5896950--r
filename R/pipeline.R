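# End-to-end orchestration: simulate (or load) a study, preprocess to the
# 10,000 s bin scale, split train/test, fit the Poisson emulator, chain its
# predicted event counts into the DLM emulator, validate on held-out runs
# and run the time-resolved sensitivity analysis.

#' Random train/test partition of the design points
#'
#' @param n Total number of runs (design points).
#' @param n_train,n_test Partition sizes; must sum to `n`.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_train_test <- function(n, n_train, n_test, seed = 1L) {
  if (n_train + n_test != n) {
    stop(sprintf("n_train + n_test (%d) must equal n (%d)",
                 n_train + n_test, n), call. = FALSE)
  }
  set.seed(seed)
  test <- if (n_test > 0) sort(sample.int(n, n_test)) else integer(0)
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Root mean squared error
#'
#' @param y_true,y_pred Equal-length numeric vectors (n >= 2).
#' @return `sqrt(mean((y_true - y_pred)^2))`.
#' @export
rmse <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  sqrt(mean((y_true - y_pred)^2))
}

#' Percentage of variance explained
#'
#' Headline definition `100 (1 - SSE/SST)`, which penalizes biased
#' predictions; the squared Pearson correlation (times 100) is returned as
#' attribute `r_squared` for comparison.
#'
#' @inheritParams rmse
#' @return Percentage (<= 100; negative when predictions are worse than
#'   the mean).
#' @export
variance_explained <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  sst <- sum((y_true - mean(y_true))^2)
  if (sst <= 0) stop("'y_true' has zero variance", call. = FALSE)
  out <- 100 * (1 - sum((y_true - y_pred)^2) / sst)
  attr(out, "r_squared") <- if (stats::sd(y_pred) > 0) {
    100 * stats::cor(y_true, y_pred)^2
  } else NA_real_
  out
}

#' Preprocess a detachment study to the averaging-window scale
#'
#' Averages the replicates of each design point (counts are averaged across
#' replicates and rounded to the nearest integer, so the Poisson likelihood
#' keeps integer support), restricts to the shear window, and condenses the
#' 2000 s slices into 10,000 s bins: counts are summed per bin, morphology
#' covariates averaged, detached volumes summed then log-transformed.
#'
#' @param study A [simulate_detachment_study()] result (or a compatible
#'   list read back from disk).
#' @return List with `poisson_data` (one row per run and bin: `run`, `bin`,
#'   `noe` and the six raw Poisson inputs), `Y_panel` (runs x bins log
#'   volume), `noe_run` (per-run mean binned count) and `design`.
#' @export
preprocess_study <- function(study) {
  cfg <- study$config
  n_design <- nrow(study$design)
  n_bins <- study$n_bins
  slice_dt <- cfg$slice_dt
  bin_dt <- cfg$shear_s / n_bins
  run_ids <- vapply(study$runs, function(r) r$design_id[1], numeric(1))
  rows <- vector("list", n_design)
  Y_panel <- matrix(NA_real_, n_design, n_bins)
  for (i in seq_len(n_design)) {
    reps <- study$runs[run_ids == i]
    avg <- reps[[1]][, c("time_s", "noe", "volume", "height", "mass",
                         "eps", "particles")]
    if (length(reps) > 1) {
      for (v in c("noe", "volume", "height", "mass", "eps", "particles")) {
        avg[[v]] <- rowMeans(sapply(reps, `[[`, v))
      }
    }
    avg$noe <- round(avg$noe)
    shear <- avg$time_s > cfg$growth_s
    sh <- avg[shear, ]
    noe_b <- average_slices(sh$noe, slice_dt, bin_dt, channel = "sum")
    vol_b <- average_slices(sh$volume, slice_dt, bin_dt, channel = "sum")
    if (any(vol_b <= 0)) {
      stop("non-positive binned volume; cannot log-transform", call. = FALSE)
    }
    Y_panel[i, ] <- log(vol_b)
    rows[[i]] <- data.frame(
      run = i, bin = seq_len(n_bins),
      time = (seq_len(n_bins) - 0.5) * bin_dt,
      noe = noe_b,
      particles = average_slices(sh$particles, slice_dt, bin_dt),
      gamma = study$design$gamma[i],
      eps = average_slices(sh$eps, slice_dt, bin_dt),
      height = average_slices(sh$height, slice_dt, bin_dt),
      mass = average_slices(sh$mass, slice_dt, bin_dt))
  }
  pd <- do.call(rbind, rows)
  list(poisson_data = pd, Y_panel = Y_panel,
       noe_run = tapply(pd$noe, pd$run, mean), design = study$design)
}

#' Pipeline configuration
#'
#' Desk-scale defaults: a 20-point design with 3 replicates and short
#' chains, suitable for minutes-long runs; scale `n_design`, `n_reps` and
#' the chain settings up for study-scale analyses (the field defaults are
#' 140 points, 5 replicates, and much longer chains).
#'
#' @param n_design,n_reps,n_bins Study dimensions.
#' @param n_train,n_test Train/test split (defaults to roughly 13:1, the
#'   conventional 130/10 at full scale).
#' @param seed Global seed fanned out to every stage.
#' @param poisson,dlm Chain-setting lists (`n_iter`, `burn_in`, `thin`).
#' @param sensitivity List with `N` (base sample size) and `bins` (`NULL`
#'   for all); set to `NULL` to skip the sensitivity stage.
#' @param out_dir Optional directory for artifact files.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n_design = 20, n_reps = 3, n_bins = 20,
                            n_train = NULL, n_test = NULL, seed = 1L,
                            poisson = list(n_iter = 40000, burn_in = 4000,
                                           thin = 10),
                            dlm = list(n_iter = 4000, burn_in = 500,
                                       thin = 5),
                            sensitivity = list(N = 2000, bins = NULL),
                            out_dir = NULL) {
  n_test <- n_test %||% max(2, round(n_design / 14))
  n_train <- n_train %||% (n_design - n_test)
  stopifnot(n_train + n_test == n_design)
  structure(list(n_design = n_design, n_reps = n_reps, n_bins = n_bins,
                 n_train = n_train, n_test = n_test, seed = seed,
                 poisson = poisson, dlm = dlm, sensitivity = sensitivity,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full surrogate-modelling pipeline
#'
#' Simulate (or accept) a detachment study, preprocess, split, fit the
#' Poisson emulator on the training rows, predict event counts for the
#' held-out runs, fit the DLM on the training log-volume panel with the
#' observed training counts in its regression matrix and the
#' Poisson-predicted counts for the test rows, validate both emulators on
#' the held-out runs, and compute time-resolved Sobol indices of the
#' fitted volume surface.
#'
#' @param config A [pipeline_config()].
#' @param study Optional pre-generated study (otherwise simulated from
#'   `config`).
#' @return List of class `pipeline_result` with the fitted emulators,
#'   predictions, `report` (RMSE, variance explained and 95 percent
#'   interval coverage per emulator) and `sobol` (or `NULL`).
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL) {
  seed <- config$seed
  if (is.null(study)) {
    study <- simulate_detachment_study(config$n_design, config$n_reps,
                                       config$n_bins,
                                       seed = child_seed(seed, "study"))
  }
  prep <- preprocess_study(study)
  split <- split_train_test(config$n_design, config$n_train, config$n_test,
                            seed = child_seed(seed, "split"))
  pd <- prep$poisson_data
  tr_rows <- pd$run %in% split$train
  covars <- c("time", "particles", "gamma", "eps", "height", "mass")

  # --- Poisson emulator: counts ~ quadratic(normalized inputs) ----------
  Xn_train <- normalize_inputs(pd[tr_rows, covars])
  basis_train <- build_quadratic_features(Xn_train)
  pfit <- fit_poisson_mcmc(basis_train, pd$noe[tr_rows],
                           prior = poisson_prior(q = ncol(basis_train)),
                           n_iter = config$poisson$n_iter,
                           burn_in = config$poisson$burn_in,
                           thin = config$poisson$thin,
                           seed = child_seed(seed, "poisson"))
  Xn_test <- normalize_inputs(pd[!tr_rows, covars], stats = Xn_train)
  basis_test <- build_quadratic_features(Xn_test)
  ppred <- predict_counts(pfit, basis_test,
                          seed = child_seed(seed, "poisson_pred"))

  # --- chain predicted counts into the DLM regression matrix ------------
  noe_run <- prep$noe_run
  noe_test_pred <- tapply(ppred$mean, pd$run[!tr_rows], mean)
  noe_col <- noe_run
  noe_col[split$test] <- noe_test_pred
  F_raw <- cbind(as.matrix(prep$design[, c("mu_m_HET", "K_s_HET", "Y_HET",
                                           "gamma", "K_n", "gamma_n",
                                           "K_e")]),
                 noe = noe_col)
  F_train <- normalize_inputs(F_raw[split$train, , drop = FALSE])
  F_test <- normalize_inputs(F_raw[split$test, , drop = FALSE],
                             stats = F_train)

  # --- DLM emulator on the training log-volume panel --------------------
  spec <- dlm_spec(F_train, m0 = 0, C0 = diag(ncol(F_train)))
  dfit <- gibbs_sample(spec, prep$Y_panel[split$train, , drop = FALSE],
                       n_iter = config$dlm$n_iter,
                       burn_in = config$dlm$burn_in,
                       thin = config$dlm$thin,
                       seed = child_seed(seed, "dlm"))
  dpred <- predict_volumes(dfit, F_test,
                           seed = child_seed(seed, "dlm_pred"))

  # --- validation on the held-out runs ----------------------------------
  y_test_counts <- pd$noe[!tr_rows]
  Y_test <- prep$Y_panel[split$test, , drop = FALSE]
  ve_pois <- variance_explained(y_test_counts, ppred$mean)
  ve_dlm <- variance_explained(as.numeric(Y_test), as.numeric(dpred$mean))
  report <- list(
    poisson = list(
      rmse = rmse(y_test_counts, ppred$mean),
      var_explained = as.numeric(ve_pois),
      r_squared = attr(ve_pois, "r_squared"),
      coverage_95 = mean(y_test_counts >= ppred$lower &
                           y_test_counts <= ppred$upper),
      acceptance_rate = pfit$acceptance_rate),
    dlm = list(
      rmse = rmse(as.numeric(Y_test), as.numeric(dpred$mean)),
      var_explained = as.numeric(ve_dlm),
      r_squared = attr(ve_dlm, "r_squared"),
      coverage_95 = mean(Y_test >= dpred$lower & Y_test <= dpred$upper)),
    split = list(n_train = config$n_train, n_test = config$n_test))

  # --- time-resolved sensitivity of the volume surface ------------------
  sobol <- NULL
  if (!is.null(config$sensitivity)) {
    sobol <- sensitivity_over_time(
      dfit, norm_stats = F_train,
      bins = config$sensitivity$bins,
      N = config$sensitivity$N,
      seed = child_seed(seed, "sobol"))
  }

  result <- structure(list(study = study, prep = prep, split = split,
                           poisson_fit = pfit, poisson_pred = ppred,
                           dlm_fit = dfit, dlm_pred = dpred,
                           F_train = F_train, F_test = F_test,
                           report = report, sobol = sobol,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(result)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("Biofilm detachment surrogate pipeline\n")
  cat(sprintf("  split: %d train / %d test design points\n",
              r$split$n_train, r$split$n_test))
  cat(sprintf("  Poisson emulator: RMSE %.3f, var explained %.1f%%, ",
              r$poisson$rmse, r$poisson$var_explained),
      sprintf("95%% coverage %.2f\n", r$poisson$coverage_95))
  cat(sprintf("  DLM emulator:     RMSE %.3f, var explained %.1f%%, ",
              r$dlm$rmse, r$dlm$var_explained),
      sprintf("95%% coverage %.2f\n", r$dlm$coverage_95))
  invisible(x)
}

#' Write pipeline artifact files
#'
#' Writes `summary.json` (validation report), `poisson_chain.csv`,
#' `psi.csv`, `phi_y.csv`, `phi_beta.csv`, `dlm_predictive.csv`,
#' `predictive.csv` and `sobol_indices.csv` under `config$out_dir`.
#'
#' @param result A [run_pipeline()] result whose config names an
#'   `out_dir`.
#' @return The output directory, invisibly.
#' @export
write_pipeline_artifacts <- function(result) {
  dir <- result$config$out_dir
  stopifnot(!is.null(dir))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(result$report, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  utils::write.csv(as.data.frame(result$poisson_fit$draws),
                   file.path(dir, "poisson_chain.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$dlm_fit$psi),
                   file.path(dir, "psi.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$dlm_fit$phi_y),
                   file.path(dir, "phi_y.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$dlm_fit$phi_beta),
                   file.path(dir, "phi_beta.csv"), row.names = FALSE)
  pp <- result$poisson_pred
  utils::write.csv(data.frame(mean = pp$mean, lower = pp$lower,
                              median = pp$median, upper = pp$upper),
                   file.path(dir, "predictive.csv"), row.names = FALSE)
  dp <- result$dlm_pred
  long <- expand.grid(run = result$split$test,
                      bin = seq_len(ncol(dp$mean)))
  long$mean <- as.numeric(dp$mean)
  long$lo95 <- as.numeric(dp$lower)
  long$hi95 <- as.numeric(dp$upper)
  utils::write.csv(long, file.path(dir, "dlm_predictive.csv"),
                   row.names = FALSE)
  if (!is.null(result$sobol)) {
    utils::write.csv(result$sobol, file.path(dir, "sobol_indices.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
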