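# Time-resolved Sobol variance-based sensitivity analysis of the emulated
# log detached volume: plain Monte-Carlo uniform sampling, Saltelli (2010)
# first-order and Jansen total-effect estimators.

#' Sample matrices for Sobol index estimation
#'
#' Draws two independent uniform sample matrices A and B over the input
#' ranges plus the k hybrid matrices `AB_i` (A with column i replaced by
#' the corresponding column of B), for `N (k + 2)` model evaluations in
#' total.
#'
#' @param ranges k x 2 matrix of `low`, `high` per input (row names become
#'   input names).
#' @param N Base sample size (>= 2).
#' @param seed Integer seed.
#' @return List with `A`, `B` (N x k) and `AB` (list of k matrices).
#' @export
saltelli_design <- function(ranges, N, seed = 1L) {
  ranges <- as.matrix(ranges)
  if (N < 2) stop("'N' must be at least 2", call. = FALSE)
  bad <- which(ranges[, 1] >= ranges[, 2])
  if (length(bad)) {
    nm <- rownames(ranges)[bad[1]] %||% as.character(bad[1])
    stop(sprintf("inverted or empty range for input '%s'", nm),
         call. = FALSE)
  }
  k <- nrow(ranges)
  set.seed(seed)
  scale_to <- function(u) {
    sweep(sweep(u, 2, ranges[, 2] - ranges[, 1], `*`), 2, ranges[, 1], `+`)
  }
  A <- scale_to(matrix(stats::runif(N * k), N, k))
  B <- scale_to(matrix(stats::runif(N * k), N, k))
  colnames(A) <- colnames(B) <- rownames(ranges)
  AB <- lapply(seq_len(k), function(i) {
    M <- A
    M[, i] <- B[, i]
    M
  })
  list(A = A, B = B, AB = AB)
}

#' Sobol first-order and total sensitivity indices
#'
#' Variance decomposition of a deterministic scalar model over independent
#' uniform inputs.  First-order indices `S_i = Var[E(y|x_i)] / Var(y)` use
#' the Saltelli (2010) estimator `mean(f(B) (f(AB_i) - f(A))) / Var(y)`;
#' total indices use the Jansen estimator
#' `mean((f(A) - f(AB_i))^2) / (2 Var(y))`.
#'
#' @param model Function mapping an n x k input matrix to an n-vector.
#' @param ranges k x 2 matrix of input ranges.
#' @param N Base sample size.
#' @param seed Integer seed.
#' @param design Optional precomputed [saltelli_design()] (for estimator
#'   cross-checks on identical samples).
#' @return Data frame of class `sobol_result` with columns `input`,
#'   `S_first`, `S_total` (raw estimates) and `S_first_clipped`,
#'   `S_total_clipped` (clamped to \[0, 1\]), plus attributes `N`, `seed`,
#'   `var_y`.
#' @export
sobol_indices <- function(model, ranges, N = 10000, seed = 1L,
                          design = NULL) {
  ranges <- as.matrix(ranges)
  if (is.null(design)) design <- saltelli_design(ranges, N, seed)
  fA <- as.numeric(model(design$A))
  fB <- as.numeric(model(design$B))
  var_y <- stats::var(c(fA, fB))
  if (!is.finite(var_y) || var_y < 1e-14 * (1 + mean(c(fA, fB))^2)) {
    stop("constant output: Var(y) is zero, Sobol indices are undefined",
         call. = FALSE)
  }
  k <- nrow(ranges)
  S1 <- ST <- numeric(k)
  for (i in seq_len(k)) {
    fABi <- as.numeric(model(design$AB[[i]]))
    S1[i] <- mean(fB * (fABi - fA)) / var_y
    ST[i] <- mean((fA - fABi)^2) / (2 * var_y)
  }
  out <- data.frame(input = rownames(ranges) %||% paste0("x", seq_len(k)),
                    S_first = S1, S_total = ST,
                    S_first_clipped = pmin(pmax(S1, 0), 1),
                    S_total_clipped = pmin(pmax(ST, 0), 1))
  attr(out, "N") <- nrow(design$A)
  attr(out, "seed") <- seed
  attr(out, "var_y") <- var_y
  class(out) <- c("sobol_result", class(out))
  out
}

#' Time-resolved Sobol indices of the emulated log detached volume
#'
#' For each time bin the evaluator maps the seven simulator parameters plus
#' the shear-event count through the posterior-mean surface of the fitted
#' dynamic linear model, `y_t(x) = x_norm . E[beta_t]`, where `x_norm`
#' applies the training min-max normalization.  The evaluator is
#' deterministic by default so the indices decompose input variance only;
#' `use_draws = TRUE` instead averages indices computed from individual
#' posterior draws of `beta_t`.
#'
#' @param fit A [gibbs_sample()] result.
#' @param ranges 8 x 2 matrix of raw input ranges in the column order of
#'   the DLM regression matrix (the seven parameters then `noe`); defaults
#'   to the stored normalization bounds, i.e. the training input ranges.
#' @param norm_stats Object carrying the training `min`/`max` attributes
#'   (e.g. the normalized training matrix); defaults to `fit$spec$F_mat`'s
#'   attributes if present.
#' @param bins Time bins to analyse (default all).
#' @param N Base sample size per bin.
#' @param seed Integer seed.
#' @param use_draws Average over posterior draws instead of the
#'   posterior-mean surface.
#' @param n_draws Number of posterior draws when `use_draws = TRUE`.
#' @return Data frame with columns `time_bin`, `input`, `S_first`,
#'   `S_total` (and clipped versions).
#' @export
sensitivity_over_time <- function(fit, ranges = NULL, norm_stats = NULL,
                                  bins = NULL, N = 10000, seed = 1L,
                                  use_draws = FALSE, n_draws = 50L) {
  p <- fit$spec$p
  norm_stats <- norm_stats %||% fit$spec$F_mat
  mn <- attr(norm_stats, "min")
  mx <- attr(norm_stats, "max")
  if (is.null(ranges)) {
    if (is.null(mn)) stop("supply 'ranges' or a normalized F with stored ",
                          "min/max attributes", call. = FALSE)
    ranges <- cbind(low = mn, high = mx)
  }
  ranges <- as.matrix(ranges)
  stopifnot(nrow(ranges) == p)
  if (is.null(mn)) { mn <- ranges[, 1]; mx <- ranges[, 2] }
  T_len <- dim(fit$beta)[3] - 1L
  bins <- bins %||% seq_len(T_len)
  if (any(bins < 1L | bins > T_len)) {
    stop("requested time bins outside the fitted panel", call. = FALSE)
  }
  Ebeta <- apply(fit$beta, c(2, 3), mean)          # p x (T+1)
  res <- vector("list", length(bins))
  for (bi in seq_along(bins)) {
    t <- bins[bi]
    surface <- function(beta_t) {
      force(beta_t)
      function(X) {
        Xn <- sweep(sweep(X, 2, mn, `-`), 2, mx - mn, `/`)
        drop(Xn %*% beta_t)
      }
    }
    if (!use_draws) {
      r <- sobol_indices(surface(Ebeta[, t + 1L]), ranges, N,
                         seed = child_seed(seed, paste0("bin", t)))
    } else {
      S <- nrow(fit$psi)
      take <- unique(round(seq(1, S, length.out = min(n_draws, S))))
      rs <- lapply(take, function(s) {
        sobol_indices(surface(fit$beta[s, , t + 1L]), ranges, N,
                      seed = child_seed(seed, paste0("bin", t, "_", s)))
      })
      r <- rs[[1]]
      for (cl in c("S_first", "S_total", "S_first_clipped",
                   "S_total_clipped")) {
        r[[cl]] <- rowMeans(sapply(rs, `[[`, cl))
      }
    }
    r$time_bin <- t
    res[[bi]] <- as.data.frame(r)
  }
  out <- do.call(rbind, res)
  out[, c("time_bin", "input", "S_first", "S_total", "S_first_clipped",
          "S_total_clipped")]
}
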