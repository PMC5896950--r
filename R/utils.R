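# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible child seed from a parent seed and a stream label.
# Keeps results independent across streams (design, trajectories, counts,
# volumes, chains) while a single global seed drives everything.
#' @keywords internal
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483587) + 1L
}

#' @keywords internal
assert_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be strictly positive and finite", name),
         call. = FALSE)
  }
  invisible(x)
}

#' @keywords internal
assert_non_negative <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("'%s' must be non-negative and finite", name), call. = FALSE)
  }
  invisible(x)
}

# Symmetrize and clip tiny negative eigenvalues so downstream Cholesky /
# sampling steps never see a numerically indefinite covariance.
#' @keywords internal
make_psd <- function(S, tol = 1e-12) {
  S <- (S + t(S)) / 2
  if (nrow(S) == 1L) return(pmax(S, 0))
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= 0) return(S)
  v <- pmax(e$values, tol * max(abs(e$values), 1))
  S2 <- e$vectors %*% (v * t(e$vectors))
  (S2 + t(S2)) / 2
}

# Draw from N(mean, cov).  Cholesky on the symmetrized covariance when it
# is numerically SPD; eigendecomposition square root (with negative
# eigenvalues clipped) for singular cases such as frozen states when W = 0.
#' @keywords internal
rmvnorm_one <- function(mean, cov) {
  p <- length(mean)
  cov <- (cov + t(cov)) / 2
  ch <- tryCatch(chol(cov), error = function(e) NULL)
  if (!is.null(ch)) {
    return(drop(mean + t(ch) %*% stats::rnorm(p)))
  }
  e <- eigen(cov, symmetric = TRUE)
  v <- pmax(e$values, 0)
  drop(mean + e$vectors %*% (sqrt(v) * stats::rnorm(p)))
}
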