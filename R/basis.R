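# Quadratic feature expansion and min-max input normalization shared by the
# Poisson and DLM emulators.

#' Column labels of the quadratic basis
#'
#' Labels `(i,j)` with `i <= j` over indices 0..p where index 0 is the
#' constant 1, giving intercept, linear, squared and pairwise-interaction
#' terms in a fixed order: (0,0), (0,1) ... (0,p), (1,1), (1,2) ... (p,p).
#'
#' @param p Number of raw inputs (default 6).
#' @return Character vector of length `1 + p + p(p+1)/2`.
#' @export
quadratic_basis_labels <- function(p = 6L) {
  idx <- cbind(0L, 0L:p)
  for (i in seq_len(p)) idx <- rbind(idx, cbind(i, i:p))
  sprintf("(%d,%d)", idx[, 1], idx[, 2])
}

#' Build the quadratic exponential-mean basis
#'
#' Expands an n x p matrix of raw inputs into all products `x_i x_j` with
#' `0 <= i <= j <= p` where `x_0` is identically 1: intercept, p linear
#' terms, and p(p+1)/2 squared and interaction terms (28 columns for the
#' six shear-event inputs time, particle count, shear rate, EPS count,
#' height, mass).
#'
#' @param x Matrix or data frame of finite raw inputs.
#' @return n x q numeric matrix with `(i,j)` column labels.
#' @export
build_quadratic_features <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("'x' must have at least one row", call. = FALSE)
  bad <- which(!stats::complete.cases(x) | apply(!is.finite(x), 1, any))
  if (length(bad)) {
    stop(sprintf("non-finite input in row %d", bad[1]), call. = FALSE)
  }
  p <- ncol(x)
  x0 <- cbind(1, x)
  cols <- vector("list", 1 + p + p * (p + 1) / 2)
  k <- 0L
  for (i in 0:p) {
    for (j in i:p) {
      k <- k + 1L
      cols[[k]] <- x0[, i + 1L] * x0[, j + 1L]
    }
  }
  out <- do.call(cbind, cols)
  colnames(out) <- quadratic_basis_labels(p)
  out
}

#' @keywords internal
norm_minmax <- function(x, range) {
  (x - range[1]) / (range[2] - range[1])
}

#' Min-max normalize emulator inputs to the unit interval
#'
#' Centers each column at its minimum and divides by its range, so all
#' inputs live on \[0, 1\].  The training minima and maxima are stored as
#' attributes so new points are mapped with the same affine transform.
#'
#' @param X Matrix or data frame of raw inputs.
#' @param stats Optional result of a previous call whose stored min/max
#'   should be reused (for test points).
#' @return Numeric matrix with attributes `min` and `max`.
#' @export
normalize_inputs <- function(X, stats = NULL) {
  X <- as.matrix(X)
  if (is.null(stats)) {
    mn <- apply(X, 2, min)
    mx <- apply(X, 2, max)
  } else {
    mn <- attr(stats, "min")
    mx <- attr(stats, "max")
  }
  cst <- which(mx - mn <= 0)
  if (length(cst)) {
    nm <- colnames(X)[cst[1]] %||% as.character(cst[1])
    stop(sprintf("column '%s' is constant; cannot min-max normalize", nm),
         call. = FALSE)
  }
  out <- sweep(sweep(X, 2, mn, `-`), 2, mx - mn, `/`)
  attr(out, "min") <- mn
  attr(out, "max") <- mx
  out
}

#' Invert a min-max normalization
#'
#' @param Xn Matrix produced by [normalize_inputs()] (or with the same
#'   `min`/`max` attributes supplied via `stats`).
#' @param stats Object carrying the `min`/`max` attributes, if not on `Xn`.
#' @return Matrix on the original scale.
#' @export
denormalize_inputs <- function(Xn, stats = Xn) {
  mn <- attr(stats, "min")
  mx <- attr(stats, "max")
  out <- sweep(sweep(as.matrix(Xn), 2, mx - mn, `*`), 2, mn, `+`)
  attr(out, "min") <- NULL
  attr(out, "max") <- NULL
  out
}
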