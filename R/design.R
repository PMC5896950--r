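#' Default individual-based simulator parameters
#'
#' Standard values of the seven varied simulator parameters: substrate
#' affinity for heterotrophs `K_s_HET` (kg m^-3), maximum specific growth
#' rate `mu_m_HET` (h^-1), growth yield `Y_HET` (gCOD/gCOD), hydrodynamic
#' shear rate `gamma` (s^-1), collision spring coefficient `K_n` (N m^-1),
#' collision viscous coefficient `gamma_n` (s^-1) and EPS stiffness per
#' unit EPS mass `K_e` (s^-2).
#'
#' @return Named numeric vector of length 7.
#' @export
default_simulator_params <- function() {
  c(K_s_HET  = 3.5e-5,
    mu_m_HET = 1.0,
    Y_HET    = 0.61,
    gamma    = 0.25,
    K_n      = 1e-4,
    gamma_n  = 1e-5,
    K_e      = 5e9)
}

#' Default parameter ranges (plus/minus 50 percent of the standard values)
#'
#' @param fraction Half-width of the range as a fraction of the default
#'   value (0.5 gives \[0.5x, 1.5x\]).
#' @return 7 x 2 matrix with columns `low`, `high` and the parameter names
#'   as row names.
#' @export
default_parameter_ranges <- function(fraction = 0.5) {
  stopifnot(fraction > 0, fraction < 1)
  p <- default_simulator_params()
  cbind(low = p * (1 - fraction), high = p * (1 + fraction))
}

#' Latin hypercube design over simulator-parameter ranges
#'
#' Generates an n-point maximin-free random Latin hypercube: each column is
#' stratified into n equal-probability intervals of its range with exactly
#' one sample per interval.
#'
#' @param n Number of design points (>= 1).
#' @param ranges Matrix with one row per parameter and columns `low`,
#'   `high`; row names become column names of the design.  Defaults to
#'   [default_parameter_ranges()].
#' @param seed Integer seed; the design is reproducible given the seed.
#' @return A data frame of class `design_matrix` (n rows, one column per
#'   parameter) with attributes `ranges` and `seed`.
#' @examples
#' d <- latin_hypercube_design(10, seed = 1)
#' range(d$gamma)   # inside [0.125, 0.375]
#' @export
latin_hypercube_design <- function(n, ranges = default_parameter_ranges(),
                                   seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  ranges <- as.matrix(ranges)
  if (ncol(ranges) != 2L) stop("'ranges' must have columns low, high",
                               call. = FALSE)
  if (is.null(rownames(ranges))) {
    rownames(ranges) <- paste0("x", seq_len(nrow(ranges)))
  }
  bad <- which(ranges[, 1] >= ranges[, 2])
  if (length(bad)) {
    stop(sprintf("inverted or empty range for parameter '%s'",
                 rownames(ranges)[bad[1]]), call. = FALSE)
  }
  set.seed(seed)
  u <- lhs::randomLHS(as.integer(n), nrow(ranges))
  x <- sweep(sweep(u, 2, ranges[, 2] - ranges[, 1], `*`),
             2, ranges[, 1], `+`)
  colnames(x) <- rownames(ranges)
  out <- as.data.frame(x)
  attr(out, "ranges") <- ranges
  attr(out, "seed") <- seed
  class(out) <- c("design_matrix", class(out))
  out
}

#' Simulation-box grid specification
#'
#' The box \{0,Lx\} x \{0,Ly\} x \{0,Lz\} is partitioned into Nx x Ny x Nz
#' Cartesian blocks; biofilm height is computed over the Nx x Ny base
#' columns of the z = 0 plane.
#'
#' @param L_x,L_y,L_z Box dimensions in micrometres.
#' @param N_x,N_y,N_z Block counts per axis.
#' @return List of class `grid_spec`.
#' @export
grid_spec <- function(L_x = 200, L_y = 40, L_z = 100,
                      N_x = 30, N_y = 12, N_z = 30) {
  assert_positive(c(L_x, L_y, L_z), "box dimensions")
  assert_positive(c(N_x, N_y, N_z), "block counts")
  structure(list(L = c(x = L_x, y = L_y, z = L_z),
                 N = c(x = as.integer(N_x), y = as.integer(N_y),
                       z = as.integer(N_z))),
            class = "grid_spec")
}

#' Mean biofilm height from a particle snapshot
#'
#' Partitions the z = 0 plane into `N_x` x `N_y` base blocks; a base column
#' is occupied when at least one particle center projects into it, and its
#' height is the maximum particle z in the column.  The mean height is the
#' discrete area-weighted integral (1/(Lx Ly)) int int h(x, y) dx dy, i.e.
#' the average of the per-column heights with vacant columns contributing
#' zero (set `vacant = "occupied-only"` to average over occupied columns
#' instead).
#'
#' @param snapshot Data frame with columns `x_um`, `y_um`, `z_um` (one
#'   particle per row), all within the box of `grid`.
#' @param grid A [grid_spec()].
#' @param vacant Convention for vacant base columns: contribute `"zero"`
#'   (default) or be excluded (`"occupied-only"`).
#' @return Mean height in micrometres; 0 (with a warning) for an empty
#'   snapshot.
#' @export
compute_biofilm_height <- function(snapshot, grid = grid_spec(),
                                   vacant = c("zero", "occupied-only")) {
  vacant <- match.arg(vacant)
  stopifnot(inherits(grid, "grid_spec"))
  if (is.null(snapshot) || nrow(snapshot) == 0L) {
    warning("empty particle snapshot; returning height 0")
    return(0)
  }
  x <- snapshot$x_um; y <- snapshot$y_um; z <- snapshot$z_um
  L <- grid$L; N <- grid$N
  if (any(x < 0 | x > L["x"] | y < 0 | y > L["y"] | z < 0 | z > L["z"])) {
    stop("particle positions outside the simulation box", call. = FALSE)
  }
  # block index per axis; particles exactly on the upper face belong to the
  # last block
  ix <- pmin(floor(x / (L["x"] / N["x"])), N["x"] - 1)
  iy <- pmin(floor(y / (L["y"] / N["y"])), N["y"] - 1)
  col_id <- ix + N["x"] * iy
  col_height <- tapply(z, col_id, max)
  if (vacant == "zero") {
    as.numeric(sum(col_height) / (N["x"] * N["y"]))
  } else {
    as.numeric(mean(col_height))
  }
}
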