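#' Time grid of a possibly unequally sampled series
#'
#' The model lives on an equally spaced latent grid of \code{n_grid} points;
#' expression is measured only at the subset \code{observed}.  Unequal
#' physical sampling is represented by mapping each measurement time onto the
#' nearest grid point (see [read_expression()]) and treating the remaining
#' grid points as unobserved: the observation model is simply skipped there.
#'
#' @param n_grid Number of grid points; the last observed point must be the
#'   final grid point, so \code{n_grid == max(observed)}.
#' @param observed Strictly increasing integer vector of observed grid
#'   indices in \code{1:n_grid}.
#' @param interval Physical time per grid step (e.g. 3 for a 3-hour grid).
#' @return An object of class \code{"time_grid"}.
#' @examples
#' time_grid(5)                       # fully observed
#' time_grid(5, c(1, 3, 5))           # points 2 and 4 unobserved
#' @export
time_grid <- function(n_grid, observed = seq_len(n_grid), interval = 1) {
  g <- new_time_grid(n_grid, observed, interval)
  if (max(g$observed) != g$n_grid)
    stop("last observed point must be the final grid point (max(observed) == n_grid)")
  g
}

# internal constructor: allows trailing unobserved grid points, which the
# leave-one-out cross-validation of alpha0 needs when the final observation
# is held out.
new_time_grid <- function(n_grid, observed, interval = 1) {
  n_grid <- as.integer(n_grid)
  observed <- as.integer(observed)
  stopifnot(length(n_grid) == 1L, n_grid >= 1L)
  if (length(observed) == 0L) stop("'observed' must be non-empty")
  if (any(observed < 1L) || any(observed > n_grid))
    stop("'observed' indices must lie in 1..n_grid")
  if (any(diff(observed) <= 0L)) stop("'observed' must be strictly increasing")
  if (!is.numeric(interval) || length(interval) != 1L || interval <= 0)
    stop("'interval' must be a positive scalar")
  structure(list(n_grid = n_grid, observed = observed,
                 interval = as.numeric(interval)),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %d grid points (interval %g), %d observed\n",
              x$n_grid, x$interval, length(x$observed)))
  invisible(x)
}

#' Observed expression series for one condition
#'
#' @param values Numeric matrix, genes x observed time points.
#' @param grid A [time_grid()] whose observed set has one entry per column.
#' @param condition Condition label, 1 or 2.
#' @return An object of class \code{"observed_series"}.
#' @export
observed_series <- function(values, grid, condition = 1L) {
  values <- as.matrix(values)
  if (!inherits(grid, "time_grid")) stop("'grid' must be a time_grid")
  if (ncol(values) != length(grid$observed))
    stop("column count must equal the number of observed grid points")
  if (!all(is.finite(values))) stop("expression values must all be finite")
  condition <- as.integer(condition)
  if (!condition %in% c(1L, 2L)) stop("'condition' must be 1 or 2")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  structure(list(values = values, grid = grid, condition = condition),
            class = "observed_series")
}

#' @export
print.observed_series <- function(x, ...) {
  cat(sprintf("<observed_series> condition %d: %d genes x %d observed / %d grid points\n",
              x$condition, nrow(x$values), ncol(x$values), x$grid$n_grid))
  invisible(x)
}

#' Directed weighted network for one condition
#'
#' Stores the autoregressive coefficients \code{coeff} (row i = regulators of
#' gene i) together with the binary edge matrix \code{edges}.  A coefficient
#' may be non-zero only where the corresponding edge is present.
#'
#' @param coeff p x p numeric matrix of AR coefficients.
#' @param edges p x p binary (0/1) matrix; defaults to \code{coeff != 0}.
#' @return An object of class \code{"network_model"}.
#' @export
network_model <- function(coeff, edges = NULL) {
  coeff <- as.matrix(coeff)
  if (nrow(coeff) != ncol(coeff)) stop("'coeff' must be square")
  if (is.null(edges)) {
    edges <- (coeff != 0) * 1L
  } else {
    edges <- as.matrix(edges)
    if (!all(dim(edges) == dim(coeff))) stop("'edges' must match dim of 'coeff'")
    if (!all(edges %in% c(0, 1))) stop("'edges' must be binary")
    if (any(coeff[edges == 0] != 0))
      stop("coefficients must be zero where no edge is present")
  }
  structure(list(coeff = coeff, edges = edges), class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %d genes, %d edges (%d autoloops)\n",
              nrow(x$coeff), sum(x$edges), sum(diag(x$edges))))
  invisible(x)
}

#' Model hyperparameters
#'
#' @param alpha0,alpha1 Coefficient-prior variance factors (times the system
#'   noise variance h_i): \code{alpha1} applies where an edge is present in at
#'   least one condition, \code{alpha0} (which must be smaller) elsewhere and
#'   enforces sparsity.
#' @param u0,k0 Shape and inverse scale of the inverse-gamma prior on the
#'   system noise variances h_i.
#' @param v0,l0 Shape and inverse scale of the inverse-gamma prior on the
#'   observation noise variances r_i.
#' @param zeta0,zeta1 Beta prior parameters of the change probabilities
#'   z_ij; either scalars (shared by all target genes) or length-p vectors.
#' @return An object of class \code{"hyper_params"}.
#' @export
hyper_params <- function(alpha0 = 0.01, alpha1 = 1000,
                         u0 = 1, k0 = 1, v0 = 1, l0 = 1,
                         zeta0 = 10, zeta1 = 10) {
  vals <- c(alpha0 = alpha0, alpha1 = alpha1, u0 = u0, k0 = k0,
            v0 = v0, l0 = l0)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all hyperparameters must be strictly positive")
  if (any(zeta0 <= 0) || any(zeta1 <= 0))
    stop("all hyperparameters must be strictly positive")
  if (alpha0 >= alpha1) stop("'alpha0' must be smaller than 'alpha1'")
  structure(list(alpha0 = alpha0, alpha1 = alpha1, u0 = u0, k0 = k0,
                 v0 = v0, l0 = l0, zeta0 = zeta0, zeta1 = zeta1),
            class = "hyper_params")
}

#' Annealing schedule
#'
#' The temperature starts at \code{tau_init} and is divided by
#' \code{cool_factor} after each converged inner loop until it drops below
#' \code{tau_min}.
#'
#' @param tau_init Initial temperature (default 2.5).
#' @param cool_factor Cooling divisor, must exceed 1 (default 1.05).
#' @param tau_min Stopping temperature (default 0.01).
#' @param inner_tol Relative tolerance on the lower bound for inner-loop
#'   convergence.
#' @param inner_max Cap on inner iterations per temperature.
#' @return An object of class \code{"anneal_schedule"}.
#' @export
anneal_schedule <- function(tau_init = 2.5, cool_factor = 1.05,
                            tau_min = 0.01, inner_tol = 1e-6,
                            inner_max = 100L) {
  if (cool_factor <= 1) stop("'cool_factor' must be > 1")
  if (!(tau_init > tau_min && tau_min > 0))
    stop("need tau_init > tau_min > 0")
  if (inner_tol <= 0 || inner_max < 1) stop("invalid inner-loop settings")
  structure(list(tau_init = tau_init, cool_factor = cool_factor,
                 tau_min = tau_min, inner_tol = inner_tol,
                 inner_max = as.integer(inner_max)),
            class = "anneal_schedule")
}

# dimension helpers ---------------------------------------------------------

n_genes <- function(x) {
  if (inherits(x, "observed_series")) return(nrow(x$values))
  if (inherits(x, "network_model")) return(nrow(x$coeff))
  stop("unsupported object")
}

check_pair <- function(data) {
  if (!is.list(data) || length(data) != 2L ||
      !all(vapply(data, inherits, logical(1), "observed_series")))
    stop("'data' must be a list of two observed_series (one per condition)")
  if (nrow(data[[1]]$values) != nrow(data[[2]]$values))
    stop("both conditions must have the same gene set")
  invisible(data)
}
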