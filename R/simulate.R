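#' Benchmark specification
#'
#' Describes one cell of the Monte-Carlo benchmark: a scale-free base
#' network whose non-autoloop edges are split into a common core and
#' condition-specific remainders, VAR(1) dynamics with Gaussian system and
#' observation noise, and an equal or three-block unequal observation
#' schedule.
#'
#' @param n_genes,n_edges Size of the base network (defaults 100 and 150).
#' @param coeff_set Pool of AR coefficients, drawn uniformly per edge
#'   (default \{-0.9 ... -0.5, 0.5 ... 0.9\}).
#' @param frac_common Fraction of non-autoloop edges shared by both
#'   conditions (default 0.7).
#' @param sys_sd,obs_sd System and observation noise standard deviations
#'   (defaults 1 and 0.1).
#' @param n_timepoints Number of observed time points per condition.
#' @param schedule \code{"equal"} or \code{"three_block"}.
#' @param n_replicates Number of replicate data sets (default 10).
#' @param seed Base random seed.
#' @export
benchmark_spec <- function(n_genes = 100L, n_edges = 150L,
                           coeff_set = c(-(9:5), 5:9) / 10,
                           frac_common = 0.7, sys_sd = 1, obs_sd = 0.1,
                           n_timepoints = 50L,
                           schedule = c("equal", "three_block"),
                           n_replicates = 10L, seed = 1L) {
  schedule <- match.arg(schedule)
  if (frac_common < 0 || frac_common > 1) stop("'frac_common' must be in [0, 1]")
  if (length(coeff_set) == 0 || any(coeff_set == 0))
    stop("'coeff_set' must be non-empty and exclude 0")
  if (sys_sd <= 0 || obs_sd < 0) stop("invalid noise levels")
  structure(list(n_genes = as.integer(n_genes), n_edges = as.integer(n_edges),
                 coeff_set = coeff_set, frac_common = frac_common,
                 sys_sd = sys_sd, obs_sd = obs_sd,
                 n_timepoints = as.integer(n_timepoints), schedule = schedule,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' Scale-free base network with autoloops on roots
#'
#' Builds the directed base network: an undirected preferential-attachment
#' graph grown to exactly \code{n_edges} edges, each edge directed by a fair
#' coin, a self-loop added to every root (in-degree zero) node, and a
#' coefficient drawn uniformly from \code{coeff_set} for every edge
#' including the autoloops.  Coefficient draws are repeated (up to 100
#' attempts) until the spectral radius is below 1 so the simulated series is
#' stationary.
#'
#' @param spec A [benchmark_spec()].
#' @param seed Seed (defaults to \code{spec$seed}).
#' @return A [network_model()].
#' @export
make_base_network <- function(spec, seed = spec$seed) {
  set.seed(seed)
  p <- spec$n_genes; m <- spec$n_edges
  if (m < p - 1 || m > p * (p - 1) / 2)
    stop("edge count not achievable for a connected simple graph of this size")
  # preferential attachment: spanning tree first, then extra edges with
  # degree-biased endpoints, keeping the graph simple
  deg <- rep(0L, p)
  edge_a <- integer(m); edge_b <- integer(m)
  has_edge <- new.env(hash = TRUE)
  key <- function(a, b) paste0(min(a, b), "-", max(a, b))
  add <- function(idx, a, b) {
    edge_a[idx] <<- a; edge_b[idx] <<- b
    deg[a] <<- deg[a] + 1L; deg[b] <<- deg[b] + 1L
    assign(key(a, b), TRUE, envir = has_edge)
  }
  add(1L, 1L, 2L)
  for (v in seq_len(p)[-(1:2)]) {
    tgt <- sample.int(v - 1L, 1L, prob = deg[1:(v - 1L)] + 1)
    add(v - 1L, v, tgt)
  }
  idx <- p   # p - 1 tree edges placed, continue to m
  guard <- 0L
  while (idx <= m) {
    a <- sample.int(p, 1L, prob = deg + 1)
    b <- sample.int(p, 1L, prob = deg + 1)
    guard <- guard + 1L
    if (guard > 100000L) stop("failed to place the requested number of edges")
    if (a == b || exists(key(a, b), envir = has_edge)) next
    add(idx, a, b)
    idx <- idx + 1L
  }
  # orient each edge by a fair coin: regulator j -> target i is (i, j)
  flip <- stats::runif(m) < 0.5
  src <- ifelse(flip, edge_a, edge_b)
  tgt <- ifelse(flip, edge_b, edge_a)
  E <- matrix(0L, p, p)
  E[cbind(tgt, src)] <- 1L
  roots <- which(rowSums(E) == 0L)   # in-degree zero after orientation
  E[cbind(roots, roots)] <- 1L
  for (attempt in 1:100) {
    A <- matrix(0, p, p)
    A[E == 1L] <- sample(spec$coeff_set, sum(E), replace = TRUE)
    if (spectral_radius(A) < 1) {
      if (attempt > 1)
        message(sprintf("re-drew coefficients %d times for stability", attempt - 1L))
      return(network_model(A, E))
    }
  }
  stop("could not find a stable coefficient assignment in 100 attempts")
}

spectral_radius <- function(A) max(Mod(eigen(A, only.values = TRUE)$values))

#' Split a base network into two condition networks
#'
#' Autoloops and a fraction \code{frac_common} of the non-autoloop edges are
#' kept in both conditions; each remaining edge is assigned to exactly one
#' condition by a fair coin.  Coefficients are carried over unchanged.  The
#' assignment is re-drawn (up to 100 attempts) if either condition's
#' effective coefficient matrix fails the stationarity check.
#'
#' @param g0 Base [network_model()].
#' @param frac_common Fraction of non-autoloop edges common to both.
#' @param seed Random seed.
#' @return List of two [network_model()]s (\code{g1}, \code{g2}).
#' @export
split_conditions <- function(g0, frac_common = 0.7, seed = 1L) {
  set.seed(seed)
  p <- n_genes(g0)
  off <- which(g0$edges == 1L & diag(p) == 0)
  n_common <- round(frac_common * length(off))
  for (attempt in 1:100) {
    common <- sample(off, n_common)
    specific <- setdiff(off, common)
    to_g1 <- specific[stats::runif(length(specific)) < 0.5]
    to_g2 <- setdiff(specific, to_g1)
    E1 <- E2 <- (g0$edges == 1L & diag(p) == 1) * 1L   # autoloops always common
    E1[common] <- 1L; E2[common] <- 1L
    E1[to_g1] <- 1L; E2[to_g2] <- 1L
    A1 <- g0$coeff * E1; A2 <- g0$coeff * E2
    if (spectral_radius(A1) < 1 && spectral_radius(A2) < 1)
      return(list(g1 = network_model(A1, E1), g2 = network_model(A2, E2)))
  }
  stop("no stable condition split found in 100 attempts")
}

#' Three-block unequal observation schedule
#'
#' Builds the unequal-spacing schedule: the grid is split into three blocks
#' of relative sizes 3:2:3; the first block is fully observed, the second
#' keeps one point of every two, the third one of every three (the last
#' point of each thinning group, so the final grid point is observed).  For
#' 25 observed points this gives a 40-point grid with blocks of 15/10/15;
#' for 50 observed points an 80-point grid with blocks of 30/20/30.
#'
#' @param n_observed Number of observed points; must be a multiple of 5.
#' @param interval Physical time per grid step.
#' @return A [time_grid()].
#' @export
three_block_schedule <- function(n_observed, interval = 1) {
  n_observed <- as.integer(n_observed)
  if (n_observed %% 5L != 0L || n_observed < 5L)
    stop("'n_observed' must be a positive multiple of 5 for the 3:2:3 block rule")
  k <- n_observed %/% 5L
  b1 <- 3L * k; b2 <- 2L * k; b3 <- 3L * k
  obs <- c(seq_len(b1),
           b1 + seq(2L, b2, by = 2L),
           b1 + b2 + seq(3L, b3, by = 3L))
  time_grid(b1 + b2 + b3, obs, interval)
}

#' Simulate an observed series from a network
#'
#' Iterates the VAR(1) dynamics \code{x_t = A x_{t-1} + eta_t} from
#' \code{x_0 = 0} with a 100-step burn-in, then emits
#' \code{y_t = x_t + rho_t} at the scheduled observation points.
#'
#' @param g A [network_model()] (its masked coefficient matrix drives the
#'   dynamics).
#' @param n_timepoints Number of observed points.
#' @param sys_sd,obs_sd Noise standard deviations.
#' @param schedule \code{"equal"} or \code{"three_block"}.
#' @param seed Random seed.
#' @param condition Condition label for the returned series.
#' @param interval Physical time per grid step.
#' @return An [observed_series()].
#' @export
simulate_series <- function(g, n_timepoints, sys_sd = 1, obs_sd = 0.1,
                            schedule = c("equal", "three_block"), seed = 1L,
                            condition = 1L, interval = 1) {
  schedule <- match.arg(schedule)
  set.seed(seed)
  p <- n_genes(g)
  grid <- if (schedule == "equal") time_grid(n_timepoints, interval = interval)
          else three_block_schedule(n_timepoints, interval)
  Tg <- grid$n_grid
  A <- g$coeff
  burn <- 100L
  x <- numeric(p)
  for (t in seq_len(burn)) x <- drop(A %*% x) + rnorm(p, 0, sys_sd)
  X <- matrix(0, p, Tg)
  for (t in seq_len(Tg)) {
    x <- drop(A %*% x) + rnorm(p, 0, sys_sd)
    X[, t] <- x
  }
  if (!all(is.finite(X)))
    stop("trajectory diverged; use a stable coefficient matrix")
  Y <- X[, grid$observed, drop = FALSE] +
    matrix(rnorm(p * length(grid$observed), 0, obs_sd), p)
  observed_series(Y, grid, condition)
}

#' Generate one replicate of the two-condition benchmark
#'
#' Builds the base network, splits it into the two condition networks, and
#' simulates one observed series per condition with independent noise.
#'
#' @param spec A [benchmark_spec()].
#' @param replicate Replicate number (offsets the seed).
#' @return List with \code{data} (two [observed_series()]), \code{truth}
#'   (the two condition [network_model()]s) and \code{g0}.
#' @export
simulate_conditions <- function(spec, replicate = 1L) {
  base_seed <- spec$seed + 7919L * (replicate - 1L)
  g0 <- make_base_network(spec, seed = base_seed)
  gs <- split_conditions(g0, spec$frac_common, seed = base_seed + 1L)
  s1 <- simulate_series(gs$g1, spec$n_timepoints, spec$sys_sd, spec$obs_sd,
                        spec$schedule, seed = base_seed + 2L, condition = 1L)
  s2 <- simulate_series(gs$g2, spec$n_timepoints, spec$sys_sd, spec$obs_sd,
                        spec$schedule, seed = base_seed + 3L, condition = 2L)
  list(data = list(s1, s2), truth = list(gs$g1, gs$g2), g0 = g0)
}
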