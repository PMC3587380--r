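#' Fit control options
#'
#' @param update_hyper When to re-estimate the inverse-gamma and Beta
#'   hyperparameters by empirical Bayes: at every inner iteration
#'   (\code{"each"}, the default, matching the listed procedure order),
#'   once per temperature (\code{"temperature"}), or \code{"never"}.
#' @param astep_sweeps Gauss-Seidel sweeps per A-step call (a few suffice).
#' @param lambda0 Diffuse initial-state prior precision.
#' @param verbose Print per-temperature progress.
#' @return A list of control settings for [anneal_fit()] / [em_fit()].
#' @export
fit_control <- function(update_hyper = c("each", "temperature", "never"),
                        astep_sweeps = 5L, lambda0 = 1e-3, verbose = FALSE) {
  list(update_hyper = match.arg(update_hyper),
       astep_sweeps = as.integer(astep_sweeps),
       lambda0 = lambda0, verbose = isTRUE(verbose))
}

#' Joint two-condition network inference by variational annealing
#'
#' Fits the joint VAR state-space model to the two conditions' series.  Each
#' inner cycle runs, in order: the variational M-step (conjugate parameter
#' posteriors), the empirical-Bayes hyperparameter updates, the variational
#' E-step (Kalman smoothing of the hidden states under the expected system),
#' and the variational A-step (tempered mean-field update of the edge
#' indicator posteriors).  Cycles repeat until the lower bound stabilizes,
#' then the temperature is divided by the cooling factor; the loop stops
#' once the temperature falls below its threshold, by which point the edge
#' posteriors are near-binary.  Networks are read off by thresholding the
#' edge probabilities at 1/2 (an exact tie counts as absent).
#'
#' Initialization follows the standard settings: tau = 2.5, all edge
#' probabilities 1/2, unit inverse-gamma posteriors, Beta parameters 10, and
#' hidden states at the observations (linearly interpolated at unobserved
#' grid points).
#'
#' @param data List of two [observed_series()] (conditions 1 and 2).
#' @param hyper A [hyper_params()]; \code{alpha1} defaults to 1000 and
#'   \code{alpha0} should be chosen by [select_alpha0()] or fixed.
#' @param sched An [anneal_schedule()].
#' @param control A [fit_control()].
#' @return A \code{"var2_fit"}: posterior blocks \code{theta},
#'   \code{edges}, \code{stats}, final \code{hyper}, the per-iteration
#'   \code{bound_trace} (temperature, iteration, tempered and plain bound),
#'   and \code{networks}, the pair of thresholded [network_model()]s.
#' @seealso [em_fit()] for the EM baseline, [run_benchmark()] for the
#'   simulation study driver.
#' @export
anneal_fit <- function(data, hyper = hyper_params(),
                       sched = anneal_schedule(), control = fit_control()) {
  taus <- anneal_temperatures(sched)
  fit_joint(data, hyper, sched, control, taus, em = FALSE)
}

#' EM-style baseline fit
#'
#' Identical loop to [anneal_fit()] but with the temperature pinned at 1 and
#' the edge indicators treated as continuous parameters in \[0, 1\] that are
#' maximized (not averaged over) each cycle; the result is discretized at
#' 1/2.  This is the baseline the annealed posterior is compared against:
#' it tends to keep more spurious edges.
#'
#' @inheritParams anneal_fit
#' @export
em_fit <- function(data, hyper = hyper_params(),
                   sched = anneal_schedule(), control = fit_control()) {
  fit_joint(data, hyper, sched, control, taus = 1, em = TRUE)
}

anneal_temperatures <- function(sched) {
  taus <- c()
  tau <- sched$tau_init
  while (tau > sched$tau_min) {
    taus <- c(taus, tau)
    tau <- tau / sched$cool_factor
  }
  taus
}

fit_joint <- function(data, hyper, sched, control, taus, em) {
  check_pair(data)
  if (data[[1]]$condition == data[[2]]$condition)
    warning("both series carry the same condition label")
  p <- n_genes(data[[1]])
  hyper_cur <- hyper
  x1_means <- lapply(data, function(s) interp_states(s)[, 1])

  # initialization: states at (interpolated) observations, edges at 1/2
  stats <- lapply(data, function(s) point_stats(interp_states(s), s))
  edges <- list(e1 = matrix(0.5, p, p), e2 = matrix(0.5, p, p))
  trace <- vector("list", 0)
  theta <- NULL

  for (ti in seq_along(taus)) {
    tau <- taus[ti]
    prev_bound <- -Inf
    for (it in seq_len(sched$inner_max)) {
      theta <- m_step(stats, edges, hyper_cur, point_mass_e = em)
      if (control$update_hyper == "each" ||
          (control$update_hyper == "temperature" && it == 1L)) {
        hyper_cur <- update_all_hyper(theta, hyper_cur)
      }
      sys <- expected_system(theta, edges, point_mass_e = em)
      stats <- lapply(1:2, function(c)
        smooth_states(data[[c]], sys, x1_means[[c]], control$lambda0))
      edges <- a_step(theta, stats, edges, hyper_cur, tau,
                      sweeps = control$astep_sweeps, em = em)
      b <- variational_bound(data, stats, theta, edges, hyper_cur, tau,
                             em = em, lambda0 = control$lambda0,
                             x1_means = x1_means)
      if (!is.finite(b[["bound"]]))
        stop("lower bound became non-finite; check the data scale and hyperparameters")
      trace[[length(trace) + 1L]] <- c(tau = tau, iter = it,
                                       bound = b[["bound"]],
                                       bound_plain = b[["bound_plain"]])
      if (is.finite(prev_bound) &&
          abs(b[["bound"]] - prev_bound) < sched$inner_tol * abs(b[["bound"]]))
        break
      prev_bound <- b[["bound"]]
    }
    if (control$verbose && (ti %% 20 == 1 || ti == length(taus)))
      message(sprintf("tau = %.4f  bound = %.4f  (%d inner)", tau,
                      prev_bound, it))
  }

  bound_trace <- as.data.frame(do.call(rbind, trace))
  networks <- lapply(1:2, function(c) {
    e <- if (c == 1) edges$e1 else edges$e2
    hard <- (e > 0.5) * 1L
    network_model(theta$mu * hard, hard)
  })
  structure(list(theta = theta, edges = edges, stats = stats,
                 hyper = hyper_cur, bound_trace = bound_trace,
                 networks = networks, mode = if (em) "em" else "anneal",
                 p = p),
            class = "var2_fit")
}

update_all_hyper <- function(theta, hyper_cur) {
  upd_h <- update_hyper_ig(theta$u, theta$k,
                           init = hyper_cur$u0)
  upd_r <- update_hyper_ig(theta$v, theta$l,
                           init = hyper_cur$v0)
  p <- nrow(theta$zeta0)
  z0 <- numeric(p); z1 <- numeric(p)
  cz0 <- rep(hyper_cur$zeta0, length.out = p)
  cz1 <- rep(hyper_cur$zeta1, length.out = p)
  for (i in seq_len(p)) {
    upd_z <- update_hyper_beta(theta$zeta0[i, ], theta$zeta1[i, ],
                               init = c(cz0[i], cz1[i]))
    z0[i] <- upd_z$zeta0; z1[i] <- upd_z$zeta1
  }
  hyper_cur$u0 <- upd_h$shape; hyper_cur$k0 <- upd_h$inv_scale
  hyper_cur$v0 <- upd_r$shape; hyper_cur$l0 <- upd_r$inv_scale
  hyper_cur$zeta0 <- z0; hyper_cur$zeta1 <- z1
  hyper_cur
}

#' @export
print.var2_fit <- function(x, ...) {
  n1 <- sum(x$networks[[1]]$edges); n2 <- sum(x$networks[[2]]$edges)
  common <- sum(x$networks[[1]]$edges & x$networks[[2]]$edges)
  cat(sprintf("<var2_fit> (%s) %d genes; edges: %d / %d (%d common, %d changes)\n",
              x$mode, x$p, n1, n2, common, n1 + n2 - 2 * common))
  cat(sprintf("  final bound %.4f after %d cycles\n",
              x$bound_trace$bound[nrow(x$bound_trace)], nrow(x$bound_trace)))
  invisible(x)
}

#' Select the sparsity hyperparameter by leave-one-time-point-out CV
#'
#' For every candidate \code{alpha0} and every observed time point of either
#' condition, the point is held out, the model is re-fit on the remaining
#' data, the hidden state at the held-out grid point is predicted by the
#' variational Kalman smoother, and the squared residual against the held-out
#' observation is accumulated.  The grid value minimizing the total squared
#' residual is returned (ties break toward the smaller value).
#'
#' Strict leave-one-out re-fits once per observed point; for long series the
#' \code{thin} argument holds out only every \code{thin}-th observed point.
#'
#' @param data List of two [observed_series()].
#' @param alpha0_grid Candidate values, all below \code{hyper$alpha1}.
#' @param hyper,sched,control Passed to [anneal_fit()].
#' @param thin Hold out every \code{thin}-th observed point (1 = strict
#'   leave-one-out).
#' @return List: \code{alpha0} (the minimizer), \code{score} (total squared
#'   residual per grid value) and \code{folds} (per-fold residuals).
#' @export
select_alpha0 <- function(data, alpha0_grid, hyper = hyper_params(),
                          sched = anneal_schedule(), control = fit_control(),
                          thin = 1L) {
  check_pair(data)
  if (length(alpha0_grid) == 0) stop("'alpha0_grid' must be non-empty")
  if (any(alpha0_grid >= hyper$alpha1))
    stop("all alpha0 candidates must be below alpha1")
  alpha0_grid <- sort(alpha0_grid)
  folds <- list()
  for (c in 1:2) {
    obs <- data[[c]]$grid$observed
    held <- obs[seq(1, length(obs), by = as.integer(thin))]
    for (t in held) {
      if (length(obs) <= 2) next   # refusing to train on a single point
      folds[[length(folds) + 1L]] <- list(c = c, t = t)
    }
  }
  res <- matrix(NA_real_, length(folds), length(alpha0_grid),
                dimnames = list(NULL, paste0("alpha0_", alpha0_grid)))
  for (gi in seq_along(alpha0_grid)) {
    hy <- hyper; hy$alpha0 <- alpha0_grid[gi]
    for (fi in seq_along(folds)) {
      fl <- folds[[fi]]
      dcv <- drop_time_point(data, fl$c, fl$t)
      fit <- anneal_fit(dcv, hy, sched, control)
      pred <- fit$stats[[fl$c]]$mean[, fl$t]
      yobs <- data[[fl$c]]$values[, match(fl$t, data[[fl$c]]$grid$observed)]
      res[fi, gi] <- sum((yobs - pred)^2)
    }
  }
  total <- colSums(res)
  list(alpha0 = alpha0_grid[which.min(total)],
       score = stats::setNames(total, alpha0_grid), folds = res)
}

# remove one observed time point from one condition; the grid keeps its
# length so the smoother still produces a prediction at the removed point.
drop_time_point <- function(data, c, t) {
  s <- data[[c]]
  keep <- s$grid$observed != t
  grid <- new_time_grid(s$grid$n_grid, s$grid$observed[keep], s$grid$interval)
  data[[c]] <- structure(list(values = s$values[, keep, drop = FALSE],
                              grid = grid, condition = s$condition),
                         class = "observed_series")
  data
}
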