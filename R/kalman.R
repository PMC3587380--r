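#' Expected system matrices under the variational posterior
#'
#' Computes the moments of the masked system matrix needed by the variational
#' Kalman smoother, taken under the factorized posterior
#' \code{Q(Theta) Q(E)}: the expected effective network \code{EA = <A o E>},
#' the scaled transition \code{K = <H^-1 A o E>}, the quadratic form
#' \code{J = <(A o E)' H^-1 (A o E)>}, and the expected noise precisions.
#' Edge indicators are independent Bernoulli under Q, so off-diagonal
#' second moments use \code{e_ij e_ik} while diagonal terms use \code{e_ij}
#' (since an indicator squared is itself).  In EM mode (\code{point_mass_e})
#' the indicators are deterministic parameters and the diagonal uses
#' \code{e_ij^2}.
#'
#' @param theta Posterior parameter block as produced by [m_step()].
#' @param edges List with elements \code{e1}, \code{e2}: p x p matrices of
#'   edge probabilities.
#' @param point_mass_e Treat the edge values as deterministic (EM mode).
#' @return List with \code{cond}, a per-condition list of \code{EA},
#'   \code{K}, \code{J}, plus \code{w} (\code{<1/h>}) and \code{vr}
#'   (\code{<1/r>}).
#' @export
expected_system <- function(theta, edges, point_mass_e = FALSE) {
  p <- nrow(theta$mu)
  w <- theta$u / theta$k
  vr <- theta$v / theta$l
  out <- list(cond = vector("list", 2), w = w, vr = vr)
  for (c in 1:2) {
    e <- if (c == 1) edges$e1 else edges$e2
    EA <- e * theta$mu
    K <- w * EA                       # row scaling by <1/h_i>
    J <- matrix(0, p, p)
    for (i in seq_len(p)) {
      Pi <- w[i] * tcrossprod(theta$mu[i, ]) + theta$prec_inv[, , i]
      Om <- tcrossprod(e[i, ])
      diag(Om) <- if (point_mass_e) e[i, ]^2 else e[i, ]
      J <- J + Pi * Om
    }
    out$cond[[c]] <- list(EA = EA, K = K, J = 0.5 * (J + t(J)))
  }
  out
}

#' Variational Kalman smoothing of the hidden expression states
#'
#' Runs exact Gaussian inference for one condition's hidden states under the
#' expected system of [expected_system()].  Grid points without an
#' observation simply omit the measurement term, which is how unequally
#' spaced series are handled.  The initial state has a diffuse Gaussian
#' prior centred on \code{x1_mean} with precision \code{lambda0}.
#'
#' Implementation: the joint posterior over all states is Gaussian with a
#' block-tridiagonal precision, solved by forward block elimination and
#' backward substitution; this is algebraically equivalent to a Kalman
#' filter/RTS smoother run with the expected parameters, with the state
#' prediction quadratic built from \code{J} rather than \code{EA' W EA}.
#'
#' @param series An [observed_series()].
#' @param sys Expected system from [expected_system()].
#' @param x1_mean Initial state mean (defaults to the first observation).
#' @param lambda0 Initial state prior precision (default 1e-3, i.e.
#'   variance 1000).
#' @return A list of class \code{"latent_stats"}: smoothed \code{mean}
#'   (p x T), \code{second} (p x p x T array of \code{<x_t x_t'>}),
#'   \code{cross} (p x p x (T-1) array of \code{<x_{t+1} x_t'>}),
#'   marginal covariances \code{cov}, the posterior log-determinant, and
#'   the pooled sufficient statistics \code{Sxx}, \code{Sxy}, \code{Syy},
#'   \code{obs_ss} used by the M-step.
#' @export
smooth_states <- function(series, sys, x1_mean = NULL, lambda0 = 1e-3) {
  stopifnot(inherits(series, "observed_series"))
  c <- series$condition
  Tg <- series$grid$n_grid
  if (is.null(x1_mean)) x1_mean <- interp_states(series)[, 1]
  res <- smoother_cpp(series$values, series$grid$observed, Tg,
                      sys$w, sys$vr, sys$cond[[c]]$J, sys$cond[[c]]$K,
                      x1_mean, lambda0)
  stats_from_smoother(res, series)
}

# assemble sufficient statistics from raw smoother output
stats_from_smoother <- function(res, series) {
  Tg <- series$grid$n_grid
  p <- nrow(res$mean)
  if (Tg >= 2) {
    Sxx <- rowSums(res$second[, , 1:(Tg - 1), drop = FALSE], dims = 2)
    Syy <- rowSums(res$second[, , 2:Tg, drop = FALSE], dims = 2)
    Sxy <- rowSums(res$cross, dims = 2)
  } else {
    Sxx <- Syy <- Sxy <- matrix(0, p, p)
  }
  obs <- series$grid$observed
  # marginal variances at the observed points: diag of each cov slice
  vdiag <- matrix(res$cov[as.vector(outer((0:(p - 1)) * (p + 1) + 1,
                                          (obs - 1) * p * p, "+"))], p)
  obs_ss <- rowSums((series$values - res$mean[, obs, drop = FALSE])^2 + vdiag)
  structure(list(mean = res$mean, second = res$second, cross = res$cross,
                 cov = res$cov, logdet_sigma = res$logdet_sigma,
                 Sxx = Sxx, Sxy = Sxy, Syy = Syy, obs_ss = obs_ss,
                 n_trans = Tg - 1L, n_obs = length(obs), n_grid = Tg,
                 jitter = res$jitter),
            class = "latent_stats")
}

# linear interpolation of the observations onto the full grid (constant
# extrapolation at the ends); used to initialize the hidden states.
interp_states <- function(series) {
  Tg <- series$grid$n_grid
  obs <- series$grid$observed
  p <- nrow(series$values)
  x <- matrix(0, p, Tg)
  for (i in seq_len(p)) {
    if (length(obs) == 1L) {
      x[i, ] <- series$values[i, 1]
    } else {
      x[i, ] <- stats::approx(obs, series$values[i, ], xout = seq_len(Tg),
                              rule = 2)$y
    }
  }
  rownames(x) <- rownames(series$values)
  x
}

# point-mass latent statistics at a given trajectory (zero posterior
# variance); used for initialization and in tests.
point_stats <- function(x, series) {
  p <- nrow(x); Tg <- ncol(x)
  second <- array(0, c(p, p, Tg))
  for (t in seq_len(Tg)) second[, , t] <- tcrossprod(x[, t])
  cross <- array(0, c(p, p, max(Tg - 1, 1)))
  if (Tg >= 2) for (t in 1:(Tg - 1)) cross[, , t] <- tcrossprod(x[, t + 1], x[, t])
  res <- list(mean = x, second = second, cross = cross,
              cov = array(0, c(p, p, Tg)), logdet_sigma = -Inf, jitter = 0)
  stats_from_smoother(res, series)
}
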