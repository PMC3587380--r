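#' Variational M-step: conjugate parameter posteriors
#'
#' Updates the factorized parameter posterior
#' \code{Q(Theta) = prod_i Q(A_i | h_i) Q(h_i) Q(r_i) prod_j Q(z_ij)} given
#' the latent-state statistics of both conditions and the current edge
#' posteriors.
#'
#' Per target gene i, \code{Q(A_i | h_i)} is Gaussian with mean \code{mu_i}
#' and covariance \code{h_i T_i^-1}, where \code{T_i} pools the masked
#' regression statistics of both conditions (off-diagonal mask
#' \code{e_ij e_ik}, diagonal \code{e_ij}) plus the expected prior precision
#' \code{f_ij / alpha1 + (1 - f_ij) / alpha0} on its diagonal.  \code{Q(h_i)}
#' and \code{Q(r_i)} are inverse-gamma with the usual conjugate updates, and
#' \code{Q(z_ij)} is Beta with the expected disagreement mass of the two
#' conditions' indicators added to \code{zeta_i0} and the agreement mass to
#' \code{zeta_i1}.
#'
#' @param stats List of two \code{latent_stats} (one per condition) from
#'   [smooth_states()].
#' @param edges List with edge-probability matrices \code{e1}, \code{e2}.
#' @param hyper A [hyper_params()].
#' @param point_mass_e EM mode: treat edge values as deterministic, so the
#'   diagonal mask uses \code{e^2}.
#' @return Posterior block of class \code{"var2_theta"}: \code{mu} (p x p,
#'   row i = coefficients onto gene i), \code{prec} and \code{prec_inv}
#'   (p x p x p arrays of the scaled precisions \code{T_i} and inverses),
#'   \code{logdet_prec}, inverse-gamma parameters \code{u, k, v, l}, and
#'   Beta parameters \code{zeta0}, \code{zeta1}.
#' @export
m_step <- function(stats, edges, hyper, point_mass_e = FALSE) {
  p <- nrow(stats[[1]]$Sxx)
  e1 <- edges$e1; e2 <- edges$e2
  f <- indicator_f(e1, e2)
  d <- f / hyper$alpha1 + (1 - f) / hyper$alpha0
  n_trans <- stats[[1]]$n_trans + stats[[2]]$n_trans
  n_obs <- stats[[1]]$n_obs + stats[[2]]$n_obs

  mu <- matrix(0, p, p)
  prec <- array(0, c(p, p, p))
  prec_inv <- array(0, c(p, p, p))
  logdet <- numeric(p)
  k <- numeric(p)
  for (i in seq_len(p)) {
    Ti <- diag(d[i, ], p)
    bi <- numeric(p)
    for (c in 1:2) {
      e <- if (c == 1) e1 else e2
      Om <- tcrossprod(e[i, ])
      diag(Om) <- if (point_mass_e) e[i, ]^2 else e[i, ]
      Ti <- Ti + stats[[c]]$Sxx * Om
      bi <- bi + e[i, ] * stats[[c]]$Sxy[i, ]
    }
    ch <- chol_with_jitter(Ti)
    mu[i, ] <- backsolve(ch, backsolve(ch, bi, transpose = TRUE))
    inv <- chol2inv(ch)
    prec[, , i] <- 0.5 * (Ti + t(Ti))
    prec_inv[, , i] <- 0.5 * (inv + t(inv))
    logdet[i] <- 2 * sum(log(diag(ch)))
    resid <- stats[[1]]$Syy[i, i] + stats[[2]]$Syy[i, i] - sum(bi * mu[i, ])
    k[i] <- hyper$k0 + 0.5 * max(resid, 0)
  }
  u <- rep(hyper$u0 + n_trans / 2, p)
  v <- rep(hyper$v0 + n_obs / 2, p)
  l <- hyper$l0 + 0.5 * (stats[[1]]$obs_ss + stats[[2]]$obs_ss)

  q <- e1 * (1 - e2) + e2 * (1 - e1)   # expected disagreement
  zeta0 <- matrix(rep(hyper$zeta0, length.out = p), p, p) + q
  zeta1 <- matrix(rep(hyper$zeta1, length.out = p), p, p) + (1 - q)

  structure(list(mu = mu, prec = prec, prec_inv = prec_inv,
                 logdet_prec = logdet, u = u, k = k, v = v, l = l,
                 zeta0 = zeta0, zeta1 = zeta1),
            class = "var2_theta")
}

chol_with_jitter <- function(M, max_tries = 6) {
  jit <- 0
  for (tr in seq_len(max_tries)) {
    ch <- tryCatch(chol(M + diag(jit, nrow(M))), error = function(e) NULL)
    if (!is.null(ch)) {
      if (jit > 0)
        message(sprintf("added jitter %g to restore positive definiteness", jit))
      return(ch)
    }
    jit <- if (jit == 0) 1e-9 else jit * 100
  }
  stop("matrix not positive definite even after jitter")
}

#' Variational A-step: annealed update of the edge posteriors
#'
#' Sweeps over every edge-indicator coordinate (both conditions) in
#' Gauss-Seidel fashion, setting each probability to the logistic of
#' \code{Delta / tau}, where \code{Delta} is the expected complete-log-joint
#' difference between the edge being present and absent: the likelihood gain
#' (linear and quadratic in the coefficient moments and state moments,
#' including cross terms with the other regulators' current probabilities),
#' the coefficient-prior gate (which couples to the counterpart condition's
#' probability through the union indicator), and the agreement potential
#' evaluated with the Beta posterior's expected log change probabilities.
#'
#' @param theta Posterior block from [m_step()].
#' @param stats List of two \code{latent_stats}.
#' @param edges Current edge posteriors (list \code{e1}, \code{e2}).
#' @param hyper A [hyper_params()].
#' @param tau Temperature (> 0); as \code{tau} grows all probabilities
#'   flatten towards 1/2, as it cools they approach 0/1.
#' @param sweeps Number of full Gauss-Seidel sweeps (default 5).
#' @param em EM mode: coordinates are deterministic parameters in \[0, 1\]
#'   maximized exactly instead of tempered.
#' @return Updated list with \code{e1}, \code{e2}; probabilities clipped to
#'   \[1e-12, 1 - 1e-12\].
#' @export
a_step <- function(theta, stats, edges, hyper, tau, sweeps = 5L, em = FALSE) {
  if (tau <= 0) stop("'tau' must be positive")
  p <- nrow(theta$mu)
  w <- theta$u / theta$k
  P <- array(0, c(p, p, p))
  for (i in seq_len(p))
    P[, , i] <- w[i] * tcrossprod(theta$mu[i, ]) + theta$prec_inv[, , i]
  Pdiag <- t(vapply(seq_len(p), function(i) diag(P[, , i]), numeric(p)))
  g <- 0.5 * (log(hyper$alpha0 / hyper$alpha1) +
                Pdiag * (1 / hyper$alpha0 - 1 / hyper$alpha1))
  psid <- digamma(theta$zeta0) - digamma(theta$zeta1)
  res <- astep_cpp(edges$e1, edges$e2, theta$mu, P,
                   stats[[1]]$Sxx, stats[[1]]$Sxy,
                   stats[[2]]$Sxx, stats[[2]]$Sxy,
                   w, g, psid, tau, as.integer(sweeps), isTRUE(em))
  list(e1 = res$e1, e2 = res$e2)
}
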