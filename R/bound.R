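#' Annealed variational lower bound
#'
#' Evaluates the lower bound maximized by the inference loop:
#' \code{<log P(Y, X, Theta, E)> + H[Q(X)] + H[Q(Theta)] + tau H[Q(E)]},
#' where the expectations are under the current factorized posterior and the
#' edge-indicator entropy is weighted by the temperature (the tempered bound
#' the annealing update is the exact coordinate maximizer of).  The diffuse
#' initial-state prior used by the smoother is included as a model term so
#' that each step of the loop is an exact coordinate ascent on this single
#' functional.  The untempered variant (edge entropy weighted by 1) is
#' returned alongside for logging.
#'
#' In EM mode the edge values are deterministic parameters: their entropy is
#' dropped and the agreement/gate terms use the continuous edge values.
#'
#' @param data List of two [observed_series()].
#' @param stats List of two \code{latent_stats}.
#' @param theta Posterior block from [m_step()].
#' @param edges Edge posteriors (list \code{e1}, \code{e2}).
#' @param hyper A [hyper_params()].
#' @param tau Temperature.
#' @param em EM mode.
#' @param lambda0 Initial-state prior precision (must match the smoother).
#' @param x1_means List of two initial-state prior means.
#' @return Named numeric vector: \code{bound} (tempered), \code{bound_plain}
#'   (edge entropy unweighted), \code{elogp}, \code{entropy_e}.
#' @export
variational_bound <- function(data, stats, theta, edges, hyper, tau,
                              em = FALSE, lambda0 = 1e-3, x1_means = NULL) {
  p <- nrow(theta$mu)
  e1 <- edges$e1; e2 <- edges$e2
  w <- theta$u / theta$k
  Elh <- digamma(theta$u) - log(theta$k)   # <log 1/h_i>
  vr <- theta$v / theta$l
  Elr <- digamma(theta$v) - log(theta$l)
  if (is.null(x1_means))
    x1_means <- lapply(data, function(s) interp_states(s)[, 1])

  Pdiag <- matrix(0, p, p)
  for (i in seq_len(p))
    Pdiag[i, ] <- w[i] * theta$mu[i, ]^2 + diag(theta$prec_inv[, , i])

  elogp <- 0
  for (c in 1:2) {
    st <- stats[[c]]
    # system transitions
    quad <- numeric(p)
    e <- if (c == 1) e1 else e2
    for (i in seq_len(p)) {
      Pi <- w[i] * tcrossprod(theta$mu[i, ]) + theta$prec_inv[, , i]
      Om <- tcrossprod(e[i, ])
      diag(Om) <- if (em) e[i, ]^2 else e[i, ]
      quad[i] <- w[i] * st$Syy[i, i] -
        2 * w[i] * sum(e[i, ] * theta$mu[i, ] * st$Sxy[i, ]) +
        sum((Pi * Om) * st$Sxx)
    }
    elogp <- elogp + st$n_trans * sum(-0.5 * log(2 * pi) + 0.5 * Elh) -
      0.5 * sum(quad)
    # diffuse initial-state prior
    m1 <- st$mean[, 1]; v1 <- diag(st$cov[, , 1])
    elogp <- elogp + sum(0.5 * log(lambda0 / (2 * pi)) -
                           0.5 * lambda0 * ((m1 - x1_means[[c]])^2 + v1))
    # observations
    elogp <- elogp + st$n_obs * sum(-0.5 * log(2 * pi) + 0.5 * Elr) -
      0.5 * sum(vr * st$obs_ss)
  }
  # gated coefficient prior
  f <- indicator_f(e1, e2)
  elogp <- elogp + sum(-0.5 * log(2 * pi) + 0.5 * matrix(Elh, p, p) -
                         0.5 * (f * log(hyper$alpha1) + (1 - f) * log(hyper$alpha0)) -
                         0.5 * Pdiag * (f / hyper$alpha1 + (1 - f) / hyper$alpha0))
  # noise variance priors
  elogp <- elogp + sum(hyper$u0 * log(hyper$k0) - lgamma(hyper$u0) -
                         (hyper$u0 + 1) * (log(theta$k) - digamma(theta$u)) -
                         hyper$k0 * w)
  elogp <- elogp + sum(hyper$v0 * log(hyper$l0) - lgamma(hyper$v0) -
                         (hyper$v0 + 1) * (log(theta$l) - digamma(theta$v)) -
                         hyper$l0 * vr)
  # agreement potential and Beta prior on z
  q <- e1 * (1 - e2) + e2 * (1 - e1)
  Elz <- digamma(theta$zeta0) - digamma(theta$zeta0 + theta$zeta1)
  El1z <- digamma(theta$zeta1) - digamma(theta$zeta0 + theta$zeta1)
  hz0 <- matrix(rep(hyper$zeta0, length.out = p), p, p)
  hz1 <- matrix(rep(hyper$zeta1, length.out = p), p, p)
  elogp <- elogp + sum(log(0.5) + (q + hz0 - 1) * Elz +
                         (1 - q + hz1 - 1) * El1z - lbeta(hz0, hz1))

  # entropies
  h_x <- 0
  for (c in 1:2)
    h_x <- h_x + 0.5 * p * stats[[c]]$n_grid * (1 + log(2 * pi)) +
      0.5 * stats[[c]]$logdet_sigma
  h_ig <- function(a, b) a + log(b) + lgamma(a) - (1 + a) * digamma(a)
  h_theta <- sum(0.5 * p * (1 + log(2 * pi)) +
                   0.5 * p * (log(theta$k) - digamma(theta$u)) -
                   0.5 * theta$logdet_prec) +
    sum(h_ig(theta$u, theta$k)) + sum(h_ig(theta$v, theta$l))
  zs <- theta$zeta0 + theta$zeta1
  h_theta <- h_theta + sum(lbeta(theta$zeta0, theta$zeta1) -
                             (theta$zeta0 - 1) * digamma(theta$zeta0) -
                             (theta$zeta1 - 1) * digamma(theta$zeta1) +
                             (zs - 2) * digamma(zs))
  ent_bern <- function(e) -e * log(e) - (1 - e) * log(1 - e)
  h_e <- if (em) 0 else sum(ent_bern(e1)) + sum(ent_bern(e2))

  c(bound = elogp + h_x + h_theta + tau * h_e,
    bound_plain = elogp + h_x + h_theta + h_e,
    elogp = elogp, entropy_e = h_e)
}
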