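#' Union indicator of a regulation across conditions
#'
#' \code{F_ij = 1 - (1 - E_ij^(1))(1 - E_ij^(2))}: on binary inputs this is
#' the logical OR of the two conditions' edge indicators; on probabilities it
#' is the probability that the edge exists in at least one condition under
#' independence.  The coefficient prior of \code{A_ij} is gated by this
#' quantity: variance \code{h_i * alpha1} where the union indicator is 1,
#' \code{h_i * alpha0} otherwise.
#'
#' @param e1,e2 Edge probabilities (or 0/1 indicators), in \[0, 1\].
#'   Vectorized.
#' @return \code{1 - (1 - e1) * (1 - e2)}.
#' @examples
#' indicator_f(1, 0)      # 1: edge present in condition 1
#' indicator_f(0.5, 0.5)  # 0.75
#' @export
indicator_f <- function(e1, e2) {
  if (any(e1 < 0 | e1 > 1) || any(e2 < 0 | e2 > 1))
    stop("edge probabilities must lie in [0, 1]")
  1 - (1 - e1) * (1 - e2)
}

#' Pairwise prior on a pair of edge indicators
#'
#' Normalized prior mass of the configuration \code{(e1, e2)} of one edge's
#' indicators under the agreement potential with change probability \code{z}:
#' \code{(1/2) z} when the indicators disagree, \code{(1/2)(1 - z)} when they
#' agree.  Summed over the four binary configurations this is 1 for every z,
#' making it a proper prior; small z favours networks that share the edge
#' status across conditions.
#'
#' @param e1,e2 Binary indicators (0 or 1). Vectorized.
#' @param z Change probability in \[0, 1\].
#' @return Prior probability of the configuration.
#' @export
potential_prior <- function(e1, e2, z) {
  if (!all(e1 %in% c(0, 1)) || !all(e2 %in% c(0, 1)))
    stop("'e1' and 'e2' must be binary")
  if (any(z < 0 | z > 1)) stop("'z' must lie in [0, 1]")
  0.5 * ifelse(e1 != e2, z, 1 - z)
}

# log inverse-gamma density with shape a and inverse scale (rate) b
dinvgamma_log <- function(x, a, b) {
  if (any(x <= 0)) return(-Inf)
  a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
}

#' Complete-data log joint density of the two-condition model
#'
#' Evaluates \code{log P(Y, X, Theta, E)} at a single point: Gaussian system
#' terms for the masked VAR transitions on the full grid, Gaussian
#' observation terms at observed grid points only, the gated Gaussian prior
#' on each coefficient (variance \code{h_i alpha1} when the edge exists in at
#' least one condition, \code{h_i alpha0} otherwise), inverse-gamma priors on
#' the noise variances, and the agreement potential times the Beta prior on
#' the change probabilities.  The initial state x_1 carries no prior of its
#' own; the first system term is the transition from t = 1 to t = 2.
#'
#' @param data List of two [observed_series()].
#' @param x List of two p x T latent state matrices (full grid).
#' @param theta List with elements \code{A} (p x p), \code{h}, \code{r}
#'   (length-p positive vectors) and \code{z} (p x p change probabilities).
#' @param edges List of two p x p binary matrices.
#' @param hyper A [hyper_params()].
#' @return The log joint density (scalar).
#' @export
complete_log_joint <- function(data, x, theta, edges, hyper) {
  check_pair(data)
  p <- n_genes(data[[1]])
  if (any(theta$h <= 0) || any(theta$r <= 0))
    stop("noise variances must be positive")
  e1 <- edges[[1]]; e2 <- edges[[2]]
  if (!all(e1 %in% c(0, 1)) || !all(e2 %in% c(0, 1)))
    stop("'edges' must be binary matrices")
  ll <- 0
  for (c in 1:2) {
    s <- data[[c]]
    xc <- as.matrix(x[[c]])
    Tg <- s$grid$n_grid
    if (ncol(xc) != Tg || nrow(xc) != p) stop("latent state dimensions inconsistent")
    B <- theta$A * edges[[c]]
    if (Tg >= 2) {
      pred <- B %*% xc[, 1:(Tg - 1), drop = FALSE]
      resid <- xc[, 2:Tg, drop = FALSE] - pred
      ll <- ll + sum(stats::dnorm(resid, 0, sqrt(theta$h), log = TRUE))
    }
    obs <- s$grid$observed
    ll <- ll + sum(stats::dnorm(s$values - xc[, obs, drop = FALSE],
                                0, sqrt(theta$r), log = TRUE))
  }
  # prior on A gated through the union indicator
  f <- indicator_f(e1, e2)
  avar <- outer(theta$h, rep(1, p)) * ifelse(f == 1, hyper$alpha1, hyper$alpha0)
  ll <- ll + sum(stats::dnorm(theta$A, 0, sqrt(avar), log = TRUE))
  # noise variance priors
  ll <- ll + sum(dinvgamma_log(theta$h, hyper$u0, hyper$k0))
  ll <- ll + sum(dinvgamma_log(theta$r, hyper$v0, hyper$l0))
  # agreement potential and Beta prior on z (zeta may be per target gene)
  z0 <- rep(hyper$zeta0, length.out = p)
  z1 <- rep(hyper$zeta1, length.out = p)
  ll <- ll + sum(log(potential_prior(e1, e2, theta$z)))
  ll <- ll + sum(stats::dbeta(theta$z, matrix(z0, p, p), matrix(z1, p, p),
                              log = TRUE))
  ll
}
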