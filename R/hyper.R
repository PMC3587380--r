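#' Empirical-Bayes update of an inverse-gamma prior
#'
#' Maximizes \code{sum_i <log IG(h_i; u0, k0)>} over \code{(u0, k0)}, the
#' expectation taken under the current inverse-gamma posteriors
#' \code{IG(u_i, k_i)} (so \code{<log h_i> = log k_i - psi(u_i)} and
#' \code{<1/h_i> = u_i / k_i}).  The inverse scale is profiled out
#' analytically, \code{k0 = p u0 / sum<1/h_i>}, and the remaining strictly
#' concave one-dimensional objective is solved by safeguarded
#' Newton-Raphson.
#'
#' @param shapes Posterior shapes \code{u_i}.
#' @param inv_scales Posterior inverse scales \code{k_i}.
#' @param init Starting value for the shape; because the Newton iteration is
#'   safeguarded to never decrease the objective, starting from the current
#'   hyperparameter guarantees the update never lowers the lower bound.
#' @param max_iter,tol Newton iteration cap and gradient tolerance.
#' @return List with \code{shape} (u0), \code{inv_scale} (k0),
#'   \code{converged}.
#' @export
update_hyper_ig <- function(shapes, inv_scales, init = 1, max_iter = 50L,
                            tol = 1e-10) {
  p <- length(shapes)
  stopifnot(length(inv_scales) == p, all(shapes > 0), all(inv_scales > 0))
  S_lh <- sum(log(inv_scales) - digamma(shapes))   # sum <log h_i>
  S_ih <- sum(shapes / inv_scales)                 # sum <1/h_i>
  obj <- function(u0) {
    k0 <- p * u0 / S_ih
    p * (u0 * log(k0) - lgamma(u0)) - (u0 + 1) * S_lh - k0 * S_ih
  }
  grad <- function(u0) p * (log(u0) - digamma(u0)) + p * log(p / S_ih) - S_lh
  hess <- function(u0) p * (1 / u0 - trigamma(u0))
  u0 <- init
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    gr <- grad(u0)
    if (abs(gr) < tol) { converged <- TRUE; break }
    step <- -gr / hess(u0)
    # safeguarded: stay positive and do not decrease the objective
    new <- u0 + step
    f0 <- obj(u0)
    tries <- 0
    while ((new <= 0 || obj(new) < f0) && tries < 60) {
      step <- step / 2; new <- u0 + step; tries <- tries + 1
    }
    if (tries >= 60) break
    u0 <- min(new, 1e8)
  }
  if (!converged && abs(grad(u0)) > 1e-6)
    warning("inverse-gamma hyperparameter update did not fully converge")
  list(shape = u0, inv_scale = p * u0 / S_ih, converged = converged)
}

#' Empirical-Bayes update of a Beta prior on change probabilities
#'
#' Maximizes \code{sum_j <log Beta(z_ij; zeta_i0, zeta_i1)>} for one target
#' gene's row of Beta posteriors, using
#' \code{<log z_ij> = psi(zeta_ij0) - psi(zeta_ij0 + zeta_ij1)}.  Solved by
#' two-dimensional safeguarded Newton-Raphson on the strictly concave
#' objective.
#'
#' @param zeta0_row,zeta1_row Posterior Beta parameters of the row.
#' @param init Length-2 starting value \code{c(zeta0, zeta1)}; see
#'   [update_hyper_ig()] for why the current hyperparameters are a safe
#'   start.
#' @param max_iter,tol Newton iteration cap and gradient tolerance.
#' @return List with \code{zeta0}, \code{zeta1}, \code{converged}.
#' @export
update_hyper_beta <- function(zeta0_row, zeta1_row, init = c(1, 1),
                              max_iter = 100L, tol = 1e-10) {
  p <- length(zeta0_row)
  stopifnot(length(zeta1_row) == p, all(zeta0_row > 0), all(zeta1_row > 0))
  S0 <- sum(digamma(zeta0_row) - digamma(zeta0_row + zeta1_row)) # sum <log z>
  S1 <- sum(digamma(zeta1_row) - digamma(zeta0_row + zeta1_row)) # sum <log(1-z)>
  obj <- function(th) {
    (th[1] - 1) * S0 + (th[2] - 1) * S1 - p * lbeta(th[1], th[2])
  }
  grad <- function(th) {
    ds <- digamma(th[1] + th[2])
    c(S0 - p * (digamma(th[1]) - ds), S1 - p * (digamma(th[2]) - ds))
  }
  th <- init
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    gr <- grad(th)
    if (max(abs(gr)) < tol * max(1, p)) { converged <- TRUE; break }
    ts <- trigamma(th[1] + th[2])
    H <- -p * matrix(c(trigamma(th[1]) - ts, -ts, -ts, trigamma(th[2]) - ts),
                     2, 2)
    step <- tryCatch(-solve(H, gr), error = function(e) gr) # fall back to ascent
    new <- th + step
    f0 <- obj(th)
    tries <- 0
    while ((any(new <= 0) || obj(new) < f0) && tries < 60) {
      step <- step / 2; new <- th + step; tries <- tries + 1
    }
    if (tries >= 60) break
    th <- pmin(new, 1e8)
  }
  if (!converged && max(abs(grad(th))) > 1e-6)
    warning("Beta hyperparameter update did not fully converge")
  list(zeta0 = th[1], zeta1 = th[2], converged = converged)
}
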