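# Independent oracles used across the suite.  These deliberately use
# different algebra than the package: dense joint-Gaussian inversion instead
# of the block-tridiagonal recursion, plain density summation instead of the
# collected log-joint formula, and closed-form conjugate evidence instead of
# the variational machinery.

# dense joint-Gaussian smoother: builds the full (T p) x (T p) precision and
# inverts it directly.
dense_smoother_oracle <- function(Y, obs, Tg, w, vr, J, K, x1mean,
                                  lambda0 = 1e-3) {
  p <- length(w)
  P <- matrix(0, p * Tg, p * Tg)
  b <- numeric(p * Tg)
  blk <- function(t) ((t - 1) * p + 1):(t * p)
  for (t in 1:Tg) {
    D <- matrix(0, p, p)
    if (t < Tg) D <- D + J
    if (t > 1) {
      D <- D + diag(w, p)
      P[blk(t), blk(t - 1)] <- -K
      P[blk(t - 1), blk(t)] <- -t(K)
    }
    if (t == 1) { D <- D + diag(lambda0, p); b[blk(1)] <- lambda0 * x1mean }
    oi <- match(t, obs)
    if (!is.na(oi)) { D <- D + diag(vr, p); b[blk(t)] <- b[blk(t)] + vr * Y[, oi] }
    P[blk(t), blk(t)] <- P[blk(t), blk(t)] + D
  }
  S <- solve(P)
  mu <- matrix(S %*% b, p, Tg)
  list(mean = mu, S = S, blk = blk,
       second = function(t) S[blk(t), blk(t)] + tcrossprod(mu[, t]),
       cross = function(t) S[blk(t + 1), blk(t)] + tcrossprod(mu[, t + 1], mu[, t]))
}

# textbook Kalman filter + RTS smoother for point-mass parameters
# x1 ~ N(m0, V0 I); x_t = B x_{t-1} + N(0, diag(h)); y_t = x_t + N(0, diag(r))
rts_oracle <- function(Y, obs, Tg, B, h, r, m0, V0) {
  p <- nrow(B)
  H <- diag(h, p); R <- diag(r, p)
  mf <- matrix(0, p, Tg); Pf <- array(0, c(p, p, Tg))
  mp <- matrix(0, p, Tg); Pp <- array(0, c(p, p, Tg))
  m <- m0; V <- diag(V0, p)
  for (t in 1:Tg) {
    if (t > 1) { m <- drop(B %*% m); V <- B %*% V %*% t(B) + H }
    mp[, t] <- m; Pp[, , t] <- V
    oi <- match(t, obs)
    if (!is.na(oi)) {
      Kg <- V %*% solve(V + R)
      m <- m + drop(Kg %*% (Y[, oi] - m))
      V <- (diag(p) - Kg) %*% V
    }
    mf[, t] <- m; Pf[, , t] <- V
  }
  ms <- mf; Ps <- Pf
  G <- array(0, c(p, p, Tg))
  for (t in (Tg - 1):1) {
    Gt <- Pf[, , t] %*% t(B) %*% solve(Pp[, , t + 1])
    ms[, t] <- mf[, t] + drop(Gt %*% (ms[, t + 1] - mp[, t + 1]))
    Ps[, , t] <- Pf[, , t] +
      Gt %*% (Ps[, , t + 1] - Pp[, , t + 1]) %*% t(Gt)
    G[, , t] <- Gt
  }
  cross <- array(0, c(p, p, Tg - 1))
  for (t in 1:(Tg - 1))
    cross[, , t] <- Ps[, , t + 1] %*% t(G[, , t]) + tcrossprod(ms[, t + 1], ms[, t])
  list(mean = ms, cov = Ps, cross = cross, filt_mean = mf, filt_cov = Pf)
}

# plain density-summation oracle for the complete-data log joint
clj_oracle <- function(data, x, theta, edges, hyper) {
  p <- nrow(theta$A)
  ll <- 0
  for (c in 1:2) {
    s <- data[[c]]; xc <- x[[c]]; Tg <- s$grid$n_grid
    B <- theta$A * edges[[c]]
    if (Tg >= 2) for (t in 2:Tg) for (i in 1:p)
      ll <- ll + dnorm(xc[i, t], sum(B[i, ] * xc[, t - 1]),
                       sqrt(theta$h[i]), log = TRUE)
    for (oi in seq_along(s$grid$observed)) {
      t <- s$grid$observed[oi]
      for (i in 1:p)
        ll <- ll + dnorm(s$values[i, oi], xc[i, t], sqrt(theta$r[i]), log = TRUE)
    }
  }
  for (i in 1:p) for (j in 1:p) {
    Fij <- max(edges[[1]][i, j], edges[[2]][i, j])
    al <- if (Fij == 1) hyper$alpha1 else hyper$alpha0
    ll <- ll + dnorm(theta$A[i, j], 0, sqrt(theta$h[i] * al), log = TRUE)
    same <- edges[[1]][i, j] == edges[[2]][i, j]
    ll <- ll + log(0.5 * if (same) 1 - theta$z[i, j] else theta$z[i, j])
    z0 <- rep(hyper$zeta0, length.out = p)[i]
    z1 <- rep(hyper$zeta1, length.out = p)[i]
    ll <- ll + dbeta(theta$z[i, j], z0, z1, log = TRUE)
  }
  for (i in 1:p) {
    ll <- ll + hyper$u0 * log(hyper$k0) - lgamma(hyper$u0) -
      (hyper$u0 + 1) * log(theta$h[i]) - hyper$k0 / theta$h[i]
    ll <- ll + hyper$v0 * log(hyper$l0) - lgamma(hyper$v0) -
      (hyper$v0 + 1) * log(theta$r[i]) - hyper$l0 / theta$r[i]
  }
  unname(ll)
}

# shared enumeration oracle for edge and change metrics
enum_metrics_oracle <- function(est, truth) {
  p <- nrow(est[[1]]$edges)
  etp <- efp <- ctp <- cfp <- 0L
  for (i in 1:p) for (j in 1:p) {
    for (c in 1:2) {
      if (est[[c]]$edges[i, j] == 1) {
        if (truth[[c]]$edges[i, j] == 1) etp <- etp + 1L else efp <- efp + 1L
      }
    }
    if (i != j) {
      e1 <- est[[1]]$edges[i, j]; e2 <- est[[2]]$edges[i, j]
      t1 <- truth[[1]]$edges[i, j]; t2 <- truth[[2]]$edges[i, j]
      if (e1 + e2 == 1) {          # predicted change
        if (t1 == e1 && t2 == e2) ctp <- ctp + 1L else cfp <- cfp + 1L
      }
    }
  }
  list(edge = list(tp = etp, fp = efp),
       change = list(tp = ctp, fp = cfp))
}

# closed-form log evidence of one target-gene row conditioned on the states:
# response xi (n), design Z (n x p), prior A ~ N(0, h D), h ~ IG(u0, k0)
nig_row_evidence <- function(xi, Z, Dv, u0, k0) {
  n <- length(xi); p <- ncol(Z)
  Tm <- crossprod(Z) + diag(1 / Dv, p)
  b <- crossprod(Z, xi)
  mu <- solve(Tm, b)
  S <- sum(xi^2) - sum(b * mu)
  -0.5 * n * log(2 * pi) - 0.5 * (sum(log(Dv)) + determinant(Tm)$modulus[1]) +
    u0 * log(k0) - lgamma(u0) + lgamma(u0 + n / 2) -
    (u0 + n / 2) * log(k0 + 0.5 * S)
}

# brute-force argmax of the marginal likelihood over all edge
# configurations, conditioning on the states at the observations
# (near-noiseless, fully observed instances).  Rows are independent given
# the states, so enumerating the 4^p indicator pairs per row enumerates the
# full 2^(2 p^2) configuration space.
bruteforce_config_oracle <- function(data, hyper) {
  p <- nrow(data[[1]]$values)
  X <- lapply(data, function(s) s$values)
  masks <- as.matrix(expand.grid(rep(list(0:1), p)))
  E1 <- matrix(0L, p, p); E2 <- matrix(0L, p, p)
  z0 <- rep(hyper$zeta0, length.out = p); z1 <- rep(hyper$zeta1, length.out = p)
  for (i in 1:p) {
    best <- -Inf; bestm <- NULL
    for (a in seq_len(nrow(masks))) for (b in seq_len(nrow(masks))) {
      m1 <- masks[a, ]; m2 <- masks[b, ]
      xi <- c(X[[1]][i, -1], X[[2]][i, -1])
      Z <- rbind(t(X[[1]][, -ncol(X[[1]]), drop = FALSE]) *
                   rep(m1, each = ncol(X[[1]]) - 1),
                 t(X[[2]][, -ncol(X[[2]]), drop = FALSE]) *
                   rep(m2, each = ncol(X[[2]]) - 1))
      Fj <- pmax(m1, m2)
      Dv <- ifelse(Fj == 1, hyper$alpha1, hyper$alpha0)
      sc <- nig_row_evidence(xi, Z, Dv, hyper$u0, hyper$k0)
      # exact Beta-integrated pair prior per regulator
      d <- as.numeric(m1 != m2)
      sc <- sc + sum(log(0.5) + lbeta(z0[i] + d, z1[i] + 1 - d) -
                       lbeta(z0[i], z1[i]))
      if (sc > best) { best <- sc; bestm <- list(m1, m2) }
    }
    E1[i, ] <- bestm[[1]]; E2[i, ] <- bestm[[2]]
  }
  list(E1 = E1, E2 = E2)
}

# small random two-condition data set from a stable sparse network
make_tiny_pair <- function(p, Tg, seed, obs_sd = 0.1, frac_common = 0.7) {
  spec <- benchmark_spec(n_genes = p,
                         n_edges = min((p * (p - 1)) %/% 2,
                                       max(p, as.integer(1.5 * p))),
                         obs_sd = obs_sd, frac_common = frac_common,
                         n_timepoints = Tg, seed = seed)
  simulate_conditions(spec, 1)
}

# a valid random posterior block (for moment and smoother tests)
random_theta <- function(p, seed) {
  set.seed(seed)
  prec <- array(0, c(p, p, p)); prec_inv <- array(0, c(p, p, p))
  ld <- numeric(p)
  for (i in 1:p) {
    M <- crossprod(matrix(rnorm(p * p), p)) + diag(p)
    prec[, , i] <- M; prec_inv[, , i] <- solve(M)
    ld[i] <- determinant(M)$modulus[1]
  }
  list(mu = matrix(rnorm(p * p, 0, 0.5), p), prec = prec,
       prec_inv = prec_inv, logdet_prec = ld,
       u = runif(p, 2, 6), k = runif(p, 1, 3),
       v = runif(p, 2, 6), l = runif(p, 1, 3),
       zeta0 = matrix(runif(p * p, 5, 15), p),
       zeta1 = matrix(runif(p * p, 5, 15), p))
}

fast_sched <- function(...) anneal_schedule(cool_factor = 1.3, ...)
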