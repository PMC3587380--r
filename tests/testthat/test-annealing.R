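point_stats_for <- function(series) varnetdiff:::point_stats(
  varnetdiff:::interp_states(series), series)

test_that("m_step recovers the prior when there are no transitions", {
  p <- 2
  g <- time_grid(1)
  set.seed(1)
  Y <- matrix(rnorm(p), p, 1)
  data <- list(observed_series(Y, g, 1), observed_series(Y, g, 2))
  stats <- lapply(data, point_stats_for)
  e <- matrix(0.5, p, p)
  hy <- hyper_params(alpha0 = 0.1, alpha1 = 10)
  th <- m_step(stats, list(e1 = e, e2 = e), hy)
  expect_equal(th$mu, matrix(0, p, p))
  f <- indicator_f(e, e)
  d <- f / hy$alpha1 + (1 - f) / hy$alpha0
  for (i in 1:p) expect_equal(th$prec[, , i], diag(d[i, ]))
  expect_equal(th$u, rep(hy$u0, p))          # no transitions pooled
  expect_equal(th$k, rep(hy$k0, p))
})

test_that("m_step reduces to pooled least squares when edges are certain and the prior is flat", {
  p <- 3; Tg <- 40
  sim <- make_tiny_pair(p, Tg, seed = 5)
  # identical deterministic edge posteriors of all ones; huge alpha1
  e <- matrix(1, p, p)
  stats <- lapply(sim$data, point_stats_for)
  hy <- hyper_params(alpha0 = 1e11, alpha1 = 1e12)
  th <- m_step(stats, list(e1 = e, e2 = e), hy)
  X <- lapply(sim$data, function(s) s$values)
  Sxx <- Sxy <- matrix(0, p, p)
  for (c in 1:2) {
    Z <- X[[c]][, -Tg, drop = FALSE]; W <- X[[c]][, -1, drop = FALSE]
    Sxx <- Sxx + tcrossprod(Z); Sxy <- Sxy + tcrossprod(W, Z)
  }
  ols <- unname(t(solve(Sxx, t(Sxy))))
  expect_equal(th$mu, ols, tolerance = 1e-6)
})

test_that("Beta updates add hard-assigned agreement and disagreement counts", {
  p <- 2
  sim <- make_tiny_pair(p, 5, seed = 6)
  stats <- lapply(sim$data, point_stats_for)
  e1 <- matrix(c(1, 0, 1, 1), p); e2 <- matrix(c(1, 1, 0, 1), p)
  hy <- hyper_params(zeta0 = 10, zeta1 = 10)
  th <- m_step(stats, list(e1 = e1, e2 = e2), hy)
  disagree <- (e1 != e2) * 1
  expect_equal(th$zeta0, 10 + disagree)
  expect_equal(th$zeta1, 10 + (1 - disagree))
})

test_that("posterior inverse-scale of the system noise stays positive", {
  for (seed in 1:5) {
    sim <- make_tiny_pair(3, 8, seed = 100 + seed)
    stats <- lapply(sim$data, point_stats_for)
    set.seed(seed)
    e <- list(e1 = matrix(runif(9), 3), e2 = matrix(runif(9), 3))
    th <- m_step(stats, e, hyper_params())
    expect_true(all(th$k > 0))
    expect_true(all(th$l > 0))
  }
})

test_that("infinite temperature flattens the edge posteriors to one half", {
  sim <- make_tiny_pair(2, 10, seed = 7)
  stats <- lapply(sim$data, point_stats_for)
  edges <- list(e1 = matrix(0.5, 2, 2), e2 = matrix(0.5, 2, 2))
  th <- m_step(stats, edges, hyper_params())
  up <- a_step(th, stats, edges, hyper_params(), tau = 1e14, sweeps = 5)
  expect_equal(up$e1, matrix(0.5, 2, 2), tolerance = 1e-10)
  expect_equal(up$e2, matrix(0.5, 2, 2), tolerance = 1e-10)
})

test_that("a_step fixed point is coordinatewise optimal for the tempered bound", {
  sim <- make_tiny_pair(2, 12, seed = 8)
  hy <- hyper_params()
  ctl <- fit_control(lambda0 = 1e-3)
  stats <- lapply(sim$data, point_stats_for)
  edges <- list(e1 = matrix(0.5, 2, 2), e2 = matrix(0.5, 2, 2))
  th <- m_step(stats, edges, hy)
  sys <- expected_system(th, edges)
  stats <- lapply(1:2, function(c) smooth_states(sim$data[[c]], sys))
  for (tau in c(1, 0.3)) {
    e <- edges
    for (rep in 1:60) e <- a_step(th, stats, e, hy, tau, sweeps = 1)
    b0 <- variational_bound(sim$data, stats, th, e, hy, tau)[["bound"]]
    grid <- seq(1e-6, 1 - 1e-6, length.out = 41)
    for (cc in c("e1", "e2")) for (i in 1:2) for (j in 1:2) {
      vals <- vapply(grid, function(g) {
        e2 <- e; e2[[cc]][i, j] <- g
        variational_bound(sim$data, stats, th, e2, hy, tau)[["bound"]]
      }, numeric(1))
      expect_lte(max(vals), b0 + 1e-7 * abs(b0))
    }
  }
})

test_that("inverse-gamma hyperparameter update is self-consistent and beats a grid", {
  # identical posteriors: the maximizer reproduces their parameters
  up <- update_hyper_ig(rep(3.2, 4), rep(1.7, 4), init = 1)
  expect_equal(up$shape, 3.2, tolerance = 1e-6)
  expect_equal(up$inv_scale, 1.7, tolerance = 1e-6)
  # random posteriors: no grid point beats the returned maximizer
  set.seed(2)
  u <- runif(3, 1, 6); k <- runif(3, 0.5, 3)
  up <- update_hyper_ig(u, k, init = 1)
  S_lh <- sum(log(k) - digamma(u)); S_ih <- sum(u / k)
  obj <- function(u0, k0) 3 * (u0 * log(k0) - lgamma(u0)) -
    (u0 + 1) * S_lh - k0 * S_ih
  best <- max(outer(seq(0.05, 12, length.out = 100),
                    seq(0.05, 12, length.out = 100), Vectorize(obj)))
  expect_gte(obj(up$shape, up$inv_scale), best)
  # stationarity of the profiled objective
  eps <- 1e-5
  g1 <- (obj(up$shape + eps, up$inv_scale) - obj(up$shape - eps, up$inv_scale)) / (2 * eps)
  g2 <- (obj(up$shape, up$inv_scale + eps) - obj(up$shape, up$inv_scale - eps)) / (2 * eps)
  expect_lt(max(abs(c(g1, g2))), 1e-5)
})

test_that("Beta hyperparameter update is self-consistent and beats a grid", {
  up <- update_hyper_beta(rep(7.5, 5), rep(2.5, 5), init = c(1, 1))
  expect_equal(up$zeta0, 7.5, tolerance = 1e-5)
  expect_equal(up$zeta1, 2.5, tolerance = 1e-5)
  set.seed(3)
  z0 <- runif(4, 2, 12); z1 <- runif(4, 2, 12)
  up <- update_hyper_beta(z0, z1, init = c(1, 1))
  S0 <- sum(digamma(z0) - digamma(z0 + z1))
  S1 <- sum(digamma(z1) - digamma(z0 + z1))
  obj <- function(a, b) (a - 1) * S0 + (b - 1) * S1 - 4 * lbeta(a, b)
  best <- max(outer(seq(0.1, 25, length.out = 100),
                    seq(0.1, 25, length.out = 100), Vectorize(obj)))
  expect_gte(obj(up$zeta0, up$zeta1), best)
  eps <- 1e-5
  g1 <- (obj(up$zeta0 + eps, up$zeta1) - obj(up$zeta0 - eps, up$zeta1)) / (2 * eps)
  g2 <- (obj(up$zeta0, up$zeta1 + eps) - obj(up$zeta0, up$zeta1 - eps)) / (2 * eps)
  expect_lt(max(abs(c(g1, g2))), 1e-5)
})

test_that("the temperature ladder starts at 2.5 and cools by 1.05", {
  sched <- anneal_schedule()
  taus <- varnetdiff:::anneal_temperatures(sched)
  expect_equal(taus[1:3], c(2.5, 2.5 / 1.05, 2.5 / 1.05^2))
  expect_true(all(taus > sched$tau_min))
  expect_lt(taus[length(taus)] / sched$cool_factor, sched$tau_min)
})

test_that("identical conditions yield identical networks and no changes", {
  spec <- benchmark_spec(n_genes = 5L, n_edges = 7L, n_timepoints = 25L,
                         seed = 11L)
  g0 <- make_base_network(spec)
  s1 <- simulate_series(g0, 25L, 1, 0.1, "equal", seed = 21L, condition = 1L)
  s2 <- s1; s2$condition <- 2L
  fit <- anneal_fit(list(s1, s2), sched = fast_sched())
  expect_equal(fit$networks[[1]]$edges, fit$networks[[2]]$edges)
  expect_equal(fit$edges$e1, fit$edges$e2, tolerance = 1e-8)
  cm <- change_metrics(fit, list(g0, g0))
  expect_equal(cm$tp + cm$fp, 0L)
})

test_that("a single strong regulation is called with near-certain posteriors", {
  # 2 genes: gene 1 drives gene 2, plus stabilizing autoloops
  A <- matrix(c(0.6, 0, 0.8, 0.5), 2, byrow = TRUE)
  g <- network_model(A)
  s1 <- simulate_series(g, 20L, 1, 0.05, "equal", seed = 31L, condition = 1L)
  s2 <- simulate_series(g, 20L, 1, 0.05, "equal", seed = 32L, condition = 2L)
  fit <- anneal_fit(list(s1, s2), sched = fast_sched())
  expect_gt(fit$edges$e1[2, 1], 0.99)   # true cross edge
  expect_lt(fit$edges$e1[1, 2], 0.01)   # absent reverse edge
  expect_gt(fit$edges$e2[2, 1], 0.99)
  # posteriors are near-binary at the final temperature
  margin <- max(pmin(c(fit$edges$e1, fit$edges$e2),
                     1 - c(fit$edges$e1, fit$edges$e2)))
  expect_lt(margin, 0.05)
})

test_that("EM mode runs a single unit temperature and mirrors the interface", {
  sim <- make_tiny_pair(3, 12, seed = 13)
  emf <- em_fit(sim$data)
  expect_equal(unique(emf$bound_trace$tau), 1)
  anf <- anneal_fit(sim$data, sched = fast_sched())
  expect_equal(dim(emf$theta$mu), dim(anf$theta$mu))
  expect_equal(dim(emf$edges$e1), dim(anf$edges$e1))
  expect_s3_class(emf$networks[[1]], "network_model")
  expect_identical(emf$mode, "em")
})

test_that("alpha0 selection returns the single grid value and accounts residuals", {
  sim <- make_tiny_pair(2, 8, seed = 14)
  sel <- select_alpha0(sim$data, 0.05, sched = fast_sched(), thin = 3L)
  expect_equal(sel$alpha0, 0.05)
  expect_equal(unname(sel$score), sum(sel$folds), tolerance = 1e-12)
  expect_error(select_alpha0(sim$data, numeric(0)), "non-empty")
  expect_error(select_alpha0(sim$data, 2000), "below alpha1")
})

test_that("alpha0 selection favours a value that recovers a clean network", {
  sim <- make_tiny_pair(3, 20, seed = 15, obs_sd = 0.02)
  sel <- select_alpha0(sim$data, c(0.01, 1), sched = fast_sched(), thin = 4L)
  hy <- hyper_params(); hy$alpha0 <- sel$alpha0
  fit <- anneal_fit(sim$data, hy, fast_sched())
  met <- edge_metrics(fit, sim$truth)
  expect_gte(met$precision, 0.8)
})

test_that("dimension mismatches are rejected", {
  sim <- make_tiny_pair(2, 6, seed = 16)
  bad <- sim$data
  bad[[2]] <- observed_series(matrix(0, 3, 6), time_grid(6), 2L)
  expect_error(anneal_fit(bad), "same gene set")
})
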