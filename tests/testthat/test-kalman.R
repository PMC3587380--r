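test_that("expected system reduces to plug-in matrices for point-mass posteriors", {
  p <- 3
  A <- matrix(c(0.5, 0, 0.2, 0, -0.6, 0, 0, 0.4, 0.7), p, byrow = TRUE)
  h <- c(1, 2, 0.5); r <- c(0.1, 0.1, 0.1)
  big <- 1e12   # near point-mass IG posteriors: <1/h> = u/k
  theta <- list(mu = A,
                prec = array(diag(big, p), c(p, p, p)),
                prec_inv = array(diag(1 / big, p), c(p, p, p)),
                logdet_prec = rep(p * log(big), p),
                u = big * h, k = big * h^2, v = big * r, l = big * r^2,
                zeta0 = matrix(10, p, p), zeta1 = matrix(10, p, p))
  E <- matrix(c(1, 0, 1, 0, 1, 0, 0, 1, 1), p, byrow = TRUE)
  sys <- expected_system(theta, list(e1 = E, e2 = 1 - E))
  B <- A * E
  expect_equal(sys$cond[[1]]$EA, B, tolerance = 1e-6)
  expect_equal(sys$cond[[1]]$K, diag(1 / h) %*% B, tolerance = 1e-6)
  expect_equal(sys$cond[[1]]$J, t(B) %*% diag(1 / h) %*% B, tolerance = 1e-6)
  expect_equal(sys$w, 1 / h, tolerance = 1e-9)
  expect_equal(sys$vr, 1 / r, tolerance = 1e-9)
})

test_that("expected effective network is linear in the edge probabilities", {
  theta <- random_theta(2, 5)
  sys <- expected_system(theta, list(e1 = matrix(0.5, 2, 2),
                                     e2 = matrix(0.5, 2, 2)))
  expect_equal(sys$cond[[1]]$EA, 0.5 * theta$mu)
  expect_equal(sys$cond[[2]]$EA, 0.5 * theta$mu)
})

test_that("expected system moments match Monte-Carlo draws from the posterior", {
  p <- 2
  theta <- random_theta(p, 9)
  e <- matrix(c(0.9, 0.3, 0.5, 0.7), p)
  sys <- expected_system(theta, list(e1 = e, e2 = e))
  n <- 1e6
  set.seed(99)
  EA_mc <- matrix(0, p, p); K_mc <- matrix(0, p, p); J_mc <- matrix(0, p, p)
  Asamp <- vector("list", p); hsamp <- vector("list", p)
  for (i in 1:p) {
    h <- 1 / rgamma(n, theta$u[i], rate = theta$k[i])  # h ~ IG(u, k)
    L <- chol(theta$prec_inv[, , i])
    Ai <- matrix(rnorm(n * p), n) %*% L * sqrt(h) +
      matrix(theta$mu[i, ], n, p, byrow = TRUE)
    Asamp[[i]] <- Ai; hsamp[[i]] <- h
  }
  Esamp <- array(0, c(n, p, p))
  for (i in 1:p) for (j in 1:p) Esamp[, i, j] <- rbinom(n, 1, e[i, j])
  for (i in 1:p) {
    AE <- Asamp[[i]] * Esamp[, i, ]
    EA_mc[i, ] <- colMeans(AE)
    K_mc[i, ] <- colMeans(AE / hsamp[[i]])
    J_mc <- J_mc + crossprod(AE / sqrt(hsamp[[i]])) / n
  }
  se <- 3 * max(abs(theta$mu)) / sqrt(n) * 50   # generous 3-SE style band
  expect_lt(max(abs(sys$cond[[1]]$EA - EA_mc)), se)
  expect_lt(max(abs(sys$cond[[1]]$K - K_mc)), se)
  expect_lt(max(abs(sys$cond[[1]]$J - J_mc)), se)
})

test_that("smoother agrees with a textbook RTS smoother under point-mass parameters", {
  p <- 2; Tg <- 5
  A <- matrix(c(0.7, 0.2, -0.3, 0.5), p)
  h <- c(0.8, 1.2); r <- c(0.3, 0.4)
  set.seed(4)
  Y <- matrix(rnorm(p * Tg), p)
  ser <- observed_series(Y, time_grid(Tg), 1L)
  sys <- list(cond = list(list(EA = A, K = diag(1 / h) %*% A,
                               J = t(A) %*% diag(1 / h) %*% A)),
              w = 1 / h, vr = 1 / r)
  st <- smooth_states(ser, sys, x1_mean = Y[, 1], lambda0 = 1e-3)
  or <- rts_oracle(Y, 1:Tg, Tg, A, h, r, Y[, 1], 1e3)
  expect_equal(st$mean, or$mean, tolerance = 1e-8)
  for (t in 1:Tg)
    expect_equal(st$second[, , t], or$cov[, , t] + tcrossprod(or$mean[, t]),
                 tolerance = 1e-8)
  for (t in 1:(Tg - 1))
    expect_equal(st$cross[, , t], or$cross[, , t], tolerance = 1e-8)
  # smoothing can only tighten the filtered covariance (Loewner order)
  for (t in 1:Tg) {
    dif <- or$filt_cov[, , t] - st$cov[, , t]
    expect_gt(min(eigen(0.5 * (dif + t(dif)), only.values = TRUE)$values), -1e-8)
  }
})

test_that("smoother matches dense joint-Gaussian inversion with skipped observations", {
  p <- 2; Tg <- 5
  theta <- random_theta(p, 17)
  edges <- list(e1 = matrix(runif(p * p), p), e2 = matrix(runif(p * p), p))
  sys <- expected_system(theta, edges)
  for (obs in list(c(1L, 3L, 5L), c(2L, 5L), 5L)) {
    set.seed(100 + length(obs))
    Y <- matrix(rnorm(p * length(obs)), p)
    ser <- observed_series(Y, new_time_grid(Tg, obs), 1L)
    x1m <- rep(0.5, p)
    st <- smooth_states(ser, sys, x1_mean = x1m)
    or <- dense_smoother_oracle(Y, obs, Tg, sys$w, sys$vr,
                                sys$cond[[1]]$J, sys$cond[[1]]$K, x1m)
    expect_equal(st$mean, or$mean, tolerance = 1e-8)
    for (t in 1:Tg)
      expect_equal(st$second[, , t], or$second(t), tolerance = 1e-8)
    for (t in 1:(Tg - 1))
      expect_equal(st$cross[, , t], or$cross(t), tolerance = 1e-8)
  }
})

test_that("noiseless observations pin the smoothed means to the data", {
  p <- 2; Tg <- 6
  theta <- random_theta(p, 23)
  theta$v <- c(1e8, 1e8); theta$l <- c(1e-4, 1e-4)  # <1/r> = 1e12
  edges <- list(e1 = matrix(0.5, p, p), e2 = matrix(0.5, p, p))
  sys <- expected_system(theta, edges)
  set.seed(5)
  Y <- matrix(rnorm(p * Tg), p)
  ser <- observed_series(Y, time_grid(Tg), 1L)
  st <- smooth_states(ser, sys)
  expect_equal(st$mean, Y, tolerance = 1e-4)
})

test_that("single anchored observation propagates through the expected dynamics", {
  p <- 2; Tg <- 4
  theta <- random_theta(p, 29)
  edges <- list(e1 = matrix(runif(4), 2), e2 = matrix(runif(4), 2))
  sys <- expected_system(theta, edges)
  Y <- matrix(c(1.5, -0.5), p, 1)
  ser <- observed_series(Y, new_time_grid(Tg, 4L), 1L)
  st <- smooth_states(ser, sys, x1_mean = c(0, 0))
  or <- dense_smoother_oracle(Y, 4L, Tg, sys$w, sys$vr,
                              sys$cond[[1]]$J, sys$cond[[1]]$K, c(0, 0))
  expect_equal(st$mean, or$mean, tolerance = 1e-8)
  for (t in 1:(Tg - 1))
    expect_equal(st$cross[, , t], or$cross(t), tolerance = 1e-8)
})
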