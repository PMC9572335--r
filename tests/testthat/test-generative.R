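test_that("zero-initialized drift is the zero field; evaluation is pure", {
  p <- sde_init(c(2, 5, 2), seed = 1)
  p$drift_net <- zero_mlp(p$drift_net)
  expect_equal(drift(c(0.3, -1), p), c(0, 0))
  p2 <- sde_init(c(2, 5, 2), seed = 2)
  z <- c(0.7, -0.2)
  expect_identical(drift(z, p2), drift(z, p2))
  expect_error(drift(c(Inf, 0), p2), class = "motionsde_invalid_argument")
})

test_that("drift gradient w.r.t. z matches central differences", {
  p <- sde_init(c(2, 8, 8, 2), seed = 4)
  z <- c(0.4, -0.9)
  fw <- mlp_forward(p$drift_net, z)
  for (comp in 1:2) {
    dY <- matrix(0, 1, 2); dY[comp] <- 1
    ana <- mlp_backward(p$drift_net, fw$cache, dY)$dX[1, ]
    num <- numeric_gradient(function(v) mlp_forward(p$drift_net, v)$out[comp], z)
    expect_equal(ana, num, tolerance = 1e-4)
  }
})

test_that("Euler-Maruyama step arithmetic", {
  # mu = 0, sigma -> small, any dt: identity
  p0 <- sde_init(c(2, 2), sigma = 1e-12, dt = 0.5, seed = 1)
  p0$drift_net <- zero_mlp(p0$drift_net)
  expect_equal(euler_maruyama_step(c(1, 2), p0, c(0, 0)), c(1, 2))

  # linear drift mu(z) = -z, dt = 0.1, no noise: contraction by 0.9
  pl <- sde_init(c(2, 2), sigma = 1e-12, dt = 0.1, seed = 1)
  pl$drift_net$params$W[[1]] <- -diag(2)
  expect_equal(euler_maruyama_step(c(1, 0), pl, c(0, 0)), c(0.9, 0))

  # pure diffusion: sigma * sqrt(dt) * eps
  pd <- sde_init(c(2, 2), sigma = 0.5, dt = 1, seed = 1)
  pd$drift_net <- zero_mlp(pd$drift_net)
  expect_equal(euler_maruyama_step(c(0, 0), pd, c(2, 0)), c(1, 0))

  expect_error(sde_init(c(2, 2), dt = 0), class = "motionsde_invalid_argument")
})

test_that("transition density is the Euler-Maruyama Gaussian", {
  p <- sde_init(c(2, 4, 2), sigma = 0.3, dt = 1, seed = 2)
  p$drift_net <- zero_mlp(p$drift_net)
  td <- transition_density(c(0.5, -0.5), p)
  expect_equal(td$mean, c(0.5, -0.5))
  expect_equal(td$cov, diag(0.09, 2))

  # Monte-Carlo consistency of the step sampler with the density
  p2 <- sde_init(c(2, 6, 2), sigma = 0.4, dt = 0.5, seed = 3)
  z <- c(0.2, 0.8)
  td2 <- transition_density(z, p2)
  draws <- with_rng(10, matrix(rnorm(2e5), 1e5, 2))
  step1 <- t(apply(draws, 1, function(e) euler_maruyama_step(z, p2, e)))
  se <- sqrt(td2$cov[1, 1] / 1e5)
  expect_lt(max(abs(colMeans(step1) - td2$mean)), 3 * se)
  expect_equal(apply(step1, 2, stats::var), rep(td2$cov[1, 1], 2),
               tolerance = 0.05)
})

test_that("trajectories: ODE limit, contraction, seeding", {
  pl <- sde_init(c(2, 2), sigma = 1e-300, dt = 0.1, seed = 1)
  pl$drift_net$params$W[[1]] <- -diag(2)
  tr <- sample_trajectory(c(1, 1), 50, pl, seed = 1)
  norms <- sqrt(rowSums(tr^2))
  expect_true(all(diff(norms) < 0))
  # sigma ~ 0 equals the forward-Euler solution exactly
  expect_equal(tr[51, ], c(1, 1) * 0.9^50, tolerance = 1e-10)

  ps <- sde_init(c(2, 4, 2), sigma = 0.3, dt = 1, seed = 2)
  t1 <- sample_trajectory(c(0, 0), 20, ps, seed = 5)
  t2 <- sample_trajectory(c(0, 0), 20, ps, seed = 5)
  t3 <- sample_trajectory(c(0, 0), 20, ps, seed = 6)
  expect_identical(t1, t2)
  expect_false(identical(t1, t3))
})

test_that("OU stationary variance matches the closed form", {
  # drift fixed to mu(z) = -z, sigma = 0.5, dt = 0.1:
  # var_inf = sigma^2 dt / (1 - (1 - dt)^2)
  p <- sde_init(c(2, 2), sigma = 0.5, dt = 0.1, seed = 1)
  p$drift_net$params$W[[1]] <- -diag(2)
  tr <- sample_trajectory(c(0, 0), 1e5, p, seed = 42)
  v_theory <- 0.5^2 * 0.1 / (1 - 0.9^2)
  v_emp <- apply(tr[-(1:1000), ], 2, stats::var)
  expect_equal(v_emp, rep(v_theory, 2), tolerance = 0.05)
})

test_that("decoder Gaussian log density closed forms", {
  d <- decoder_init(c(2, 5, 4), obs_log_sd = log(0.7), seed = 1)
  g <- decode(c(0.1, 0.2), d)
  ld_at_mean <- g$log_density(g$mean)
  expect_equal(ld_at_mean, -4 * (log(0.7) + 0.5 * log(2 * pi)))

  d2 <- d; d2$obs_log_sd <- log(1.4)
  g2 <- decode(c(0.1, 0.2), d2)
  expect_equal(ld_at_mean - g2$log_density(g2$mean), 4 * log(2))

  dz <- decoder_init(c(2, 5, 4), seed = 2)
  dz$decoder_net$params$W[[2]][] <- 0
  dz$decoder_net$params$b[[2]][] <- 0
  expect_equal(decode(c(3, -3), dz)$mean, matrix(0, 1, 4))
})

test_that("PCA prior: centering, linearity, and exact plane recovery", {
  X <- with_rng(3, matrix(rnorm(400), 100, 4))
  pr <- fit_prior(X)
  expect_equal(prior_mean(colMeans(X), pr), c(0, 0), tolerance = 1e-12)

  u <- rnorm(4); v <- rnorm(4)
  lin <- prior_mean(colMeans(X) + 2 * u + 3 * v, pr)
  parts <- 2 * (prior_mean(colMeans(X) + u, pr)) +
    3 * (prior_mean(colMeans(X) + v, pr))
  expect_equal(lin, parts, tolerance = 1e-10)

  # data exactly on a known 2-D plane: projection reconstructs it exactly
  B <- qr.Q(qr(matrix(rnorm(8), 4, 2)))          # orthonormal basis
  coords <- with_rng(4, matrix(rnorm(120), 60, 2) %*% diag(c(3, 1.5)))
  planar <- coords %*% t(B)
  pr2 <- fit_prior(planar)
  Z <- prior_mean(planar, pr2)
  recon <- sweep(Z %*% t(pr2$rotation), 2, pr2$center, "+")
  expect_equal(recon, planar, tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: largest loading of each component is positive
  for (j in 1:2) expect_gt(pr2$rotation[which.max(abs(pr2$rotation[, j])), j], 0)

  expect_error(prior_mean(rep(0, 4), structure(list(), class = "lst")),
               class = "motionsde_not_fitted")
})
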