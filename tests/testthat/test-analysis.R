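test_that("trailing moving average shapes and worked values", {
  expect_equal(smooth_trajectory(rep(3.5, 10)), rep(3.5, 10))
  expect_equal(smooth_trajectory(c(0, 0, 0, 0, 5), window = 5)[5], 1)
  expect_equal(smooth_trajectory(c(0, 0, 0, 0, 5), window = 5),
               c(0, 0, 0, 0, 1))
  m <- matrix(rnorm(40), 20, 2)
  expect_equal(dim(smooth_trajectory(m)), dim(m))
  # trailing: first entries average the shorter available history
  expect_equal(smooth_trajectory(c(2, 4, 6), window = 5), c(2, 3, 4))
  expect_error(smooth_trajectory(1:5, window = 0),
               class = "motionsde_invalid_argument")
})

test_that("KDE closed form, locality, and threshold calibration", {
  # single point with forced bandwidth h: density at the point = 1/(2 pi h^2)
  r1 <- fit_latent_region(matrix(c(0.5, -0.5), 1, 2), "one", bandwidth = 0.3)
  expect_equal(kde_density(r1, c(0.5, -0.5)), 1 / (2 * pi * 0.3^2))

  pts <- with_rng(2, matrix(rnorm(800), 400, 2))
  r <- fit_latent_region(pts, "walking")
  expect_gt(kde_density(r, pts[1, ]), kde_density(r, c(100, 100)))
  # ~95% of training points are members at the 5th-percentile threshold
  frac <- mean(region_membership(pts, r)$member)
  expect_gte(frac, 0.94)
  expect_lte(frac, 0.96)
  # extreme points are non-members with ~zero density
  far <- region_membership(c(1e6, 1e6), r)
  expect_false(far$member)
  expect_lt(far$density, 1e-12)
  # purity: batched and single evaluations agree
  expect_equal(region_membership(pts[5, ], r)$density,
               region_membership(pts, r)$density[5])

  expect_error(fit_latent_region(matrix(1, 20, 2), "flat"),
               class = "motionsde_degenerate_data")
  expect_error(fit_latent_region(matrix(rnorm(10), 5, 2), "few"),
               class = "motionsde_invalid_argument")
})

test_that("region density integrates to about 1", {
  pts <- with_rng(3, matrix(rnorm(400, sd = c(1, 2)), 200, 2, byrow = TRUE))
  r <- fit_latent_region(pts, "m")
  lo <- apply(pts, 2, min) - 4 * max(r$bandwidth)
  hi <- apply(pts, 2, max) + 4 * max(r$bandwidth)
  grid_n <- 4e4
  qp <- with_rng(4, cbind(runif(grid_n, lo[1], hi[1]),
                          runif(grid_n, lo[2], hi[2])))
  vol <- prod(hi - lo)
  integral <- mean(kde_density(r, qp)) * vol
  expect_equal(integral, 1, tolerance = 0.05)
})

test_that("switch labeling on synthetic latent clouds", {
  set.seed(11)
  walk_pts <- matrix(rnorm(600, sd = 0.4), 300, 2)
  run_pts <- sweep(matrix(rnorm(600, sd = 0.4), 300, 2), 2, c(5, 5), "+")
  regions <- list(walking = fit_latent_region(walk_pts, "walking"),
                  running = fit_latent_region(run_pts, "running"))

  # trajectory drawn from walking training latents: all walking, 0 switches
  det <- detect_motion_switch(walk_pts[1:80, ], regions)
  expect_true(all(det$labels == "walking"))
  expect_length(det$switch_indices, 0)

  # far-away trajectory: all abnormal, 0 switches
  far <- sweep(matrix(rnorm(80, sd = 0.1), 40, 2), 2, c(50, -50), "+")
  det_far <- detect_motion_switch(far, regions)
  expect_true(all(det_far$labels == "abnormal"))
  expect_length(det_far$switch_indices, 0)

  # a hard jump between the clouds: exactly one switch (smoothing lag only)
  traj <- rbind(walk_pts[1:60, ], run_pts[1:60, ])
  det_sw <- detect_motion_switch(traj, regions, window = 5)
  expect_length(det_sw$switch_indices, 1)
  expect_lte(abs(det_sw$switch_indices - 61), 5)

  expect_error(detect_motion_switch(traj, regions["walking"]),
               class = "motionsde_invalid_argument")
})

test_that("initial-state optimization solves the linear toy exactly", {
  # zero drift, single linear decoder layer W, constant observations:
  # the optimum is the least-squares solution of z W = c
  m <- tiny_model(T = 8, seed = 12)
  m$sde$drift_net <- zero_mlp(m$sde$drift_net)
  m$decoder$decoder_net <- mlp_init(c(2, 4), seed = 1)
  W <- matrix(c(1, 0.5, -0.3, 0.8, 0.2, -1, 0.7, 0.1), 2, 4)
  m$decoder$decoder_net$params$W[[1]] <- W
  m$prior <- plain_prior()
  cvec <- c(0.8, -0.4, 0.3, 1.1)
  obs <- matrix(cvec, 6, 4, byrow = TRUE)
  res <- optimize_initial_state(obs, m, n_iter = 4000, lr = 0.05)
  z_star <- drop(cvec %*% t(W) %*% solve(W %*% t(W)))
  expect_equal(res$z_init_star, z_star, tolerance = 1e-4)
  # zero drift: the propagated z0 equals the optimized start
  expect_equal(res$z0_estimate, res$z_init_star)
})

test_that("initial-state optimization is monitored descent with a fallback", {
  m <- tiny_model(T = 8, seed = 13)
  m$prior <- fit_prior(with_rng(1, matrix(rnorm(80), 20, 4)))
  obs <- with_rng(2, matrix(rnorm(24), 6, 4))
  res <- optimize_initial_state(obs, m, n_iter = 200)
  expect_s3_class(res, "init_state_result")
  expect_lte(res$final_discrepancy, res$initial_discrepancy)
  expect_lte(res$final_discrepancy, res$trace[1])
  expect_true(all(diff(res$trace) <= 0))
  expect_false(res$fallback)

  # restarting at a previously found optimum cannot improve it
  res2 <- optimize_initial_state(obs, m, n_iter = 200,
                                 z_init = res$z_init_star)
  expect_lte(res2$final_discrepancy, res$final_discrepancy + 1e-12)
})

test_that("user identification scoring conventions", {
  net0 <- zero_mlp(mlp_init(c(6, 4, 1), seed = 1))
  x <- with_rng(5, matrix(rnorm(40), 10, 4))
  za <- with_rng(6, matrix(rnorm(20), 10, 2))
  zb <- with_rng(7, matrix(rnorm(20), 10, 2))
  sc <- user_identification_score(x, za, zb, net0)
  expect_equal(sc$accuracy, 0.5)           # chance level for the zero net
  expect_true(all(sc$prob_same > 0 & sc$prob_same < 1))
  expect_true(all(sc$prob_other > 0 & sc$prob_other < 1))
  net <- mlp_init(c(6, 4, 1), seed = 2)
  sc2 <- user_identification_score(x, za, zb, net)
  expect_true(all(sc2$prob_same > 0 & sc2$prob_same < 1))
  expect_error(user_identification_score(x, za, zb,
                                         mlp_init(c(4, 1), seed = 1)),
               class = "motionsde_not_fitted")
})
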