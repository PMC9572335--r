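test_that("Gaussian KL closed forms and guards", {
  expect_equal(gaussian_kl(c(1, 2), 0.7, c(1, 2), 0.7), 0)
  expect_equal(gaussian_kl(0, 1, 1, 1, k = 1), 0.5)
  expect_equal(gaussian_kl(c(0, 0), 1, c(0, 0), 2), 2 * log(2) + 2 / 8 - 1)
  expect_error(gaussian_kl(0, 0, 0, 1), class = "motionsde_invalid_argument")
  expect_error(gaussian_kl(0, 1, 0, -1), class = "motionsde_invalid_argument")
  # non-negativity over random draws
  with_rng(5, for (i in 1:50) {
    expect_gte(gaussian_kl(rnorm(2), exp(rnorm(1)), rnorm(2), exp(rnorm(1))), 0)
  })
})

test_that("ELBO assembles from the three closed-form pieces on a hand toy", {
  # all-zero networks, unit posterior/observation sds, zeros for data and
  # noise; horizon T = 1 (3 frames): recon = 2 * 4 * (-0.5 log 2pi),
  # kl_init = KL(N(0,1)||N(0,0.2^2)), kl_trans = KL(N(0,1)||N(0,sigma_p^2))
  m <- tiny_model(T = 4, embed_dim = 8, seed = 1)
  m$transformer <- zero_transformer(m$transformer)
  m$decoder$decoder_net <- zero_mlp(m$decoder$decoder_net)
  m$decoder$obs_log_sd <- 0
  m$sde$drift_net <- zero_mlp(m$sde$drift_net)
  m$sde$diffusion_raw <- log(expm1(0.3))
  m$q_log_sd <- 0
  m$prior <- plain_prior(sigma0 = 0.2)

  w <- matrix(0, 3, 4)
  bd <- elbo(w, m, eps = matrix(0, 2, 2))
  expect_equal(bd$recon, 2 * (-4 * 0.5 * log(2 * pi)))
  expect_equal(bd$kl_initial, gaussian_kl(c(0, 0), 1, c(0, 0), 0.2))
  sp <- motionsde:::sde_sigma(m$sde)
  expect_equal(bd$kl_transitions, gaussian_kl(c(0, 0), 1, c(0, 0), sp))
  expect_equal(bd$elbo, bd$recon - bd$kl_initial - bd$kl_transitions)

  # T = 0 toy (2 frames) with posterior matched to the prior: only recon
  m0 <- m
  m0$q_log_sd <- log(0.2)
  bd0 <- elbo(matrix(0, 2, 4), m0, eps = matrix(0, 1, 2))
  expect_equal(bd0$kl_initial, 0)
  expect_equal(bd0$kl_transitions, 0)
  expect_equal(bd0$elbo, bd0$recon)
})

test_that("ELBO is per-window and invariant to evaluation order", {
  m <- tiny_model(T = 6, seed = 2)
  w1 <- with_rng(1, matrix(rnorm(28), 7, 4))
  w2 <- with_rng(2, matrix(rnorm(28), 7, 4))
  a1 <- elbo(w1, m, seed = 4)$elbo
  a2 <- elbo(w2, m, seed = 5)$elbo
  b2 <- elbo(w2, m, seed = 5)$elbo
  b1 <- elbo(w1, m, seed = 4)$elbo
  expect_identical(a1 + a2, b1 + b2)
})

test_that("single-sample ELBO noise shrinks with more Monte-Carlo samples", {
  m <- tiny_model(T = 5, seed = 7)
  w <- with_rng(3, matrix(rnorm(24), 6, 4))
  e1 <- vapply(1:60, function(s) elbo(w, m, seed = s)$elbo, numeric(1))
  e4 <- vapply(1:60, function(s) {
    mean(vapply(1:4, function(k) elbo(w, m, seed = s * 101 + k)$elbo,
                numeric(1)))
  }, numeric(1))
  expect_true(is.finite(stats::var(e1)))
  expect_lt(stats::var(e4), 0.6 * stats::var(e1))
})

test_that("contrast loss closed forms, symmetry, and guards", {
  net0 <- zero_mlp(mlp_init(c(6, 4, 1), seed = 1))
  x <- list(with_rng(1, matrix(rnorm(20), 5, 4)),
            with_rng(2, matrix(rnorm(20), 5, 4)))
  z <- list(with_rng(3, matrix(rnorm(10), 5, 2)),
            with_rng(4, matrix(rnorm(10), 5, 2)))
  # C == 0 everywhere: 2 log 2 per (ordered pair, t); 2 pairs x 5 steps
  expect_equal(contrast_loss(x, z, net0), 2 * 5 * 2 * log(2))

  # saturation limit: when the scorer is (near) perfectly separating for a
  # pair — huge positive logits on matched pairs, huge negative on
  # mismatched — that pair's loss vanishes and so does its gradient
  net_sep <- zero_mlp(mlp_init(c(6, 1), seed = 2))
  net_sep$params$W[[1]][5, 1] <- 50   # logit = 50 * z1
  cp <- motionsde:::contrast_pair_grads(net_sep, x[[1]],
                                        matrix(1, 5, 2), matrix(-1, 5, 2))
  expect_lt(cp$loss, 1e-6)
  expect_lt(max(abs(cp$dz_a)), 1e-6)

  # relabeling users leaves the double sum unchanged
  expect_equal(contrast_loss(x, z, net0),
               contrast_loss(rev(x), rev(z), net0))
  expect_error(contrast_loss(x[1], z[1], net0),
               class = "motionsde_invalid_argument")
})

test_that("training reduces the loss, reproduces bit-identically by seed", {
  wins <- walking_windows(n_windows = 8, T = 10, seed = 5)
  m <- tiny_model(T = 10, seed = 9)
  m$prior <- fit_prior(do.call(rbind, wins))
  cfg <- train_config(n_epochs = 15, batch_size = 4, seed = 0)
  fit1 <- train_motion_model(m, wins, val_windows = wins[1:2], config = cfg)
  expect_lt(fit1$history$train_loss[15], fit1$history$train_loss[1])
  expect_true(all(is.finite(fit1$history$val_loss)))

  fit2 <- train_motion_model(m, wins, val_windows = wins[1:2], config = cfg)
  expect_identical(fit1$history, fit2$history)
  fit3 <- train_motion_model(m, wins, val_windows = wins[1:2],
                             config = train_config(n_epochs = 15,
                                                   batch_size = 4, seed = 1))
  expect_false(identical(fit1$history$train_loss, fit3$history$train_loss))
})

test_that("contrast_weight = 0 leaves the contrast network untouched", {
  wins <- walking_windows(n_windows = 6, T = 8, seed = 6)
  m <- tiny_model(T = 8, seed = 10)
  m$prior <- fit_prior(do.call(rbind, wins))
  before <- m$contrast$params
  fit <- train_motion_model(m, wins,
                            config = train_config(n_epochs = 3, seed = 0),
                            users = rep(c("a", "b"), 3))
  expect_identical(fit$model$contrast$params, before)
})

test_that("contrastive training requires at least two users", {
  wins <- walking_windows(n_windows = 4, T = 8, seed = 7)
  m <- tiny_model(T = 8, seed = 11)
  m$prior <- fit_prior(do.call(rbind, wins))
  expect_error(
    train_motion_model(m, wins,
                       config = train_config(n_epochs = 1,
                                             contrast_weight = 1, seed = 0),
                       users = rep("a", 4)),
    class = "motionsde_invalid_argument")
})

test_that("overfitting detector fires on U-shaped traces only", {
  u_shape <- c(seq(5, 1, length.out = 30), seq(1.05, 3, length.out = 30))
  expect_true(detect_overfitting(u_shape, patience = 10))
  monotone <- seq(5, 1, length.out = 60)
  expect_false(detect_overfitting(monotone, patience = 10))
  expect_false(detect_overfitting(u_shape[1:12], patience = 10))
})
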