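## Generative component theta: the simplified latent neural SDE
## dz = mu_theta(z) dt + sigma_theta dW (drift = small MLP, diffusion = one
## positive scalar), a Gaussian decoder over midpoint targets, and a
## PCA-anchored prior on the initial latent state.

#' Initialize the latent SDE parameters
#'
#' @param drift_sizes layer widths of the drift MLP (default `c(2, 64, 64, 2)`)
#' @param sigma initial diffusion magnitude, stored as its inverse softplus
#'   so the effective sigma is always positive
#' @param dt Euler-Maruyama time step; one unit per 30 Hz sample (default 1)
#' @param seed weight seed
#' @return an object of class `sde_params`
#' @export
sde_init <- function(drift_sizes = c(2L, 64L, 64L, 2L), sigma = 0.1, dt = 1,
                     seed = 0L) {
  assert_that(dt > 0, "invalid_argument", "dt must be positive")
  assert_that(sigma > 0, "invalid_argument", "initial sigma must be positive")
  assert_that(drift_sizes[1] == 2L && drift_sizes[length(drift_sizes)] == 2L,
              "invalid_argument", "drift maps R^2 -> R^2")
  structure(list(
    drift_net = mlp_init(drift_sizes, "tanh", seed = derive_seed(seed, "drift")),
    # inverse softplus so softplus(diffusion_raw) == sigma at init
    diffusion_raw = log(expm1(sigma)),
    dt = dt), class = "sde_params")
}

sde_sigma <- function(sde, diffusion_raw = sde$diffusion_raw) {
  softplus(diffusion_raw)
}

#' Drift field of the latent SDE
#'
#' @param z a latent 2-vector or n x 2 matrix of latent states
#' @param params an [sde_init()] object
#' @return drift value(s), same shape as `z`
#' @export
drift <- function(z, params) {
  assert_that(inherits(params, "sde_params"), "invalid_argument",
              "params must be sde_params")
  single <- !is.matrix(z)
  out <- mlp_forward(params$drift_net, z)$out
  if (single) drop(out) else out
}

#' One Euler-Maruyama step
#'
#' `z' = z + mu_theta(z) dt + sigma_theta sqrt(dt) noise` with `noise` a
#' standard-normal draw (zeros give the deterministic Euler step).
#'
#' @param z latent 2-vector
#' @param params an [sde_init()] object
#' @param noise standard-normal 2-vector (or zeros)
#' @return the next latent state (2-vector)
#' @export
#' @examples
#' p <- sde_init(c(2, 2), sigma = 0.5, dt = 1, seed = 1)
#' p$drift_net$params$W[[1]][] <- 0
#' euler_maruyama_step(c(0, 0), p, noise = c(2, 0))  # (1, 0)
euler_maruyama_step <- function(z, params, noise = c(0, 0)) {
  assert_that(inherits(params, "sde_params") && params$dt > 0,
              "invalid_argument", "params must be sde_params with dt > 0")
  assert_that(length(z) == 2L && all(is.finite(z)), "invalid_argument",
              "z must be a finite 2-vector")
  z + drift(z, params) * params$dt +
    sde_sigma(params) * sqrt(params$dt) * noise
}

#' One-step transition density of the discretized SDE
#'
#' Under Euler-Maruyama the transition `p(z_t | z_{t-1})` is Gaussian with
#' mean `z_{t-1} + mu_theta(z_{t-1}) dt` and isotropic covariance
#' `sigma_theta^2 dt I_2`.
#'
#' @param z_prev previous latent 2-vector
#' @param params an [sde_init()] object
#' @return list with `mean` (2-vector) and `cov` (2 x 2 matrix)
#' @export
transition_density <- function(z_prev, params) {
  assert_that(length(z_prev) == 2L && all(is.finite(z_prev)),
              "invalid_argument", "z_prev must be a finite 2-vector")
  m <- z_prev + drift(z_prev, params) * params$dt
  s2 <- sde_sigma(params)^2 * params$dt
  list(mean = as.numeric(m), cov = diag(s2, 2L))
}

#' Simulate a latent trajectory by iterated Euler-Maruyama steps
#'
#' @param z0 initial latent 2-vector
#' @param n_steps number of steps (>= 1)
#' @param params an [sde_init()] object
#' @param seed integer seed for the Brownian increments
#' @return an `(n_steps + 1) x 2` matrix of states, first row `z0`
#' @export
sample_trajectory <- function(z0, n_steps, params, seed = 0L) {
  assert_that(n_steps >= 1, "invalid_argument", "n_steps must be >= 1")
  n_steps <- as.integer(n_steps)
  noise <- with_seed(seed, matrix(stats::rnorm(2L * n_steps), n_steps, 2L))
  sig <- sde_sigma(params) * sqrt(params$dt)
  Z <- matrix(0, n_steps + 1L, 2L)
  Z[1L, ] <- z0
  for (i in seq_len(n_steps)) {
    zi <- Z[i, ]
    Z[i + 1L, ] <- zi + drift(zi, params) * params$dt + sig * noise[i, ]
  }
  Z
}

#' Initialize the Gaussian observation decoder
#'
#' A feed-forward map from the 2-D latent state to the 4-channel midpoint
#' target, with one learned log standard deviation shared across channels.
#'
#' @param sizes layer widths (default `c(2, 64, 64, 4)`)
#' @param obs_log_sd initial log observation sd (default `log(0.5)`)
#' @param seed weight seed
#' @return an object of class `decoder_params`
#' @export
decoder_init <- function(sizes = c(2L, 64L, 64L, 4L), obs_log_sd = log(0.5),
                         seed = 0L) {
  structure(list(
    decoder_net = mlp_init(sizes, "tanh", seed = derive_seed(seed, "decoder")),
    obs_log_sd = obs_log_sd), class = "decoder_params")
}

#' Decode a latent state into a Gaussian over observation space
#'
#' @param z latent 2-vector or n x 2 matrix
#' @param params a [decoder_init()] object
#' @return list with `mean` (n x 4), `sd` (scalar), and `log_density(x)`, a
#'   function evaluating the Gaussian log density row-wise at 4-vectors
#' @export
decode <- function(z, params) {
  assert_that(inherits(params, "decoder_params"), "invalid_argument",
              "params must be decoder_params")
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  assert_that(all(is.finite(z)), "invalid_argument", "z must be finite")
  mean <- mlp_forward(params$decoder_net, z)$out
  sd <- exp(params$obs_log_sd)
  d <- ncol(mean)
  list(mean = mean, sd = sd,
       log_density = function(x) {
         x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
         rowSums(-log(sd) - 0.5 * log(2 * pi) - (x - mean)^2 / (2 * sd^2))
       })
}

gaussian_logdens_iso <- function(x, mean, sd) {
  # sum over rows and channels of independent N(mean, sd^2) log densities
  sum(-log(sd) - 0.5 * log(2 * pi) - (x - mean)^2 / (2 * sd^2))
}

#' Fit the PCA-anchored prior over initial latent states
#'
#' The prior is `p(z0) = N(mu0, sigma0^2 I_2)` with `mu0` the projection of
#' the first observed frame onto the two leading principal components of the
#' normalized training frames, and `sigma0 = 0.2` fixed. The sign of each
#' component is fixed by forcing its largest-magnitude loading positive.
#'
#' @param train_frames n x 4 matrix of normalized training frames
#' @param sigma0 prior standard deviation (default 0.2, not trained)
#' @return an object of class `latent_prior`
#' @export
fit_prior <- function(train_frames, sigma0 = 0.2) {
  train_frames <- as.matrix(train_frames)
  assert_that(nrow(train_frames) >= 3L, "invalid_argument",
              "need >= 3 frames to fit the PCA prior")
  pc <- stats::prcomp(train_frames, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(center = pc$center, rotation = rot, sigma0 = sigma0),
            class = "latent_prior")
}

#' Prior mean for an initial frame
#'
#' Projects the frame(s) onto the fitted 2-component PCA map.
#'
#' @param x a 4-vector (the initial frame `x_0`) or n x 4 matrix
#' @param prior a [fit_prior()] object
#' @return a 2-vector (or n x 2 matrix) prior mean `mu0`
#' @export
prior_mean <- function(x, prior) {
  assert_that(inherits(prior, "latent_prior"), "not_fitted",
              "prior must be fitted with fit_prior()")
  single <- !is.matrix(x)
  if (single) x <- matrix(x, nrow = 1L)
  out <- unname(sweep(x, 2L, prior$center) %*% prior$rotation)
  if (single) drop(out) else out
}
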