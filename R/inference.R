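## phi-parameterized filtering posterior q(z_t | x_{0:t}): the causal
## transformer yields the per-step posterior means; the scale is one learned
## global scalar (isotropic covariance).

#' Posterior means for a window of frames
#'
#' Runs the causal transformer over frames `x_0..x_{n-1}` and returns the
#' mean of `q(z_t | x_{0:t})` for every `t`. Because of the causal mask,
#' `mu_t` is a function of `x_{0:t}` only: perturbing later frames leaves
#' earlier outputs bit-identical. Inference is deterministic (no dropout).
#'
#' @param model a `motion_model` (or a raw `transformer`)
#' @param frames an n x 4 matrix of normalized frames, `n <= max_len`
#' @return an n x 2 matrix of posterior means
#' @export
posterior_means <- function(model, frames) {
  tf <- if (inherits(model, "motion_model")) model$transformer else model
  assert_that(inherits(tf, "transformer"), "invalid_argument",
              "model must be a motion_model or transformer")
  transformer_forward(tf, as.matrix(frames))$out
}

#' Reparameterized posterior samples
#'
#' `z_t = mu_t + exp(q_log_sd) * eps_t`, `eps_t ~ N(0, I_2)`.
#'
#' @param means n x 2 matrix of posterior means
#' @param q_log_sd log posterior standard deviation (scalar)
#' @param seed integer seed for the draw
#' @return an n x 2 matrix of latent samples
#' @export
sample_posterior <- function(means, q_log_sd, seed = 0L) {
  means <- as.matrix(means)
  assert_that(all(is.finite(means)), "invalid_argument",
              "posterior means must be finite")
  eps <- with_seed(seed, matrix(stats::rnorm(length(means)),
                                nrow(means), ncol(means)))
  means + exp(q_log_sd) * eps
}

#' Attention heat map of one transformer layer
#'
#' Returns the n x n attention-weight matrix `softmax(Q K^T / sqrt(d_K))`
#' (with the causal mask) produced while encoding `frames`. Rows sum to 1;
#' strictly upper-triangular entries are exactly 0. For display parity with
#' the usual heat-map figures, `span = c(50, 90)` selects the 0-based
#' half-open row range `[50, 90)`.
#'
#' @param model a `motion_model` or `transformer`
#' @param frames n x 4 matrix of normalized frames
#' @param layer_index 1-based layer number (1 = first layer)
#' @param span optional 0-based half-open row range to slice, e.g. `c(50, 90)`
#' @return an object of class `attention_map`: list with `weights` and
#'   `layer`
#' @export
attention_heatmap <- function(model, frames, layer_index = 1L, span = NULL) {
  tf <- if (inherits(model, "motion_model")) model$transformer else model
  assert_that(inherits(tf, "transformer"), "invalid_argument",
              "model must be a motion_model or transformer")
  assert_that(layer_index >= 1L && layer_index <= tf$cfg$n_layers,
              "invalid_argument",
              sprintf("layer_index must be in 1..%d", tf$cfg$n_layers))
  W <- transformer_forward(tf, as.matrix(frames))$attn[[layer_index]]
  if (!is.null(span)) {
    assert_that(length(span) == 2L && span[1] >= 0 && span[2] <= nrow(W) &&
                  span[1] < span[2], "invalid_argument",
                "span must be a 0-based half-open range inside the window")
    W <- W[(span[1] + 1L):span[2], , drop = FALSE]
  }
  structure(list(weights = W, layer = layer_index), class = "attention_map")
}

#' Mean attention weight as a function of lag
#'
#' Averages the attention weights at each query-key lag (`i - j`), a compact
#' summary of how strongly the encoder looks back whole periods; for
#' strongly periodic signals the profile peaks at multiples of the period.
#'
#' @param map an [attention_heatmap()] result or bare weight matrix
#' @param min_row first (1-based) row to include, skipping short-history rows
#' @return data frame with `lag` and `weight`
#' @export
attention_lag_profile <- function(map, min_row = 2L) {
  W <- if (inherits(map, "attention_map")) map$weights else as.matrix(map)
  n <- nrow(W)
  lags <- list()
  for (i in seq.int(min_row, n)) {
    for (j in seq_len(ncol(W))) {
      if (j <= i) {
        lag <- i - j
        lags[[as.character(lag)]] <- c(lags[[as.character(lag)]], W[i, j])
      }
    }
  }
  data.frame(lag = as.integer(names(lags)),
             weight = vapply(lags, mean, numeric(1)), row.names = NULL)
}

#' Stitched latent trajectory of a full recording
#'
#' Normalizes the recording with the model's stored statistics, cuts it into
#' consecutive chunks of the transformer's maximum length, and concatenates
#' the per-chunk posterior means into one latent trajectory.
#'
#' @param model a fitted `motion_model` (with `stats`)
#' @param x a `sensor_recording`, or an n x 4 matrix of frames (raw frames
#'   are normalized with the model statistics unless `normalized = TRUE`)
#' @param normalized set TRUE if `x` is already z-scored
#' @return an n x 2 matrix of latent posterior means
#' @export
latent_trajectory <- function(model, x, normalized = FALSE) {
  assert_that(inherits(model, "motion_model"), "invalid_argument",
              "model must be a motion_model")
  if (inherits(x, "sensor_recording")) x <- sensor_frames(x)
  x <- as.matrix(x)
  if (!normalized) {
    assert_that(!is.null(model$stats), "not_fitted",
                "model carries no normalization statistics")
    x <- apply_zscore(x, model$stats)
  }
  chunk <- model$transformer$cfg$max_len
  n <- nrow(x)
  starts <- seq.int(1L, n, by = chunk)
  do.call(rbind, lapply(starts, function(s) {
    posterior_means(model, x[s:min(n, s + chunk - 1L), , drop = FALSE])
  }))
}
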