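# Shared builders for tiny models and toy constructions.

# A small untrained model with identity-like normalization and a prior fit
# on random frames, ready for elbo()/training smoke tests.
tiny_model <- function(T = 6L, embed_dim = 8L, seed = 3L, n_layers = 2L) {
  m <- new_motion_model(T = T, embed_dim = embed_dim, n_layers = n_layers,
                        drift_hidden = 5L, decoder_hidden = 5L,
                        contrast_hidden = 4L, seed = seed)
  m$stats <- structure(list(mean = rep(0, 4), sd = rep(1, 4)),
                       class = "norm_stats")
  m$prior <- fit_prior(with_rng(seed + 1L, matrix(rnorm(80), 20, 4)))
  m
}

# identity-ish prior: center 0, projection onto the first two coordinates
plain_prior <- function(sigma0 = 0.2) {
  structure(list(center = rep(0, 4),
                 rotation = rbind(diag(2), matrix(0, 2, 2)),
                 sigma0 = sigma0),
            class = "latent_prior")
}

with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# zero out every weight of an mlp
zero_mlp <- function(net) {
  net$params <- rapply(net$params, function(a) a * 0, how = "replace")
  net
}

# set every transformer parameter to zero (output identically zero)
zero_transformer <- function(tf) {
  tf$params <- rapply(tf$params, function(a) a * 0, how = "replace")
  tf
}

# central-difference gradient of f at x (numeric vector)
numeric_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# training windows from one synthetic walking recording (normalized)
walking_windows <- function(n_windows = 10L, T = 10L, seed = 5L,
                            noise_sd = 0.05) {
  rec <- generate_recording(motion_archetype("walking"),
                            subject_profile("w1",
                                            phase_offsets = c(0.4, 1.9, 3.4),
                                            noise_sd = noise_sd),
                            n_steps = max((T + 1L) * n_windows + 10L, 62L),
                            seed = seed)
  fr <- sensor_frames(rec)
  st <- fit_zscore(fr)
  make_windows(apply_zscore(fr, st), T = T, stride = T)[seq_len(n_windows)]
}
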