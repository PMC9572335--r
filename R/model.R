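#' Construct an untrained motion model
#'
#' Bundles the generative component (latent SDE drift net, scalar diffusion,
#' Gaussian decoder, PCA prior placeholder) with the inference component
#' (causal transformer and global posterior scale) and an optional contrast
#' network for user identification.
#'
#' @param T window length in model steps; the transformer consumes up to
#'   `T + 1` frames (default 90)
#' @param embed_dim transformer embedding width (default 32)
#' @param n_layers transformer layers (default 2)
#' @param n_heads attention heads (default 1)
#' @param drift_hidden hidden widths of the drift MLP (default `c(64, 64)`)
#' @param decoder_hidden hidden widths of the decoder MLP (default `c(64, 64)`)
#' @param contrast_hidden hidden widths of the contrast MLP (default 64)
#' @param sigma initial diffusion magnitude (default 0.1)
#' @param dt Euler-Maruyama step (default 1, one unit per sample)
#' @param q_log_sd initial log posterior sd (default `log(0.2)`)
#' @param obs_log_sd initial log observation sd (default `log(0.5)`)
#' @param seed weight seed
#' @return an object of class `motion_model`
#' @export
new_motion_model <- function(T = 90L, embed_dim = 32L, n_layers = 2L,
                             n_heads = 1L, drift_hidden = c(64L, 64L),
                             decoder_hidden = c(64L, 64L),
                             contrast_hidden = 64L,
                             sigma = 0.1, dt = 1, q_log_sd = log(0.2),
                             obs_log_sd = log(0.5), seed = 0L) {
  cfg <- transformer_config(n_layers = n_layers, n_heads = n_heads,
                            embed_dim = embed_dim, max_len = T + 1L,
                            token_in_dim = 4L, out_dim = 2L)
  structure(list(
    T = as.integer(T),
    transformer = transformer_init(cfg, seed = derive_seed(seed, "tf")),
    decoder = decoder_init(c(2L, decoder_hidden, 4L), obs_log_sd = obs_log_sd,
                           seed = derive_seed(seed, "dec")),
    sde = sde_init(c(2L, drift_hidden, 2L), sigma = sigma, dt = dt,
                   seed = derive_seed(seed, "sde")),
    contrast = mlp_init(c(6L, contrast_hidden, 1L), "tanh",
                        seed = derive_seed(seed, "contrast")),
    q_log_sd = q_log_sd,
    prior = NULL, stats = NULL), class = "motion_model")
}

#' @export
print.motion_model <- function(x, ...) {
  cfg <- x$transformer$cfg
  cat(sprintf(paste0(
    "<motion_model> latent SDE (drift %s, sigma=%.4g) + GPT2 posterior ",
    "(%d layers, %d head(s), embed %d)\n  window T=%d, %s\n"),
    paste(x$sde$drift_net$sizes, collapse = "-"), sde_sigma(x$sde),
    cfg$n_layers, cfg$n_heads, cfg$embed_dim, x$T,
    if (is.null(x$prior)) "prior unfit" else "prior fitted"))
  invisible(x)
}

## ---- trainable-parameter plumbing ------------------------------------------

get_trainable <- function(model, with_contrast = FALSE) {
  tr <- list(tf = model$transformer$params,
             dec = model$decoder$decoder_net$params,
             dec_log_sd = model$decoder$obs_log_sd,
             drift = model$sde$drift_net$params,
             diff_raw = model$sde$diffusion_raw,
             q_log_sd = model$q_log_sd)
  if (with_contrast) tr$contrast <- model$contrast$params
  tr
}

set_trainable <- function(model, tr) {
  model$transformer$params <- tr$tf
  model$decoder$decoder_net$params <- tr$dec
  model$decoder$obs_log_sd <- tr$dec_log_sd
  model$sde$drift_net$params <- tr$drift
  model$sde$diffusion_raw <- tr$diff_raw
  model$q_log_sd <- tr$q_log_sd
  if (!is.null(tr$contrast)) model$contrast$params <- tr$contrast
  model
}
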