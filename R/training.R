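## ELBO construction, closed-form Gaussian KLs, the optional contrastive
## term, and the AdamW training loop that maximizes the sequential evidence
## lower bound jointly over generative (theta) and inference (phi)
## parameters.

#' Closed-form KL divergence between isotropic Gaussians
#'
#' `KL(N(mu_q, sd_q^2 I_k) || N(mu_p, sd_p^2 I_k)) =
#' k log(sd_p / sd_q) + (k sd_q^2 + ||mu_q - mu_p||^2) / (2 sd_p^2) - k / 2`.
#' Always non-negative; zero iff the distributions coincide.
#'
#' @param mu_q,mu_p mean k-vectors
#' @param sd_q,sd_p positive scalar standard deviations
#' @param k dimension (default `length(mu_q)`)
#' @return the KL divergence (scalar)
#' @export
#' @examples
#' gaussian_kl(0, 1, 1, 1, k = 1)      # 0.5
#' gaussian_kl(c(0, 0), 1, c(0, 0), 2) # 2 log 2 + 2/8 - 1
gaussian_kl <- function(mu_q, sd_q, mu_p, sd_p, k = length(mu_q)) {
  assert_that(length(sd_q) == 1L && length(sd_p) == 1L &&
                is.finite(sd_q) && is.finite(sd_p) && sd_q > 0 && sd_p > 0,
              "invalid_argument", "standard deviations must be positive scalars")
  assert_that(length(mu_q) == length(mu_p), "invalid_argument",
              "means must have equal length")
  k * log(sd_p / sd_q) + (k * sd_q^2 + sum((mu_q - mu_p)^2)) / (2 * sd_p^2) - k / 2
}

## ---- ELBO forward/backward over one window ---------------------------------
## A window of L frames x_0..x_{L-1} gives horizon T = L - 2: the transformer
## consumes x_0..x_{T}, the decoder reconstructs the L - 1 midpoint targets
## xbar_1..xbar_{L-1}, and L - 2 transition KLs tie consecutive posteriors
## through the SDE. All gradients are of the per-window LOSS (negative ELBO).

elbo_pass <- function(model, window, eps, want_grads = TRUE) {
  window <- as.matrix(window)
  L <- nrow(window)
  assert_that(L >= 2L, "invalid_argument", "a window needs >= 2 frames")
  assert_that(!is.null(model$prior), "not_fitted",
              "model prior is unfit; run fit_prior()/fit_motion_model() first")
  n <- L - 1L                                   # posterior steps z_0..z_{T}
  Xin <- window[seq_len(n), , drop = FALSE]
  fw <- transformer_forward(model$transformer, Xin)
  mu <- fw$out
  sq <- exp(model$q_log_sd)
  Z <- mu + sq * eps
  Xbar <- midpoint_targets(window)              # n x 4

  dec_fw <- mlp_forward(model$decoder$decoder_net, Z)
  dm <- dec_fw$out
  sx <- exp(model$decoder$obs_log_sd)
  resid <- Xbar - dm
  recon <- sum(-model$decoder$obs_log_sd - 0.5 * log(2 * pi) -
                 resid^2 / (2 * sx^2))

  mu0p <- prior_mean(window[1L, ], model$prior)
  s0 <- model$prior$sigma0
  kl_init <- gaussian_kl(mu[1L, ], sq, mu0p, s0, k = 2L)

  sp <- sde_sigma(model$sde) * sqrt(model$sde$dt)
  n_tr <- n - 1L
  if (n_tr > 0L) {
    zprev <- Z[seq_len(n_tr), , drop = FALSE]
    drift_fw <- mlp_forward(model$sde$drift_net, zprev)
    mp <- zprev + drift_fw$out * model$sde$dt
    diffs <- mu[-1L, , drop = FALSE] - mp
    d2 <- rowSums(diffs^2)
    kl_tr_each <- 2 * log(sp / sq) + (2 * sq^2 + d2) / (2 * sp^2) - 1
    kl_tr <- sum(kl_tr_each)
  } else {
    kl_tr <- 0
    kl_tr_each <- numeric(0)
  }

  breakdown <- structure(list(recon = recon, kl_initial = kl_init,
                              kl_transitions = kl_tr,
                              elbo = recon - kl_init - kl_tr, contrast = 0),
                         class = "elbo_breakdown")
  if (!want_grads) return(list(breakdown = breakdown, mu = mu, Z = Z))

  ## gradients of loss = -elbo
  d_dm <- -resid / sx^2
  g_dec_log_sd <- sum(1 - resid^2 / sx^2)
  dec_bw <- mlp_backward(model$decoder$decoder_net, dec_fw$cache, d_dm)
  dZ <- dec_bw$dX
  dmu <- matrix(0, n, 2L)
  g_q <- 0

  dmu[1L, ] <- dmu[1L, ] + (mu[1L, ] - mu0p) / s0^2
  g_q <- g_q - 2 + 2 * sq^2 / s0^2

  g_diff_raw <- 0
  g_drift <- NULL
  if (n_tr > 0L) {
    dmu[-1L, ] <- dmu[-1L, ] + diffs / sp^2
    d_mp <- -diffs / sp^2
    drift_bw <- mlp_backward(model$sde$drift_net, drift_fw$cache,
                             d_mp * model$sde$dt)
    g_drift <- drift_bw$grads
    dZ[seq_len(n_tr), ] <- dZ[seq_len(n_tr), ] + d_mp + drift_bw$dX
    g_q <- g_q + n_tr * (-2 + 2 * sq^2 / sp^2)
    d_sp <- sum(2 / sp - (2 * sq^2 + d2) / sp^3)
    g_diff_raw <- d_sp * sqrt(model$sde$dt) * sigmoid(model$sde$diffusion_raw)
  } else {
    g_drift <- rapply(model$sde$drift_net$params, function(a) a * 0,
                      how = "replace")
  }

  list(breakdown = breakdown, mu = mu, Z = Z, eps = eps, sq = sq,
       tf_fw = fw, dmu = dmu, dZ = dZ, g_q = g_q,
       grads = list(dec = dec_bw$grads, dec_log_sd = g_dec_log_sd,
                    drift = g_drift, diff_raw = g_diff_raw))
}

## Fold sampled-z gradients into posterior-mean gradients and run the
## transformer backward pass. extra_dZ adds contrast-term gradients.
elbo_finish <- function(model, pass, extra_dZ = NULL) {
  dZ <- pass$dZ
  if (!is.null(extra_dZ)) dZ <- dZ + extra_dZ
  dmu <- pass$dmu + dZ
  g_q <- pass$g_q + sum(dZ * pass$sq * pass$eps)
  g_tf <- transformer_backward(model$transformer, pass$tf_fw$cache, dmu)
  grads <- pass$grads
  grads$tf <- g_tf
  grads$q_log_sd <- g_q
  grads
}

#' Evidence lower bound of one window
#'
#' Computes the sequential ELBO: the reconstruction expectation of the
#' midpoint targets under one reparameterized posterior sample per step,
#' minus the initial-state KL against the PCA-anchored prior, minus the
#' closed-form transition KLs against the Euler-Maruyama transition density
#' evaluated at the sampled previous state.
#'
#' @param window an `L x 4` matrix of normalized frames (`L >= 2`)
#' @param model a `motion_model` with a fitted prior
#' @param seed integer seed for the reparameterized draws (ignored when
#'   `eps` is given)
#' @param eps optional `(L - 1) x 2` matrix of standard-normal draws; pass
#'   zeros for a deterministic evaluation
#' @return an `elbo_breakdown`: list with `recon`, `kl_initial`,
#'   `kl_transitions`, `elbo` and `contrast` (0 here)
#' @export
elbo <- function(window, model, seed = 0L, eps = NULL) {
  window <- as.matrix(window)
  n <- nrow(window) - 1L
  if (is.null(eps)) {
    eps <- with_seed(seed, matrix(stats::rnorm(2L * n), n, 2L))
  }
  assert_that(is.matrix(eps) && nrow(eps) == n && ncol(eps) == 2L,
              "invalid_argument", "eps must be an (L-1) x 2 matrix")
  elbo_pass(model, window, eps, want_grads = FALSE)$breakdown
}

#' @export
print.elbo_breakdown <- function(x, ...) {
  cat(sprintf("ELBO %.4f = recon %.4f - KL0 %.4f - KLtrans %.4f\n",
              x$elbo, x$recon, x$kl_initial, x$kl_transitions))
  invisible(x)
}

## ---- contrastive term ------------------------------------------------------

contrast_logit <- function(net, x, z) {
  mlp_forward(net, cbind(as.matrix(x), as.matrix(z)))$out[, 1L]
}

#' Contrastive user-identification loss
#'
#' For every ordered pair of users `(a, b != a)` and every time step, the
#' contrast network `C(x, z)` is pushed to score user `a`'s own
#' (observation, latent) pairs high and cross-user pairs
#' `(x_t^(a), z_t^(b))` low:
#' `-sum log(sigmoid(C(x^a, z^a))) - sum log(1 - sigmoid(C(x^a, z^b)))`.
#' With `literal_form = TRUE` the negative term is evaluated as
#' `log(sigmoid(1 - C))` exactly as sometimes printed; the default is the
#' standard discriminator form.
#'
#' @param x_seqs list (one element per user) of n x 4 observation matrices
#' @param z_seqs parallel list of n x 2 latent matrices
#' @param net the contrast MLP (input width 6, output 1)
#' @param literal_form evaluate negatives as `log(sigmoid(1 - C))`
#' @return the total loss (scalar, lower is better; 0 in the perfect limit)
#' @export
#' @examples
#' net <- mlp_init(c(6, 1), seed = 1, zero_init = TRUE)
#' x <- list(matrix(0, 3, 4), matrix(1, 3, 4))
#' z <- list(matrix(0, 3, 2), matrix(1, 3, 2))
#' contrast_loss(x, z, net) / (2 * 3)  # 2 log 2 per (pair, t)
contrast_loss <- function(x_seqs, z_seqs, net, literal_form = FALSE) {
  assert_that(is.list(x_seqs) && is.list(z_seqs) &&
                length(x_seqs) == length(z_seqs), "invalid_argument",
              "x_seqs and z_seqs must be parallel lists")
  n_users <- length(x_seqs)
  assert_that(n_users >= 2L, "invalid_argument",
              "contrast loss needs at least 2 users")
  total <- 0
  for (a in seq_len(n_users)) {
    c_pos <- contrast_logit(net, x_seqs[[a]], z_seqs[[a]])
    for (b in seq_len(n_users)) {
      if (b == a) next
      c_neg <- contrast_logit(net, x_seqs[[a]], z_seqs[[b]])
      neg_term <- if (literal_form) log(sigmoid(1 - c_neg)) else
        log1p(-sigmoid(c_neg))
      total <- total - sum(log(sigmoid(c_pos))) - sum(neg_term)
    }
  }
  total
}

## Loss + gradients for one (a, b) training pair: returns contrast-net
## gradients and the gradients w.r.t. both users' latent samples.
contrast_pair_grads <- function(net, x_a, z_a, z_b, literal_form = FALSE) {
  fw_pos <- mlp_forward(net, cbind(x_a, z_a))
  fw_neg <- mlp_forward(net, cbind(x_a, z_b))
  c_pos <- fw_pos$out[, 1L]
  c_neg <- fw_neg$out[, 1L]
  if (literal_form) {
    loss <- -sum(log(sigmoid(c_pos))) - sum(log(sigmoid(1 - c_neg)))
    d_neg <- 1 - sigmoid(1 - c_neg)
  } else {
    loss <- -sum(log(sigmoid(c_pos))) - sum(log1p(-sigmoid(c_neg)))
    d_neg <- sigmoid(c_neg)
  }
  d_pos <- sigmoid(c_pos) - 1
  bw_pos <- mlp_backward(net, fw_pos$cache, matrix(d_pos, ncol = 1L))
  bw_neg <- mlp_backward(net, fw_neg$cache, matrix(d_neg, ncol = 1L))
  g_net <- add_nested(bw_pos$grads, bw_neg$grads)
  list(loss = loss, g_net = g_net,
       dz_a = bw_pos$dX[, 5:6, drop = FALSE],
       dz_b = bw_neg$dX[, 5:6, drop = FALSE])
}

add_nested <- function(a, b) {
  if (is.list(a)) return(mapply(add_nested, a, b, SIMPLIFY = FALSE))
  a + b
}

## ---- optimizer -------------------------------------------------------------

adamw_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adamw_step <- function(par, grad, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  par <- par - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * par)
  list(par = par, state = state)
}

#' Training configuration
#'
#' @param batch_size windows per gradient step (default 128)
#' @param learning_rate AdamW step size (default 1e-3)
#' @param weight_decay decoupled weight decay (default 1e-2)
#' @param n_epochs training epochs
#' @param seed seed driving batch order and reparameterized draws
#' @param contrast_weight weight of the contrastive term (0 disables it and
#'   leaves the contrast network untouched)
#' @param mc_samples Monte-Carlo samples per window for the ELBO (default 1)
#' @param literal_contrast use the literal `log(sigmoid(1 - C))` negatives
#' @return a `train_config`
#' @export
train_config <- function(batch_size = 128L, learning_rate = 1e-3,
                         weight_decay = 1e-2, n_epochs = 50L, seed = 0L,
                         contrast_weight = 0, mc_samples = 1L,
                         literal_contrast = FALSE) {
  assert_that(batch_size >= 1 && mc_samples >= 1 && n_epochs >= 1 &&
                learning_rate > 0 && weight_decay >= 0 && contrast_weight >= 0,
              "invalid_argument", "invalid training configuration")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 n_epochs = as.integer(n_epochs), seed = as.integer(seed),
                 contrast_weight = contrast_weight,
                 mc_samples = as.integer(mc_samples),
                 literal_contrast = literal_contrast),
            class = "train_config")
}

window_loss_value <- function(model, window, eps) {
  -elbo_pass(model, window, eps, want_grads = FALSE)$breakdown$elbo
}

#' Train a motion model by stochastic ELBO maximization
#'
#' AdamW minimizes the mean per-window negative ELBO (plus, optionally, the
#' weighted contrastive term) with one reparameterized sample per step.
#' Every KL summand is checked non-negative each step, a NaN loss aborts
#' with a diagnostic naming the offending term, and a fixed seed reproduces
#' the loss history bit-for-bit.
#'
#' @param model a `motion_model` with a fitted prior and statistics
#' @param train_windows list of `(T+1) x 4` normalized windows
#' @param val_windows optional validation windows (monitoring only)
#' @param config a [train_config()]
#' @param users optional character vector, one user id per training window;
#'   required when `contrast_weight > 0`
#' @return list with the trained `model` and `history` (data frame of
#'   per-epoch train/validation losses)
#' @export
train_motion_model <- function(model, train_windows, val_windows = NULL,
                               config = train_config(), users = NULL) {
  assert_that(length(train_windows) >= 1, "invalid_argument",
              "training set is empty")
  use_contrast <- config$contrast_weight > 0
  if (use_contrast) {
    assert_that(!is.null(users) && length(users) == length(train_windows),
                "invalid_argument",
                "contrastive training needs one user id per window")
    assert_that(length(unique(users)) >= 2L, "invalid_argument",
                "contrastive training needs at least 2 users")
  }
  tr <- get_trainable(model, with_contrast = use_contrast)
  skel <- tr
  par <- flatten_params(tr)
  state <- adamw_state(length(par))
  nw <- length(train_windows)
  hist_train <- hist_val <- numeric(config$n_epochs)

  for (epoch in seq_len(config$n_epochs)) {
    set.seed(derive_seed(config$seed, paste0("epoch-", epoch)))
    perm <- sample.int(nw)
    epoch_loss <- 0
    for (batch_start in seq.int(1L, nw, by = config$batch_size)) {
      idx <- perm[batch_start:min(nw, batch_start + config$batch_size - 1L)]
      gacc <- numeric(length(par))
      batch_loss <- 0
      passes <- vector("list", length(idx))
      for (s in seq_len(config$mc_samples)) {
        extra_dZ <- vector("list", length(idx))  # NULL entries = no contrast term
        for (j in seq_along(idx)) {
          w <- train_windows[[idx[j]]]
          eps <- matrix(stats::rnorm(2L * (nrow(w) - 1L)), nrow(w) - 1L, 2L)
          p <- elbo_pass(model, w, eps, want_grads = TRUE)
          bd <- p$breakdown
          if (!all(is.finite(c(bd$recon, bd$kl_initial, bd$kl_transitions)))) {
            msde_stop("optimization_failure", sprintf(
              "non-finite loss at epoch %d (recon=%g, kl_init=%g, kl_trans=%g)",
              epoch, bd$recon, bd$kl_initial, bd$kl_transitions))
          }
          stopifnot(bd$kl_initial >= -1e-9, bd$kl_transitions >= -1e-9)
          batch_loss <- batch_loss - bd$elbo
          passes[[j]] <- p
        }
        if (use_contrast) {
          batch_users <- users[idx]
          for (j in seq_along(idx)) {
            others <- which(batch_users != batch_users[j])
            if (!length(others)) next
            k <- others[sample.int(length(others), 1L)]
            # pair by timestep; truncate to the shorter window
            n_t <- min(nrow(passes[[j]]$Z), nrow(passes[[k]]$Z))
            cp <- contrast_pair_grads(
              model$contrast,
              train_windows[[idx[j]]][seq_len(n_t), , drop = FALSE],
              passes[[j]]$Z[seq_len(n_t), , drop = FALSE],
              passes[[k]]$Z[seq_len(n_t), , drop = FALSE],
              literal_form = config$literal_contrast)
            batch_loss <- batch_loss + config$contrast_weight * cp$loss
            add_to <- function(store, jj, d) {
              cur <- store[[jj]]
              if (is.null(cur)) cur <- matrix(0, nrow(passes[[jj]]$Z), 2L)
              cur[seq_len(nrow(d)), ] <- cur[seq_len(nrow(d)), ] +
                config$contrast_weight * d
              cur
            }
            extra_dZ[[j]] <- add_to(extra_dZ, j, cp$dz_a)
            extra_dZ[[k]] <- add_to(extra_dZ, k, cp$dz_b)
            cg <- flatten_params(cp$g_net) * config$contrast_weight
            gacc[(length(gacc) - length(cg) + 1L):length(gacc)] <-
              gacc[(length(gacc) - length(cg) + 1L):length(gacc)] + cg
          }
        }
        for (j in seq_along(idx)) {
          g <- elbo_finish(model, passes[[j]], extra_dZ[[j]])
          gl <- list(tf = g$tf, dec = g$dec, dec_log_sd = g$dec_log_sd,
                     drift = g$drift, diff_raw = g$diff_raw,
                     q_log_sd = g$q_log_sd)
          if (use_contrast) {
            gl$contrast <- rapply(model$contrast$params, function(a) a * 0,
                                  how = "replace")
          }
          gacc <- gacc + flatten_params(gl)
        }
      }
      denom <- length(idx) * config$mc_samples
      upd <- adamw_step(par, gacc / denom, state,
                        lr = config$learning_rate,
                        weight_decay = config$weight_decay)
      par <- upd$par
      state <- upd$state
      model <- set_trainable(model, unflatten_params(par, skel))
      epoch_loss <- epoch_loss + batch_loss / config$mc_samples
    }
    hist_train[epoch] <- epoch_loss / nw
    if (!is.null(val_windows) && length(val_windows)) {
      vseed <- derive_seed(config$seed, paste0("val-", epoch))
      vloss <- 0
      for (vw in val_windows) {
        veps <- with_seed(vseed, matrix(stats::rnorm(2L * (nrow(vw) - 1L)),
                                        nrow(vw) - 1L, 2L))
        vloss <- vloss + window_loss_value(model, vw, veps)
      }
      hist_val[epoch] <- vloss / length(val_windows)
    } else {
      hist_val[epoch] <- NA_real_
    }
  }
  list(model = model,
       history = data.frame(epoch = seq_len(config$n_epochs),
                            train_loss = hist_train, val_loss = hist_val))
}

#' Early-warning check for overfitting
#'
#' Implements the usual criterion on a validation-loss trace: overfitting is
#' flagged when the trace stopped decreasing at least `patience` epochs ago
#' and has tended to increase since (the mean of the last `patience` values
#' exceeds the best value by `min_delta`).
#'
#' @param val_trace numeric vector of per-epoch validation losses
#' @param patience number of epochs without improvement (default 10)
#' @param min_delta required increase over the best value (default 0)
#' @return TRUE if the trace shows the stop-then-increase pattern
#' @export
detect_overfitting <- function(val_trace, patience = 10L, min_delta = 0) {
  val_trace <- val_trace[is.finite(val_trace)]
  if (length(val_trace) <= patience) return(FALSE)
  best <- which.min(val_trace)
  n <- length(val_trace)
  (n - best) >= patience &&
    mean(val_trace[(n - patience + 1L):n]) > val_trace[best] + min_delta
}
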