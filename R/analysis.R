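## Post-training analyses: optimized initial latent states, kernel-density
## "normal latent regions", membership tests, motion-switch detection and
## user-identification scoring.

#' Optimize the initial latent state against a pre-window of observations
#'
#' Given extra observations `x_{-T0:0}` before time zero, finds the latent
#' state `z_{-T0}*` whose deterministic (drift-only) rollout through the
#' trained SDE best reproduces the observed midpoint targets, by
#' adaptive-moment gradient descent on `z_{-T0}` with all model weights
#' frozen. If the optimizer somehow ends worse than the PCA initialization,
#' the PCA result is returned with `fallback = TRUE` — the optimized start
#' is never worse than the baseline.
#'
#' @param observations `(T0 + 1) x 4` matrix of normalized frames
#'   `x_{-T0}..x_0`
#' @param model a trained `motion_model` (fitted prior required)
#' @param n_iter optimizer iterations (default 500)
#' @param lr optimizer step size (default 1e-2)
#' @param z_init optional starting point overriding the PCA projection
#' @return an `init_state_result`: list with `z_init_star`, `z0_estimate`,
#'   `final_discrepancy`, `trace` (best-so-far discrepancy per iteration,
#'   non-increasing) and `fallback`
#' @export
optimize_initial_state <- function(observations, model, n_iter = 500L,
                                   lr = 1e-2, z_init = NULL) {
  observations <- as.matrix(observations)
  T0 <- nrow(observations) - 1L
  assert_that(T0 >= 1L, "invalid_argument",
              "need at least 2 frames (T0 >= 1) of pre-window observations")
  assert_that(!is.null(model$prior), "not_fitted", "model prior is unfit")
  targets <- midpoint_targets(observations)        # T0 x 4

  ## discrepancy of a drift-only rollout started at z, with its gradient
  ## propagated back through the unrolled chain:
  ## g_i = d(dec_i) + (I + dt J_drift(z_i))^T g_{i+1}
  objective <- function(z) {
    states <- matrix(0, T0 + 1L, 2L)
    states[1L, ] <- z
    drift_caches <- vector("list", T0)
    for (i in seq_len(T0)) {
      fw <- mlp_forward(model$sde$drift_net, states[i, , drop = FALSE])
      drift_caches[[i]] <- fw$cache
      states[i + 1L, ] <- states[i, ] + fw$out[1L, ] * model$sde$dt
    }
    dec_fw <- mlp_forward(model$decoder$decoder_net,
                          states[seq_len(T0), , drop = FALSE])
    resid <- dec_fw$out - targets
    disc <- sum(resid^2)
    dec_bw <- mlp_backward(model$decoder$decoder_net, dec_fw$cache, 2 * resid)
    carry <- c(0, 0)                               # gradient w.r.t. z_{i+1}
    for (i in rev(seq_len(T0))) {
      jt <- mlp_backward(model$sde$drift_net, drift_caches[[i]],
                         matrix(carry * model$sde$dt, 1L))$dX[1L, ]
      carry <- dec_bw$dX[i, ] + carry + jt
    }
    list(value = disc, grad = carry, z0 = states[T0 + 1L, ])
  }

  z_start <- if (is.null(z_init))
    as.numeric(prior_mean(observations[1L, ], model$prior)) else
    as.numeric(z_init)
  z <- z_start
  init <- objective(z)
  init_disc <- init$value
  best <- list(z = z, value = init$value, z0 = init$z0)
  m <- v <- c(0, 0)
  trace <- numeric(n_iter)
  cur <- init
  for (it in seq_len(n_iter)) {
    g <- cur$grad
    if (!all(is.finite(g))) {
      msde_stop("optimization_failure",
                "non-finite gradient in initial-state optimization")
    }
    m <- 0.9 * m + 0.1 * g
    v <- 0.999 * v + 0.001 * g^2
    mhat <- m / (1 - 0.9^it); vhat <- v / (1 - 0.999^it)
    z <- z - lr * mhat / (sqrt(vhat) + 1e-8)
    cur <- objective(z)
    if (!is.finite(cur$value)) {
      msde_stop("optimization_failure",
                "non-finite discrepancy in initial-state optimization")
    }
    if (cur$value < best$value) best <- list(z = z, value = cur$value, z0 = cur$z0)
    trace[it] <- best$value
  }
  fallback <- best$value > init_disc
  if (fallback) best <- list(z = z_start, value = init_disc, z0 = init$z0)
  structure(list(z_init_star = best$z, z0_estimate = best$z0,
                 final_discrepancy = best$value,
                 initial_discrepancy = init_disc,
                 trace = trace, fallback = fallback),
            class = "init_state_result")
}

#' Fit a kernel-density "normal latent region" for one motion
#'
#' Bivariate Gaussian kernel density over the motion's training latent
#' points with per-axis Scott's-rule bandwidths (`sd_j * n^(-1/6)`); the
#' membership threshold is the `q`-th percentile of the density evaluated at
#' the training points, so about `100 - q` percent of them are members.
#'
#' @param points n x 2 matrix of latent points (n >= 10 unless `bandwidth`
#'   is forced)
#' @param label motion name
#' @param q percentile defining the membership threshold (default 5)
#' @param bandwidth optional scalar or 2-vector overriding Scott's rule
#' @return an object of class `latent_region`
#' @export
fit_latent_region <- function(points, label = "motion", q = 5,
                              bandwidth = NULL) {
  points <- as.matrix(points)
  assert_that(ncol(points) == 2L && all(is.finite(points)),
              "invalid_argument", "points must be a finite n x 2 matrix")
  if (is.null(bandwidth)) {
    assert_that(nrow(points) >= 10L, "invalid_argument",
                "need >= 10 latent points to fit a region")
    sds <- apply(points, 2L, stats::sd)
    if (any(sds <= 0)) {
      msde_stop("degenerate_data",
                "latent points are degenerate (zero spread); cannot fit KDE")
    }
    bandwidth <- sds * nrow(points)^(-1 / 6)
  } else {
    bandwidth <- rep(as.numeric(bandwidth), length.out = 2L)
    assert_that(all(bandwidth > 0), "invalid_argument",
                "bandwidth must be positive")
  }
  region <- structure(list(points = points, bandwidth = bandwidth,
                           label = label, threshold = NA_real_),
                      class = "latent_region")
  dens <- kde_density(region, points)
  region$threshold <- as.numeric(stats::quantile(dens, q / 100))
  region
}

#' Kernel density of a fitted latent region
#'
#' @param region a [fit_latent_region()] object
#' @param z a 2-vector or n x 2 matrix of query points
#' @return density value(s)
#' @export
kde_density <- function(region, z) {
  assert_that(inherits(region, "latent_region"), "not_fitted",
              "region must come from fit_latent_region()")
  if (!is.matrix(z)) z <- matrix(z, ncol = 2L)
  h <- region$bandwidth
  p <- region$points
  n <- nrow(p)
  vapply(seq_len(nrow(z)), function(i) {
    u1 <- (z[i, 1L] - p[, 1L]) / h[1L]
    u2 <- (z[i, 2L] - p[, 2L]) / h[2L]
    sum(exp(-0.5 * (u1^2 + u2^2))) / (n * 2 * pi * h[1L] * h[2L])
  }, numeric(1))
}

#' Membership of latent points in a normal region
#'
#' A point belongs to the region iff its kernel density is at least the
#' region's threshold.
#'
#' @param z a 2-vector or n x 2 matrix
#' @param region a [fit_latent_region()] object
#' @return list with logical `member` and numeric `density`
#' @export
region_membership <- function(z, region) {
  d <- kde_density(region, z)
  list(member = d >= region$threshold, density = d)
}

#' Label a latent trajectory by motion region and detect switches
#'
#' The trajectory is smoothed with a trailing moving average (window 5 by
#' default, matching online use) and each step is labeled by the region of
#' highest kernel density — or `"abnormal"` when it is below every region's
#' membership threshold. A motion switch is a step where the region label
#' changes to a different region than the previously held one; `"abnormal"`
#' steps mark off-manifold excursions but do not themselves constitute
#' switches (a walking-abnormal-walking transient is no switch, and a
#' walking-abnormal-running passage is one switch, dated at the first
#' running step).
#'
#' @param latents n x 2 latent trajectory
#' @param regions named list of [fit_latent_region()] objects (>= 2)
#' @param window smoothing window (default 5)
#' @return list with `labels` (length n), `switch_indices` (1-based steps
#'   where the held region changes) and the `densities` matrix
#' @export
detect_motion_switch <- function(latents, regions, window = 5L) {
  assert_that(is.list(regions) && length(regions) >= 2L, "invalid_argument",
              "need at least 2 fitted regions")
  latents <- as.matrix(latents)
  sm <- smooth_trajectory(latents, window = window)
  dens <- sapply(regions, function(r) kde_density(r, sm))
  if (!is.matrix(dens)) dens <- matrix(dens, nrow = 1L)
  labs <- vapply(seq_len(nrow(dens)), function(i) {
    row <- dens[i, ]
    ok <- vapply(seq_along(regions), function(j)
      row[j] >= regions[[j]]$threshold, logical(1))
    if (!any(ok)) return("abnormal")
    names(regions)[which.max(row)]
  }, character(1))
  held <- NA_character_
  switches <- integer(0)
  for (i in seq_along(labs)) {
    if (labs[i] == "abnormal") next
    if (!is.na(held) && labs[i] != held) switches <- c(switches, i)
    held <- labs[i]
  }
  list(labels = labs, switch_indices = switches, densities = dens)
}

#' Score user identification with the contrast network
#'
#' Evaluates `sigmoid(C(x_t, z_t))` for matched (same-user) and mismatched
#' (other-user) pairings and reports the pairing accuracy: the fraction of
#' matched pairs scoring above 0.5 plus mismatched pairs scoring below 0.5.
#'
#' @param x_seq n x 4 observation frames of user a
#' @param z_same n x 2 latent samples of user a (matched)
#' @param z_other n x 2 latent samples of another user (mismatched)
#' @param net the trained contrast MLP
#' @return list with `prob_same`, `prob_other` (both in (0, 1)) and
#'   `accuracy`
#' @export
user_identification_score <- function(x_seq, z_same, z_other, net) {
  assert_that(inherits(net, "mlp") && net$sizes[1L] == 6L, "not_fitted",
              "net must be the (x, z) contrast MLP")
  x_seq <- as.matrix(x_seq)
  n <- min(nrow(x_seq), nrow(as.matrix(z_same)), nrow(as.matrix(z_other)))
  ps <- sigmoid(contrast_logit(net, x_seq[seq_len(n), , drop = FALSE],
                               as.matrix(z_same)[seq_len(n), , drop = FALSE]))
  po <- sigmoid(contrast_logit(net, x_seq[seq_len(n), , drop = FALSE],
                               as.matrix(z_other)[seq_len(n), , drop = FALSE]))
  # ties at exactly 0.5 (e.g. an all-zero network) count half, so an
  # uninformative scorer sits at chance level
  list(prob_same = ps, prob_other = po,
       accuracy = mean(c((ps > 0.5) + 0.5 * (ps == 0.5),
                         (po < 0.5) + 0.5 * (po == 0.5))))
}
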