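#' Gyroscope magnitude feature
#'
#' The Euclidean norm of the three angular-velocity axes,
#' `sqrt(wx^2 + wy^2 + wz^2)`, appended to the raw axes as a fourth input
#' channel before normalization.
#'
#' @param omega a 3-vector, or an n x 3 matrix of angular velocities (rad/s)
#' @return a scalar, or a length-n vector for matrix input
#' @export
#' @examples
#' compute_magnitude(c(3, 4, 0))  # 5
compute_magnitude <- function(omega) {
  if (is.matrix(omega)) {
    assert_that(ncol(omega) == 3L && all(is.finite(omega)), "invalid_argument",
                "omega must be a finite n x 3 matrix")
    return(sqrt(rowSums(omega^2)))
  }
  assert_that(length(omega) == 3L && all(is.finite(omega)), "invalid_argument",
              "omega must be a finite 3-vector")
  sqrt(sum(omega^2))
}

#' Build the 4-channel observation frames of a recording
#'
#' Columns: raw `omega_x`, `omega_y`, `omega_z` plus the magnitude `omega_t`.
#' The magnitude is computed from the raw axes first; all four channels are
#' z-scored afterwards (see [fit_zscore()]).
#'
#' @param recording a `sensor_recording`
#' @return an n x 4 matrix of raw (un-normalized) frames
#' @export
sensor_frames <- function(recording) {
  assert_that(inherits(recording, "sensor_recording"), "invalid_argument",
              "recording must be a sensor_recording")
  cbind(recording$omega, omega_t = compute_magnitude(recording$omega))
}

#' Fit z-score normalization statistics
#'
#' Per-channel mean and population standard deviation (divisor n, not n-1),
#' to be fit on the training split only and then applied to every split.
#'
#' @param frames an n x 4 matrix of training frames (n >= 2)
#' @return an object of class `norm_stats` with fields `mean` and `sd`
#' @export
#' @examples
#' s <- fit_zscore(matrix(c(0, 2), 2, 1))
#' apply_zscore(matrix(c(0, 2), 2, 1), s)  # -1, 1
fit_zscore <- function(frames) {
  frames <- as.matrix(frames)
  assert_that(nrow(frames) >= 2L && all(is.finite(frames)), "invalid_argument",
              "need >= 2 finite frames to fit z-scores")
  mu <- colMeans(frames)
  sd <- sqrt(colMeans(sweep(frames, 2L, mu)^2))
  if (any(sd <= 0)) {
    msde_stop("degenerate_data", sprintf(
      "channel(s) %s have zero variance; cannot z-score",
      paste(which(sd <= 0), collapse = ", ")))
  }
  structure(list(mean = mu, sd = sd), class = "norm_stats")
}

#' @rdname fit_zscore
#' @param stats a fitted `norm_stats`
#' @export
apply_zscore <- function(frames, stats) {
  assert_that(inherits(stats, "norm_stats"), "invalid_argument",
              "stats must come from fit_zscore()")
  frames <- as.matrix(frames)
  assert_that(ncol(frames) == length(stats$mean), "invalid_argument",
              "frame width does not match the fitted statistics")
  sweep(sweep(frames, 2L, stats$mean), 2L, stats$sd, "/")
}

#' Chronological train/test split
#'
#' The first `floor(train_fraction * n)` rows are training data, the rest
#' test — no shuffling, so the test segment is strictly in the recording's
#' future and normalization statistics fit on the training segment leak
#' nothing from it.
#'
#' @param frames an n x d matrix (or a `sensor_recording`, split on rows of
#'   its frames)
#' @param train_fraction fraction of rows assigned to training (default 0.8)
#' @return list with `train` and `test` matrices
#' @export
split_train_test <- function(frames, train_fraction = 0.8) {
  if (inherits(frames, "sensor_recording")) frames <- sensor_frames(frames)
  frames <- as.matrix(frames)
  assert_that(train_fraction > 0 && train_fraction <= 1, "invalid_argument",
              "train_fraction must be in (0, 1]")
  n <- nrow(frames)
  assert_that(n >= 2L, "invalid_argument", "recording too short to split")
  n_train <- floor(train_fraction * n)
  if (n_train >= n) {
    warning("train_fraction leaves an empty test split")
    n_train <- n
  }
  list(train = frames[seq_len(n_train), , drop = FALSE],
       test  = frames[setdiff(seq_len(n), seq_len(n_train)), , drop = FALSE])
}

#' Cut a frame sequence into fixed-length windows
#'
#' Windows carry `T + 1` frames so that `T` posterior steps, `T` midpoint
#' targets and the transition chain are all defined; the last partial window
#' is dropped. Windows use 0-based half-open index ranges
#' `[start, start + T + 1)`.
#'
#' @param frames an n x d matrix with `n >= T + 1`
#' @param T window length in model steps (default 90)
#' @param stride step between window starts (default `T`, non-overlapping)
#' @return list of `(T + 1) x d` matrices
#' @export
#' @examples
#' length(make_windows(matrix(0, 271, 4), T = 90, stride = 90))  # 3
make_windows <- function(frames, T = 90L, stride = T) {
  frames <- as.matrix(frames)
  assert_that(T >= 1 && stride >= 1, "invalid_argument",
              "T and stride must be positive")
  n <- nrow(frames)
  L <- as.integer(T) + 1L
  assert_that(n >= L, "invalid_argument",
              sprintf("need at least T + 1 = %d frames, got %d", L, n))
  starts <- seq.int(1L, n - L + 1L, by = as.integer(stride))
  lapply(starts, function(s) frames[s:(s + L - 1L), , drop = FALSE])
}

#' Midpoint reconstruction targets
#'
#' The decoder models `p(xbar_{t+1} | z_t)` where
#' `xbar_{t+1} = (x_t + x_{t+1}) / 2` — the average of reconstruction and
#' one-step prediction. A window of `L` frames yields `L - 1` targets.
#'
#' @param window an `L x d` matrix of frames, `L >= 2`
#' @return an `(L - 1) x d` matrix of midpoint targets
#' @export
midpoint_targets <- function(window) {
  window <- as.matrix(window)
  n <- nrow(window)
  assert_that(n >= 2L, "invalid_argument",
              "need at least 2 frames for midpoint targets")
  (window[-n, , drop = FALSE] + window[-1L, , drop = FALSE]) / 2
}

#' Full preprocessing pipeline for one or more recordings
#'
#' For each recording: build 4-channel frames (magnitude first), split
#' chronologically, then z-score with statistics fit on the pooled training
#' segments only, and window both splits. The fixed order
#' magnitude -> z-score (train-fit) -> window is part of the model contract.
#'
#' @param recordings a `sensor_recording` or list of them
#' @param T window length in model steps (default 90)
#' @param stride window stride (default `T`)
#' @param train_fraction chronological training fraction (default 0.8)
#' @return list with `train_windows`, `test_windows` (each a list of
#'   `(T+1) x 4` matrices), parallel `train_meta` / `test_meta` data frames
#'   (subject, motion), `stats` (fitted `norm_stats`), and `train_frames`
#'   (pooled normalized training frames, used to fit the latent prior)
#' @export
preprocess_recordings <- function(recordings, T = 90L, stride = T,
                                  train_fraction = 0.8) {
  if (inherits(recordings, "sensor_recording")) recordings <- list(recordings)
  assert_that(length(recordings) >= 1 &&
                all(vapply(recordings, inherits, logical(1), "sensor_recording")),
              "invalid_argument", "recordings must be sensor_recording objects")
  splits <- lapply(recordings, split_train_test, train_fraction = train_fraction)
  stats <- fit_zscore(do.call(rbind, lapply(splits, `[[`, "train")))
  out <- list(train_windows = list(), test_windows = list(),
              train_meta = NULL, test_meta = NULL, stats = stats)
  meta_tr <- meta_te <- list()
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    tr <- apply_zscore(splits[[i]]$train, stats)
    wtr <- make_windows(tr, T = T, stride = stride)
    out$train_windows <- c(out$train_windows, wtr)
    meta_tr[[i]] <- data.frame(subject = rep(rec$subject_id, length(wtr)),
                               motion = rep(rec$motion, length(wtr)))
    if (nrow(splits[[i]]$test) >= T + 1L) {
      te <- apply_zscore(splits[[i]]$test, stats)
      wte <- make_windows(te, T = T, stride = stride)
      out$test_windows <- c(out$test_windows, wte)
      meta_te[[i]] <- data.frame(subject = rep(rec$subject_id, length(wte)),
                                 motion = rep(rec$motion, length(wte)))
    }
  }
  out$train_meta <- do.call(rbind, meta_tr)
  out$test_meta <- if (length(meta_te)) do.call(rbind, meta_te)
  out$train_frames <- do.call(rbind, lapply(splits, function(s)
    apply_zscore(s$train, stats)))
  out
}
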