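#' Fit the full model to one or more recordings
#'
#' The end-to-end pipeline: builds 4-channel frames (magnitude feature),
#' splits each recording 80/20 chronologically, z-scores with statistics
#' fit on the pooled training segments, windows both splits, fits the PCA
#' prior on the training frames, and trains the latent SDE + transformer
#' posterior by ELBO maximization (the 20% test windows serve as the
#' validation monitoring set).
#'
#' @param recordings a `sensor_recording` or list of them
#' @param T window length in model steps (default 90)
#' @param stride window stride (default `T`)
#' @param train_fraction chronological training fraction (default 0.8)
#' @param model a `motion_model` to start from; by default one is created
#'   with `...` passed to [new_motion_model()]
#' @param config a [train_config()]
#' @param contrast_by grouping for the optional contrastive term: contrast
#'   users against each other (`"subject"`, the user-identification setting)
#'   or motions against each other (`"motion"`, sharpening the shared latent
#'   space of a multi-motion run)
#' @param ... further arguments to [new_motion_model()]
#' @return a `motion_fit`: list with the trained `model`, `history`, the
#'   preprocessed `data` (windows, metadata, statistics) and the config
#' @export
#' @examples
#' \donttest{
#' rec <- generate_recording(motion_archetype("walking"),
#'                           subject_profile("s1"), 600, seed = 1)
#' fit <- fit_motion_model(rec, T = 30, config = train_config(n_epochs = 2))
#' }
fit_motion_model <- function(recordings, T = 90L, stride = T,
                             train_fraction = 0.8, model = NULL,
                             config = train_config(),
                             contrast_by = c("subject", "motion"), ...) {
  contrast_by <- match.arg(contrast_by)
  data <- preprocess_recordings(recordings, T = T, stride = stride,
                                train_fraction = train_fraction)
  if (is.null(model)) {
    model <- new_motion_model(T = T, seed = derive_seed(config$seed, "model"),
                              ...)
  }
  assert_that(model$T >= T, "invalid_argument",
              "model window length is smaller than the requested T")
  model$stats <- data$stats
  model$prior <- fit_prior(data$train_frames)
  fit <- train_motion_model(model, data$train_windows,
                            val_windows = data$test_windows,
                            config = config,
                            users = data$train_meta[[contrast_by]])
  structure(list(model = fit$model, history = fit$history, data = data,
                 config = config), class = "motion_fit")
}

#' @export
print.motion_fit <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf(
    "<motion_fit> %d train / %d test windows, %d epochs\n  final loss: train %.4f, val %s\n",
    length(x$data$train_windows), length(x$data$test_windows), n,
    x$history$train_loss[n],
    if (is.finite(x$history$val_loss[n]))
      sprintf("%.4f", x$history$val_loss[n]) else "NA"))
  print(x$model)
  invisible(x)
}
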