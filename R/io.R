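#' Read a gyroscope sensor log
#'
#' Expects a CSV with header columns `timestamp,omega_x,omega_y,omega_z`
#' (seconds and rad/s). Extra columns are ignored with a warning; missing
#' required columns are a format error; non-numeric cells are a parse error
#' reporting the first offending row; non-monotone timestamps are rejected.
#'
#' @param path file path
#' @param subject_id,motion optional labels attached to the recording
#' @return a `sensor_recording`
#' @export
read_sensor_csv <- function(path, subject_id = "unknown", motion = "unknown") {
  assert_that(file.exists(path), "invalid_argument",
              sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  need <- c("timestamp", "omega_x", "omega_y", "omega_z")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    msde_stop("format_error", sprintf("missing column(s): %s",
                                      paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(raw), need)
  if (length(extra)) {
    warning(sprintf("ignoring extra column(s): %s",
                    paste(extra, collapse = ", ")))
  }
  num <- lapply(need, function(cn) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(!is.finite(v) & nzchar(raw[[cn]]))
    bad <- c(bad, which(is.na(v)))
    if (length(bad)) {
      msde_stop("parse_error", sprintf(
        "non-numeric value in column '%s' at data row %d", cn, min(bad)))
    }
    v
  })
  names(num) <- need
  ts <- num$timestamp
  assert_that(length(ts) >= 2L, "format_error", "recording has < 2 samples")
  if (any(diff(ts) <= 0)) {
    msde_stop("format_error", "timestamps must be strictly increasing")
  }
  omega <- cbind(omega_x = num$omega_x, omega_y = num$omega_y,
                 omega_z = num$omega_z)
  rate <- 1 / stats::median(diff(ts))
  rec <- structure(list(subject_id = subject_id, motion = motion,
                        sample_rate = rate, timestamps = ts, omega = omega),
                   class = "sensor_recording")
  rec
}

#' Write a recording as a sensor CSV
#'
#' Values are written with 17 significant digits so a write/read cycle
#' round-trips doubles exactly.
#'
#' @param recording a `sensor_recording`
#' @param path destination file
#' @return `path`, invisibly
#' @export
write_sensor_csv <- function(recording, path) {
  assert_that(inherits(recording, "sensor_recording"), "invalid_argument",
              "recording must be a sensor_recording")
  fmt <- function(v) sprintf("%.17g", v)
  lines <- c("timestamp,omega_x,omega_y,omega_z",
             paste(fmt(recording$timestamps), fmt(recording$omega[, 1L]),
                   fmt(recording$omega[, 2L]), fmt(recording$omega[, 3L]),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Save / load a fitted model bundle
#'
#' The bundle contains every weight, the PCA prior, the normalization
#' statistics and the configuration snapshot; loading it and re-running
#' inference on the same input reproduces latent trajectories bit-for-bit.
#'
#' @param model a `motion_model`
#' @param path destination file (RDS)
#' @return `path` invisibly (`save`), or the `motion_model` (`load`)
#' @export
save_model_bundle <- function(model, path) {
  assert_that(inherits(model, "motion_model"), "invalid_argument",
              "model must be a motion_model")
  saveRDS(list(format = "motionsde-bundle", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(path) {
  assert_that(file.exists(path), "invalid_argument",
              sprintf("file not found: %s", path))
  b <- readRDS(path)
  assert_that(is.list(b) && identical(b$format, "motionsde-bundle"),
              "format_error", "not a motionsde model bundle")
  b$model
}

## ---- run configuration -----------------------------------------------------

run_config_defaults <- function() {
  list(data_dir = ".", output_dir = ".",
       T = 90L, stride = 90L, train_fraction = 0.8,
       embed_dim = 32L, n_layers = 2L, drift_hidden = 64L,
       decoder_hidden = 64L,
       batch_size = 128L, learning_rate = 1e-3, weight_decay = 1e-2,
       n_epochs = 50L, contrast_weight = 0,
       T0 = 30L, kde_percentile = 5, smoothing_window = 5L,
       seed = 0L)
}

#' Read / write a run configuration
#'
#' A flat, human-editable YAML key-value document covering paths,
#' preprocessing, model, training and analysis settings plus the single
#' global seed from which every module seed is derived. Unknown keys are an
#' error (fail fast); omitted keys take their defaults. The file form
#' round-trips losslessly.
#'
#' @param path YAML file path
#' @return a named list of settings
#' @export
read_run_config <- function(path) {
  assert_that(file.exists(path), "invalid_argument",
              sprintf("file not found: %s", path))
  user <- yaml::read_yaml(path)
  defs <- run_config_defaults()
  unknown <- setdiff(names(user), names(defs))
  if (length(unknown)) {
    msde_stop("format_error", sprintf("unknown config key(s): %s",
                                      paste(unknown, collapse = ", ")))
  }
  utils::modifyList(defs, user)
}

#' @rdname read_run_config
#' @param config a named list of settings (unknown keys rejected)
#' @export
write_run_config <- function(config, path) {
  unknown <- setdiff(names(config), names(run_config_defaults()))
  if (length(unknown)) {
    msde_stop("format_error", sprintf("unknown config key(s): %s",
                                      paste(unknown, collapse = ", ")))
  }
  yaml::write_yaml(config, path)
  invisible(path)
}
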