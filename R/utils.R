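#' Classed error helper
#'
#' All user-facing errors in the package carry a subclass so callers (and the
#' test suite) can distinguish invalid arguments from degenerate data,
#' unfitted models, file-format problems and optimization failures.
#'
#' @param class short error class, e.g. "invalid_argument"
#' @param msg message
#' @noRd
msde_stop <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(paste0("motionsde_", class), "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

assert_that <- function(ok, class, msg) {
  if (!isTRUE(ok)) msde_stop(class, msg)
  invisible(TRUE)
}

#' Run code with a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so generators are pure
#' functions of their arguments without clobbering the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Derive a module seed from a global seed
#'
#' One global seed deterministically derives every per-module / per-call seed
#' through a fixed integer hash of a text label, keeping whole-pipeline runs
#' reproducible from a single number. Results stay below 2^31 - 1.
#'
#' @param seed integer global seed
#' @param label character tag naming the consumer (e.g. "train", "subject-3")
#' @return an integer seed
#' @export
#' @examples
#' derive_seed(1L, "train")
derive_seed <- function(seed, label) {
  h <- 0
  for (v in utf8ToInt(as.character(label))) h <- (h * 131 + v) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h) %% 2147483647)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
sigmoid  <- function(x) 1 / (1 + exp(-x))

#' Dominant discrete-Fourier period of a signal
#'
#' Returns `length(x) / k*` where `k*` is the non-DC frequency bin with the
#' largest modulus — the period (in samples) of the strongest oscillation.
#' Used throughout to check that latent trajectories preserve the time-domain
#' frequency of the gyroscope signal (walking about 30 samples per cycle,
#' running about 20 at 30 Hz).
#'
#' @param x numeric vector (one channel of a signal or latent coordinate)
#' @return dominant period in samples
#' @export
#' @examples
#' dominant_period(sin(2 * pi * (0:299) / 30))  # 30
dominant_period <- function(x) {
  assert_that(is.numeric(x) && length(x) >= 4, "invalid_argument",
              "dominant_period() needs a numeric signal of length >= 4")
  n <- length(x)
  mod <- Mod(stats::fft(x - mean(x)))
  half <- mod[2:floor(n / 2 + 1)]
  n / which.max(half)
}

## ---- nested parameter-list helpers -----------------------------------------
## Trainable parameters live in nested lists of numeric arrays; the optimizer
## works on a single flat vector. unflatten restores the original shapes.

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(v, skeleton) {
  i <- 0L
  rebuild <- function(s) {
    if (is.list(s)) return(lapply(s, rebuild))
    n <- length(s)
    out <- v[(i + 1L):(i + n)]
    i <<- i + n
    if (!is.null(dim(s))) dim(out) <- dim(s)
    out
  }
  out <- rebuild(skeleton)
  stopifnot(i == length(v))
  out
}

#' Trailing moving average used to smooth latent trajectories
#'
#' The first `window - 1` entries average over the shorter history that is
#' available (a causal filter: no future samples are used), so the output has
#' the same length as the input.
#'
#' @param latents numeric vector or matrix (rows = time steps)
#' @param window rolling window size in steps (default 5)
#' @return smoothed object of the same shape
#' @export
#' @examples
#' smooth_trajectory(c(0, 0, 0, 0, 5), window = 5)  # last value 1
smooth_trajectory <- function(latents, window = 5L) {
  assert_that(is.numeric(window) && length(window) == 1L && window >= 1,
              "invalid_argument", "window must be a positive integer")
  window <- as.integer(window)
  smooth1 <- function(x) {
    n <- length(x)
    cs <- cumsum(x)
    lag <- c(rep(0, min(window, n)), cs[seq_len(max(0L, n - window))])
    denom <- pmin(seq_len(n), window)
    (cs - lag) / denom
  }
  if (is.matrix(latents)) apply(latents, 2L, smooth1) else smooth1(latents)
}
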