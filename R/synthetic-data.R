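#' Motion archetype
#'
#' Describes one repetitive motion class as seen by a leg-mounted smartphone
#' gyroscope sampled at 30 Hz: a fundamental period in samples, per-axis base
#' amplitudes, and the relative weights of the harmonics that make the signal
#' non-sinusoidal. Walking completes a cycle in about 30 samples and running
#' in about 20; squats (slow) and jumping jacks are given fixture defaults of
#' 45 and 25 samples.
#'
#' @param name one of "walking", "running", "squats", "jumping_jacks"
#' @param period_samples samples per motion cycle (default by name)
#' @param amplitude_profile 3-vector of per-axis base amplitudes (rad/s)
#' @param harmonic_weights relative amplitudes of the fundamental and its
#'   harmonics (default `c(1, 0.4, 0.15)`)
#' @return an object of class `motion_archetype`
#' @export
#' @examples
#' motion_archetype("walking")$period_samples  # 30
motion_archetype <- function(name = c("walking", "running", "squats", "jumping_jacks"),
                             period_samples = NULL,
                             amplitude_profile = NULL,
                             harmonic_weights = c(1, 0.4, 0.15)) {
  name <- match.arg(name)
  # axis mixes differ by motion: leg swing (walking) is dominated by rotation
  # about the mediolateral axis (y here), running adds strong thigh pitch
  # (x), squats are slow hip-hinge rotations (z-heavy), jumping jacks mix
  # abduction (x) and z. Distinct mixes keep the motions on distinct
  # directions of observation space, as different exercises excite different
  # rotation axes of a pocket-worn sensor.
  defaults <- list(
    walking       = list(period = 30L, amp = c(1.2, 2.5, 0.8)),
    running       = list(period = 20L, amp = c(4.0, 2.2, 1.6)),
    squats        = list(period = 45L, amp = c(0.5, 0.7, 1.6)),
    jumping_jacks = list(period = 25L, amp = c(2.4, 1.0, 2.6))
  )[[name]]
  if (is.null(period_samples)) period_samples <- defaults$period
  if (is.null(amplitude_profile)) amplitude_profile <- defaults$amp
  assert_that(length(period_samples) == 1L && is.finite(period_samples) &&
                period_samples >= 2, "invalid_argument",
              "period_samples must be a single number >= 2")
  assert_that(length(amplitude_profile) == 3L &&
                all(is.finite(amplitude_profile)) &&
                all(amplitude_profile >= 0), "invalid_argument",
              "amplitude_profile must be 3 finite non-negative amplitudes")
  assert_that(length(harmonic_weights) >= 1L && all(is.finite(harmonic_weights)),
              "invalid_argument", "harmonic_weights must be finite")
  structure(list(name = name,
                 period_samples = as.numeric(period_samples),
                 amplitude_profile = as.numeric(amplitude_profile),
                 harmonic_weights = as.numeric(harmonic_weights)),
            class = "motion_archetype")
}

#' Subject profile for the synthetic cohort
#'
#' Per-subject variation applied on top of a motion archetype: a tempo
#' multiplier, an overall amplitude multiplier, per-axis phase offsets and a
#' white-noise standard deviation — the stand-in for anatomical and pacing
#' differences between recruited subjects.
#'
#' @param subject_id character id
#' @param period_scale tempo multiplier, in (0.5, 2)
#' @param amplitude_scale amplitude multiplier, in (0.5, 2)
#' @param phase_offsets 3-vector of per-axis phases (radians)
#' @param noise_sd additive white Gaussian noise sd (rad/s)
#' @return an object of class `subject_profile`
#' @export
subject_profile <- function(subject_id, period_scale = 1, amplitude_scale = 1,
                            phase_offsets = c(0, 0, 0), noise_sd = 0.05) {
  assert_that(period_scale > 0.5 && period_scale < 2 &&
                amplitude_scale > 0.5 && amplitude_scale < 2,
              "invalid_argument", "subject scales must lie in (0.5, 2)")
  assert_that(length(phase_offsets) == 3L && all(is.finite(phase_offsets)),
              "invalid_argument", "phase_offsets must be 3 finite radians")
  assert_that(is.finite(noise_sd) && noise_sd >= 0, "invalid_argument",
              "noise_sd must be non-negative")
  structure(list(subject_id = as.character(subject_id),
                 period_scale = period_scale,
                 amplitude_scale = amplitude_scale,
                 phase_offsets = as.numeric(phase_offsets),
                 noise_sd = noise_sd),
            class = "subject_profile")
}

new_sensor_recording <- function(subject_id, motion, sample_rate, omega) {
  n <- nrow(omega)
  structure(list(subject_id = subject_id, motion = motion,
                 sample_rate = sample_rate,
                 timestamps = (seq_len(n) - 1) / sample_rate,
                 omega = omega),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> subject=%s motion=%s  %d samples @ %g Hz\n",
              x$subject_id, x$motion, nrow(x$omega), x$sample_rate))
  invisible(x)
}

## Core synthesizer: one archetype per step (allows mid-recording switches),
## phase carried by accumulation so switches are phase-continuous.
synth_omega <- function(arch_per_step, subject, seed) {
  n <- length(arch_per_step)
  freq <- vapply(arch_per_step, function(a)
    1 / (a$period_samples * subject$period_scale), numeric(1))
  theta <- cumsum(c(0, 2 * pi * freq[-n]))  # theta_0 = 0
  omega <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    a <- arch_per_step[[i]]
    for (ax in 1:3) {
      s <- 0
      for (h in seq_along(a$harmonic_weights)) {
        s <- s + a$harmonic_weights[h] *
          sin(h * (theta[i] + subject$phase_offsets[ax]))
      }
      omega[i, ax] <- subject$amplitude_scale * a$amplitude_profile[ax] * s
    }
  }
  if (subject$noise_sd > 0) {
    omega <- omega + with_seed(seed, matrix(
      stats::rnorm(n * 3L, 0, subject$noise_sd), n, 3L))
  }
  colnames(omega) <- c("omega_x", "omega_y", "omega_z")
  omega
}

## Vectorized fast path for a constant archetype (identical output to
## synth_omega with a constant archetype list).
synth_omega_const <- function(arch, subject, n, seed) {
  freq <- 1 / (arch$period_samples * subject$period_scale)
  # accumulated phase, matching synth_omega() bit-for-bit
  theta <- cumsum(c(0, rep(2 * pi * freq, n - 1L)))
  omega <- matrix(0, n, 3L)
  for (ax in 1:3) {
    s <- numeric(n)
    for (h in seq_along(arch$harmonic_weights)) {
      s <- s + arch$harmonic_weights[h] *
        sin(h * (theta + subject$phase_offsets[ax]))
    }
    omega[, ax] <- subject$amplitude_scale * arch$amplitude_profile[ax] * s
  }
  if (subject$noise_sd > 0) {
    omega <- omega + with_seed(seed, matrix(
      stats::rnorm(n * 3L, 0, subject$noise_sd), n, 3L))
  }
  colnames(omega) <- c("omega_x", "omega_y", "omega_z")
  omega
}

#' Generate one synthetic gyroscope recording
#'
#' Each axis is a sum of harmonics of the archetype's fundamental frequency
#' (scaled by the subject's tempo), with per-axis phase offsets, an overall
#' amplitude scale, and additive white Gaussian noise. The same arguments and
#' seed always reproduce the identical recording.
#'
#' @param archetype a [motion_archetype()]
#' @param subject a [subject_profile()]
#' @param n_steps number of samples (>= 2 effective periods)
#' @param seed integer seed for the noise
#' @param sample_rate sampling rate in Hz (default 30)
#' @return a `sensor_recording`
#' @export
#' @examples
#' rec <- generate_recording(motion_archetype("walking"),
#'                           subject_profile("s1", noise_sd = 0), 300, seed = 1)
#' dominant_period(rec$omega[, 2])  # 30
generate_recording <- function(archetype, subject, n_steps, seed,
                               sample_rate = 30) {
  assert_that(inherits(archetype, "motion_archetype"), "invalid_argument",
              "archetype must be a motion_archetype")
  assert_that(inherits(subject, "subject_profile"), "invalid_argument",
              "subject must be a subject_profile")
  assert_that(length(n_steps) == 1L && is.finite(n_steps) && n_steps > 0,
              "invalid_argument", "n_steps must be a positive integer")
  assert_that(length(sample_rate) == 1L && is.finite(sample_rate) &&
                sample_rate > 0, "invalid_argument",
              "sample_rate must be positive")
  eff_period <- archetype$period_samples * subject$period_scale
  assert_that(n_steps >= 2 * eff_period, "invalid_argument",
              sprintf("n_steps must cover >= 2 effective periods (%.1f samples)",
                      2 * eff_period))
  omega <- synth_omega_const(archetype, subject, as.integer(n_steps), seed)
  new_sensor_recording(subject$subject_id, archetype$name, sample_rate, omega)
}

#' Generate a multi-subject, multi-motion cohort
#'
#' Draws subject profiles reproducibly (tempo ~ U(0.85, 1.15), amplitude ~
#' U(0.7, 1.3), phases ~ U(0, 2pi), noise sd 0.05 rad/s) and produces one
#' recording per (subject, motion) pair.
#'
#' @param n_subjects number of subjects (>= 1)
#' @param motions list of [motion_archetype()] objects
#' @param n_steps samples per recording
#' @param seed integer seed; drives both profile draws and noise
#' @param noise_sd per-subject noise sd (default 0.05 rad/s)
#' @return list with `subjects` (profiles) and `recordings`
#' @export
generate_cohort <- function(n_subjects, motions, n_steps, seed, noise_sd = 0.05) {
  assert_that(length(n_subjects) == 1L && n_subjects >= 1, "invalid_argument",
              "n_subjects must be >= 1")
  assert_that(is.list(motions) && length(motions) >= 1 &&
                all(vapply(motions, inherits, logical(1), "motion_archetype")),
              "invalid_argument", "motions must be a non-empty list of archetypes")
  subjects <- lapply(seq_len(n_subjects), function(i) {
    with_seed(derive_seed(seed, paste0("subject-", i)), {
      subject_profile(sprintf("S%02d", i),
                      period_scale = stats::runif(1, 0.85, 1.15),
                      amplitude_scale = stats::runif(1, 0.7, 1.3),
                      phase_offsets = stats::runif(3, 0, 2 * pi),
                      noise_sd = noise_sd)
    })
  })
  recordings <- list()
  for (i in seq_len(n_subjects)) {
    for (m in seq_along(motions)) {
      rec_seed <- derive_seed(seed, sprintf("rec-%d-%s", i, motions[[m]]$name))
      recordings[[length(recordings) + 1L]] <-
        generate_recording(motions[[m]], subjects[[i]], n_steps, rec_seed)
    }
  }
  list(subjects = subjects, recordings = recordings)
}

#' Generate a recording that switches motion mid-stream
#'
#' Samples before `switch_step` (0-based) follow `arch_a`, samples from
#' `switch_step` on follow `arch_b`. The oscillator phase is accumulated
#' across the switch, so the waveform is phase-continuous — the frequency
#' changes without an artificial discontinuity spike.
#'
#' @param arch_a,arch_b motion archetypes before/after the switch
#' @param switch_step 0-based sample index of the switch, in `[0, n_steps)`
#' @param subject a [subject_profile()]
#' @param n_steps total number of samples
#' @param seed integer noise seed
#' @param sample_rate sampling rate in Hz (default 30)
#' @return a `sensor_recording` with motion label `"a->b"`
#' @export
generate_switching_recording <- function(arch_a, arch_b, switch_step, subject,
                                         n_steps, seed, sample_rate = 30) {
  assert_that(inherits(arch_a, "motion_archetype") &&
                inherits(arch_b, "motion_archetype"), "invalid_argument",
              "arch_a and arch_b must be motion_archetype objects")
  assert_that(length(switch_step) == 1L && switch_step >= 0 &&
                switch_step < n_steps, "invalid_argument",
              "switch_step must lie in [0, n_steps)")
  n_steps <- as.integer(n_steps)
  arch_per_step <- c(rep(list(arch_a), switch_step),
                     rep(list(arch_b), n_steps - switch_step))
  omega <- synth_omega(arch_per_step, subject, seed)
  rec <- new_sensor_recording(subject$subject_id,
                              paste0(arch_a$name, "->", arch_b$name),
                              sample_rate, omega)
  rec$switch_step <- as.integer(switch_step)
  rec
}
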