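# ---- Synthetic piezoelectric signal generation and torque labelling ----

# Run code with a local, restorable RNG state when a seed is given.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Generator calibration
#'
#' Phenomenological calibration of the piezoelectric signal generator:
#' force-to-voltage sensitivity, frequency-dependent relative amplitude
#' attenuation (normalized to 1 at 2 Hz and interpolated linearly between the
#' measured frequencies, clamped outside their range), biphasic pulse duty
#' fraction, and additive noise sources (white, cardiac, respiratory, and
#' Poisson mechanical transients).
#'
#' The defaults reproduce the characterized film: 0.50 V/N sensitivity
#' (5.76 V at the 11.5 N standard load, 2 Hz) falling to 3.89 V at 10 Hz.
#'
#' @param sensitivity volts per newton (> 0).
#' @param atten_freq frequencies (Hz) at which attenuation is tabulated.
#' @param atten relative amplitudes at \code{atten_freq} (first entry 1).
#' @param duty pulse width as a fraction of the cycle period, in (0, 1].
#' @param noise list: \code{white_sd} (V), \code{cardiac_hz}/\code{cardiac_amp},
#'   \code{resp_hz}/\code{resp_amp}, \code{transient_rate} (1/s),
#'   \code{transient_amp} (V).
#' @return object of class \code{generator_calibration}.
#' @export
generator_calibration <- function(sensitivity = 5.76 / 11.5,
                                  atten_freq = c(2, 5, 8, 10),
                                  atten = c(5.76, 4.74, 4.275, 3.89) / 5.76,
                                  duty = 0.4,
                                  noise = list(white_sd = 0.05,
                                               cardiac_hz = 1.2, cardiac_amp = 0.05,
                                               resp_hz = 0.3, resp_amp = 0.08,
                                               transient_rate = 0.05,
                                               transient_amp = 0.5)) {
  stopifnot(sensitivity > 0, length(atten_freq) == length(atten),
            all(atten > 0), duty > 0, duty <= 1)
  if (is.unsorted(atten_freq)) stop("atten_freq must be increasing")
  if (any(diff(atten) > 1e-12))
    stop("attenuation must be non-increasing with frequency")
  need <- c("white_sd", "cardiac_amp", "resp_amp", "transient_amp",
            "cardiac_hz", "resp_hz", "transient_rate")
  miss <- setdiff(need, names(noise))
  if (length(miss)) stop("noise config missing: ", paste(miss, collapse = ", "))
  if (any(unlist(noise[c("white_sd", "cardiac_amp", "resp_amp", "transient_amp")]) < 0))
    stop("noise amplitudes must be >= 0")
  structure(list(sensitivity = sensitivity, atten_freq = atten_freq,
                 atten = atten, duty = duty, noise = noise),
            class = "generator_calibration")
}

#' Relative amplitude attenuation at a loading frequency
#'
#' @param calib a \code{\link{generator_calibration}}.
#' @param freq loading frequency (Hz); vectorized.
#' @return relative amplitude(s), 1 at 2 Hz.
#' @export
attenuation <- function(calib, freq) {
  stopifnot(inherits(calib, "generator_calibration"))
  stats::approx(calib$atten_freq, calib$atten, xout = freq, rule = 2)$y
}

#' Subject anthropometry for torque labelling
#'
#' @param body_weight body weight (N); default chosen so that the default
#'   foot weight is 10.98 N.
#' @param foot_weight effective foot weight (N), default 1.4\% of body weight.
#' @param shank_length knee-to-ankle distance (m), default 0.47.
#' @return object of class \code{subject_params}.
#' @export
subject_params <- function(body_weight = 10.98 / 0.014,
                           foot_weight = 0.014 * body_weight,
                           shank_length = 0.47) {
  stopifnot(body_weight > 0, foot_weight > 0, shank_length > 0)
  structure(list(body_weight = body_weight, foot_weight = foot_weight,
                 shank_length = shank_length), class = "subject_params")
}

#' Knee joint torque label
#'
#' \eqn{\tau = F L \sin(\theta)} with \eqn{F} the combined foot weight and
#' external load, \eqn{L} the shank length, and \eqn{\theta} the angle of the
#' lower leg from vertical.
#'
#' @param subject a \code{\link{subject_params}}.
#' @param load external load (N), >= 0.
#' @param angle knee angle (degrees), in [0, 180]; vectorized with load.
#' @return torque (Nm).
#' @examples
#' torque_label(subject_params(), 58.8, 90)  # 32.80 Nm
#' @export
torque_label <- function(subject, load, angle) {
  stopifnot(inherits(subject, "subject_params"))
  if (any(load < 0)) stop("load must be non-negative")
  if (any(angle < 0 | angle > 180)) stop("angle must lie in [0, 180] degrees")
  (load + subject$foot_weight) * subject$shank_length * sin(angle * pi / 180)
}

#' Motion condition grid
#'
#' The labelled condition grid: external loads crossed with knee angles, each
#' with its derived torque and a class index (0-based, ordered by increasing
#' torque).
#'
#' @param subject a \code{\link{subject_params}}.
#' @param loads external loads (N), default \code{c(0, 9.8, 58.8)}.
#' @param angles knee angles (deg), default \code{c(20, 60, 90)}.
#' @return data.frame with columns load, angle, torque, class.
#' @export
motion_conditions <- function(subject = subject_params(),
                              loads = c(0, 9.8, 58.8),
                              angles = c(20, 60, 90)) {
  grid <- expand.grid(load = loads, angle = angles)
  grid$torque <- torque_label(subject, grid$load, grid$angle)
  if (anyDuplicated(signif(grid$torque, 12)))
    stop("duplicate torque labels across conditions: class map ill-defined")
  grid$class <- rank(grid$torque) - 1L
  grid[order(grid$class), c("load", "angle", "torque", "class")]
}

#' Event schedule
#'
#' @param onset event onset times (s), strictly increasing.
#' @param load,angle per-event condition (recycled if scalar).
#' @return data.frame of class \code{event_schedule}.
#' @export
event_schedule <- function(onset, load, angle) {
  if (length(onset) && any(diff(onset) <= 0))
    stop("event onsets must be strictly increasing")
  df <- data.frame(onset = onset, load = rep_len(load, length(onset)),
                   angle = rep_len(angle, length(onset)))
  class(df) <- c("event_schedule", "data.frame")
  df
}

#' Regular flexion-exercise schedule
#'
#' One knee-flexion event every \code{interval} seconds (default 3 s),
#' cycling through the supplied conditions.
#'
#' @param conditions data.frame with load and angle columns (e.g. from
#'   \code{\link{motion_conditions}}).
#' @param n_events number of events.
#' @param interval inter-event interval (s), default 3.
#' @param start onset of the first event (s), default 0.
#' @return an \code{\link{event_schedule}}.
#' @export
regular_schedule <- function(conditions, n_events, interval = 3, start = 0) {
  idx <- rep_len(seq_len(nrow(conditions)), n_events)
  event_schedule(start + (seq_len(n_events) - 1) * interval,
                 conditions$load[idx], conditions$angle[idx])
}

# Biphasic flexion/compression pulse on [0, width): a positive loading lobe
# followed by an equal negative unloading lobe, returning exactly to baseline.
# `harmonic` adds a same-support second-harmonic component (angle encoding).
.pulse <- function(t, width, amplitude, harmonic = 0) {
  inside <- t >= 0 & t < width
  out <- numeric(length(t))
  ph <- t[inside] / width
  out[inside] <- amplitude * (sin(2 * pi * ph) + harmonic * sin(4 * pi * ph))
  out
}

# Angle-dependent pulse shaping: duration shrinks with flexion angle, a
# second harmonic grows with it, and the motion micro-vibration burst rides
# at an angle-dependent carrier frequency, so angle is recoverable from the
# magnitude spectrum regardless of the event's position in the window.
.angle_width <- function(angle, base = 0.8) base * (0.5 + 0.5 * (1 - angle / 180))
.angle_harmonic <- function(angle) 0.35 * angle / 90
.angle_carrier <- function(angle) 10 + angle / 3   # Hz: 16.7 / 30 / 40 at 20/60/90 deg

# Flexion event: biphasic loading/unloading pulse plus a Hann-enveloped
# vibrational burst (relative amplitude `vib`) at the angle carrier frequency.
.flexion_pulse <- function(t, angle, amplitude, vib = 0.35) {
  w <- .angle_width(angle)
  inside <- t >= 0 & t < w
  out <- numeric(length(t))
  ph <- t[inside] / w
  env <- 0.5 * (1 - cos(2 * pi * ph))
  out[inside] <- amplitude *
    (sin(2 * pi * ph) + .angle_harmonic(angle) * sin(4 * pi * ph) +
       vib * env * sin(2 * pi * .angle_carrier(angle) * t[inside]))
  out
}

# Additive noise per calibration; one draw per call from the current RNG.
.noise_trace <- function(calib, n, fs) {
  nz <- calib$noise
  t <- (seq_len(n) - 1) / fs
  x <- stats::rnorm(n, 0, nz$white_sd)
  x <- x + nz$cardiac_amp * sin(2 * pi * nz$cardiac_hz * t + stats::runif(1, 0, 2 * pi))
  x <- x + nz$resp_amp * sin(2 * pi * nz$resp_hz * t + stats::runif(1, 0, 2 * pi))
  k <- stats::rpois(1, nz$transient_rate * n / fs)
  if (k > 0) {
    centers <- stats::runif(k, 0, n / fs)
    signs <- sample(c(-1, 1), k, replace = TRUE)
    for (i in seq_len(k))                      # 20 ms mechanical spike
      x <- x + signs[i] * nz$transient_amp * exp(-((t - centers[i]) / 0.02)^2)
  }
  x
}

#' Waveform container
#'
#' @param samples voltage samples (V), finite.
#' @param fs sampling rate (Hz), default 1000.
#' @return object of class \code{waveform}.
#' @export
waveform <- function(samples, fs = 1000) {
  stopifnot(fs > 0)
  if (!all(is.finite(samples))) stop("waveform samples must be finite")
  structure(list(samples = as.numeric(samples), fs = fs), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("Waveform: %d samples at %g Hz (%.3f s), range [%.3f, %.3f] V\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
plot.waveform <- function(x, ...) {
  t <- (seq_along(x$samples) - 1) / x$fs
  graphics::plot(t, x$samples, type = "l", xlab = "time (s)",
                 ylab = "voltage (V)", ...)
  invisible(x)
}

#' Simulate the standard cyclic-compression bench test
#'
#' Periodic biphasic pulses at the punch frequency with peak amplitude
#' \code{sensitivity * peak_force * attenuation(freq)}; the voltage returns to
#' zero during unloading.
#'
#' @param calib a \code{\link{generator_calibration}}.
#' @param freq punch frequency (Hz); must not exceed \code{fs / 2}.
#' @param peak_force peak compression force (N), default 11.5.
#' @param n_cycles number of cycles, >= 1, default 5.
#' @param fs sampling rate (Hz), default 1000.
#' @param noise add calibration noise sources, default TRUE.
#' @param seed RNG seed for the noise realization.
#' @return a \code{\link{waveform}}.
#' @examples
#' w <- simulate_standard_test(generator_calibration(), 2, 11.5, noise = FALSE)
#' max(w$samples)  # 5.76 V
#' @export
simulate_standard_test <- function(calib, freq, peak_force = 11.5, n_cycles = 5,
                                   fs = 1000, noise = TRUE, seed = NULL) {
  stopifnot(inherits(calib, "generator_calibration"), n_cycles >= 1)
  if (peak_force < 0) stop("peak force must be non-negative")
  if (freq > fs / 2) stop("punch frequency exceeds the Nyquist limit fs/2")
  period <- 1 / freq
  n <- round(n_cycles * period * fs)
  t <- (seq_len(n) - 1) / fs
  amp <- calib$sensitivity * peak_force * attenuation(calib, freq)
  x <- numeric(n)
  for (c0 in (seq_len(n_cycles) - 1) * period)
    x <- x + .pulse(t - c0, calib$duty * period, amp)
  if (noise) x <- x + .with_seed(seed, .noise_trace(calib, n, fs))
  waveform(x, fs)
}

#' Simulate a labelled knee-flexion session
#'
#' One flexion pulse per scheduled event. Pulse amplitude scales with the
#' condition force (foot weight + external load) through the generator
#' sensitivity; the knee angle modulates pulse duration and the weight of a
#' second-harmonic component so that angle is recoverable from the spectrum.
#' Rest intervals are baseline plus noise. The schedule is returned unchanged.
#'
#' @param subject a \code{\link{subject_params}}.
#' @param schedule an \code{\link{event_schedule}}.
#' @param calib a \code{\link{generator_calibration}}.
#' @param fs sampling rate (Hz), default 1000.
#' @param duration total duration (s); default covers the last event.
#' @param noise add noise, default TRUE.
#' @param jitter uniform onset jitter half-width (s), default 0 (events fire
#'   exactly on schedule; the returned labels are unaffected either way).
#' @param seed RNG seed.
#' @return list with elements \code{waveform} and \code{schedule}.
#' @export
simulate_session <- function(subject, schedule, calib = generator_calibration(),
                             fs = 1000, duration = NULL, noise = TRUE,
                             jitter = 0, seed = NULL) {
  stopifnot(inherits(subject, "subject_params"),
            inherits(schedule, "event_schedule"))
  widths <- .angle_width(schedule$angle)
  if (nrow(schedule) > 1 &&
      any(schedule$onset[-1] < (schedule$onset + widths)[-nrow(schedule)]))
    stop("overlapping events: pulses exceed inter-event spacing")
  if (is.null(duration))
    duration <- if (nrow(schedule)) max(schedule$onset + widths) else 0
  if (nrow(schedule) && max(schedule$onset + widths) > duration + 1e-9)
    stop("schedule does not fit the requested duration")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  .with_seed(seed, {
    x <- numeric(n)
    for (i in seq_len(nrow(schedule))) {
      on <- schedule$onset[i]
      if (jitter > 0) on <- max(0, on + stats::runif(1, -jitter, jitter))
      force_i <- subject$foot_weight + schedule$load[i]
      amp <- calib$sensitivity * force_i * attenuation(calib, 1 / widths[i])
      x <- x + .flexion_pulse(t - on, schedule$angle[i], amp)
    }
    if (noise && n > 0) x <- x + .noise_trace(calib, n, fs)
    list(waveform = waveform(x, fs), schedule = schedule)
  })
}

#' Build a labelled segment dataset
#'
#' Generates fixed-length (3 s at 1000 Hz by default) labelled segments: one
#' flexion event per segment for every motion condition, optionally plus
#' rest-state (zero torque) segments of pure baseline noise.
#'
#' @param conditions condition grid from \code{\link{motion_conditions}}.
#' @param n_per_condition segments per condition, default 100.
#' @param include_rest add rest segments, default TRUE.
#' @param rest_n number of rest segments, default \code{n_per_condition}
#'   (a 1:9 rest ratio for the default 9-condition grid).
#' @param subject a \code{\link{subject_params}}.
#' @param calib a \code{\link{generator_calibration}}.
#' @param segment_length samples per segment, default 3000.
#' @param fs sampling rate (Hz), default 1000.
#' @param noise add noise, default TRUE.
#' @param jitter uniform event-onset jitter half-width within the segment (s),
#'   default 0.1.
#' @param seed RNG seed.
#' @return object of class \code{torque_dataset}: \code{segments} (matrix,
#'   one row per segment) and \code{labels} (segment_id, load, angle,
#'   torque, class; class is the 0-based torque rank, rest = lowest).
#' @export
build_dataset <- function(conditions, n_per_condition = 100,
                          include_rest = TRUE, rest_n = n_per_condition,
                          subject = subject_params(),
                          calib = generator_calibration(),
                          segment_length = 3000, fs = 1000, noise = TRUE,
                          jitter = 0.1, seed = NULL) {
  stopifnot(n_per_condition >= 1, segment_length >= 1)
  if (anyDuplicated(signif(conditions$torque, 12)))
    stop("duplicate torque labels across conditions: class map ill-defined")
  lab <- conditions[rep(seq_len(nrow(conditions)), each = n_per_condition), ]
  if (include_rest && rest_n > 0) {
    rest <- data.frame(load = NA_real_, angle = NA_real_, torque = 0,
                       class = NA_integer_)
    if (any(abs(conditions$torque) < 1e-12))
      stop("rest segments requested but a zero-torque condition already exists")
    lab <- rbind(lab[, c("load", "angle", "torque", "class")],
                 rest[rep(1, rest_n), ])
  } else {
    lab <- lab[, c("load", "angle", "torque", "class")]
  }
  lab$class <- rank(lab$torque, ties.method = "min")
  lab$class <- as.integer(factor(lab$class)) - 1L
  lab <- data.frame(segment_id = seq_len(nrow(lab)), lab, row.names = NULL)

  t <- (seq_len(segment_length) - 1) / fs
  base_on <- 0.5
  .with_seed(seed, {
    segs <- matrix(0, nrow(lab), segment_length)
    for (i in seq_len(nrow(lab))) {
      if (!is.na(lab$load[i])) {
        on <- base_on + if (jitter > 0) stats::runif(1, -jitter, jitter) else 0
        amp <- calib$sensitivity * (subject$foot_weight + lab$load[i]) *
          attenuation(calib, 1 / .angle_width(lab$angle[i]))
        segs[i, ] <- .flexion_pulse(t - on, lab$angle[i], amp)
      }
      if (noise) segs[i, ] <- segs[i, ] + .noise_trace(calib, segment_length, fs)
    }
    structure(list(segments = segs, labels = lab, fs = fs,
                   conditions = conditions, subject = subject, calib = calib),
              class = "torque_dataset")
  })
}

#' @export
print.torque_dataset <- function(x, ...) {
  cat(sprintf("Labelled segment dataset: %d segments x %d samples at %g Hz, %d classes\n",
              nrow(x$segments), ncol(x$segments), x$fs,
              length(unique(x$labels$class))))
  invisible(x)
}
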