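# ---- Preprocessing: segmentation, artefact suppression, STFT features ----

.as_samples <- function(x) if (inherits(x, "waveform")) x$samples else as.numeric(x)

#' Cut event-aligned fixed-length segments from a trace
#'
#' One segment of \code{length} samples per scheduled event, starting at the
#' event onset. Events whose window would run past the end of the trace are
#' dropped with a warning.
#'
#' @param wave a \code{\link{waveform}}.
#' @param schedule an \code{\link{event_schedule}}.
#' @param length segment length in samples, default 3000 (3 s at 1000 Hz).
#' @return list: \code{segments} (matrix, one row per kept event) and
#'   \code{schedule} (the kept schedule rows).
#' @export
segment_events <- function(wave, schedule, length = 3000) {
  stopifnot(inherits(wave, "waveform"), length >= 1)
  n <- base::length(wave$samples)
  start <- round(schedule$onset * wave$fs) + 1L
  keep <- start + length - 1L <= n
  if (any(!keep))
    warning(sum(!keep), " event(s) too close to the end of the trace; dropped")
  segs <- matrix(0, sum(keep), length)
  for (i in seq_along(which(keep)))
    segs[i, ] <- wave$samples[start[which(keep)[i]] + 0:(length - 1L)]
  list(segments = segs, schedule = schedule[keep, , drop = FALSE])
}

#' Short-time Fourier transform magnitude spectrogram
#'
#' Hann-windowed STFT with the stated analysis configuration (256-sample
#' window, 50\% overlap by default); frames are taken without zero padding,
#' so a 3000-sample segment yields 22 frames of 129 frequency bins.
#'
#' @param x a \code{\link{waveform}} or numeric vector.
#' @param fs sampling rate (Hz); taken from the waveform when available.
#' @param window window length in samples, default 256.
#' @param overlap overlap fraction in [0, 1), default 0.5.
#' @return object of class \code{tfmap}: \code{magnitude} (bins x frames),
#'   \code{freq} (Hz), \code{time} (s, frame centres), window and overlap.
#' @export
stft_spectrogram <- function(x, fs = if (inherits(x, "waveform")) x$fs else 1000,
                             window = 256, overlap = 0.5) {
  s <- .as_samples(x)
  stopifnot(window >= 2, overlap >= 0, overlap < 1)
  if (length(s) < window)
    stop("segment shorter than the analysis window (", length(s), " < ", window, ")")
  hop <- round(window * (1 - overlap))
  nframe <- floor((length(s) - window) / hop) + 1L
  win <- 0.5 * (1 - cos(2 * pi * seq_len(window) / window))  # periodic Hann
  starts <- (seq_len(nframe) - 1L) * hop
  frames <- vapply(starts, function(k) s[k + seq_len(window)] * win,
                   numeric(window))
  spec <- stats::mvfft(frames)[seq_len(floor(window / 2) + 1), , drop = FALSE]
  structure(list(magnitude = abs(spec),
                 freq = (seq_len(floor(window / 2) + 1) - 1) * fs / window,
                 time = (starts + window / 2) / fs,
                 window = window, overlap = overlap),
            class = "tfmap")
}

#' @export
print.tfmap <- function(x, ...) {
  cat(sprintf("STFT magnitude map: %d bins x %d frames (window %d, overlap %g%%)\n",
              nrow(x$magnitude), ncol(x$magnitude), x$window, 100 * x$overlap))
  invisible(x)
}

#' Suppress low-frequency physiological artefacts
#'
#' Zero-phase Butterworth high-pass (applied forwards and backwards) removing
#' DC, respiratory (~0.3 Hz) and cardiac (~1-2 Hz) drift below the cutoff
#' while leaving the motion band essentially untouched.
#'
#' @param x a \code{\link{waveform}} or numeric vector.
#' @param fs sampling rate (Hz); taken from the waveform when available.
#' @param cutoff high-pass cutoff (Hz), default 1.5; must be below fs/2.
#' @param order Butterworth order (per pass), default 4.
#' @return filtered signal, same type as the input.
#' @export
suppress_artefacts <- function(x, fs = if (inherits(x, "waveform")) x$fs else 1000,
                               cutoff = 1.5, order = 4) {
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency fs/2")
  s <- .as_samples(x)
  filt <- signal::butter(order, cutoff / (fs / 2), type = "high")
  out <- signal::filtfilt(filt, s)
  if (inherits(x, "waveform")) waveform(out, fs) else out
}

#' Mean-spectrum feature vector
#'
#' Per-bin time average of the STFT magnitude: the frame-mean of each
#' frequency component, yielding one feature per bin.
#'
#' @param tfmap a \code{\link{stft_spectrogram}} result.
#' @return numeric feature vector (length = number of bins) with the bin
#'   frequencies attached as attribute \code{freq}.
#' @export
mean_spectrum_features <- function(tfmap) {
  stopifnot(inherits(tfmap, "tfmap"))
  if (ncol(tfmap$magnitude) < 1 || nrow(tfmap$magnitude) < 1)
    stop("empty time-frequency map")
  structure(rowMeans(tfmap$magnitude), freq = tfmap$freq)
}

# Shared single-segment pipeline: high-pass, STFT, per-bin mean, DC bin zeroed
# (the physiological band lies inside the DC bin at fs/window resolution).
.featurize_segment <- function(s, fs, window, overlap, cutoff) {
  s <- suppress_artefacts(s, fs = fs, cutoff = cutoff)
  v <- mean_spectrum_features(stft_spectrogram(s, fs = fs, window = window,
                                               overlap = overlap))
  v[1] <- 0
  v
}

#' Feature matrix for a labelled session
#'
#' Composition of \code{\link{segment_events}},
#' \code{\link{suppress_artefacts}}, \code{\link{stft_spectrogram}} and
#' \code{\link{mean_spectrum_features}}; row order matches the (kept)
#' schedule order.
#'
#' @param wave a \code{\link{waveform}}.
#' @param schedule an \code{\link{event_schedule}}.
#' @param segment_length samples per segment, default 3000.
#' @param window,overlap STFT configuration, default 256 / 0.5.
#' @param cutoff artefact high-pass cutoff (Hz), default 1.5.
#' @return list: \code{features} (events x bins matrix) and \code{schedule}.
#' @export
featurize <- function(wave, schedule, segment_length = 3000, window = 256,
                      overlap = 0.5, cutoff = 1.5) {
  seg <- segment_events(wave, schedule, segment_length)
  feats <- t(apply(seg$segments, 1, .featurize_segment, fs = wave$fs,
                   window = window, overlap = overlap, cutoff = cutoff))
  if (nrow(seg$segments) == 0) feats <- matrix(0, 0, floor(window / 2) + 1)
  list(features = feats, schedule = seg$schedule)
}

#' Feature matrix for a segment dataset
#'
#' @param dataset a \code{\link{build_dataset}} result.
#' @param window,overlap,cutoff as in \code{\link{featurize}}.
#' @return list: \code{features} (segments x bins) and \code{labels}.
#' @export
featurize_dataset <- function(dataset, window = 256, overlap = 0.5, cutoff = 1.5) {
  stopifnot(inherits(dataset, "torque_dataset"))
  feats <- t(apply(dataset$segments, 1, .featurize_segment, fs = dataset$fs,
                   window = window, overlap = overlap, cutoff = cutoff))
  list(features = feats, labels = dataset$labels)
}
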