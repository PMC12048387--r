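# ---- Streaming inference: circular buffer, cadence steps, threshold alerts ----

#' Create a real-time monitoring state
#'
#' Holds the circular sample buffer (capacity 3000 samples ~ 3 s at 1000 Hz),
#' the inference cadence, the torque warning threshold, and the trained
#' classifier used for decoding. The state is a plain value: the push and
#' step functions return updated copies, keeping tests reproducible.
#'
#' @param model a fitted classification \code{\link{torque_net}} whose
#'   class-value map is in Nm (a rest/zero-torque class should be present
#'   for realistic streams).
#' @param capacity buffer capacity in samples, default 3000.
#' @param cadence inference cadence (s), default 3.
#' @param threshold torque warning threshold (Nm), default 30; must be > 0.
#' @param fs sampling rate (Hz), default 1000.
#' @param window,overlap,cutoff feature configuration, as in
#'   \code{\link{featurize}}.
#' @return object of class \code{stream_state}.
#' @export
stream_state <- function(model, capacity = 3000, cadence = 3, threshold = 30,
                         fs = 1000, window = 256, overlap = 0.5, cutoff = 1.5) {
  stopifnot(inherits(model, "torque_net"), capacity >= window,
            cadence > 0, threshold > 0, fs > 0)
  if (model$task != "classification")
    stop("streaming inference uses the classification model")
  structure(list(model = model, buffer = numeric(0), capacity = as.integer(capacity),
                 cadence = cadence, threshold = threshold, fs = fs,
                 window = window, overlap = overlap, cutoff = cutoff,
                 ingested = 0), class = "stream_state")
}

#' @export
print.stream_state <- function(x, ...) {
  cat(sprintf(paste0("Stream state: %d/%d samples buffered, cadence %g s, ",
                     "threshold %g Nm, %.1f s ingested\n"),
              length(x$buffer), x$capacity, x$cadence, x$threshold,
              x$ingested / x$fs))
  invisible(x)
}

#' Push samples into the circular buffer
#'
#' The buffer retains only the most recent \code{capacity} samples in arrival
#' order; older samples are evicted first.
#'
#' @param state a \code{\link{stream_state}}.
#' @param chunk numeric samples (finite).
#' @return the updated state.
#' @export
buffer_push <- function(state, chunk) {
  stopifnot(inherits(state, "stream_state"))
  chunk <- .as_samples(chunk)
  if (!all(is.finite(chunk))) stop("chunk contains non-finite samples")
  buf <- c(state$buffer, chunk)
  n <- length(buf)
  if (n > state$capacity) buf <- buf[(n - state$capacity + 1):n]
  state$buffer <- buf
  state$ingested <- state$ingested + length(chunk)
  state
}

#' One inference step on the current buffer
#'
#' Extracts mean-spectrum features from the buffered window, classifies them,
#' decodes the probability-weighted torque, and raises an alert if and only
#' if the decoded torque exceeds the threshold. With a buffer that is not yet
#' full this is a no-op (a notice is logged via \code{message}).
#'
#' @param state a \code{\link{stream_state}}.
#' @return list: \code{ready} flag; when ready, \code{class} (hard class
#'   value, Nm), \code{torque} (decoded, Nm), and \code{alert} (NULL or a
#'   list with \code{t}, \code{torque}, \code{message}).
#' @export
step_inference <- function(state) {
  stopifnot(inherits(state, "stream_state"))
  if (length(state$buffer) < state$capacity) {
    message("buffer not full (", length(state$buffer), "/", state$capacity,
            " samples); skipping inference")
    return(list(ready = FALSE, class = NA_real_, torque = NA_real_, alert = NULL))
  }
  v <- .featurize_segment(state$buffer, fs = state$fs, window = state$window,
                          overlap = state$overlap, cutoff = state$cutoff)
  pr <- predict(state$model, matrix(v, nrow = 1), type = "prob")
  torque <- decode_weighted(pr, state$model$class_values)
  cls <- state$model$class_values[max.col(pr)]
  alert <- NULL
  if (torque > state$threshold) {
    t_s <- state$ingested / state$fs
    alert <- list(t = t_s, torque = torque,
                  message = sprintf("t=%.1f s: decoded torque %.2f Nm exceeds %g Nm",
                                    t_s, torque, state$threshold))
  }
  list(ready = TRUE, class = cls, torque = torque, alert = alert)
}

#' Run streaming inference over a recorded trace
#'
#' Feeds the trace to the buffer in cadence-sized chunks and performs one
#' inference per cadence step (steps fire on whole multiples of the cadence
#' in ingested samples, not wall-clock time). Each step appends one row to
#' the monitoring log; the log is optionally written as CSV.
#'
#' @param source a \code{\link{waveform}} (sampled at the state's rate) or
#'   numeric vector.
#' @param state a \code{\link{stream_state}}.
#' @param log_path optional CSV output path.
#' @return data.frame log: \code{t_s}, \code{class}, \code{torque_Nm},
#'   \code{alert} (logical); invisibly also the final state as attribute
#'   \code{state}.
#' @export
run_stream <- function(source, state, log_path = NULL) {
  stopifnot(inherits(state, "stream_state"))
  if (inherits(source, "waveform") && source$fs != state$fs)
    stop("source sampling rate does not match the stream state")
  s <- .as_samples(source)
  chunk_n <- round(state$cadence * state$fs)
  n_steps <- floor(length(s) / chunk_n)
  if (length(s) < state$capacity)
    warning("source shorter than one buffer; empty monitoring log")
  rows <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    state <- buffer_push(state, s[(k - 1) * chunk_n + seq_len(chunk_n)])
    res <- suppressMessages(step_inference(state))
    rows[[k]] <- data.frame(t_s = state$ingested / state$fs,
                            class = res$class, torque_Nm = res$torque,
                            alert = !is.null(res$alert))
  }
  log <- if (n_steps) do.call(rbind, rows) else
    data.frame(t_s = numeric(0), class = numeric(0), torque_Nm = numeric(0),
               alert = logical(0))
  log <- log[!is.na(log$torque_Nm), , drop = FALSE]
  rownames(log) <- NULL
  if (!is.null(log_path)) utils::write.csv(log, log_path, row.names = FALSE)
  attr(log, "state") <- state
  log
}
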