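# ---- File interfaces: waveform/feature CSV and YAML configuration ----

#' Write a waveform as CSV
#'
#' Columns \code{time_s, voltage_V}.
#'
#' @param wave a \code{\link{waveform}}.
#' @param path output path.
#' @export
write_waveform_csv <- function(wave, path) {
  stopifnot(inherits(wave, "waveform"))
  utils::write.csv(data.frame(time_s = (seq_along(wave$samples) - 1) / wave$fs,
                              voltage_V = wave$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a waveform CSV
#'
#' Expects columns \code{time_s, voltage_V} with uniform sampling.
#'
#' @param path input path.
#' @return a \code{\link{waveform}}.
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "voltage_V") %in% names(df)))
    stop("expected columns time_s, voltage_V")
  dt <- diff(df$time_s)
  if (length(dt) && (max(dt) - min(dt)) > 1e-9 * max(dt, 1))
    stop("time stamps are not uniformly sampled")
  fs <- if (length(dt)) 1 / stats::median(dt) else 1000
  waveform(df$voltage_V, fs = fs)
}

#' Write a labelled feature matrix as CSV
#'
#' Columns \code{segment_id, f_0 ... f_<k-1>, torque_Nm, class}.
#'
#' @param features feature matrix (segments x bins).
#' @param labels label data.frame with \code{segment_id}, \code{torque},
#'   \code{class}.
#' @param path output path.
#' @export
write_features_csv <- function(features, labels, path) {
  stopifnot(nrow(features) == nrow(labels))
  df <- as.data.frame(features)
  names(df) <- paste0("f_", seq_len(ncol(features)) - 1)
  df <- cbind(segment_id = labels$segment_id, df,
              torque_Nm = labels$torque, class = labels$class)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML file with optional blocks \code{generator} (calibration fields),
#' \code{features} (window, overlap, cutoff), \code{realtime} (capacity,
#' cadence, threshold), and \code{design} (bounds, grid, stretch); entries
#' override the package defaults.
#'
#' @param path YAML path.
#' @return nested list of configuration values with defaults filled in.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    features = list(window = 256, overlap = 0.5, cutoff = 1.5),
    realtime = list(capacity = 3000, cadence = 3, threshold = 30),
    design = list(lower = c(a = 5, b = 1, theta = 150),
                  upper = c(a = 15, b = 5, theta = 179),
                  grid = c(5, 5), stretch = 10, delta = 0.01, max_iter = 40)
  )
  out <- utils::modifyList(defaults, cfg[setdiff(names(cfg), "generator")])
  out$generator <- if (is.null(cfg$generator)) generator_calibration() else
    do.call(generator_calibration, cfg$generator)
  out
}
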