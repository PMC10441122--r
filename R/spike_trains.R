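#' Per-electrode spike-time container
#'
#' The central exchange object of the pipeline: a named list of sorted spike
#' times (seconds from recording start), one entry per electrode, together
#' with the protocol they were recorded under and, when spikes were detected
#' from waveforms, the per-channel noise SD used by the detector.
#'
#' @param trains Named list of numeric vectors; each vector holds one
#'   electrode's spike times in seconds, strictly increasing.
#' @param protocol A [phase_protocol()] covering the recording span.
#' @param noise_sd Optional named numeric vector of per-channel noise SD (uV).
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(trains, protocol, noise_sd = NULL) {
  stopifnot(inherits(protocol, "phase_protocol"))
  if (is.null(names(trains)) || anyDuplicated(names(trains)))
    stop("`trains` must be a named list with unique electrode ids")
  trains <- lapply(trains, function(x) {
    x <- as.numeric(x)
    if (is.unsorted(x, strictly = TRUE)) x <- sort(unique(x))
    x
  })
  bad <- vapply(trains, function(x)
    length(x) > 0 && (x[1] < 0 || x[length(x)] >= protocol$total_duration),
    logical(1))
  if (any(bad))
    stop("spike times outside [0, total_duration) on electrode(s): ",
         paste(names(trains)[bad], collapse = ", "))
  structure(list(trains = trains, protocol = protocol, noise_sd = noise_sd),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  n <- vapply(x$trains, length, integer(1))
  cat("<spike_train_set> ", length(n), " electrodes, ",
      sum(n), " spikes over ", x$protocol$total_duration, " s\n", sep = "")
  invisible(x)
}

#' Number of spikes per electrode
#' @param spikes A [spike_train_set()].
#' @return Named integer vector.
#' @export
spike_counts <- function(spikes) {
  stopifnot(inherits(spikes, "spike_train_set"))
  vapply(spikes$trains, length, integer(1))
}

#' Write spike trains to CSV
#'
#' Long format with columns `electrode_id, spike_time_s`, one row per spike.
#'
#' @param spikes A [spike_train_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_train_set"))
  n <- vapply(spikes$trains, length, integer(1))
  df <- data.frame(
    electrode_id = rep(names(spikes$trains), n),
    spike_time_s = unlist(spikes$trains, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spike trains from CSV
#'
#' Expects the format written by [write_spike_trains()].
#'
#' @param path CSV file with columns `electrode_id, spike_time_s`.
#' @param protocol A [phase_protocol()] for the recording.
#' @return A [spike_train_set()].
#' @export
read_spike_trains <- function(path, protocol) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("electrode_id", "spike_time_s") %in% names(df)))
    stop("expected columns electrode_id, spike_time_s")
  trains <- split(df$spike_time_s, df$electrode_id)
  spike_train_set(lapply(trains, sort), protocol)
}
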