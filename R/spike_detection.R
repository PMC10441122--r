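#' Raw multichannel MEA recording
#'
#' @param samples Numeric matrix, channels x samples, in uV.
#' @param fs Sampling rate, Hz (default 10000).
#' @param t0 Recording start time, s (default 0).
#' @param channel_ids Channel identifiers; default `el01`, `el02`, ...
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(samples, fs = 10000, t0 = 0, channel_ids = NULL) {
  samples <- as.matrix(samples)
  if (fs <= 0) stop("fs must be positive")
  if (is.null(channel_ids))
    channel_ids <- sprintf("el%02d", seq_len(nrow(samples)))
  if (length(channel_ids) != nrow(samples))
    stop("channel_ids length must match number of rows")
  structure(list(samples = samples, fs = fs, t0 = t0,
                 channel_ids = as.character(channel_ids)),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat("<raw_recording> ", nrow(x$samples), " channels x ",
      ncol(x$samples), " samples @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Robust per-channel noise SD
#'
#' Estimates the SD of the biological noise on each channel over a reference
#' window, by default the first pre-exposure phase. The estimator is the
#' median absolute deviation scaled to the Gaussian SD (MAD x 1.4826), which
#' is insensitive to the sparse large-amplitude spikes embedded in the
#' signal.
#'
#' @param recording A [raw_recording()].
#' @param window Numeric length-2 vector `c(start, end)` in seconds relative
#'   to recording start; must span at least 1 s.
#' @return Named numeric vector of per-channel noise SD in uV. Channels with
#'   zero estimated SD (constant signal) are returned as 0 with a warning.
#' @export
estimate_noise_sd <- function(recording,
                              window = c(0, ncol(recording$samples) /
                                           recording$fs)) {
  stopifnot(inherits(recording, "raw_recording"))
  n <- ncol(recording$samples)
  i0 <- max(floor(window[1] * recording$fs) + 1L, 1L)
  i1 <- min(ceiling(window[2] * recording$fs), n)
  if (i1 - i0 + 1L < recording$fs)
    stop("noise window must span at least 1 s within the recording")
  sds <- apply(recording$samples[, i0:i1, drop = FALSE], 1,
               stats::mad, constant = 1.4826)
  names(sds) <- recording$channel_ids
  if (any(sds == 0))
    warning("zero-variance channel(s): ",
            paste(recording$channel_ids[sds == 0], collapse = ", "),
            " (flagged; spike detection will skip them)")
  sds
}

# Rolling max/min over a w-sample window via iterated pmax/pmin; returns
# vectors of length n - w + 1 (window starting at each sample).
roll_extrema <- function(x, w) {
  n <- length(x)
  m <- n - w + 1L
  mx <- x[seq_len(m)]
  mn <- mx
  if (w > 1L) for (k in seq_len(w - 1L)) {
    sh <- x[(1L + k):(m + k)]
    mx <- pmax(mx, sh)
    mn <- pmin(mn, sh)
  }
  list(max = mx, min = mn)
}

#' Peak-to-peak threshold spike detection
#'
#' Declares one spike wherever the peak-to-peak signal amplitude within a
#' sliding window (default 2 ms) exceeds `threshold_factor` (default 8)
#' times the channel's noise SD. The spike is timestamped at the negative
#' peak of the qualifying excursion; detections closer than the refractory
#' period are merged into one (the deeper trough is kept).
#'
#' @param recording A [raw_recording()].
#' @param noise_sd Per-channel noise SD in uV; by default estimated with
#'   [estimate_noise_sd()] over `noise_window`.
#' @param threshold_factor Multiplier on the noise SD (default 8).
#' @param window_s Sliding-window length, s (default 0.002).
#' @param refractory_s Merge window for nearby detections, s (default 0.001).
#' @param protocol A [phase_protocol()] attached to the result; by default a
#'   single phase spanning the recording. For protocol recordings, pass the
#'   protocol and set `noise_window` to its first baseline phase.
#' @param noise_window Window passed to [estimate_noise_sd()] when
#'   `noise_sd` is missing; default the span of the first protocol phase.
#' @return A [spike_train_set()] with the per-channel noise SD attached.
#'   Channels whose noise SD is 0 are skipped with a warning.
#' @export
detect_spikes <- function(recording, noise_sd = NULL, threshold_factor = 8,
                          window_s = 0.002, refractory_s = 0.001,
                          protocol = NULL, noise_window = NULL) {
  stopifnot(inherits(recording, "raw_recording"))
  fs <- recording$fs
  nsamp <- ncol(recording$samples)
  if (is.null(protocol))
    protocol <- phase_protocol("all", nsamp / fs)
  if (is.null(noise_window))
    noise_window <- c(protocol$start[1], protocol$end[1])
  if (is.null(noise_sd))
    noise_sd <- suppressWarnings(estimate_noise_sd(recording, noise_window))
  noise_sd <- rep_len(noise_sd, nrow(recording$samples))
  w <- round(window_s * fs)
  if (w < 2L) stop("window too short for the sampling rate")
  refr <- refractory_s
  trains <- stats::setNames(vector("list", nrow(recording$samples)),
                            recording$channel_ids)
  skipped <- character(0)
  for (ci in seq_len(nrow(recording$samples))) {
    id <- recording$channel_ids[ci]
    if (noise_sd[ci] <= 0) {
      skipped <- c(skipped, id)
      trains[[id]] <- numeric(0)
      next
    }
    x <- recording$samples[ci, ]
    thr <- threshold_factor * noise_sd[ci]
    re <- roll_extrema(x, w)
    q <- which(re$max - re$min > thr)   # qualifying window start samples
    if (length(q) == 0L) {
      trains[[id]] <- numeric(0)
      next
    }
    ## merge overlapping qualifying windows into excursions
    grp <- cumsum(c(1L, diff(q) > w))
    times <- troughs <- numeric(max(grp))
    for (g in seq_len(max(grp))) {
      qs <- q[grp == g]
      lo <- qs[1]
      hi <- min(qs[length(qs)] + w - 1L, nsamp)
      seg <- x[lo:hi]
      k <- which.min(seg)
      times[g] <- (lo + k - 2L) / fs
      troughs[g] <- seg[k]
    }
    ## refractory merge: keep the deeper trough among detections closer
    ## than the refractory period
    if (length(times) > 1L && refr > 0) {
      keep <- rep(TRUE, length(times))
      i <- 1L
      for (j in 2L:length(times)) {
        if (times[j] - times[i] < refr) {
          if (troughs[j] < troughs[i]) { keep[i] <- FALSE; i <- j }
          else keep[j] <- FALSE
        } else i <- j
      }
      times <- times[keep]
    }
    trains[[id]] <- times[times < protocol$total_duration]
  }
  if (length(skipped))
    warning("skipped zero-noise channel(s): ", paste(skipped, collapse = ", "))
  spike_train_set(trains, protocol,
                  noise_sd = stats::setNames(noise_sd, recording$channel_ids))
}
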