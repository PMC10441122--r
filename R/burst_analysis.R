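# Moving average with partial windows at the edges (window must be odd).
moving_average <- function(x, w = 3L) {
  if (w <= 1L) return(x)
  h <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Local maxima of a vector; edge bins count as peaks when they exceed their
# single inner neighbour. Plateaus resolve to the leftmost bin of the run.
local_peaks <- function(y) {
  padded <- c(-Inf, y, -Inf)
  r <- rle(padded)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  is_peak <- logical(k)
  if (k >= 3L)
    for (i in 2L:(k - 1L))
      is_peak[i] <- r$values[i] > r$values[i - 1L] &&
        r$values[i] > r$values[i + 1L]
  sort(starts[is_peak] - 1L)  # un-pad
}

#' Adaptive ISI threshold from the logarithmic ISI histogram
#'
#' Builds the histogram of log10(ISI) (ISIs in ms) at a fixed bin width,
#' smooths it with a short moving average, and locates its peaks. Bursty
#' trains show a bimodal histogram: an intra-burst peak at short ISIs and a
#' second peak at the inter-burst timescale. When at least two peaks are
#' found and the first lies below `max_threshold_ms`, the threshold is the
#' ISI at the (leftmost) minimum between the first and second peaks;
#' otherwise the fixed fallback `max_threshold_ms` is used.
#'
#' @param times Sorted spike times, s (a single electrode's train).
#' @param bin_width Histogram bin width in log10(ms) units (default 0.1).
#' @param max_threshold_ms Upper bound for the intra-burst peak position and
#'   fallback threshold, ms (default 100).
#' @param smooth_bins Moving-average smoothing span in bins (default 3).
#' @param min_isis Minimum number of ISIs required (default 10).
#' @param min_peak_frac Minimum height of a candidate peak as a fraction of
#'   the histogram maximum (default 0.1); discards spurious micro-peaks
#'   produced by isolated short ISIs.
#' @return List with `threshold` (s; `NA` when fewer than `min_isis` ISIs —
#'   the electrode then has no bursts), `fallback` (logical), and the
#'   histogram pieces `mids` (log10 ms), `counts`, `smoothed`, `peaks`
#'   (bin indices).
#' @export
logisi_threshold <- function(times, bin_width = 0.1, max_threshold_ms = 100,
                             smooth_bins = 3L, min_isis = 10L,
                             min_peak_frac = 0.1) {
  if (bin_width <= 0) stop("bin_width must be positive")
  isi_ms <- diff(times) * 1000
  isi_ms <- isi_ms[isi_ms > 0]
  if (length(isi_ms) < min_isis)
    return(list(threshold = NA_real_, fallback = TRUE,
                mids = numeric(0), counts = numeric(0),
                smoothed = numeric(0), peaks = integer(0)))
  lg <- log10(isi_ms)
  breaks <- seq(floor(min(lg) / bin_width) * bin_width,
                ceiling(max(lg) / bin_width) * bin_width + bin_width,
                by = bin_width)
  counts <- as.numeric(table(cut(lg, breaks, right = FALSE)))
  mids <- breaks[-length(breaks)] + bin_width / 2
  sm <- moving_average(counts, smooth_bins)
  peaks <- local_peaks(sm)
  peaks <- peaks[sm[peaks] >= min_peak_frac * max(sm)]
  fallback <- TRUE
  threshold_ms <- max_threshold_ms
  if (length(peaks) >= 2L && 10^mids[peaks[1]] < max_threshold_ms &&
      peaks[2] - peaks[1] >= 2L) {
    between <- sm[(peaks[1] + 1L):(peaks[2] - 1L)]
    {
      valley <- peaks[1] + which.min(between)  # leftmost minimum
      threshold_ms <- 10^mids[valley]
      fallback <- FALSE
    }
  }
  list(threshold = threshold_ms / 1000, fallback = fallback,
       mids = mids, counts = counts, smoothed = sm, peaks = peaks)
}

#' Detect bursts on one electrode
#'
#' A burst is a maximal run of consecutive spikes whose inter-spike
#' intervals are all at or below the threshold, containing at least
#' `min_spikes` spikes. Every other spike is an outside-burst spike, so the
#' partition of spikes into in-burst and outside-burst is exhaustive and
#' exclusive.
#'
#' @param times Sorted spike times, s.
#' @param threshold ISI threshold, s (e.g. from [logisi_threshold()]).
#' @param min_spikes Minimum spikes per burst (default 3).
#' @return Data frame with one row per burst: `start`, `end` (s),
#'   `n_spikes`, `duration` (s).
#' @export
detect_bursts <- function(times, threshold, min_spikes = 3L) {
  if (min_spikes < 2L) stop("min_spikes must be >= 2")
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0), duration = numeric(0))
  if (is.na(threshold)) return(empty)
  if (threshold <= 0) stop("threshold must be positive")
  if (length(times) < min_spikes) return(empty)
  r <- rle(diff(times) <= threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= (min_spikes - 1L)
  if (!any(ok)) return(empty)
  i0 <- starts[ok]             # index of first spike of each burst
  i1 <- ends[ok] + 1L          # index of last spike
  data.frame(start = times[i0], end = times[i1],
             n_spikes = i1 - i0 + 1L,
             duration = times[i1] - times[i0])
}

#' Detect bursts on every electrode of a spike-train set
#'
#' Runs [logisi_threshold()] and [detect_bursts()] per electrode and
#' collects the results.
#'
#' @param spikes A [spike_train_set()].
#' @param bin_width,max_threshold_ms,smooth_bins,min_isis Passed to
#'   [logisi_threshold()].
#' @param min_spikes Passed to [detect_bursts()] (default 3).
#' @return An object of class `burst_train`: list with `bursts` (data frame
#'   `electrode, start, end, n_spikes, duration`), `thresholds` (named, s;
#'   `NA` where too few ISIs), `min_spikes`, `protocol`.
#' @export
detect_all_bursts <- function(spikes, bin_width = 0.1,
                              max_threshold_ms = 100, smooth_bins = 3L,
                              min_isis = 10L, min_spikes = 3L) {
  stopifnot(inherits(spikes, "spike_train_set"))
  ids <- names(spikes$trains)
  thresholds <- stats::setNames(rep(NA_real_, length(ids)), ids)
  per <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    tr <- spikes$trains[[ids[i]]]
    th <- logisi_threshold(tr, bin_width, max_threshold_ms, smooth_bins,
                           min_isis)
    thresholds[ids[i]] <- th$threshold
    b <- detect_bursts(tr, th$threshold, min_spikes)
    if (nrow(b) > 0) b <- cbind(electrode = ids[i], b)
    per[[i]] <- b
  }
  per <- per[vapply(per, nrow, integer(1)) > 0]
  bursts <- if (length(per)) do.call(rbind, per) else
    data.frame(electrode = character(0), start = numeric(0),
               end = numeric(0), n_spikes = integer(0),
               duration = numeric(0))
  rownames(bursts) <- NULL
  structure(list(bursts = bursts, thresholds = thresholds,
                 min_spikes = min_spikes, protocol = spikes$protocol),
            class = "burst_train")
}

#' @export
print.burst_train <- function(x, ...) {
  cat("<burst_train> ", nrow(x$bursts), " bursts on ",
      length(unique(x$bursts$electrode)), " of ",
      length(x$thresholds), " electrodes\n", sep = "")
  invisible(x)
}

#' Detect network bursts
#'
#' Pools the per-electrode burst onsets, derives an adaptive grouping
#' threshold from the histogram of log inter-onset intervals (the same
#' valley-finding algorithm as [logisi_threshold()]), groups onsets closer
#' than the threshold into candidate network events, and reports those in
#' which the fraction of distinct participating electrodes (relative to
#' `active_set`) reaches `min_fraction`.
#'
#' @param bursts A `burst_train` from [detect_all_bursts()].
#' @param active_set Electrode ids forming the synchrony denominator
#'   (typically the electrodes bursting-active in the first baseline phase).
#' @param min_fraction Minimum participating fraction (default 0.2).
#' @param max_threshold_ms Fallback/limit for the grouping threshold, ms
#'   (default 100).
#' @return Data frame with one row per network burst: `start`, `end` (s),
#'   `n_electrodes`, `fraction`.
#' @export
detect_network_bursts <- function(bursts, active_set, min_fraction = 0.2,
                                  max_threshold_ms = 100) {
  stopifnot(inherits(bursts, "burst_train"))
  if (length(active_set) == 0) stop("active_set must be non-empty")
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_electrodes = integer(0), fraction = numeric(0))
  b <- bursts$bursts[bursts$bursts$electrode %in% active_set, ]
  if (nrow(b) == 0) return(empty)
  o <- order(b$start)
  onset <- b$start[o]
  th <- logisi_threshold(onset, max_threshold_ms = max_threshold_ms)
  gap_thr <- if (is.na(th$threshold)) max_threshold_ms / 1000 else th$threshold
  grp <- cumsum(c(1L, diff(onset) > gap_thr))
  out <- lapply(split(o, grp), function(ix) {
    members <- b[ix, ]
    data.frame(start = min(members$start), end = max(members$end),
               n_electrodes = length(unique(members$electrode)),
               fraction = length(unique(members$electrode)) /
                 length(active_set))
  })
  out <- do.call(rbind, out)
  out <- out[out$fraction >= min_fraction, , drop = FALSE]
  rownames(out) <- NULL
  out
}
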