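# Shared fixtures: small protocols and scenarios sized for fast tests.

short_protocol <- function(phase_s = 60) {
  phase_protocol(c("S1", "S2", "E", "P1", "P2"), phase_s)
}

# A small but still bursty culture: fewer electrodes, faster events, so a
# 5 x 60 s protocol yields enough bursts per electrode for the logISI
# histogram to be well formed.
small_config <- function(...) {
  scenario_config(n_electrodes = 12, network_burst_rate = 30,
                  participation_prob = 0.7, tonic_rate = 0.5,
                  inactive_fraction = 0, ...)
}

# Independent valley oracle: histogram the log10 ISIs on the same grid with
# hist(), smooth with a 3-tap filter, and brute-force the minimum between
# the two modes (global maxima below / above the mode boundary).
oracle_valley_ms <- function(isi_ms, bin = 0.1, boundary_ms = 100) {
  lg <- log10(isi_ms)
  breaks <- seq(floor(min(lg) / bin) * bin,
                ceiling(max(lg) / bin) * bin + bin, by = bin)
  h <- hist(lg, breaks = breaks, right = FALSE, plot = FALSE)
  sm <- as.numeric(stats::filter(h$counts, rep(1 / 3, 3)))
  sm[is.na(sm)] <- h$counts[is.na(sm)]
  lo <- which(10^h$mids < boundary_ms)
  hi <- which(10^h$mids >= boundary_ms)
  p1 <- lo[which.max(sm[lo])]
  p2 <- hi[which.max(sm[hi])]
  valley <- (p1:p2)[which.min(sm[p1:p2])]
  10^h$mids[valley]
}

# Interval Jaccard overlap.
jaccard <- function(a0, a1, b0, b1) {
  inter <- pmax(0, pmin(a1, b1) - pmax(a0, b0))
  union <- pmax(a1, b1) - pmin(a0, b0)
  ifelse(union > 0, inter / union, 0)
}

# Match detected times against ground truth within a tolerance; returns
# counts of matched truth spikes and unmatched detections.
match_times <- function(detected, truth, tol = 5e-4) {
  matched <- vapply(truth, function(t) any(abs(detected - t) <= tol),
                    logical(1))
  false_pos <- vapply(detected, function(t) !any(abs(truth - t) <= tol),
                      logical(1))
  list(recall = sum(matched), n_truth = length(truth),
       fp = sum(false_pos), n_detected = length(detected))
}
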