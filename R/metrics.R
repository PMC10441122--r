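# Per-spike in-burst membership for one electrode: TRUE when the spike lies
# inside one of the electrode's (disjoint, ordered) burst intervals.
in_burst_flags <- function(times, starts, ends) {
  if (length(times) == 0L || length(starts) == 0L)
    return(rep(FALSE, length(times)))
  idx <- findInterval(times, starts)
  idx > 0L & times <= ends[pmax(idx, 1L)]
}

#' Per-electrode, per-phase activity rates
#'
#' For every electrode and protocol phase: firing rate FR (spikes/s),
#' bursting rate BR (bursts/min; a burst belongs to the phase containing its
#' start time), mean burst duration (s; `NA` when the electrode has no burst
#' in the phase), and outside-burst firing rate OBFR (spikes/s not inside
#' any burst). These are the per-electrode quantities that the network
#' metrics aggregate.
#'
#' @param spikes A [spike_train_set()].
#' @param bursts A `burst_train` from [detect_all_bursts()].
#' @return Data frame: `electrode, phase, fr, br, mean_bd, obfr`.
#' @export
electrode_phase_rates <- function(spikes, bursts) {
  stopifnot(inherits(spikes, "spike_train_set"),
            inherits(bursts, "burst_train"))
  protocol <- spikes$protocol
  durs <- phase_durations(protocol)
  ids <- names(spikes$trains)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    tr <- spikes$trains[[id]]
    bd <- bursts$bursts[bursts$bursts$electrode == id, ]
    inb <- in_burst_flags(tr, bd$start, bd$end)
    sp_phase <- if (length(tr)) phase_of(tr, protocol) else character(0)
    b_phase <- if (nrow(bd)) phase_of(bd$start, protocol) else character(0)
    n_sp <- table(factor(sp_phase, levels = protocol$labels))
    n_out <- table(factor(sp_phase[!inb], levels = protocol$labels))
    n_b <- table(factor(b_phase, levels = protocol$labels))
    mbd <- tapply(bd$duration, factor(b_phase, levels = protocol$labels),
                  mean)
    out[[i]] <- data.frame(
      electrode = id,
      phase = protocol$labels,
      fr = as.numeric(n_sp) / durs,
      br = as.numeric(n_b) / durs * 60,
      mean_bd = as.numeric(mbd),
      obfr = as.numeric(n_out) / durs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Electrodes active in the baseline phase
#'
#' An electrode is spiking-active when its firing rate in the reference
#' phase is at least `fr_min` (default 0.1 Hz), and bursting-active when its
#' burst rate there is at least `br_min_hz` (default 0.04 Hz, i.e. 36 bursts
#' in a 900-s phase). Both bounds are inclusive.
#'
#' @param rates Output of [electrode_phase_rates()].
#' @param phase Reference phase label (default `"S1"`).
#' @param kind `"spiking"` or `"bursting"`.
#' @param fr_min Spike-rate threshold, Hz.
#' @param br_min_hz Burst-rate threshold, Hz.
#' @return Character vector of electrode ids.
#' @export
active_electrodes <- function(rates, phase = "S1",
                              kind = c("spiking", "bursting"),
                              fr_min = 0.1, br_min_hz = 0.04) {
  kind <- match.arg(kind)
  r <- rates[rates$phase == phase, ]
  if (nrow(r) == 0) stop("phase not present in rates: ", phase)
  ok <- if (kind == "spiking") r$fr >= fr_min else r$br >= br_min_hz * 60
  sort(r$electrode[ok])
}

#' Per-phase network metrics
#'
#' Computes the four per-phase network metrics over the baseline-defined
#' active-electrode sets:
#'
#' * MFR (Hz): sum of per-electrode firing rates over the spiking-active
#'   set, divided by the number of spiking-active electrodes in the
#'   baseline phase, N_S(S1);
#' * MBR (bursts/min): sum of burst rates over the bursting-active set,
#'   divided by N_B(S1);
#' * MBD (s): sum of per-electrode mean burst durations over the
#'   bursting-active set, divided by N_B(S1) (or by the number of
#'   bursting-active electrodes with bursts in the phase when
#'   `mbd_denominator = "per_phase"`); `NA` when no such electrode bursts;
#' * MOBFR (Hz): sum of outside-burst firing rates over the bursting-active
#'   set, divided by N_B(S1).
#'
#' The active sets are computed once from the baseline phase and reused for
#' every phase, so later changes in activity do not change the denominators.
#'
#' @param spikes A [spike_train_set()].
#' @param bursts A `burst_train` from [detect_all_bursts()].
#' @param baseline Baseline phase label (default: first protocol phase).
#' @param mbd_denominator `"s1"` (baseline bursting-active count) or
#'   `"per_phase"` (electrodes with bursts in the phase).
#' @param culture Culture identifier stored in the table (default `"c1"`).
#' @return A `metrics_table` data frame: `culture, phase, MFR, MBR, MBD,
#'   MOBFR, n_active_spiking, n_active_bursting`, or `NULL` (with a
#'   warning) when no electrode passes an activity filter — the culture is
#'   then unusable.
#' @export
compute_phase_metrics <- function(spikes, bursts, baseline = NULL,
                                  mbd_denominator = c("s1", "per_phase"),
                                  culture = "c1") {
  mbd_denominator <- match.arg(mbd_denominator)
  protocol <- spikes$protocol
  if (is.null(baseline)) baseline <- protocol$labels[1]
  rates <- electrode_phase_rates(spikes, bursts)
  act_s <- active_electrodes(rates, baseline, "spiking")
  act_b <- active_electrodes(rates, baseline, "bursting")
  if (length(act_s) == 0 || length(act_b) == 0) {
    warning("culture ", culture, " unusable: no active electrodes in ",
            baseline, " (spiking: ", length(act_s),
            ", bursting: ", length(act_b), ")")
    return(NULL)
  }
  rows <- lapply(protocol$labels, function(ph) {
    r <- rates[rates$phase == ph, ]
    rs <- r[r$electrode %in% act_s, ]
    rb <- r[r$electrode %in% act_b, ]
    has_bd <- !is.na(rb$mean_bd)
    mbd_n <- if (mbd_denominator == "s1") length(act_b) else sum(has_bd)
    data.frame(
      culture = culture, phase = ph,
      MFR = sum(rs$fr) / length(act_s),
      MBR = sum(rb$br) / length(act_b),
      MBD = if (any(has_bd)) sum(rb$mean_bd[has_bd]) / mbd_n else NA_real_,
      MOBFR = sum(rb$obfr) / length(act_b),
      n_active_spiking = length(act_s),
      n_active_bursting = length(act_b))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("metrics_table", "data.frame")
  attr(out, "baseline") <- baseline
  attr(out, "normalized") <- FALSE
  out
}

#' Normalize metrics to the baseline phase
#'
#' Expresses each metric per culture as a percentage of its baseline-phase
#' value (baseline = 100). A metric whose baseline value is 0 or missing is
#' undefined for that culture and becomes `NA` (with a message). Applying
#' the normalization twice is the identity.
#'
#' @param table A `metrics_table` (possibly covering several cultures).
#' @param baseline Baseline phase label; defaults to the table's own.
#' @return A normalized `metrics_table` (values in percent).
#' @export
normalize_metrics <- function(table, baseline = NULL) {
  stopifnot(inherits(table, "metrics_table"))
  if (is.null(baseline)) baseline <- attr(table, "baseline") %||% table$phase[1]
  metrics <- c("MFR", "MBR", "MBD", "MOBFR")
  out <- table
  for (cu in unique(out$culture)) {
    sel <- out$culture == cu
    base <- out[sel & out$phase == baseline, ]
    if (nrow(base) != 1) stop("baseline phase missing for culture ", cu)
    for (m in metrics) {
      b <- base[[m]]
      if (is.na(b) || b == 0) {
        if (!all(is.na(out[sel, m]))) {
          message("metric ", m, " undefined for culture ", cu,
                  " (baseline value ", b, ")")
          out[sel, m] <- NA_real_
        }
      } else {
        out[sel, m] <- 100 * out[sel, m] / b
      }
    }
  }
  attr(out, "baseline") <- baseline
  attr(out, "normalized") <- TRUE
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-minute normalized MBR time course (one culture)
#'
#' Counts bursts on the baseline bursting-active electrode set per time bin
#' (default 60 s), converts to bursts/min per active electrode, and
#' normalizes so the mean over baseline-phase bins is 100%.
#'
#' @param spikes A [spike_train_set()].
#' @param bursts A `burst_train`.
#' @param bin_s Bin width, s; must divide every phase duration (default 60).
#' @param baseline Baseline phase label (default: first protocol phase).
#' @return Data frame `bin_start` (s), `mbr` (bursts/min per electrode),
#'   `mbr_norm` (% of baseline mean).
#' @export
mbr_timecourse <- function(spikes, bursts, bin_s = 60, baseline = NULL) {
  protocol <- spikes$protocol
  if (is.null(baseline)) baseline <- protocol$labels[1]
  if (any(abs(phase_durations(protocol) / bin_s -
                round(phase_durations(protocol) / bin_s)) > 1e-9))
    stop("bin_s must divide every phase duration")
  rates <- electrode_phase_rates(spikes, bursts)
  act_b <- active_electrodes(rates, baseline, "bursting")
  if (length(act_b) == 0) stop("no bursting-active electrodes in ", baseline)
  edges <- seq(0, protocol$total_duration, by = bin_s)
  b <- bursts$bursts[bursts$bursts$electrode %in% act_b, ]
  counts <- as.numeric(table(cut(b$start, edges, right = FALSE)))
  mbr <- counts / length(act_b) * (60 / bin_s)
  bin_start <- edges[-length(edges)]
  base_sel <- bin_start >= protocol$start[match(baseline, protocol$labels)] &
    bin_start < protocol$end[match(baseline, protocol$labels)]
  base_mean <- mean(mbr[base_sel])
  data.frame(bin_start = bin_start, mbr = mbr,
             mbr_norm = 100 * mbr / base_mean)
}

#' Aggregate per-culture MBR time courses
#'
#' @param series List of data frames from [mbr_timecourse()], one per
#'   culture (identical binning).
#' @return Data frame `bin_start, mean, sem` of the normalized series
#'   across cultures.
#' @export
aggregate_timecourse <- function(series) {
  stopifnot(length(series) >= 1)
  m <- vapply(series, function(s) s$mbr_norm, numeric(nrow(series[[1]])))
  m <- matrix(m, nrow = nrow(series[[1]]))
  data.frame(bin_start = series[[1]]$bin_start,
             mean = rowMeans(m),
             sem = apply(m, 1, stats::sd) / sqrt(ncol(m)))
}
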