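#' Scenario configuration for the synthetic culture generator
#'
#' Parameters of the doubly stochastic generative model used to emulate
#' mature dissociated cortical cultures on a 60-electrode MEA: network-burst
#' events arrive as a (possibly phase-modulated) Poisson process; each event
#' recruits each active electrode independently; recruited electrodes emit a
#' short high-frequency spike burst; tonic (outside-burst) spikes arrive as
#' independent Poisson processes per electrode. Phase-restricted exposure
#' effects enter through three per-phase multiplier tracks:
#'
#' * `burst_multipliers` scale the network-burst initiation rate
#'   (RF-like suppression acts on burst generation);
#' * `tonic_multipliers` scale the tonic firing rate;
#' * `retain_multipliers` thin every emitted spike with the given retention
#'   probability (uniform firing suppression, heat-like when persistent).
#'
#' Multiplier transitions at phase boundaries are instantaneous when
#' `onset_tau`/`recovery_tau` are 0, otherwise relax exponentially with the
#' given time constants (onset when the target is lower than the current
#' level, recovery when higher).
#'
#' @param n_electrodes Number of electrodes (default 60).
#' @param network_burst_rate Baseline network-burst initiation rate,
#'   events/min (default 10).
#' @param participation_prob Probability an active electrode joins a given
#'   network-burst event (default 0.6).
#' @param spikes_per_burst_mean Mean spikes per electrode burst; counts are
#'   drawn as 1 + Poisson(mean - 1) (default 8).
#' @param intra_burst_isi Mean intra-burst inter-spike interval, s
#'   (default 0.010).
#' @param isi_shape Gamma shape of intra-burst ISIs; larger = more regular
#'   (default 4).
#' @param burst_onset_jitter SD of the per-electrode burst-onset jitter
#'   around the network event time, s (default 0.015).
#' @param tonic_rate Tonic (outside-burst) Poisson rate per active
#'   electrode, Hz (default 0.5).
#' @param inactive_fraction Fraction of electrodes with sub-threshold
#'   activity: no burst participation, tonic rate `inactive_tonic_rate`
#'   (default 0.15).
#' @param inactive_tonic_rate Tonic rate of inactive electrodes, Hz
#'   (default 0.02).
#' @param burst_multipliers,tonic_multipliers,retain_multipliers Named
#'   numeric vectors of per-phase multipliers (names = phase labels);
#'   missing phases default to 1. Retention probabilities must be in [0, 1].
#' @param onset_tau,recovery_tau Exponential relaxation time constants for
#'   multiplier transitions, s; 0 = instantaneous (default 0).
#' @return An object of class `scenario_config`.
#' @seealso [generate_scenario()], [exposure_multipliers()]
#' @export
scenario_config <- function(n_electrodes = 60,
                            network_burst_rate = 10,
                            participation_prob = 0.6,
                            spikes_per_burst_mean = 8,
                            intra_burst_isi = 0.010,
                            isi_shape = 4,
                            burst_onset_jitter = 0.015,
                            tonic_rate = 0.5,
                            inactive_fraction = 0.15,
                            inactive_tonic_rate = 0.02,
                            burst_multipliers = NULL,
                            tonic_multipliers = NULL,
                            retain_multipliers = NULL,
                            onset_tau = 0,
                            recovery_tau = 0) {
  cfg <- list(n_electrodes = as.integer(n_electrodes),
              network_burst_rate = network_burst_rate,
              participation_prob = participation_prob,
              spikes_per_burst_mean = spikes_per_burst_mean,
              intra_burst_isi = intra_burst_isi,
              isi_shape = isi_shape,
              burst_onset_jitter = burst_onset_jitter,
              tonic_rate = tonic_rate,
              inactive_fraction = inactive_fraction,
              inactive_tonic_rate = inactive_tonic_rate,
              burst_multipliers = burst_multipliers,
              tonic_multipliers = tonic_multipliers,
              retain_multipliers = retain_multipliers,
              onset_tau = onset_tau,
              recovery_tau = recovery_tau)
  with(cfg, {
    if (n_electrodes < 1) stop("n_electrodes must be >= 1")
    if (network_burst_rate < 0 || tonic_rate < 0 || inactive_tonic_rate < 0)
      stop("rates must be non-negative")
    if (participation_prob < 0 || participation_prob > 1 ||
        inactive_fraction < 0 || inactive_fraction > 1)
      stop("probabilities must be in [0, 1]")
    if (spikes_per_burst_mean < 1 || intra_burst_isi <= 0 || isi_shape <= 0)
      stop("burst structure parameters out of range")
    if (onset_tau < 0 || recovery_tau < 0) stop("taus must be >= 0")
    if (!is.null(retain_multipliers) &&
        (any(retain_multipliers < 0) || any(retain_multipliers > 1)))
      stop("retain_multipliers are probabilities and must be in [0, 1]")
    for (m in list(burst_multipliers, tonic_multipliers))
      if (!is.null(m) && any(m < 0)) stop("multipliers must be >= 0")
  })
  structure(cfg, class = "scenario_config")
}

#' Per-phase multipliers for an exposure scenario
#'
#' Convenience constructor for the multiplier vectors of
#' [scenario_config()]: applies `value` during the exposure phase only
#' (RF-like, reversible) or from the exposure phase through the end of the
#' protocol (heat-like, persistent).
#'
#' @param value Multiplier applied during the affected phases.
#' @param protocol A [phase_protocol()].
#' @param exposure_phase Label of the exposure phase (default `"E"`).
#' @param persistent If `TRUE`, apply from `exposure_phase` onward.
#' @return Named numeric vector over all protocol phases.
#' @export
exposure_multipliers <- function(value, protocol = phase_protocol(),
                                 exposure_phase = "E", persistent = FALSE) {
  stopifnot(exposure_phase %in% protocol$labels)
  m <- stats::setNames(rep(1, length(protocol$labels)), protocol$labels)
  i <- match(exposure_phase, protocol$labels)
  if (persistent) m[i:length(m)] <- value else m[i] <- value
  m
}

# Piecewise-exponential multiplier timeline: per-phase targets relaxed with
# onset_tau (downward) / recovery_tau (upward) at each phase boundary.
# Returns list(fun = vectorized m(t), max = supremum over [0, total)).
multiplier_timeline <- function(targets, protocol, onset_tau, recovery_tau) {
  targ <- stats::setNames(rep(1, length(protocol$labels)), protocol$labels)
  if (!is.null(targets)) {
    unknown <- setdiff(names(targets), protocol$labels)
    if (length(unknown))
      stop("multiplier names not in protocol: ", paste(unknown, collapse = ", "))
    targ[names(targets)] <- targets
  }
  k <- length(targ)
  start_level <- numeric(k)   # level at each phase start
  start_level[1] <- targ[1]
  tau <- numeric(k)           # relaxation constant within each phase
  tau[1] <- 0
  if (k > 1) for (i in 2:k) {
    dur <- protocol$end[i - 1] - protocol$start[i - 1]
    prev_end <- if (tau[i - 1] == 0) targ[i - 1] else
      targ[i - 1] + (start_level[i - 1] - targ[i - 1]) * exp(-dur / tau[i - 1])
    start_level[i] <- prev_end
    tau[i] <- if (targ[i] < prev_end) onset_tau else recovery_tau
  }
  fun <- function(t) {
    i <- findInterval(t, c(protocol$start, protocol$total_duration))
    i[i < 1L] <- 1L
    i[i > k] <- k
    out <- targ[i]
    relax <- tau[i] > 0
    if (any(relax)) {
      ii <- i[relax]
      out[relax] <- targ[ii] + (start_level[ii] - targ[ii]) *
        exp(-(t[relax] - protocol$start[ii]) / tau[ii])
    }
    unname(out)
  }
  list(fun = fun, max = max(targ, start_level))
}

# Inhomogeneous Poisson times on [0, total) by thinning.
rpoisson_times <- function(base_rate_hz, tl, total) {
  lam_max <- base_rate_hz * tl$max
  if (lam_max <= 0) return(numeric(0))
  n <- stats::rpois(1L, lam_max * total)
  if (n == 0L) return(numeric(0))
  t <- sort(stats::runif(n, 0, total))
  keep <- stats::runif(n) <= tl$fun(t) / tl$max
  t[keep]
}

#' Generate a synthetic MEA culture
#'
#' Draws one culture from the doubly stochastic model described in
#' [scenario_config()] and returns the spike trains together with the
#' generator's ground truth (network-event times, per-electrode burst
#' intervals, per-phase true event counts), so that detection and metric
#' stages can be validated against known structure.
#'
#' @param config A [scenario_config()].
#' @param protocol A [phase_protocol()] (default: five 15-min phases).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return An object of class `synthetic_dataset`: list with elements
#'   `spikes` ([spike_train_set()]), `ground_truth` (list: `event_times`,
#'   `bursts` data frame with `electrode, event, start, end, n_spikes`,
#'   `phase_event_counts`, `active_electrodes`), `config`, `protocol`,
#'   `seed`.
#' @export
generate_scenario <- function(config, protocol = phase_protocol(),
                              seed = NULL) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(protocol, "phase_protocol"))
  if (protocol$total_duration <= 0) stop("degenerate protocol")
  if (!is.null(seed)) set.seed(seed)
  total <- protocol$total_duration
  ne <- config$n_electrodes
  elec <- sprintf("el%02d", seq_len(ne))

  n_inactive <- round(config$inactive_fraction * ne)
  inactive <- if (n_inactive > 0) sample(elec, n_inactive) else character(0)
  active <- setdiff(elec, inactive)

  tl_burst <- multiplier_timeline(config$burst_multipliers, protocol,
                                  config$onset_tau, config$recovery_tau)
  tl_tonic <- multiplier_timeline(config$tonic_multipliers, protocol,
                                  config$onset_tau, config$recovery_tau)
  tl_retain <- multiplier_timeline(config$retain_multipliers, protocol,
                                   config$onset_tau, config$recovery_tau)

  ## network-burst events
  ev <- rpoisson_times(config$network_burst_rate / 60, tl_burst, total)
  nev <- length(ev)

  ## burst recruitment: one row per (event, active electrode) pair recruited
  bursts <- NULL
  spike_df <- list()
  if (nev > 0 && length(active) > 0) {
    rec <- matrix(stats::runif(nev * length(active)) <= config$participation_prob,
                  nrow = nev)
    idx <- which(rec, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      onset <- ev[idx[, 1]] +
        stats::rnorm(nrow(idx), 0, config$burst_onset_jitter)
      nsp <- 1L + stats::rpois(nrow(idx),
                               max(config$spikes_per_burst_mean - 1, 0))
      tot_isi <- sum(nsp - 1L)
      isis <- stats::rgamma(tot_isi, shape = config$isi_shape,
                            rate = config$isi_shape / config$intra_burst_isi)
      ## spike times: onset + within-burst cumulative ISI (first spike at
      ## onset). Non-first spikes carry an ISI increment; grouped cumsum.
      bid <- rep.int(seq_len(nrow(idx)), nsp)
      inc <- numeric(length(bid))
      inc[duplicated(bid)] <- isis
      cs <- cumsum(inc)
      first_idx <- which(!duplicated(bid))
      within <- cs - cs[first_idx][bid]
      st <- onset[bid] + within
      spike_df$burst <- data.frame(
        electrode = active[idx[, 2]][bid], time = st)
      last <- cumsum(nsp)
      bursts <- data.frame(
        electrode = active[idx[, 2]],
        event = idx[, 1],
        start = onset,
        end = st[last],
        n_spikes = nsp)
    }
  }

  ## tonic spikes
  tonic_for <- function(ids, rate) {
    if (length(ids) == 0 || rate <= 0) return(NULL)
    times <- lapply(ids, function(e) rpoisson_times(rate, tl_tonic, total))
    n <- lengths(times)
    if (sum(n) == 0) return(NULL)
    data.frame(electrode = rep(ids, n), time = unlist(times))
  }
  spike_df$tonic <- tonic_for(active, config$tonic_rate)
  spike_df$inactive <- tonic_for(inactive, config$inactive_tonic_rate)

  all_spikes <- do.call(rbind, spike_df[!vapply(spike_df, is.null, logical(1))])
  if (is.null(all_spikes))
    all_spikes <- data.frame(electrode = character(0), time = numeric(0))

  ## uniform retention thinning (heat-like firing suppression)
  if (nrow(all_spikes) > 0 && !is.null(config$retain_multipliers)) {
    keep <- stats::runif(nrow(all_spikes)) <= tl_retain$fun(all_spikes$time)
    all_spikes <- all_spikes[keep, ]
  }
  in_span <- all_spikes$time >= 0 & all_spikes$time < total
  all_spikes <- all_spikes[in_span, ]

  trains <- stats::setNames(vector("list", ne), elec)
  got <- split(all_spikes$time, factor(all_spikes$electrode, levels = elec))
  for (e in elec) trains[[e]] <- sort(unique(got[[e]]))

  phase_counts <- if (nev > 0)
    table(factor(phase_of(ev[ev < total], protocol),
                 levels = protocol$labels))
  else
    table(factor(character(0), levels = protocol$labels))

  structure(
    list(spikes = spike_train_set(trains, protocol),
         ground_truth = list(
           event_times = ev,
           bursts = bursts,
           phase_event_counts = as.integer(phase_counts) |>
             stats::setNames(protocol$labels),
           active_electrodes = sort(active)),
         config = config,
         protocol = protocol,
         seed = seed),
    class = "synthetic_dataset")
}

#' Simulate several cultures under one scenario
#'
#' @param config A [scenario_config()].
#' @param protocol A [phase_protocol()].
#' @param n_cultures Number of independent cultures.
#' @param seed Base seed; culture `i` uses `seed + i - 1`.
#' @return List of [generate_scenario()] results, named `culture01`, ...
#' @export
simulate_cultures <- function(config, protocol = phase_protocol(),
                              n_cultures = 1, seed = 1) {
  stopifnot(n_cultures >= 1)
  out <- lapply(seq_len(n_cultures), function(i)
    generate_scenario(config, protocol, seed = seed + i - 1))
  names(out) <- sprintf("culture%02d", seq_len(n_cultures))
  out
}

#' Render spike trains as raw multichannel waveforms
#'
#' Places a spike waveform template at every spike time (template trough
#' aligned to the spike time) on top of white Gaussian noise, emulating the
#' extracellular voltage signal the spike detector sees.
#'
#' @param dataset A `synthetic_dataset` or [spike_train_set()].
#' @param amplitude_uV Peak-to-peak template amplitude in uV (default 100).
#' @param noise_sd Noise SD in uV (default 5).
#' @param fs Sampling rate, Hz (default 10000).
#' @param template Optional numeric template (arbitrary scale; rescaled to
#'   `amplitude_uV` peak-to-peak). Default: biphasic 1-ms sine transient.
#' @param seed Optional integer seed for the noise.
#' @return A [raw_recording()].
#' @export
synthesize_waveforms <- function(dataset, amplitude_uV = 100, noise_sd = 5,
                                 fs = 10000, template = NULL, seed = NULL) {
  spikes <- if (inherits(dataset, "synthetic_dataset")) dataset$spikes else dataset
  stopifnot(inherits(spikes, "spike_train_set"))
  if (fs < 1000) stop("fs must be >= 1 kHz")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(template)) {
    ns <- max(round(0.001 * fs), 4L)
    template <- sin(2 * pi * seq(0, 1, length.out = ns))
  }
  if (length(template) / fs >= 0.002) stop("template duration must be < 2 ms")
  rng <- max(template) - min(template)
  if (rng <= 0) stop("template must be non-constant")
  template <- template / rng * amplitude_uV
  trough <- which.min(template)
  total <- spikes$protocol$total_duration
  nsamp <- round(total * fs)
  ids <- names(spikes$trains)
  x <- matrix(stats::rnorm(length(ids) * nsamp, 0, noise_sd),
              nrow = length(ids))
  truncated <- FALSE
  for (ci in seq_along(ids)) {
    for (st in spikes$trains[[ids[ci]]]) {
      pos <- round(st * fs) + 1L - (trough - 1L)  # template start sample
      i0 <- max(pos, 1L)
      i1 <- min(pos + length(template) - 1L, nsamp)
      if (i1 < pos + length(template) - 1L || i0 > pos) truncated <- TRUE
      if (i0 > i1) next
      x[ci, i0:i1] <- x[ci, i0:i1] + template[(i0 - pos + 1L):(i1 - pos + 1L)]
    }
  }
  if (truncated)
    warning("template truncated at recording edge for some spikes")
  raw_recording(x, fs = fs, channel_ids = ids)
}

#' Generate a synthetic temperature transient
#'
#' First-order heating: `dT(t) = (SAR * tau / C) * (1 - exp(-t/tau))` from
#' exposure onset, with optional additive Gaussian measurement noise. The
#' initial slope of the noiseless curve is `SAR / C` by construction.
#'
#' @param sar Specific absorption rate, W/kg.
#' @param tau Thermal time constant, s.
#' @param C Specific heat capacity, J/(kg K) (default 4196.8, culture
#'   medium).
#' @param duration Trace duration, s (default 900).
#' @param fs Sampling rate, Hz (default 1).
#' @param noise_sd Measurement noise SD, degrees C (default 0).
#' @param baseline Baseline temperature, degrees C (default 37).
#' @param seed Optional integer seed.
#' @return A [temperature_trace()] with `t_on = 0`, `t_off = duration`.
#' @export
generate_temperature_trace <- function(sar, tau, C = 4196.8, duration = 900,
                                       fs = 1, noise_sd = 0, baseline = 37,
                                       seed = NULL) {
  if (tau <= 0 || C <= 0 || duration <= 0 || fs <= 0)
    stop("tau, C, duration, fs must be positive")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = 1 / fs)
  dT <- (sar * tau / C) * (1 - exp(-t / tau))
  if (noise_sd > 0) dT <- dT + stats::rnorm(length(t), 0, noise_sd)
  temperature_trace(t, baseline + dT, t_on = 0, t_off = duration,
                    baseline = baseline)
}
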