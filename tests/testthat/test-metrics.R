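# Deterministic single-phase culture with exactly known rates:
#   elA: 90 bursts of 5 spikes at 10 ms ISI, every 10 s -> FR 0.5 Hz,
#        BR 6/min, BD 40 ms
#   elB: 90 bursts of 10 spikes at 10 ms ISI             -> FR 1.0 Hz,
#        BR 6/min, BD 90 ms
#   elC: 45 lone spikes at 20 s spacing                  -> FR 0.05 Hz
deterministic_culture <- function() {
  p <- phase_protocol("S1", 900)
  starts <- seq(0.5, 890.5, by = 10)
  elA <- as.vector(outer(seq(0, 0.04, by = 0.01), starts, "+"))
  elB <- as.vector(outer(seq(0, 0.09, by = 0.01), starts, "+"))
  elC <- seq(10, 890, by = 20)
  spikes <- spike_train_set(list(elA = sort(elA), elB = sort(elB),
                                 elC = elC), p)
  list(spikes = spikes, bursts = detect_all_bursts(spikes), protocol = p)
}

test_that("metric equations give the exact values on a known culture", {
  cu <- deterministic_culture()
  rates <- electrode_phase_rates(cu$spikes, cu$bursts)
  expect_equal(rates$fr, c(0.5, 1.0, 0.05))
  expect_equal(rates$br, c(6, 6, 0))
  expect_equal(rates$mean_bd[1:2], c(0.04, 0.09), tolerance = 1e-9)
  expect_equal(active_electrodes(rates, "S1", "spiking"), c("elA", "elB"))
  expect_equal(active_electrodes(rates, "S1", "bursting"), c("elA", "elB"))
  m <- compute_phase_metrics(cu$spikes, cu$bursts)
  # inactive elC excluded from both the sum and the count
  expect_equal(m$MFR, 0.75)           # (0.5 + 1.0) / 2
  expect_equal(m$MBR, 6)              # (6 + 6) / 2 bursts/min
  expect_equal(m$MBD, 0.065, tolerance = 1e-9)
  expect_equal(m$MOBFR, 0)            # every spike of elA/elB is in a burst
  expect_equal(m$n_active_spiking, 2)
  expect_equal(m$n_active_bursting, 2)
})

test_that("activity thresholds are boundary-inclusive", {
  rates <- data.frame(
    electrode = c("a", "b", "c", "d"), phase = "S1",
    fr = c(0.1, 0.0999, 5, 0.05),
    br = c(2.4, 2.39, 10, 0),
    mean_bd = NA_real_, obfr = 0)
  expect_equal(active_electrodes(rates, "S1", "spiking"), c("a", "c"))
  # 0.04 Hz = 2.4 bursts/min = 36 bursts in a 900 s phase
  expect_equal(active_electrodes(rates, "S1", "bursting"), c("a", "c"))
})

test_that("FR decomposes into in-burst and outside-burst rates", {
  d <- generate_scenario(small_config(), short_protocol(), seed = 31)
  bursts <- detect_all_bursts(d$spikes)
  rates <- electrode_phase_rates(d$spikes, bursts)
  p <- d$protocol
  for (e in sample(names(d$spikes$trains), 5)) {
    tr <- d$spikes$trains[[e]]
    b <- bursts$bursts[bursts$bursts$electrode == e, ]
    for (ph in p$labels) {
      sel <- rates$electrode == e & rates$phase == ph
      in_ph <- tr[phase_of(tr, p) == ph]
      n_in <- sum(vapply(in_ph, function(t)
        any(t >= b$start & t <= b$end), logical(1)))
      dur <- unname(phase_durations(p)[ph])
      expect_equal(rates$fr[sel] * dur,
                   n_in + rates$obfr[sel] * dur, tolerance = 1e-9)
    }
  }
})

test_that("normalization sets the baseline to exactly 100 and is idempotent", {
  d <- generate_scenario(small_config(), short_protocol(), seed = 32)
  bursts <- detect_all_bursts(d$spikes)
  m <- compute_phase_metrics(d$spikes, bursts)
  nm <- normalize_metrics(m)
  for (col in c("MFR", "MBR", "MBD", "MOBFR"))
    expect_equal(nm[[col]][nm$phase == "S1"], 100)
  expect_equal(normalize_metrics(nm), nm)
})

test_that("a zero-baseline metric becomes undefined, not infinite", {
  cu <- deterministic_culture()
  m <- compute_phase_metrics(cu$spikes, cu$bursts)
  expect_equal(m$MOBFR, 0)
  expect_message(nm <- normalize_metrics(m), "MOBFR")
  expect_true(is.na(nm$MOBFR))
  expect_equal(nm$MFR, 100)
})

test_that("active sets are frozen in S1 and reused for later phases", {
  p <- short_protocol()
  starts <- seq(0.5, 55.5, by = 5)
  burst5 <- function(t0) as.vector(outer(seq(0, 0.04, by = 0.01), t0, "+"))
  base <- sort(burst5(starts))
  # elD is silent before E and bursts heavily from E onward
  late <- sort(burst5(seq(120.5, 295.5, by = 5)))
  s1 <- spike_train_set(list(elA = base, elB = base + 0.3,
                             elC = base + 0.7), p)
  s2 <- spike_train_set(list(elA = base, elB = base + 0.3,
                             elC = base + 0.7, elD = late), p)
  m1 <- compute_phase_metrics(s1, detect_all_bursts(s1))
  m2 <- compute_phase_metrics(s2, detect_all_bursts(s2))
  expect_equal(m2$n_active_spiking, m1$n_active_spiking)
  expect_equal(m2$n_active_bursting, m1$n_active_bursting)
  expect_equal(m2$MBR, m1$MBR)
  expect_equal(m2$MFR, m1$MFR)
})

test_that("metrics recover the generator's expected rates", {
  # closed-form expectation for active electrodes:
  #   FR = tonic + event_rate * participation * spikes_per_burst
  #   BR = event_rate * participation (bursts/min)
  cfg <- small_config()
  exp_fr <- cfg$tonic_rate + cfg$network_burst_rate / 60 *
    cfg$participation_prob * cfg$spikes_per_burst_mean
  exp_br <- cfg$network_burst_rate * cfg$participation_prob
  vals <- t(sapply(1:6, function(s) {
    d <- generate_scenario(cfg, short_protocol(), seed = 40 + s)
    m <- compute_phase_metrics(d$spikes, detect_all_bursts(d$spikes))
    c(mean(m$MFR), mean(m$MBR))
  }))
  expect_equal(mean(vals[, 1]), exp_fr, tolerance = 0.05)
  expect_equal(mean(vals[, 2]), exp_br, tolerance = 0.05)
})

test_that("MBR time course reflects a step suppression during E", {
  p <- short_protocol()
  cfg <- small_config(burst_multipliers = c(E = 0.5))
  series <- lapply(1:8, function(s) {
    d <- generate_scenario(cfg, p, seed = 50 + s)
    mbr_timecourse(d$spikes, detect_all_bursts(d$spikes), bin_s = 20)
  })
  agg <- aggregate_timecourse(series)
  expect_equal(nrow(agg), 15)  # 300 s / 20 s bins
  in_E <- agg$bin_start >= 120 & agg$bin_start < 180
  expect_equal(mean(agg$mean[in_E]), 50, tolerance = 0.2)
  expect_equal(mean(agg$mean[!in_E]), 100, tolerance = 0.1)
})

test_that("sham MBR time course is stationary", {
  p <- short_protocol()
  series <- lapply(1:8, function(s) {
    d <- generate_scenario(small_config(), p, seed = 60 + s)
    mbr_timecourse(d$spikes, detect_all_bursts(d$spikes), bin_s = 20)
  })
  agg <- aggregate_timecourse(series)
  fit <- lm(mean ~ bin_start, data = agg)
  ci <- confint(fit)["bin_start", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})
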