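test_that("same seed reproduces the dataset exactly", {
  p <- short_protocol()
  cfg <- small_config()
  d1 <- generate_scenario(cfg, p, seed = 1)
  d2 <- generate_scenario(cfg, p, seed = 1)
  expect_identical(d1$spikes$trains, d2$spikes$trains)
  expect_identical(d1$ground_truth$event_times, d2$ground_truth$event_times)
  d3 <- generate_scenario(cfg, p, seed = 2)
  expect_false(identical(d1$spikes$trains, d3$spikes$trains))
})

test_that("spike times are sorted and within the protocol span", {
  d <- generate_scenario(small_config(), short_protocol(), seed = 1)
  for (tr in d$spikes$trains) {
    expect_false(is.unsorted(tr, strictly = TRUE))
    if (length(tr)) {
      expect_gte(tr[1], 0)
      expect_lt(tr[length(tr)], d$protocol$total_duration)
    }
  }
})

test_that("ground-truth burst intervals contain their member spikes", {
  d <- generate_scenario(small_config(), short_protocol(), seed = 3)
  b <- d$ground_truth$bursts
  expect_true(all(b$end >= b$start))
  # every ground-truth interval overlaps spikes of its electrode
  for (i in sample(nrow(b), 50)) {
    tr <- d$spikes$trains[[b$electrode[i]]]
    expect_true(any(tr >= b$start[i] - 1e-9 & tr <= b$end[i] + 1e-9))
  }
})

test_that("sham scenario has stationary true event rate across phases", {
  p <- short_protocol()
  tot <- matrix(0, 20, 5)
  for (s in 1:20)
    tot[s, ] <- generate_scenario(small_config(), p,
                                  seed = s)$ground_truth$phase_event_counts
  m <- colMeans(tot)
  expect_lt(max(abs(m / mean(m) - 1)), 0.15)
})

test_that("phase multipliers thin the true event counts proportionally", {
  p <- short_protocol()
  cfg <- small_config(burst_multipliers = c(E = 0.5))
  tot <- matrix(0, 30, 5)
  for (s in 1:30)
    tot[s, ] <- generate_scenario(cfg, p, seed = s)$ground_truth$phase_event_counts
  m <- colMeans(tot)
  names(m) <- p$labels
  ratio <- m["E"] / mean(m[c("S1", "S2", "P1", "P2")])
  expect_lt(abs(ratio - 0.5), 0.08)
})

test_that("retention multipliers thin spikes uniformly and persistently", {
  p <- short_protocol()
  cfg <- small_config(
    retain_multipliers = exposure_multipliers(0.5, p, persistent = TRUE))
  ref <- small_config()
  n_eff <- matrix(0, 10, 5)
  n_ref <- matrix(0, 10, 5)
  count_by_phase <- function(d) {
    all <- sort(unlist(d$spikes$trains, use.names = FALSE))
    as.numeric(table(factor(phase_of(all, p), levels = p$labels)))
  }
  for (s in 1:10) {
    n_eff[s, ] <- count_by_phase(generate_scenario(cfg, p, seed = s))
    n_ref[s, ] <- count_by_phase(generate_scenario(ref, p, seed = s))
  }
  ratio <- colMeans(n_eff) / colMeans(n_ref)
  expect_lt(max(abs(ratio[1:2] - 1)), 0.05)    # S1, S2 untouched
  expect_lt(max(abs(ratio[3:5] - 0.5)), 0.05)  # E, P1, P2 halved
})

test_that("multiplier relaxation is gradual with nonzero taus", {
  p <- short_protocol()
  tl <- mearf:::multiplier_timeline(c(E = 0.5), p, onset_tau = 20,
                                    recovery_tau = 20)
  tE <- p$start[3]
  # entering E: starts at 1, relaxes toward 0.5
  expect_equal(tl$fun(tE), 1, tolerance = 1e-6)
  expect_equal(tl$fun(tE + 20), 0.5 + 0.5 * exp(-1), tolerance = 1e-6)
  # leaving E: recovery toward 1 from the level reached at end of E
  end_E <- 0.5 + 0.5 * exp(-60 / 20)
  expect_equal(tl$fun(p$start[4]), end_E, tolerance = 1e-6)
  expect_gt(tl$fun(p$start[4] + 40), 0.9)
})

test_that("degenerate configs are rejected", {
  expect_error(scenario_config(n_electrodes = 0))
  expect_error(scenario_config(participation_prob = 1.5))
  expect_error(scenario_config(retain_multipliers = c(E = 1.2)),
               "probabilities")
  expect_error(scenario_config(network_burst_rate = -1))
})

test_that("pure-noise waveforms have the requested noise SD", {
  p <- phase_protocol("all", 2)
  sts <- spike_train_set(list(el01 = numeric(0)), p)
  rec <- synthesize_waveforms(sts, noise_sd = 5, seed = 1)
  expect_equal(sd(rec$samples[1, ]), 5, tolerance = 0.2)
  expect_equal(ncol(rec$samples), 20000)
})

test_that("a lone spike produces one suprathreshold excursion", {
  p <- phase_protocol("all", 1)
  sts <- spike_train_set(list(el01 = 0.5), p)
  rec <- synthesize_waveforms(sts, amplitude_uV = 50, noise_sd = 0, seed = 1)
  x <- rec$samples[1, ]
  expect_equal(max(x) - min(x), 50, tolerance = 1e-6)
  expect_equal(which.min(x) / rec$fs, 0.5, tolerance = 1e-3)
})

test_that("noiseless waveform round trip recovers every injected spike", {
  p <- phase_protocol("all", 5)
  set.seed(4)
  truth <- sort(sample(seq(0.05, 4.95, by = 0.01), 40))
  sts <- spike_train_set(list(el01 = truth), p)
  rec <- synthesize_waveforms(sts, amplitude_uV = 50, noise_sd = 0, seed = 1)
  det <- detect_spikes(rec, noise_sd = 5, protocol = p)
  m <- match_times(det$trains$el01, truth)
  expect_equal(m$recall, length(truth))
  expect_equal(m$fp, 0)
})

test_that("temperature trace matches the first-order model", {
  # no exposure -> flat at baseline
  tr0 <- generate_temperature_trace(0, 120, duration = 300)
  expect_equal(tr0$temperature, rep(37, length(tr0$time)))
  # printed end-of-exposure rise for the high-SAR condition
  tr <- generate_temperature_trace(28, 120, C = 4196.8, duration = 900)
  expect_equal(tr$temperature[tr$time == 900] - 37, 0.80, tolerance = 0.005)
  # initial slope equals SAR / C (finite difference near t = 0)
  tr_fine <- generate_temperature_trace(28, 120, duration = 10, fs = 100)
  fd <- diff(tr_fine$temperature[1:2]) * 100
  expect_equal(fd, 28 / 4196.8, tolerance = 0.01 * 28 / 4196.8)
})
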