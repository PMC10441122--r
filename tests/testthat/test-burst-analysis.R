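test_that("logISI threshold falls in the valley of a bimodal ISI mixture", {
  set.seed(21)
  isi_ms <- sample(c(rlnorm(500, log(10), 0.15), rlnorm(500, log(2000), 0.15)))
  times <- cumsum(isi_ms) / 1000
  th <- logisi_threshold(times)
  thr_ms <- th$threshold * 1000
  expect_false(th$fallback)
  expect_gt(thr_ms, 10)
  expect_lt(thr_ms, 2000)
  oracle_ms <- oracle_valley_ms(diff(times) * 1000)
  # within one histogram bin (0.1 in log10) of the brute-force valley
  expect_lte(abs(log10(thr_ms) - log10(oracle_ms)), 0.1 + 1e-9)
})

test_that("logISI threshold is log-domain equivariant", {
  set.seed(22)
  isi_ms <- sample(c(rlnorm(400, log(8), 0.2), rlnorm(400, log(1500), 0.2)))
  t1 <- cumsum(isi_ms) / 1000
  t10 <- cumsum(isi_ms * 10) / 1000
  th1 <- logisi_threshold(t1)
  # a decade-scaled train needs a larger peak bound to keep its intra-burst
  # peak admissible
  th10 <- logisi_threshold(t10, max_threshold_ms = 1000)
  expect_false(th1$fallback)
  expect_false(th10$fallback)
  expect_lte(abs(log10(th10$threshold / th1$threshold) - 1), 0.1 + 1e-9)
})

test_that("unimodal slow trains fall back and give zero bursts", {
  set.seed(23)
  times <- cumsum(rlnorm(200, log(1), 0.1))  # ISIs around 1 s
  th <- logisi_threshold(times)
  expect_true(th$fallback)
  expect_equal(th$threshold, 0.1)
  expect_equal(nrow(detect_bursts(times, th$threshold)), 0)
})

test_that("too few ISIs yields no threshold and no bursts", {
  th <- logisi_threshold(c(0.1, 0.2, 0.3))
  expect_true(is.na(th$threshold))
  expect_equal(nrow(detect_bursts(c(0.1, 0.2, 0.3), th$threshold)), 0)
})

test_that("burst definition is forced on deterministic trains", {
  # constant 1 s ISI, threshold 100 ms: no bursts, all spikes outside
  slow <- seq(0, 99, by = 1)
  expect_equal(nrow(detect_bursts(slow, 0.1)), 0)
  # motif: 5 spikes at 10 ms ISI then a 5 s gap
  motif <- as.vector(outer(seq(0, 0.04, by = 0.01), seq(0, 45, by = 5), "+"))
  b <- detect_bursts(sort(motif), 0.1, min_spikes = 3)
  expect_equal(nrow(b), 10)
  expect_equal(b$duration, rep(0.04, 10), tolerance = 1e-12)
  expect_equal(b$n_spikes, rep(5L, 10))
  expect_equal(sum(b$n_spikes), length(motif))  # none outside
})

test_that("bursts are disjoint, maximal, and respect the ISI bound", {
  set.seed(24)
  for (rep in 1:10) {
    times <- sort(runif(300, 0, 60))
    thr <- runif(1, 0.02, 0.5)
    b <- detect_bursts(times, thr, min_spikes = 3)
    if (nrow(b) == 0) next
    expect_true(all(b$start <= b$end))
    if (nrow(b) > 1) expect_true(all(b$start[-1] > b$end[-nrow(b)]))
    for (i in seq_len(nrow(b))) {
      members <- times[times >= b$start[i] & times <= b$end[i]]
      expect_gte(length(members), 3)
      expect_true(all(diff(members) <= thr + 1e-12))
      # maximality: the run cannot be extended on either side
      before <- times[times < b$start[i]]
      after <- times[times > b$end[i]]
      if (length(before)) expect_gt(b$start[i] - max(before), thr)
      if (length(after)) expect_gt(min(after) - b$end[i], thr)
    }
  }
})

test_that("spike partition into in/outside burst is conservative", {
  set.seed(25)
  for (rep in 1:10) {
    times <- sort(runif(250, 0, 30))
    thr <- runif(1, 0.02, 0.3)
    b <- detect_bursts(times, thr)
    n_in <- sum(vapply(times, function(t)
      any(t >= b$start & t <= b$end), logical(1)))
    expect_equal(n_in, sum(b$n_spikes))
  }
})

test_that("a larger ISI threshold never declassifies in-burst spikes", {
  set.seed(26)
  times <- sort(runif(400, 0, 60))
  n_in <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.5), function(thr)
    sum(detect_bursts(times, thr)$n_spikes), numeric(1))
  expect_true(all(diff(n_in) >= 0))
})

test_that("detected bursts match generator ground truth", {
  d <- generate_scenario(small_config(), short_protocol(), seed = 27)
  det <- detect_all_bursts(d$spikes)
  gt <- d$ground_truth$bursts
  gt <- gt[gt$n_spikes >= 3, ]
  matched <- logical(nrow(gt))
  for (i in seq_len(nrow(gt))) {
    db <- det$bursts[det$bursts$electrode == gt$electrode[i], ]
    if (nrow(db) == 0) next
    matched[i] <- any(jaccard(gt$start[i], gt$end[i], db$start, db$end) >= 0.5)
  }
  expect_gte(mean(matched), 0.9)
})

mk_burst_train <- function(df, protocol, electrodes) {
  structure(list(bursts = df,
                 thresholds = stats::setNames(rep(0.1, length(electrodes)),
                                              electrodes),
                 min_spikes = 3L, protocol = protocol),
            class = "burst_train")
}

test_that("co-onset bursts on half the electrodes form network bursts", {
  p <- phase_protocol("all", 300)
  els <- sprintf("el%02d", 1:10)
  onsets <- seq(5, 195, by = 10)  # 20 events
  df <- do.call(rbind, lapply(onsets, function(o)
    data.frame(electrode = els[1:5],
               start = o + seq(0, 0.04, by = 0.01),
               end = o + seq(0, 0.04, by = 0.01) + 0.05,
               n_spikes = 5L, duration = 0.05)))
  bt <- mk_burst_train(df, p, els)
  nb <- detect_network_bursts(bt, active_set = els)
  expect_equal(nrow(nb), 20)
  expect_equal(nb$fraction, rep(0.5, 20))
  expect_equal(nb$n_electrodes, rep(5L, 20))
})

test_that("a single bursting electrode never reaches the synchrony bar", {
  p <- phase_protocol("all", 300)
  els <- sprintf("el%02d", 1:10)
  onsets <- seq(5, 195, by = 10)
  df <- data.frame(electrode = els[1], start = onsets, end = onsets + 0.05,
                   n_spikes = 5L, duration = 0.05)
  nb <- detect_network_bursts(mk_burst_train(df, p, els), active_set = els)
  expect_equal(nrow(nb), 0)
})

test_that("network bursts recover the generator's event times", {
  d <- generate_scenario(small_config(), short_protocol(), seed = 28)
  det <- detect_all_bursts(d$spikes)
  rates <- electrode_phase_rates(d$spikes, det)
  act <- active_electrodes(rates, "S1", "bursting")
  nb <- detect_network_bursts(det, act)
  ev <- d$ground_truth$event_times
  hit <- vapply(ev, function(e)
    any(nb$start >= e - 0.15 & nb$start <= e + 0.3), logical(1))
  expect_gte(mean(hit), 0.9)
})
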