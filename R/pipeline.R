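#' Analyse one culture's spike trains
#'
#' Runs burst detection, network-burst detection, and the per-phase metric
#' computation for a single culture.
#'
#' @param spikes A [spike_train_set()].
#' @param culture Culture identifier.
#' @param burst_params Named list of overrides for [detect_all_bursts()].
#' @param baseline Baseline phase label (default: first protocol phase).
#' @param mbd_denominator See [compute_phase_metrics()].
#' @param net_min_fraction Synchrony fraction for
#'   [detect_network_bursts()] (default 0.2).
#' @return List with `bursts`, `network_bursts`, `metrics` (raw
#'   `metrics_table`, `NULL` when the culture is unusable), `rates`,
#'   `timecourse`.
#' @export
analyze_culture <- function(spikes, culture = "c1", burst_params = list(),
                            baseline = NULL,
                            mbd_denominator = "s1",
                            net_min_fraction = 0.2) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (is.null(baseline)) baseline <- spikes$protocol$labels[1]
  bursts <- do.call(detect_all_bursts, c(list(spikes), burst_params))
  rates <- electrode_phase_rates(spikes, bursts)
  act_b <- active_electrodes(rates, baseline, "bursting")
  nb <- if (length(act_b))
    detect_network_bursts(bursts, act_b, net_min_fraction)
  else
    NULL
  metrics <- compute_phase_metrics(spikes, bursts, baseline = baseline,
                                   mbd_denominator = mbd_denominator,
                                   culture = culture)
  tc <- if (!is.null(metrics)) mbr_timecourse(spikes, bursts,
                                              baseline = baseline) else NULL
  list(bursts = bursts, network_bursts = nb, metrics = metrics,
       rates = rates, timecourse = tc)
}

#' Run the full multi-culture pipeline
#'
#' Applies [analyze_culture()] to each culture, stacks the per-culture
#' metric tables, normalizes them to the baseline phase, aggregates the
#' per-minute MBR time course, and runs the nonparametric phase statistics.
#' Cultures with no active electrodes are flagged and excluded.
#'
#' @param cultures Named list of [spike_train_set()] or `synthetic_dataset`
#'   objects.
#' @param ... Passed to [analyze_culture()].
#' @return List with `metrics_raw`, `metrics_normalized`
#'   (`metrics_table`s), `stats` (`stats_report`), `timecourse`
#'   (aggregated), `per_culture` (full per-culture results), `flagged`
#'   (character vector of unusable cultures).
#' @export
run_pipeline <- function(cultures, ...) {
  if (is.null(names(cultures)))
    names(cultures) <- sprintf("culture%02d", seq_along(cultures))
  per <- list()
  flagged <- character(0)
  for (cu in names(cultures)) {
    x <- cultures[[cu]]
    spikes <- if (inherits(x, "synthetic_dataset")) x$spikes else x
    res <- analyze_culture(spikes, culture = cu, ...)
    per[[cu]] <- res
    if (is.null(res$metrics)) flagged <- c(flagged, cu)
  }
  usable <- setdiff(names(cultures), flagged)
  if (length(usable) == 0) stop("no usable cultures")
  raw <- do.call(rbind, lapply(per[usable], `[[`, "metrics"))
  rownames(raw) <- NULL
  class(raw) <- c("metrics_table", "data.frame")
  attr(raw, "baseline") <- attr(per[[usable[1]]]$metrics, "baseline")
  attr(raw, "normalized") <- FALSE
  norm <- normalize_metrics(raw)
  tc <- aggregate_timecourse(lapply(per[usable], `[[`, "timecourse"))
  st <- if (length(usable) >= 2) phase_stats(norm) else NULL
  list(metrics_raw = raw, metrics_normalized = norm, stats = st,
       timecourse = tc, per_culture = per, flagged = flagged)
}

stats_report_to_df <- function(report) {
  rows <- list()
  for (m in names(report)) {
    pw <- report[[m]]$pairwise_p
    mc <- report[[m]]$median_change
    if (is.null(pw)) next
    ph <- rownames(pw)
    for (i in seq_along(ph)) for (j in seq_along(ph)) {
      if (j <= i) next
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, phase_a = ph[j], phase_b = ph[i],
        p_adj = pw[i, j],
        median_change_pct =
          if (!is.null(mc) && ph[j] %in% rownames(mc)) mc[ph[j], ph[i]]
          else NA_real_)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(metric = character(0), phase_a = character(0),
               phase_b = character(0), p_adj = numeric(0),
               median_change_pct = numeric(0))
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; see [run_analysis()] for the recognized keys.
#' @return A named list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' End-to-end analysis run
#'
#' Orchestrates simulate/ingest, burst detection, metrics, normalization,
#' time course, and statistics, persisting every stage output plus a
#' manifest so any stage can be audited independently. Identical
#' configuration and seed give byte-identical outputs.
#'
#' Recognized configuration keys (all optional unless noted):
#' * `protocol`: list with `labels` and `durations` (s);
#' * `input` (required): list with `type = "simulate"` (keys: `scenario` =
#'   arguments of [scenario_config()], `n_cultures`, `seed`) or
#'   `type = "spikes"` (key: `paths`, CSV files readable by
#'   [read_spike_trains()]);
#' * `burst`: overrides for [detect_all_bursts()];
#' * `metrics`: `baseline`, `mbd_denominator`;
#' * `stats`: `p_adjust_method`;
#' * `out_dir`: output directory (required unless `write = FALSE`).
#'
#' @param config Named list or path to a YAML file.
#' @param write Persist outputs to `config$out_dir` (default `TRUE`).
#' @return The [run_pipeline()] result, plus `manifest`, invisibly when
#'   writing.
#' @export
run_analysis <- function(config, write = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  protocol <- if (!is.null(config$protocol))
    phase_protocol(config$protocol$labels,
                   config$protocol$durations)
  else phase_protocol()
  input <- config$input
  if (is.null(input$type)) stop("config$input$type is required")
  cultures <- switch(
    input$type,
    simulate = {
      cfg <- do.call(scenario_config, input$scenario %||% list())
      simulate_cultures(cfg, protocol,
                        n_cultures = input$n_cultures %||% 1,
                        seed = input$seed %||% 1)
    },
    spikes = {
      paths <- input$paths
      if (is.null(paths)) stop("config$input$paths is required")
      sets <- lapply(paths, read_spike_trains, protocol = protocol)
      names(sets) <- sprintf("culture%02d", seq_along(sets))
      sets
    },
    stop("unknown input type: ", input$type))
  res <- run_pipeline(
    cultures,
    burst_params = config$burst %||% list(),
    baseline = config$metrics$baseline %||% NULL,
    mbd_denominator = config$metrics$mbd_denominator %||% "s1")
  if (!is.null(config$stats$p_adjust_method) && !is.null(res$stats))
    res$stats <- phase_stats(res$metrics_normalized,
                             p_adjust_method = config$stats$p_adjust_method)
  manifest <- list(
    package = "mearf",
    version = as.character(utils::packageVersion("mearf")),
    config = config,
    n_cultures = length(cultures),
    flagged = res$flagged)
  res$manifest <- manifest
  if (write) {
    out_dir <- config$out_dir
    if (is.null(out_dir)) stop("config$out_dir is required when write = TRUE")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(res$metrics_raw),
                     file.path(out_dir, "metrics_raw.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(as.data.frame(res$metrics_normalized),
                     file.path(out_dir, "metrics_normalized.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(res$timecourse,
                     file.path(out_dir, "mbr_timecourse.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(res$stats)) {
      jsonlite::write_json(
        list(pairs = stats_report_to_df(res$stats),
             omnibus = lapply(res$stats, function(m)
               list(H = m$H, p = m$p_omnibus, n = m$n_cultures))),
        file.path(out_dir, "stats.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(res)
}
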