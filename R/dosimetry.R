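#' Temperature transient container
#'
#' @param time Sample times, s, strictly increasing.
#' @param temperature Temperatures, degrees C.
#' @param t_on,t_off Exposure window, s (defaults: trace span).
#' @param baseline Baseline temperature, degrees C; default: mean of
#'   pre-exposure samples, or the first sample when none exist.
#' @return An object of class `temperature_trace`.
#' @export
temperature_trace <- function(time, temperature, t_on = NULL, t_off = NULL,
                              baseline = NULL) {
  time <- as.numeric(time); temperature <- as.numeric(temperature)
  if (length(time) != length(temperature))
    stop("time and temperature must have the same length")
  if (is.unsorted(time, strictly = TRUE))
    stop("time must be strictly increasing")
  if (is.null(t_on)) t_on <- time[1]
  if (is.null(t_off)) t_off <- time[length(time)]
  if (t_on < time[1] || t_off > time[length(time)] || t_off <= t_on)
    stop("exposure window must lie within the trace span")
  if (is.null(baseline)) {
    pre <- temperature[time < t_on]
    baseline <- if (length(pre)) mean(pre) else temperature[1]
  }
  structure(list(time = time, temperature = temperature,
                 t_on = t_on, t_off = t_off, baseline = baseline),
            class = "temperature_trace")
}

#' @export
print.temperature_trace <- function(x, ...) {
  cat("<temperature_trace> ", length(x$time), " samples, exposure [",
      x$t_on, ", ", x$t_off, "] s, baseline ",
      round(x$baseline, 3), " C\n", sep = "")
  invisible(x)
}

#' Read a temperature trace from CSV
#'
#' Two columns `time_s, temp_C`; optional leading comment lines of the form
#' `# key=value` carrying `t_on`, `t_off`, `baseline`.
#'
#' @param path CSV path.
#' @return A [temperature_trace()].
#' @export
read_temperature_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- regmatches(h, regexec("#\\s*([A-Za-z_]+)\\s*=\\s*([-0-9.eE+]+)", h))[[1]]
    if (length(kv) == 3) meta[[kv[2]]] <- as.numeric(kv[3])
  }
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  if (!all(c("time_s", "temp_C") %in% names(df)))
    stop("expected columns time_s, temp_C")
  temperature_trace(df$time_s, df$temp_C,
                    t_on = meta$t_on, t_off = meta$t_off,
                    baseline = meta$baseline)
}

#' Write a temperature trace to CSV
#' @param trace A [temperature_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_temperature_trace <- function(trace, path) {
  stopifnot(inherits(trace, "temperature_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# t_on=%g", trace$t_on), con)
  writeLines(sprintf("# t_off=%g", trace$t_off), con)
  writeLines(sprintf("# baseline=%g", trace$baseline), con)
  utils::write.csv(data.frame(time_s = trace$time,
                              temp_C = trace$temperature),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Initial slope of a heating transient
#'
#' Fits the single-compartment heating model
#' `dT(t) = A * (1 - exp(-(t - t_on)/tau))` by nonlinear least squares to
#' the post-onset segment of the trace (by default the first 5 min of
#' exposure, long enough to constrain tau while dominated by the initial
#' rise) and returns the model's initial slope `A / tau`, the quantity the
#' thermometric SAR estimate needs.
#'
#' @param trace A [temperature_trace()].
#' @param fit_window_s Length of the fitted segment after `t_on`, s
#'   (default 300; truncated to the available exposure).
#' @param linear_fallback If `TRUE`, fall back to a straight-line fit over
#'   the first 30 s when the exponential fit fails to converge.
#' @return List with `slope` (K/s), `A` (C), `tau` (s), `rms` (residual
#'   RMS, C), `method` (`"exponential"` or `"linear"`).
#' @export
fit_initial_slope <- function(trace, fit_window_s = 300,
                              linear_fallback = FALSE) {
  stopifnot(inherits(trace, "temperature_trace"))
  hi <- min(trace$t_on + fit_window_s, trace$t_off)
  sel <- trace$time >= trace$t_on & trace$time <= hi
  if (sum(sel) < 10) stop("need >= 10 samples after exposure onset")
  t <- trace$time[sel] - trace$t_on
  dT <- trace$temperature[sel] - trace$baseline
  if (max(dT) - min(dT) <= 0 || max(dT) <= 0)
    stop("no heating detected: trace does not rise above baseline")
  ## profiled least squares: for fixed tau the model is linear in A, so
  ## A_hat(tau) = <f, dT> / <f, f> with f = 1 - exp(-t/tau); the remaining
  ## 1-D problem in log(tau) is solved by golden-section search. This is
  ## deterministic and has no starting-value failure mode.
  span <- max(t[t > 0])
  rss_of <- function(ltau) {
    f <- 1 - exp(-t / exp(ltau))
    A <- sum(f * dT) / sum(f * f)
    sum((dT - A * f)^2)
  }
  opt <- stats::optimize(rss_of, c(log(span / 1e3), log(span * 10)))
  tau <- exp(opt$minimum)
  f <- 1 - exp(-t / tau)
  A <- sum(f * dT) / sum(f * f)
  if (!is.finite(A) || A <= 0) {
    if (!linear_fallback)
      stop("exponential fit degenerate: no rising transient")
    sel30 <- t <= 30
    lf <- stats::lm(dT[sel30] ~ t[sel30])
    return(list(slope = unname(stats::coef(lf)[2]), A = NA_real_,
                tau = NA_real_,
                rms = sqrt(mean(stats::residuals(lf)^2)),
                method = "linear"))
  }
  list(slope = A / tau, A = A, tau = tau,
       rms = sqrt(mean((dT - A * f)^2)),
       method = "exponential")
}

#' SAR from the initial temperature slope
#'
#' The thermometric estimate `SAR = C * dT/dt` at exposure onset, where C
#' is the specific heat capacity of the medium.
#'
#' @param slope Initial slope, K/s (e.g. from [fit_initial_slope()]).
#' @param C Specific heat capacity, J/(kg K) (default 4196.8).
#' @return SAR in W/kg.
#' @export
sar_from_slope <- function(slope, C = 4196.8) {
  if (C <= 0) stop("C must be positive")
  C * slope
}

#' Estimate SAR from a temperature trace
#'
#' Convenience wrapper: [fit_initial_slope()] then [sar_from_slope()].
#'
#' @param trace A [temperature_trace()].
#' @param C Specific heat capacity, J/(kg K) (default 4196.8).
#' @param ... Passed to [fit_initial_slope()].
#' @return List with `sar` (W/kg), `sar_3sf` (rounded to 3 significant
#'   figures), `C`, and the fit diagnostics of [fit_initial_slope()].
#' @export
estimate_sar <- function(trace, C = 4196.8, ...) {
  fit <- fit_initial_slope(trace, ...)
  sar <- sar_from_slope(fit$slope, C)
  c(list(sar = sar, sar_3sf = signif(sar, 3), C = C), fit)
}

#' Input power required for a target SAR
#'
#' Given the thermometric calibration (SAR per watt of incident power),
#' returns the incident power in dBm needed to reach a target SAR,
#' reported to 0.1 dBm.
#'
#' @param target_sar Target SAR, W/kg.
#' @param sar_per_watt Calibration, (W/kg)/W.
#' @return Power in dBm (rounded to 1 decimal).
#' @export
required_input_power_dbm <- function(target_sar, sar_per_watt) {
  if (target_sar <= 0 || sar_per_watt <= 0)
    stop("target_sar and sar_per_watt must be positive")
  p_w <- target_sar / sar_per_watt
  round(10 * log10(p_w * 1000), 1)
}

#' dBm to watts
#' @param dbm Power in dBm.
#' @return Power in W.
#' @export
dbm_to_watts <- function(dbm) 10^(dbm / 10) / 1000

#' Watts to dBm
#' @param watts Power in W.
#' @return Power in dBm.
#' @export
watts_to_dbm <- function(watts) {
  if (any(watts <= 0)) stop("watts must be positive")
  10 * log10(watts * 1000)
}

#' Simulate a first-order heating transient
#'
#' Single-compartment heat balance: during exposure the temperature rise is
#' `dT(t) = (SAR * tau / C) * (1 - exp(-t/tau))` (initial slope `SAR / C`,
#' steady state `SAR * tau / C`); after `t_off` the rise decays as a
#' symmetric exponential with the same time constant.
#'
#' @param sar SAR, W/kg.
#' @param tau Thermal time constant, s.
#' @param C Specific heat capacity, J/(kg K) (default 4196.8).
#' @param duration Exposure duration, s (default 900).
#' @param cooldown Post-exposure tail duration, s (default 0).
#' @param fs Sampling rate, Hz (default 1).
#' @param baseline Baseline temperature, degrees C (default 37).
#' @return A [temperature_trace()] with `t_on = 0`, `t_off = duration`.
#' @export
simulate_heating <- function(sar, tau, C = 4196.8, duration = 900,
                             cooldown = 0, fs = 1, baseline = 37) {
  if (tau <= 0 || C <= 0 || duration <= 0 || fs <= 0)
    stop("tau, C, duration, fs must be positive")
  t <- seq(0, duration + cooldown, by = 1 / fs)
  dT_end <- (sar * tau / C) * (1 - exp(-duration / tau))
  dT <- ifelse(t <= duration,
               (sar * tau / C) * (1 - exp(-t / tau)),
               dT_end * exp(-(t - duration) / tau))
  temperature_trace(t, baseline + dT, t_on = 0, t_off = duration,
                    baseline = baseline)
}

#' Temperature rise of the first-order model at a given time
#'
#' Closed form `dT(t) = (SAR * tau / C) * (1 - exp(-t/tau))`.
#'
#' @param t Time since exposure onset, s.
#' @param sar SAR, W/kg.
#' @param tau Thermal time constant, s.
#' @param C Specific heat capacity, J/(kg K) (default 4196.8).
#' @return Temperature rise in degrees C.
#' @export
heating_rise <- function(t, sar, tau, C = 4196.8) {
  (sar * tau / C) * (1 - exp(-t / tau))
}
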