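#' @name event_analysis
#' @title Blockage-event statistics for single-channel recordings
#'
#' @description
#' The single-molecule analysis chain: idealise a noisy current trace into
#' discrete blockage events by hysteresis thresholding, summarise them as an
#' event rate f_e (events per second of recording) and a dwell time tau_d
#' (mean residence in the pore, from a censored single-exponential fit), and
#' extrapolate the voltage dependence of either quantity to zero voltage by
#' ordinary least squares on the log scale — the concentration-driven
#' translocation rate a channel sustains with no applied field.
NULL

#' Event-detection configuration
#'
#' A blockage starts when the current crosses the threshold placed at
#' `threshold_fraction` of the open-to-blocked amplitude and ends when it
#' re-crosses toward the open level with a hysteresis band of
#' `hysteresis_fraction` of the amplitude, which prevents noise near the
#' threshold from splitting events.
#'
#' @param threshold_fraction fraction of the amplitude, in (0, 1);
#'   default 0.5.
#' @param min_dwell shortest accepted event, seconds; `NULL` (default) means
#'   three samples' worth at the trace's sampling rate.
#' @param open_level_estimate `"median"` (default) or `"mode"` of the samples.
#' @param hysteresis_fraction hysteresis band width as a fraction of the
#'   amplitude (default 0.1).
#' @param blocked_level blocked-state current, pA (default 0: complete
#'   closure).
#' @return an object of class `detection_config`.
#' @export
detection_config <- function(threshold_fraction = 0.5, min_dwell = NULL,
                             open_level_estimate = c("median", "mode"),
                             hysteresis_fraction = 0.1, blocked_level = 0) {
  .check_number(threshold_fraction, "threshold_fraction")
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("threshold_fraction must be in (0, 1)", call. = FALSE)
  }
  if (!is.null(min_dwell)) .check_number(min_dwell, "min_dwell", lower = 0)
  .check_number(hysteresis_fraction, "hysteresis_fraction", lower = 0)
  .check_number(blocked_level, "blocked_level")
  structure(list(threshold_fraction = threshold_fraction,
                 min_dwell = min_dwell,
                 open_level_estimate = match.arg(open_level_estimate),
                 hysteresis_fraction = hysteresis_fraction,
                 blocked_level = blocked_level),
            class = "detection_config")
}

.open_level <- function(samples, how) {
  if (how == "median") return(median(samples))
  d <- stats::density(samples, n = 512)
  d$x[which.max(d$y)]
}

#' Detect blockage events in a current trace
#'
#' Hysteresis thresholding (see [detection_config()]). Events shorter than
#' `min_dwell` are discarded, as are blockages in progress at either trace
#' boundary (a small O(tau/duration) censoring bias, documented rather than
#' corrected).
#'
#' @param trace a `current_trace` (from [simulate_trace()] or
#'   [read_trace_csv()]); at least 100 samples, with the open level at least
#'   four noise standard deviations from the blocked level.
#' @param config a [detection_config()].
#' @param V_mv,conc_uM optional recording metadata carried into the table.
#' @return an `event_table`: data frame with columns `onset_s`, `dwell_s`,
#'   `mean_blocked_pA`, with attributes `duration`, `V_mv`, `conc_uM`,
#'   `open_level`, `min_dwell`.
#' @export
detect_events <- function(trace, config = detection_config(),
                          V_mv = NA_real_, conc_uM = NA_real_) {
  stopifnot(inherits(trace, "current_trace"),
            inherits(config, "detection_config"))
  x <- trace$samples
  if (length(x) < 100L) stop("trace too short (< 100 samples)", call. = FALSE)
  fs <- trace$sampling_rate
  open <- .open_level(x, config$open_level_estimate)
  amp <- config$blocked_level - open
  if (amp == 0) stop("flat trace: open level equals blocked level",
                     call. = FALSE)
  dirn_pre <- sign(amp)
  # robust noise estimate from the open side of the midpoint
  open_side <- x[dirn_pre * (x - (open + 0.5 * amp)) < 0]
  noise_sd <- stats::mad(open_side, center = open)
  if (abs(amp) <= 4 * noise_sd) {
    stop("open and blocked levels not distinguishable (amplitude < 4 sd of noise)",
         call. = FALSE)
  }
  enter_thr <- open + config$threshold_fraction * amp
  exit_thr <- open + (config$threshold_fraction - config$hysteresis_fraction) * amp
  dirn <- sign(amp)
  # zones: 1 past the entry threshold (blocked side), 2 past the exit
  # threshold (open side), 0 inside the hysteresis band
  zone <- integer(length(x))
  zone[dirn * (x - enter_thr) > 0] <- 1L
  zone[dirn * (x - exit_thr) < 0] <- 2L
  r <- rle(zone)
  ends_cum <- cumsum(r$lengths)
  starts_run <- ends_cum - r$lengths + 1L
  ev_start <- integer(0); ev_end <- integer(0)
  state <- 0L # 0 open, 1 blocked
  cur <- NA_integer_
  for (k in seq_along(r$values)) {
    v <- r$values[k]
    if (state == 0L && v == 1L) {
      state <- 1L; cur <- starts_run[k]
    } else if (state == 1L && v == 2L) {
      ev_start <- c(ev_start, cur); ev_end <- c(ev_end, starts_run[k] - 1L)
      state <- 0L; cur <- NA_integer_
    }
  }
  # drop blockage in progress at t = 0 (trace starts below threshold)
  if (length(ev_start) && zone[1] == 1L && ev_start[1] == 1L) {
    ev_start <- ev_start[-1]; ev_end <- ev_end[-1]
  }
  min_dwell <- if (is.null(config$min_dwell)) 3 / fs else config$min_dwell
  if (length(ev_start)) {
    dwell <- (ev_end - ev_start + 1L) / fs
    keep <- dwell >= min_dwell
    ev_start <- ev_start[keep]; ev_end <- ev_end[keep]; dwell <- dwell[keep]
  } else {
    dwell <- numeric(0)
  }
  cs <- c(0, cumsum(x))
  mean_blocked <- if (length(ev_start)) {
    (cs[ev_end + 1L] - cs[ev_start]) / (ev_end - ev_start + 1L)
  } else numeric(0)
  out <- data.frame(onset_s = (ev_start - 1L) / fs, dwell_s = dwell,
                    mean_blocked_pA = mean_blocked)
  structure(out,
            duration = length(x) / fs, V_mv = V_mv, conc_uM = conc_uM,
            open_level = open, min_dwell = min_dwell, noise_sd = noise_sd,
            class = c("event_table", "data.frame"))
}

#' Event rate with exact Poisson confidence interval
#'
#' f_e = number of events per second of recording; the 95% interval uses the
#' exact Poisson (gamma-quantile) bounds, so it is valid down to zero events.
#'
#' @param table an `event_table` from [detect_events()] (or any data frame
#'   with a `duration` attribute).
#' @return list with `rate` (events/s), `ci_low`, `ci_high`, `n_events`,
#'   `duration`.
#' @export
event_rate <- function(table) {
  dur <- attr(table, "duration")
  if (is.null(dur) || !is.finite(dur) || dur <= 0) {
    stop("event table must carry a positive trace duration", call. = FALSE)
  }
  n <- nrow(table)
  list(rate = n / dur,
       ci_low = if (n == 0) 0 else qgamma(0.025, n) / dur,
       ci_high = qgamma(0.975, n + 1) / dur,
       n_events = n, duration = dur)
}

#' Censored single-exponential dwell-time fit
#'
#' Events are only observed above the detector's minimum dwell `t_min`, so
#' the dwell sample is left-truncated. For an exponential distribution the
#' memoryless property makes the maximum-likelihood estimate of the mean
#' simply `mean(dwell - t_min)` over the events with dwell >= t_min. The 95%
#' confidence interval is a nonparametric bootstrap (percentile method) at a
#' fixed seed.
#'
#' @param table an `event_table`, or a numeric vector of dwell times
#'   (seconds).
#' @param t_min left-censoring bound, seconds; defaults to the detector's
#'   `min_dwell` when `table` is an `event_table`, else 0.
#' @param n_boot bootstrap resamples (default 1000).
#' @param min_events smallest sample size accepted (default 50).
#' @param seed bootstrap RNG seed.
#' @return a `dwell_fit` list: `tau_d`, `ci_low`, `ci_high`, `n_events`,
#'   `t_min`.
#' @export
fit_dwell <- function(table, t_min = NULL, n_boot = 1000L, min_events = 50L,
                      seed = 1L) {
  if (is.data.frame(table)) {
    dwells <- table$dwell_s
    if (is.null(t_min)) t_min <- attr(table, "min_dwell")
  } else {
    dwells <- as.numeric(table)
  }
  if (is.null(t_min)) t_min <- 0
  dwells <- dwells[is.finite(dwells) & dwells >= t_min]
  n <- length(dwells)
  if (n < min_events) {
    stop(sprintf("too few events for a dwell fit (%d < %d)", n, min_events),
         call. = FALSE)
  }
  if (max(dwells) == min(dwells)) {
    stop("degenerate dwell sample: all dwells equal", call. = FALSE)
  }
  excess <- dwells - t_min
  tau <- mean(excess)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      mean(excess[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
  })
  ci <- quantile(boot, c(0.025, 0.975), names = FALSE)
  structure(list(tau_d = tau, ci_low = min(ci[1], tau),
                 ci_high = max(ci[2], tau), n_events = n, t_min = t_min),
            class = "dwell_fit")
}

#' Log-linear extrapolation of a voltage series to zero voltage
#'
#' Fits ordinary least squares of `log(value)` on `|V|` and reports the
#' slope (per mV) and the back-transformed intercept — the quantity's value
#' at zero applied voltage. Appropriate when rates depend exponentially on
#' voltage, as in the two-state gating model.
#'
#' @param points data frame with columns `V_mv` and `value` (all values
#'   positive, at least 3 points, all voltages of one sign or zero).
#' @param quantity `"event_rate"` or `"dwell_time"` (label only).
#' @return a `voltage_trend` list: `quantity`, `slope_per_mv` (of
#'   log(value) vs |V|), `intercept_at_zero`, `r_squared`, `n_points`.
#' @export
extrapolate_zero_voltage <- function(points,
                                     quantity = c("event_rate", "dwell_time")) {
  quantity <- match.arg(quantity)
  stopifnot(is.data.frame(points), all(c("V_mv", "value") %in% names(points)))
  if (nrow(points) < 3L) stop("need at least 3 voltage points", call. = FALSE)
  if (any(!is.finite(points$value) | points$value <= 0)) {
    stop("all values must be positive for the log-linear fit", call. = FALSE)
  }
  s <- sign(points$V_mv)
  if (any(s > 0) && any(s < 0)) {
    stop("voltages must share one sign (or be zero)", call. = FALSE)
  }
  fit <- lm(log(value) ~ absV, data = data.frame(absV = abs(points$V_mv),
                                                 value = points$value))
  y <- log(points$value)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(quantity = quantity,
                 slope_per_mv = unname(coef(fit)[2]),
                 intercept_at_zero = exp(unname(coef(fit)[1])),
                 r_squared = r2,
                 n_points = nrow(points)),
            class = "voltage_trend")
}

#' Full simulate-detect-fit-extrapolate recovery pipeline
#'
#' Runs a voltage series through the whole chain and recovers the gating
#' parameters. The entry rate fed to the extrapolation is
#' `n_events / total_open_time` — the maximum-likelihood entry rate under
#' the alternating-renewal model — because the raw event rate
#' f_e = n/duration is biased low by the fraction of time the channel spends
#' blocked. Both are reported per voltage.
#'
#' @inheritParams simulate_voltage_series
#' @param detection a [detection_config()].
#' @return list with `per_voltage` (data frame: V_mv, n_events, f_e,
#'   entry_rate, tau_d), `entry_trend` and `dwell_trend`
#'   ([extrapolate_zero_voltage()] results), and `recovered`
#'   (k_on0_C, alpha_on, tau0, alpha_off).
#' @export
recover_gating <- function(gating, config, conc_uM, voltages_mv,
                           detection = detection_config()) {
  sims <- simulate_voltage_series(gating, config, conc_uM, voltages_mv)
  rows <- lapply(sims, function(s) {
    tab <- detect_events(s$trace, detection, V_mv = s$V_mv,
                         conc_uM = s$conc_uM)
    er <- event_rate(tab)
    fit <- fit_dwell(tab)
    open_time <- attr(tab, "duration") - sum(tab$dwell_s)
    data.frame(V_mv = s$V_mv, n_events = er$n_events, f_e = er$rate,
               entry_rate = er$n_events / open_time, tau_d = fit$tau_d)
  })
  per_v <- do.call(rbind, rows)
  entry_trend <- extrapolate_zero_voltage(
    data.frame(V_mv = per_v$V_mv, value = per_v$entry_rate), "event_rate")
  dwell_trend <- extrapolate_zero_voltage(
    data.frame(V_mv = per_v$V_mv, value = per_v$tau_d), "dwell_time")
  list(per_voltage = per_v,
       entry_trend = entry_trend,
       dwell_trend = dwell_trend,
       recovered = list(k_on0_C = entry_trend$intercept_at_zero,
                        alpha_on = entry_trend$slope_per_mv,
                        tau0 = dwell_trend$intercept_at_zero,
                        alpha_off = -dwell_trend$slope_per_mv))
}
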