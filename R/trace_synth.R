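#' @name trace_synth
#' @title Synthetic single-channel recordings
#'
#' @description
#' Generates single-channel current traces as a two-state alternating-renewal
#' process: the channel is open until a peptide enters (rate
#' `k_on(V, C) = k_on0 * C * exp(alpha_on * |V|)` per second), stays fully
#' blocked for an exponentially distributed dwell with mean
#' `tau_d(V) = tau0 * exp(-alpha_off * |V|)`, and reopens. Exponential
#' voltage dependence makes log-linear extrapolation of rates to zero
#' voltage exact on synthetic data. Gaussian baseline noise is added per
#' sample and the trace is low-pass filtered with a Gaussian FIR kernel
#' emulating the recording chain's 2.5 kHz filter. Every simulation carries
#' a ground-truth event ledger, so detector attrition is measurable.
NULL

#' Voltage-dependent two-state gating model
#'
#' @param k_on0 entry events per second per micromolar at V = 0.
#' @param alpha_on voltage sensitivity of entry, per mV (>= 0).
#' @param tau0 mean blocked dwell at V = 0, seconds.
#' @param alpha_off voltage sensitivity of the dwell, per mV (>= 0).
#' @return an object of class `gating_model`.
#' @export
gating_model <- function(k_on0, alpha_on, tau0, alpha_off) {
  .check_number(k_on0, "k_on0", lower = 0, allow_zero = FALSE)
  .check_number(alpha_on, "alpha_on", lower = 0)
  .check_number(tau0, "tau0", lower = 0, allow_zero = FALSE)
  .check_number(alpha_off, "alpha_off", lower = 0)
  structure(list(k_on0 = k_on0, alpha_on = alpha_on,
                 tau0 = tau0, alpha_off = alpha_off),
            class = "gating_model")
}

#' @rdname gating_model
#' @param gating a `gating_model`.
#' @param V_mv membrane voltage, mV.
#' @param conc_uM peptide concentration, micromolar.
#' @return `k_on()`: entry rate in events/s; `tau_d()`: mean dwell in s.
#' @export
k_on <- function(gating, V_mv, conc_uM) {
  stopifnot(inherits(gating, "gating_model"))
  gating$k_on0 * conc_uM * exp(gating$alpha_on * abs(V_mv))
}

#' @rdname gating_model
#' @export
tau_d <- function(gating, V_mv) {
  stopifnot(inherits(gating, "gating_model"))
  gating$tau0 * exp(-gating$alpha_off * abs(V_mv))
}

#' Trace simulation configuration
#'
#' @param duration trace length, seconds.
#' @param i_open open-channel current, pA.
#' @param i_blocked blocked-level current, pA (default 0: complete closure).
#' @param noise_sd Gaussian baseline noise standard deviation, pA.
#' @param sampling_rate acquisition rate, Hz (default 50 kHz; must exceed
#'   twice the filter cutoff).
#' @param filter_cutoff -3 dB cutoff of the Gaussian low-pass filter, Hz
#'   (default 2500); `Inf` disables filtering.
#' @param seed integer RNG seed.
#' @return an object of class `trace_config`.
#' @export
trace_config <- function(duration, i_open, i_blocked = 0, noise_sd = 0,
                         sampling_rate = 50000, filter_cutoff = 2500,
                         seed = 1L) {
  .check_number(duration, "duration", lower = 0, allow_zero = FALSE)
  .check_number(i_open, "i_open")
  .check_number(i_blocked, "i_blocked")
  if (i_open == i_blocked) stop("i_open must differ from i_blocked",
                                call. = FALSE)
  .check_number(noise_sd, "noise_sd", lower = 0)
  .check_number(sampling_rate, "sampling_rate", lower = 0, allow_zero = FALSE)
  if (!(is.numeric(filter_cutoff) && length(filter_cutoff) == 1L &&
        (is.infinite(filter_cutoff) || filter_cutoff > 0))) {
    stop("`filter_cutoff` must be a positive number or Inf", call. = FALSE)
  }
  if (is.finite(filter_cutoff) && sampling_rate <= 2 * filter_cutoff) {
    stop("sampling_rate must exceed twice the filter cutoff", call. = FALSE)
  }
  structure(list(duration = duration, i_open = i_open, i_blocked = i_blocked,
                 noise_sd = noise_sd, sampling_rate = sampling_rate,
                 filter_cutoff = filter_cutoff, seed = as.integer(seed)),
            class = "trace_config")
}

# Gaussian FIR kernel with -3 dB point at `cutoff` Hz:
# |H(f)| = exp(-2 pi^2 sigma^2 f^2) = 2^{-1/2} at f = cutoff
# => sigma = sqrt(ln 2) / (2 pi cutoff) seconds.
.gaussian_kernel <- function(sampling_rate, cutoff) {
  sigma <- sqrt(log(2)) / (2 * pi * cutoff) * sampling_rate # in samples
  half <- max(1L, ceiling(4 * sigma))
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Low-pass filter a sample vector with a Gaussian FIR kernel
#'
#' Edge samples are handled by replicate-padding so the filtered trace has
#' the same length and no edge transient toward zero.
#'
#' @param samples numeric vector.
#' @param sampling_rate Hz.
#' @param cutoff -3 dB cutoff, Hz; `Inf` returns the input unchanged.
#' @return filtered vector of the same length.
#' @export
lowpass_gaussian <- function(samples, sampling_rate, cutoff) {
  if (is.infinite(cutoff)) return(samples)
  k <- .gaussian_kernel(sampling_rate, cutoff)
  half <- (length(k) - 1L) / 2L
  padded <- c(rep(samples[1L], half), samples,
              rep(samples[length(samples)], half))
  out <- stats::filter(padded, k, method = "convolution", sides = 2)
  as.numeric(out[(half + 1L):(half + length(samples))])
}

# Draw alternating open/blocked sojourns covering `duration` seconds,
# starting open. Returns data.frame(onset, dwell) of blockages (ground
# truth), dwells truncated at the trace end.
.draw_gating_sequence <- function(rate_on, mean_dwell, duration) {
  onsets <- numeric(0); dwells <- numeric(0)
  t <- 0
  if (rate_on <= 0) return(data.frame(onset = onsets, dwell = dwells))
  repeat {
    n <- max(16L, ceiling(1.5 * (duration - t) /
                            (1 / rate_on + mean_dwell)))
    open <- rexp(n, rate = rate_on)
    blocked <- rexp(n, rate = 1 / mean_dwell)
    for (i in seq_len(n)) {
      t <- t + open[i]
      if (t >= duration) return(data.frame(onset = onsets, dwell = dwells))
      d <- min(blocked[i], duration - t)
      onsets <- c(onsets, t); dwells <- c(dwells, d)
      t <- t + blocked[i]
      if (t >= duration) return(data.frame(onset = onsets, dwell = dwells))
    }
  }
}

#' Simulate a single-channel current trace with ground truth
#'
#' Open sojourns are drawn i.i.d. Exp(rate = k_on(V, C)) and blocked dwells
#' i.i.d. Exp(rate = 1/tau_d(V)); the ideal two-level trace at
#' `i_open`/`i_blocked` receives per-sample Gaussian noise and is low-pass
#' filtered. Identical inputs and seed give bit-identical output; the
#' caller's RNG state is left untouched.
#'
#' @param gating a [gating_model()].
#' @param config a [trace_config()].
#' @param conc_uM peptide concentration on the entry side, micromolar
#'   (0 gives an event-free trace).
#' @param V_mv applied membrane voltage, mV.
#' @return a list of class `sim_trace` with elements `trace` (class
#'   `current_trace`: `sampling_rate`, `samples`) and `ledger` (data frame
#'   `onset`, `dwell` of ground-truth blockages, seconds; the final dwell is
#'   truncated at the trace end if the blockage is still in progress).
#' @export
simulate_trace <- function(gating, config, conc_uM, V_mv) {
  stopifnot(inherits(gating, "gating_model"), inherits(config, "trace_config"))
  .check_number(conc_uM, "conc_uM", lower = 0)
  .check_number(V_mv, "V_mv")
  rate <- k_on(gating, V_mv, conc_uM)
  dwell_mean <- tau_d(gating, V_mv)
  fs <- config$sampling_rate
  n_samples <- round(config$duration * fs)

  with_seed(config$seed, {
    ledger <- .draw_gating_sequence(rate, dwell_mean, config$duration)
    # piecewise-constant ideal trace: sample i covers [(i-1)/fs, i/fs)
    samples <- rep(config$i_open, n_samples)
    if (nrow(ledger)) {
      a <- pmin(n_samples, floor(ledger$onset * fs) + 1L)
      b <- pmin(n_samples, floor((ledger$onset + ledger$dwell) * fs))
      for (i in seq_len(nrow(ledger))) {
        if (b[i] >= a[i]) samples[a[i]:b[i]] <- config$i_blocked
      }
    }
    if (config$noise_sd > 0) {
      samples <- samples + rnorm(n_samples, sd = config$noise_sd)
    }
    samples <- lowpass_gaussian(samples, fs, config$filter_cutoff)
    structure(list(
      trace = structure(list(sampling_rate = fs, samples = samples,
                             duration = config$duration,
                             i_open = config$i_open,
                             i_blocked = config$i_blocked),
                        class = "current_trace"),
      ledger = ledger,
      V_mv = V_mv, conc_uM = conc_uM),
      class = "sim_trace")
  })
}

#' Simulate one trace per voltage with derived seeds
#'
#' Runs [simulate_trace()] independently at each voltage, with the per-voltage
#' seed `config$seed + index - 1` so the series is reproducible as a whole.
#'
#' @inheritParams simulate_trace
#' @param voltages_mv nonempty numeric vector of membrane voltages, mV.
#' @return a list of `sim_trace` objects, one per voltage, in input order.
#' @export
simulate_voltage_series <- function(gating, config, conc_uM, voltages_mv) {
  if (!length(voltages_mv)) stop("empty voltage list", call. = FALSE)
  lapply(seq_along(voltages_mv), function(i) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    simulate_trace(gating, cfg_i, conc_uM, voltages_mv[i])
  })
}

#' Write / read a current trace as CSV (time_s, current_pA)
#'
#' @param trace a `current_trace`.
#' @param path CSV path.
#' @return `read_trace_csv()` returns a `current_trace` (sampling rate
#'   recovered from the time column).
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  n <- length(trace$samples)
  write.csv(data.frame(time_s = (seq_len(n) - 1) / trace$sampling_rate,
                       current_pA = trace$samples),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("trace file not found: %s", path),
                               call. = FALSE)
  d <- read.csv(path)
  stopifnot(all(c("time_s", "current_pA") %in% names(d)), nrow(d) >= 2)
  fs <- 1 / median(diff(d$time_s))
  structure(list(sampling_rate = fs, samples = d$current_pA,
                 duration = nrow(d) / fs),
            class = "current_trace")
}

#' Write an event ledger as TSV (onset_s, dwell_s)
#'
#' @param ledger data frame with columns `onset`, `dwell` (seconds).
#' @param path TSV path.
#' @export
write_ledger_tsv <- function(ledger, path) {
  stopifnot(all(c("onset", "dwell") %in% names(ledger)))
  write.table(data.frame(onset_s = ledger$onset, dwell_s = ledger$dwell),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
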