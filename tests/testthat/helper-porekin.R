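# shared fixtures and small oracles

# closed-form Nernst potential, mV, trans-minus-cis convention
nernst_mv <- function(z, c_cis, c_trans, temperature_K = 298.15) {
  1000 * 8.31446262 * temperature_K / (z * 96485.33212) * log(c_cis / c_trans)
}

ptm_fixture <- function() {
  read_fasta(system.file("extdata", "protamine.fasta", package = "porekin"))[[1]]
}

# fast noiseless, unfiltered trace settings for exactness tests
noiseless_config <- function(duration, seed = 1L, sampling_rate = 10000) {
  trace_config(duration = duration, i_open = 50, i_blocked = 0,
               noise_sd = 0, sampling_rate = sampling_rate,
               filter_cutoff = Inf, seed = seed)
}

# wrap a plain dwell set as an event table (ground-truth ledger route)
ledger_as_table <- function(ledger, duration, min_dwell = 0) {
  structure(data.frame(onset_s = ledger$onset, dwell_s = ledger$dwell,
                       mean_blocked_pA = rep(0, length(ledger$onset))),
            duration = duration, min_dwell = min_dwell,
            class = c("event_table", "data.frame"))
}

write_temp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}
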