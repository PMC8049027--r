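#!/usr/bin/env Rscript
# Liposome tandem-assay kinetics: concentration independence and flux
# estimation.
#
# Simulates dye-displacement fluorescence curves for a liposome carrying
# one channel in the exit-limited transport regime at three outside
# peptide concentrations, measures the initial rates, and inverts the
# largest-concentration rate into molecules per second per channel. In
# this regime the initial rate barely changes over a 10-fold concentration
# range - the signature that escape from the pore, not entry, limits the
# flux.

suppressMessages(library(porekin))
dir.create("results", showWarnings = FALSE)

assay <- assay_config() # 700 uM CX4, 500 uM LCG, 100 nm liposome, 1 channel
transport <- transport_model(k_entry = 1000, k_exit = 2)

concs_uM <- c(0.1, 0.5, 1.0)
grid <- seq(0, 30, by = 0.002)
curves <- lapply(concs_uM, function(c_uM) {
  simulate_influx(assay, transport, c_uM * 1e-6, grid)
})

long <- do.call(rbind, Map(function(cur, c_uM) {
  keep <- seq(1, nrow(cur), by = 50) # thin to 0.1 s for the output table
  data.frame(conc_uM = c_uM, time_s = cur$time_s[keep],
             f_rel = cur$f_rel[keep])
}, curves, concs_uM))
write.csv(long, "results/assay_curves.csv", row.names = FALSE)

rates <- vapply(curves, initial_rate, numeric(1), window = 0.1)
spread <- (max(rates) - min(rates)) / min(rates)
flux <- flux_per_channel(rates[length(rates)], assay)

cat("initial fluorescence rates (f_rel per s):\n")
print(data.frame(conc_uM = concs_uM, rate_per_s = signif(rates, 4)),
      row.names = FALSE)
cat(sprintf("spread across a 10-fold concentration range: %.1f%%\n",
            100 * spread))
cat(sprintf("estimated flux per channel at 1 uM: %.2f molecules/s (simulator exit rate %.1f)\n",
            flux, transport$k_exit))

jsonlite::write_json(
  list(conc_uM = concs_uM, initial_rates_per_s = rates,
       rate_spread_fraction = spread,
       flux_per_channel_molecules_s = flux,
       true_k_exit = transport$k_exit),
  "results/assay_summary.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/assay_curves.csv, results/assay_summary.json\n")
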