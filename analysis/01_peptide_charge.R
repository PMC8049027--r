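#!/usr/bin/env Rscript
# Charge bookkeeping for the translocating peptide.
#
# The reversal-potential analysis rests on three numbers read off the
# protamine sequence: its length, its arginine count (every arginine
# contributes +1 e, there are no acidic residues), and the number of
# divalent sulfate counterions that neutralise it. This script computes
# them from the packaged FASTA and writes the report.

suppressMessages(library(porekin))
dir.create("results", showWarnings = FALSE)

ptm <- read_fasta(porekin_fixture("protamine.fasta"))[[1]]
rep <- peptide_report(ptm, charge_model())

cat(sprintf("peptide %s: %d residues, %d arginines\n",
            rep$name, rep$length, rep$arg_count))
cat(sprintf("effective net charge: %+d e (side-chain model, termini ignored)\n",
            rep$net_charge_e))
cat(sprintf("sulfate counterions (z = -2): %d\n", rep$counterion_count))
cat(sprintf("free-base mass: %.1f Da (the salt form weighs more)\n",
            peptide_mass(ptm)))

jsonlite::write_json(c(rep, list(free_base_mass_Da = peptide_mass(ptm))),
                     "results/peptide_report.json",
                     auto_unbox = TRUE, digits = NA)
cat("wrote results/peptide_report.json\n")
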