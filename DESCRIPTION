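Package: porekin
Title: Transport Kinetics of Polycationic Peptides Through Wide Nanopore Channels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for quantifying passive translocation of
    polycationic peptides (protamine) through the CymA-family nanopore:
    multivalent Goldman-Hodgkin-Katz reversal-potential analysis and
    permeability-ratio inference, synthetic single-channel gating traces
    with blockage-event detection, censored-exponential dwell-time fitting
    and zero-voltage extrapolation, and a liposome indicator-displacement
    (tandem) assay model converting fluorescence influx kinetics into
    per-channel molecular fluxes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
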