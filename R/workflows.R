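#' @name workflows
#' @title End-to-end analysis workflows
#'
#' @description
#' Two composed pipelines: the reversal-potential worked example on the
#' packaged protamine fixtures, and the synthetic parameter-recovery suites
#' (single-channel electrophysiology and liposome assay) that validate the
#' whole analysis chain on data with known ground truth.
NULL

#' Path to a packaged fixture
#'
#' @param file fixture filename under `extdata` (default lists them).
#' @return full path.
#' @export
porekin_fixture <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "porekin"),
                      full.names = TRUE))
  }
  p <- system.file("extdata", file, package = "porekin")
  if (p == "") stop(sprintf("fixture not found: %s", file), call. = FALSE)
  p
}

#' Reversal-potential worked example on the packaged fixtures
#'
#' End to end: peptide charge quantities from the packaged protamine FASTA;
#' inference of the sulfate permeability (peptide tied to potassium) from
#' the measured reversal potential under the packaged ionic conditions; and
#' the forward check — the reversal potential computed with the inferred
#' ratios set.
#'
#' @param v_rev_mv measured reversal potential, mV (default -20, trans minus
#'   cis).
#' @param sulfate_per_peptide mobile sulfates per peptide (default 11; see
#'   [ptm_reversal_conditions()]).
#' @param out optional path to write the report as JSON.
#' @return a list: `peptide` ([peptide_report()]), `conditions` (the species
#'   table), `inference` (`P_SO4_over_P_K`, tie, conventions), `forward`
#'   (`V_rev_mv` recomputed with the inferred ratios).
#' @export
run_worked_example <- function(v_rev_mv = -20,
                               sulfate_per_peptide = 11,
                               out = NULL) {
  ptm <- read_fasta(porekin_fixture("protamine.fasta"))[[1]]
  pep <- peptide_report(ptm, charge_model())
  sys0 <- ptm_reversal_conditions(sulfate_per_peptide = sulfate_per_peptide,
                                  ptm_charge = pep$net_charge_e)
  inferred <- infer_permeability(sys0, v_rev_mv, tie = c(Ptm = "K"))
  p_so4 <- attr(inferred, "inferred_P") /
    inferred$species$P[inferred$species$name == "K"]
  # forward check at the printed permeability ratio 1:1:48, and the
  # self-consistency round trip at the inferred ratio
  printed <- ptm_reversal_conditions(sulfate_per_peptide = sulfate_per_peptide,
                                     ptm_charge = pep$net_charge_e,
                                     P_Ptm = 1, P_SO4 = 48)
  report <- list(
    peptide = pep,
    conditions = inferred$species,
    temperature_K = inferred$temperature_K,
    voltage_convention = inferred$voltage_convention,
    inference = list(v_rev_measured_mv = v_rev_mv,
                     tie = "P_Ptm = P_K",
                     P_SO4_over_P_K = p_so4),
    forward = list(ratios = "K:Ptm:SO4 = 1:1:48",
                   V_rev_mv = reversal_potential(printed),
                   V_rev_at_inferred_mv = reversal_potential(inferred)))
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA)
  }
  report
}

#' Synthetic parameter-recovery suites
#'
#' Runs the two round-trip validations at fixed seeds and reports recovered
#' against true parameters: (1) electrophysiology — simulate a voltage
#' series, detect events, fit dwells, extrapolate to zero voltage
#' ([recover_gating()]); (2) assay — simulate exit-limited influx, measure
#' the initial rate, invert to a per-channel flux ([flux_per_channel()]).
#' Identical seeds give identical reports.
#'
#' @param seed integer seed for the trace simulations.
#' @param duration_s per-voltage trace length, seconds (default 100).
#' @param sampling_rate acquisition rate, Hz.
#' @param out optional path to write the report as JSON.
#' @return a list with components `electrophysiology` (true, recovered,
#'   per-voltage table) and `assay` (true k_exit, recovered flux).
#' @export
run_recovery_suite <- function(seed = 1L, duration_s = 100,
                               sampling_rate = 25000, out = NULL) {
  gating <- gating_model(k_on0 = 1.0, alpha_on = 0.03,
                         tau0 = 0.1, alpha_off = 0.02)
  cfg <- trace_config(duration = duration_s, i_open = 50, i_blocked = 0,
                      noise_sd = 2.5, sampling_rate = sampling_rate,
                      filter_cutoff = 2500, seed = seed)
  rec <- recover_gating(gating, cfg, conc_uM = 1,
                        voltages_mv = c(-20, -40, -60, -80, -100))
  # exit-limited regime; the rate window must sit before internal free
  # peptide builds enough to drive efflux, hence the dense early grid
  assay <- assay_config()
  transport <- transport_model(k_entry = 1000, k_exit = 2)
  curve <- simulate_influx(assay, transport, c_out = 1e-6,
                           t_grid = seq(0, 2, by = 0.002))
  flux <- flux_per_channel(initial_rate(curve, window = 0.1), assay)
  report <- list(
    electrophysiology = list(
      true = list(k_on0_C = 1.0, alpha_on = 0.03, tau0 = 0.1,
                  alpha_off = 0.02),
      recovered = rec$recovered,
      per_voltage = rec$per_voltage),
    assay = list(true_k_exit = transport$k_exit,
                 recovered_flux_per_channel = flux))
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA)
  }
  report
}
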