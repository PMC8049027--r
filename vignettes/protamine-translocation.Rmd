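---
title: "Quantifying peptide translocation through a wide nanopore: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying peptide translocation through a wide nanopore: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porekin)
```

porekin quantifies passive translocation of a polycationic peptide
(protamine, a 32-residue, +21 e arginine-rich polycation) through a wide
membrane channel — the cyclodextrin-uptake porin CymA of *Klebsiella
oxytoca*, whose N-terminally truncated mutant forms a quiet ~15 Å pore —
by three mutually supporting routes: reversal-potential electrodiffusion
analysis, single-channel blockage statistics, and liposome
dye-displacement influx kinetics. This vignette explains each model, its
assumptions, the tunable parameters, and the numerical choices; the
companion scripts under `analysis/` run each stage and write its tables.

## Peptide charge model

The electrodiffusion analysis treats the peptide as a point charge. The
default `charge_model()` counts +1 per arginine or lysine side chain and
−1 per aspartate or glutamate, and ignores the termini (their +1/−1
cancel for a free peptide) and histidine. For protamine this gives +21 e,
equal to its arginine count — exactly the effective charge the analysis
assumes. Counterion stoichiometry is plain charge covering:
`ceiling(21/2) = 11` divalent sulfates. pH-dependent (pKa-based) charges
are deliberately out of scope: the experiments run near neutral pH where
the side-chain model is adequate, and the analysis needs an integer
effective valence, not a titration curve.

```{r peptide}
ptm <- read_fasta(porekin_fixture("protamine.fasta"))[[1]]
unlist(peptide_report(ptm))
```

The packaged sequence is salmine A1 protamine; its identity is validated
by the three counts above (32 residues, 21 Arg, +21 e). The free-base
mass computed from the sequence (~4.25 kDa) is below the ~5 kDa often
quoted for the peptide, which refers to the sulfate salt; mass is
therefore a convenience output, never an anchor of the analysis.

## Electrodiffusion: the GHK model and its conventions

Each permeant species contributes the constant-field (GHK) charge flux

$$\Phi_i = P_i z_i^2 u\,
  \frac{c_{cis,i} - c_{trans,i}\,e^{z_i u}}{e^{z_i u} - 1},
  \qquad u = \frac{F V_m}{RT},$$

in relative units, with the membrane voltage in the
$V_m = V_{trans} - V_{cis}$ convention (cis grounded, as in the
recordings) and positive flux meaning positive charge moving cis to
trans. Three properties anchor the implementation and are asserted in the
tests: the $V\to 0$ limit is the Fick flux $P_i z_i (c_{cis}-c_{trans})$;
a single species reverses exactly at its Nernst potential
$(RT/z_iF)\ln(c_{cis}/c_{trans})$ (so a ten-fold cation gradient on cis
reverses at +59.16 mV in this convention); and the total flux is strictly
decreasing in $V$, so the reversal potential is the unique root, found by
bracketed root-finding on ±300 mV to $10^{-10}$ mV. The flux is evaluated
by a series expansion for $|z_i u| < 10^{-6}$ and in an overflow-safe
rearrangement for $z_i u > 30$ (relevant for the +21 peptide, where
$|z u|$ reaches ~240 at the bracket edge).

Because $\Phi_i$ is linear in $P_i$, inferring one unknown permeability
from a measured reversal potential is an exact linear solve, not an
optimisation. One measured voltage cannot determine two ratios, so the
peptide permeability is tied to potassium (`tie = c(Ptm = "K")`) — the
same assumption under which the published ratio K⁺:Ptm²¹⁺:SO₄²⁻ of
1:1:48 was derived. The ionic bookkeeping of the packaged conditions: a
0.1 mM K₂SO₄ background contributes 0.2 mM K⁺ and 0.1 mM SO₄²⁻ per side;
0.25 mM protamine sulfate on cis adds 0.25 mM peptide and, by default,
11 × 0.25 mM mobile sulfate. The alternative exact-charge-balance
bookkeeping (10.5 sulfates per peptide) is available through
`ptm_reversal_conditions(sulfate_per_peptide = 10.5)`; both land within a
few percent of each other.

```{r ghk}
inferred <- infer_permeability(ptm_reversal_conditions(), -20,
                               tie = c(Ptm = "K"))
attr(inferred, "inferred_P")                   # P_SO4 / P_K
reversal_potential(ptm_reversal_conditions(P_Ptm = 1, P_SO4 = 48))
```

The pair (−20 mV, ratio 48) is only approximately self-consistent under
this model: the inference at exactly −20 mV returns ≈ 43.5, and the
forward solve at ratio 48 returns ≈ −20.9 mV. Both sit comfortably inside
the measurement's own precision ("about −20 mV"), and the package reports
them as computed rather than forcing agreement.

Zero-voltage molar fluxes are reported as the relative Fick fluxes
$P_i\,\Delta c_i$; converting them to absolute molecules per second
requires a calibration scale the reversal-potential measurement does not
provide, so `zero_voltage_flux()` only applies a caller-supplied scale.
Notably, the relative $P\,\Delta c$ ratio of sulfate to peptide is 528:1
under the default bookkeeping — the model does not reproduce a simple
small integer ratio of absolute fluxes, and no such number is claimed.

## Synthetic single-channel traces

No raw recordings accompany the published analysis, so the single-channel
chain is validated on synthetic data with known ground truth. The
generative model is the minimal one consistent with discrete,
complete-closure blockages and single-exponential dwell fits: a two-state
alternating renewal process. Open sojourns are exponential with entry
rate $k_{on}(V, C) = k_{on,0}\, C\, e^{\alpha_{on}|V|}$ (per second;
$C$ in µM) and blocked dwells exponential with mean
$\tau_d(V) = \tau_0\, e^{-\alpha_{off}|V|}$. The exponential voltage
dependence matches the observed trend — stronger voltages pull more
peptides in and push them through faster — and makes log-linear
extrapolation to zero voltage exact on synthetic data, so extrapolation
bias is measurable. Sub-states, flicker and 1/f noise are out of scope.

The ideal two-level trace (open current `i_open`, blocked 0 pA by
default) receives per-sample Gaussian noise and a Gaussian FIR low-pass
filter whose −3 dB cutoff defaults to 2.5 kHz, the filter setting of the
recordings; the default acquisition rate is 50 kHz (the true acquisition
rate is not published; it only needs to comfortably oversample the
filter). The Gaussian kernel stands in for the recording chain's 4-pole
Bessel filter — both are monotone-step, near-linear-phase low-pass
responses, and the kernel's σ is set from the cutoff as
$\sigma = \sqrt{\ln 2}/(2\pi f_c)$. Ground-truth events shorter than the
filter rise time stay in the ledger: detector attrition is a property to
measure, not to hide.

## Event detection and dwell statistics

Detection is hysteresis thresholding: an event opens when the current
crosses 50% of the open-to-blocked amplitude and closes on re-crossing a
band 10% of the amplitude nearer the open level, which prevents noise
near threshold from splitting events. Both fractions are configurable;
50% is robust here because the blockages are complete closures. Events
shorter than `min_dwell` (default: three samples) are discarded, as are
blockages in progress at either trace boundary — a censoring bias of
order $\tau_d/\mathrm{duration}$, documented rather than corrected. On
noiseless traces the detector reproduces the ground-truth ledger exactly
(onsets within one sample); with 5% noise and the 2.5 kHz filter it
recovers ≥ 99% of millisecond events with no false positives.

The dwell fit exploits memorylessness: for exponential dwells observed
above a known bound $t_{min}$, the maximum-likelihood mean is simply
$\widehat{\tau}_d = \overline{(d - t_{min})}$ over events with
$d \ge t_{min}$; its 95% interval is a fixed-seed nonparametric bootstrap
(1000 resamples). Event rates carry exact Poisson (gamma-quantile)
intervals, valid at zero events.

Two event-rate conventions coexist deliberately. The reported event rate
$f_e$ is events per second of recording, the quantity a voltage-ramp
figure displays. For recovering $k_{on}$, however, $f_e$ is biased low by
the fraction of time the channel is blocked (about 20% at −100 mV under
the validation conditions), so the extrapolation uses the renewal-model
MLE `n_events / total_open_time`. Both appear in the per-voltage table.

The validation suite simulates five voltages (−20 … −100 mV), 200 s each,
at gating $(k_{on,0}, \alpha_{on}, \tau_0, \alpha_{off}) =
(1.0\ \mathrm{s^{-1}\mu M^{-1}}, 0.03\ \mathrm{mV^{-1}}, 0.1\ \mathrm{s},
0.02\ \mathrm{mV^{-1}})$ and 1 µM peptide — chosen so the zero-voltage
entry rate sits at the ~1–2 events/s scale the experiments extrapolate
to, with 300–3000 events per voltage, comparable to the ≥ 1000 analysed
per voltage experimentally. The full pipeline recovers the rate and
dwell intercepts within 15% and both voltage sensitivities within 20%;
shorter 100 s recordings are used in the interactive recovery suite,
where the same bounds hold.

## Liposome tandem assay

The assay encapsulates a calixarene receptor (CX4, 700 µM) and the dye
lucigenin (LCG, 500 µM) in ~100 nm liposomes; CX4 quenches bound LCG, and
peptide entering through the channel displaces the dye, turning
fluorescence on. The model has three layers:

1. **Competitive equilibrium.** 1:1 binding of CX4 with each of LCG and
   peptide, solved from conservation and mass action by monotone
   root-finding in the free receptor concentration plus Newton polishing;
   totals are conserved to better than $10^{-12}$ relative (asserted on
   1000 random systems). The association constants are not published with
   the experiments; the package defaults ($K_{CL} = 10^5$,
   $K_{CP} = 10^7$ L/mol) make displacement strongly favourable, and all
   validation of this module is by round trip and invariant, never
   against printed fluorescence values.
2. **Transport.** A saturable per-channel flux
   $j(C) = k_{exit} k_{entry} C/(k_{entry} C + k_{exit})$: entry is
   concentration-dependent, escape into the lumen is not. When
   $k_{entry} C \gg k_{exit}$ the influx is exit-limited and the initial
   rate becomes independent of the outside concentration — the
   experiments' key qualitative observation, reproduced within 2% over
   0.1–1 µM by the defaults used in the validation
   ($k_{entry} = 1000\ \mathrm{s^{-1}\mu M^{-1}}$,
   $k_{exit} = 2\ \mathrm{s^{-1}}$, spanning the 1–3 molecules/s scale).
   Efflux uses the same law at the free internal concentration — the
   channel is symmetric, consistent with permeation being observed from
   both sides with similar efficiency.
3. **Integration.** The ODE state is the *total* internal peptide
   (free + receptor-bound): $dP_{tot}/dt = n_{ch}[j(c_{out}) -
   j(P_{free})]/(N_A V_{lip})$ with $V_{lip} = (\pi/6)d^3$, integrated
   with `deSolve::lsoda` at relative tolerance $10^{-8}$; the free
   concentration comes from the equilibrium at every step. The
   encapsulated receptor buffers the incoming peptide, producing the
   rapid initial rise and slow approach to plateau.

One numerical consequence of the exit-limited defaults deserves emphasis:
because the efflux path also saturates at sub-micromolar free
concentrations, the net influx starts decaying on a ~0.4 s timescale.
Initial rates are therefore measured on a dense early grid (2 ms steps)
over a 0.1 s window following the lag threshold (baseline + 3 SD of the
pre-addition segment). With that window the chain-rule identity — initial
slope = influx rate × binding-curve derivative — holds within 5%, and
the inverse estimator `flux_per_channel()` recovers the simulator's
$k_{exit}$ within 15%.

The inverse estimator divides the fluorescence rate by the binding-curve
derivative at the quenched baseline (central difference), then scales by
$N_A V_{lip}/n_{ch}$. Liposome diameter (100 nm) and channel count (1)
are configuration, not measurements: in the real assay they enter through
a population average the published analysis derives in material not
reproduced here, so the estimator is validated by round-trip recovery
only.

## What the synthetic data do and do not show

The generators emulate: exponential open/blocked gating with
voltage-dependent rates, complete closures, Gaussian noise, the 2.5 kHz
filter; and for the assay, lag–rise–plateau curves with
concentration-independent initial rates. They do not emulate: wild-type
loop flicker, multi-channel membranes, liposome size polydispersity,
photophysics, baseline drift, or non-exponential dwell mixtures. Passing
the recovery suites therefore demonstrates that the *analysis chain* is
unbiased under its own model assumptions at realistic event counts — not
that those assumptions hold for any particular recording.

## Degenerate inputs and edge behaviour

Zero substrate gives a valid, event-free trace; zero channels or zero
outside peptide give flat assay baselines; empty event tables carry exact
zero-event Poisson bounds; dwell fits refuse fewer than 50 events or a
degenerate all-equal sample; the reversal-potential solver refuses
brackets without a sign change (reporting the flux at both ends) and
non-monotone totals; inferred negative permeabilities are an error that
flags inconsistent sign conventions rather than being clamped. All
stochastic functions take explicit seeds and restore the caller's RNG
state.
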