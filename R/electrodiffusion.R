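#' @name electrodiffusion
#' @title Multivalent Goldman-Hodgkin-Katz electrodiffusion
#'
#' @description
#' Constant-field (GHK) treatment of ion flow through a wide channel under an
#' ionic gradient. Each permeant species i with valence z_i, relative
#' permeability P_i and bath concentrations c_cis, c_trans contributes a
#' charge flux (relative units)
#'
#' \deqn{\Phi_i = P_i z_i^2 u \frac{c_{cis,i} - c_{trans,i} e^{z_i u}}
#'   {e^{z_i u} - 1}, \qquad u = \frac{F V_m}{R T},}
#'
#' in the voltage convention V_m = V_trans - V_cis (cis grounded). The
#' reversal potential is the voltage at which the total charge flux vanishes;
#' measuring it under a known gradient lets one solve for an unknown relative
#' permeability, because each \eqn{\Phi_i} is linear in P_i. At V_m = 0 the
#' charge flux reduces to the Fick limit \eqn{P_i z_i (c_{cis} - c_{trans})}
#' and the molar flux to \eqn{P_i (c_{cis} - c_{trans})}.
#'
#' Permeabilities are relative to a reference species (dimensionless); no
#' absolute calibration is claimed without a caller-supplied scale.
NULL

#' Define a permeant ion species
#'
#' @param name species label.
#' @param z signed integer valence (e units), nonzero. A polycationic peptide
#'   enters with its effective charge (e.g. +21 for protamine).
#' @param P relative permeability (dimensionless, nonnegative), or `NA` to
#'   mark the species whose permeability [infer_permeability()] solves for.
#' @param c_cis,c_trans bath concentrations, mol/L.
#' @return a one-row data frame.
#' @export
ion_species <- function(name, z, P, c_cis, c_trans) {
  .check_number(z, "z", allow_zero = FALSE)
  if (!is.na(P)) .check_number(P, "P", lower = 0)
  .check_number(c_cis, "c_cis", lower = 0)
  .check_number(c_trans, "c_trans", lower = 0)
  data.frame(name = as.character(name), z = as.integer(z), P = as.numeric(P),
             c_cis = c_cis, c_trans = c_trans, stringsAsFactors = FALSE)
}

#' Assemble a membrane system
#'
#' @param species list of [ion_species()] rows (or a data frame with columns
#'   name, z, P, c_cis, c_trans).
#' @param temperature_K absolute temperature, K (default 298.15, i.e. 25 C).
#' @return an object of class `membrane_system`: the species table plus
#'   temperature; the voltage convention is fixed to trans-minus-cis.
#' @export
membrane_system <- function(species, temperature_K = 298.15) {
  if (is.data.frame(species)) {
    tab <- species
  } else {
    tab <- do.call(rbind, species)
  }
  stopifnot(all(c("name", "z", "P", "c_cis", "c_trans") %in% names(tab)))
  .check_number(temperature_K, "temperature_K", lower = 250, upper = 350)
  if (any(tab$z == 0)) stop("valence must be nonzero", call. = FALSE)
  if (anyDuplicated(tab$name)) stop("duplicate species names", call. = FALSE)
  structure(list(species = tab, temperature_K = temperature_K,
                 voltage_convention = "trans_minus_cis"),
            class = "membrane_system")
}

#' @export
print.membrane_system <- function(x, ...) {
  cat(sprintf("<membrane_system> T = %.2f K, V_m = V_trans - V_cis\n",
              x$temperature_K))
  print(x$species, row.names = FALSE)
  invisible(x)
}

# Per-species GHK charge flux per unit permeability, overflow-safe.
# Phi/P = z^2 u (c_cis - c_trans e^{zu}) / (e^{zu} - 1), u = F V_m / (R T),
# V_m = V_trans - V_cis; positive flux = positive charge moving cis->trans.
# V_mv in millivolts; concentrations mol/L.
.ghk_phi_per_P <- function(z, c_cis, c_trans, V_mv, temperature_K) {
  u <- .FARADAY * (V_mv / 1000) / (.GAS_R * temperature_K)
  zu <- z * u
  if (abs(zu) < 1e-6) {
    # series about u = 0: Phi/P = z (c_cis - c_trans)
    #                             - z^2 u (c_cis + c_trans)/2 + O(u^2)
    return(z * (c_cis - c_trans) - z^2 * u * (c_cis + c_trans) / 2)
  }
  if (zu > 30) {
    # multiply through by exp(-zu): (c_cis e^{-zu} - c_trans)/(1 - e^{-zu})
    e <- exp(-zu)
    return(z^2 * u * (c_cis * e - c_trans) / (1 - e))
  }
  z^2 * u * (c_cis - c_trans * exp(zu)) / (exp(zu) - 1)
}

#' GHK charge and molar fluxes at a given membrane voltage
#'
#' @param system a [membrane_system()].
#' @param V_mv membrane voltage, mV, in the trans-minus-cis convention
#'   (|V_mv| <= 500).
#' @return a `flux_report`: the species table with columns `charge_flux`
#'   (relative units; positive for net positive charge moving cis to trans)
#'   and `molar_flux_v0` (the zero-voltage Fick flux P * (c_cis - c_trans)),
#'   with attributes `V_mv`, `total_charge_flux` and the voltage convention.
#' @export
ghk_charge_flux <- function(system, V_mv) {
  stopifnot(inherits(system, "membrane_system"))
  .check_number(V_mv, "V_mv", lower = -500, upper = 500)
  sp <- system$species
  if (anyNA(sp$P)) {
    stop("all permeabilities must be set (use infer_permeability first)",
         call. = FALSE)
  }
  phi <- vapply(seq_len(nrow(sp)), function(i) {
    sp$P[i] * .ghk_phi_per_P(sp$z[i], sp$c_cis[i], sp$c_trans[i], V_mv,
                             system$temperature_K)
  }, numeric(1))
  out <- sp
  out$charge_flux <- phi
  out$molar_flux_v0 <- sp$P * (sp$c_cis - sp$c_trans)
  structure(out, V_mv = V_mv, total_charge_flux = sum(phi),
            voltage_convention = system$voltage_convention,
            class = c("flux_report", "data.frame"))
}

.total_flux_fun <- function(system) {
  function(V) attr(ghk_charge_flux(system, V), "total_charge_flux")
}

#' Zero-current (reversal) potential of a membrane system
#'
#' Finds the membrane voltage at which the total GHK charge flux vanishes,
#' by bracketed root-finding on \[-300, 300\] mV. Requires species of both
#' valence signs; the total flux is strictly monotone (decreasing) in the
#' voltage for nonnegative permeabilities, so the root is unique — a
#' non-monotone total on the bracket is reported as an error.
#'
#' @param system a [membrane_system()] with all permeabilities set.
#' @param bracket_mv search interval, mV.
#' @param tol_mv root tolerance, mV.
#' @return reversal potential in mV (trans minus cis).
#' @export
reversal_potential <- function(system, bracket_mv = c(-300, 300),
                               tol_mv = 1e-10) {
  stopifnot(inherits(system, "membrane_system"))
  f <- .total_flux_fun(system)
  lo <- f(bracket_mv[1]); hi <- f(bracket_mv[2])
  if (sign(lo) == sign(hi)) {
    stop(sprintf(
      "total charge flux does not change sign on [%g, %g] mV (flux %g at lower, %g at upper)",
      bracket_mv[1], bracket_mv[2], lo, hi), call. = FALSE)
  }
  grid <- seq(bracket_mv[1], bracket_mv[2], length.out = 61)
  vals <- vapply(grid, f, numeric(1))
  # the physical total flux is strictly decreasing in V; anything else
  # signals an ill-posed system with possibly multiple roots
  if (any(diff(vals) > 1e-12 * max(abs(vals)))) {
    stop("total charge flux is non-monotone on the bracket: multiple roots",
         call. = FALSE)
  }
  uniroot(f, bracket_mv, tol = tol_mv)$root
}

#' Infer an unknown relative permeability from a measured reversal potential
#'
#' With one species' permeability marked `NA` (optionally after tying two
#' species together), solves the zero-total-current condition at the measured
#' reversal potential for the free permeability. The GHK charge flux is
#' linear in each P_i, so the solve is exact:
#' \eqn{P_{free} = -\sum_{known} \Phi_i / \phi_{free}} where
#' \eqn{\phi_{free}} is the free species' flux per unit permeability.
#'
#' For the protamine experiment the measured reversal potential alone cannot
#' determine two ratios, so the peptide permeability is tied to potassium
#' (`tie = c(Ptm = "K")`) and the sulfate permeability is solved for.
#'
#' @param system a [membrane_system()] with exactly one `NA` permeability
#'   after applying `tie`.
#' @param V_rev_mv measured reversal potential, mV (trans minus cis).
#' @param tie optional named character vector `c(A = "B")` setting P_A equal
#'   to P_B before solving.
#' @return the updated `membrane_system`, with attributes `inferred`
#'   (species name) and `inferred_P` (its permeability).
#' @export
infer_permeability <- function(system, V_rev_mv, tie = NULL) {
  stopifnot(inherits(system, "membrane_system"))
  .check_number(V_rev_mv, "V_rev_mv", lower = -500, upper = 500)
  sp <- system$species
  if (!is.null(tie)) {
    for (a in names(tie)) {
      b <- tie[[a]]
      ia <- match(a, sp$name); ib <- match(b, sp$name)
      if (is.na(ia) || is.na(ib)) {
        stop("tie refers to unknown species", call. = FALSE)
      }
      if (is.na(sp$P[ib])) stop("tie target has unknown permeability",
                                call. = FALSE)
      sp$P[ia] <- sp$P[ib]
    }
  }
  free <- which(is.na(sp$P))
  if (length(free) != 1L) {
    stop(sprintf("need exactly one free permeability after ties, found %d",
                 length(free)), call. = FALSE)
  }
  phi_per_P <- vapply(seq_len(nrow(sp)), function(i) {
    .ghk_phi_per_P(sp$z[i], sp$c_cis[i], sp$c_trans[i], V_rev_mv,
                   system$temperature_K)
  }, numeric(1))
  known_flux <- sum(sp$P[-free] * phi_per_P[-free])
  if (phi_per_P[free] == 0) {
    stop("free species carries no flux at the measured reversal potential",
         call. = FALSE)
  }
  P_free <- -known_flux / phi_per_P[free]
  if (P_free < 0) {
    stop(sprintf(
      "inferred permeability is negative (%g): check sign convention or concentrations",
      P_free), call. = FALSE)
  }
  sp$P[free] <- P_free
  out <- membrane_system(sp, system$temperature_K)
  attr(out, "inferred") <- sp$name[free]
  attr(out, "inferred_P") <- P_free
  out
}

#' Zero-voltage (Fick) molar fluxes
#'
#' At zero membrane voltage the GHK molar flux of each species reduces to
#' P_i * (c_cis - c_trans), in relative units; an optional caller-supplied
#' scale converts to absolute molecules per second. No absolute calibration
#' is claimed without a scale.
#'
#' @param system a [membrane_system()].
#' @param scale optional multiplier, molecules/s per unit P * (mol/L).
#' @return data frame with columns `name` and `molar_flux` (and
#'   `molecules_per_s` when `scale` is given).
#' @export
zero_voltage_flux <- function(system, scale = NULL) {
  stopifnot(inherits(system, "membrane_system"))
  sp <- system$species
  out <- data.frame(name = sp$name,
                    molar_flux = sp$P * (sp$c_cis - sp$c_trans),
                    stringsAsFactors = FALSE)
  if (!is.null(scale)) {
    .check_number(scale, "scale", lower = 0)
    out$molecules_per_s <- out$molar_flux * scale
  }
  out
}

#' Ionic conditions of the protamine reversal-potential experiment
#'
#' Builds the membrane system of the measurement: a 0.1 mM potassium sulfate
#' background on both sides (0.2 mM K+, 0.1 mM SO4) plus a protamine sulfate
#' gradient on the cis side. Each added protamine (effective charge +21 e)
#' brings `sulfate_per_peptide` mobile sulfate ions: 11 by the integer
#' charge-balance stoichiometry (the default), or 10.5 for exact charge
#' balance — both bookkeepings are runnable.
#'
#' @param ptm_cis_M protamine concentration added to cis, mol/L
#'   (default 0.25 mM).
#' @param sulfate_per_peptide mobile sulfates accompanying each peptide
#'   (default 11; 10.5 for exact charge balance).
#' @param k2so4_M potassium sulfate background each side, mol/L
#'   (default 0.1 mM).
#' @param ptm_charge effective peptide valence (default +21).
#' @param P_K,P_Ptm,P_SO4 relative permeabilities; `NA` marks the unknown to
#'   be inferred.
#' @param temperature_K temperature, K.
#' @return a [membrane_system()] with species K, Ptm, SO4.
#' @export
ptm_reversal_conditions <- function(ptm_cis_M = 0.25e-3,
                                    sulfate_per_peptide = 11,
                                    k2so4_M = 0.1e-3,
                                    ptm_charge = 21L,
                                    P_K = 1, P_Ptm = NA, P_SO4 = NA,
                                    temperature_K = 298.15) {
  membrane_system(list(
    ion_species("K", +1, P_K, c_cis = 2 * k2so4_M, c_trans = 2 * k2so4_M),
    ion_species("Ptm", ptm_charge, P_Ptm, c_cis = ptm_cis_M, c_trans = 0),
    ion_species("SO4", -2, P_SO4,
                c_cis = k2so4_M + sulfate_per_peptide * ptm_cis_M,
                c_trans = k2so4_M)
  ), temperature_K = temperature_K)
}

#' Read / write ionic-conditions JSON
#'
#' The interchange format is
#' `{"temperature_K": 298.15, "species": [{"name", "z", "P", "c_cis_M",
#' "c_trans_M"}, ...]}`; a `null` permeability marks the unknown for
#' [infer_permeability()].
#'
#' @param path JSON file path.
#' @return [read_conditions()]: a [membrane_system()].
#' @export
read_conditions <- function(path) {
  if (!file.exists(path)) stop(sprintf("conditions file not found: %s", path),
                               call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- j$species
  membrane_system(data.frame(
    name = sp$name, z = as.integer(sp$z),
    P = vapply(seq_along(sp$name),
               function(i) if (is.null(sp$P[[i]]) || is.na(sp$P[[i]])) NA_real_
                           else as.numeric(sp$P[[i]]), numeric(1)),
    c_cis = sp$c_cis_M, c_trans = sp$c_trans_M,
    stringsAsFactors = FALSE), temperature_K = j$temperature_K)
}

#' @rdname read_conditions
#' @param system a [membrane_system()].
#' @export
write_conditions <- function(system, path) {
  stopifnot(inherits(system, "membrane_system"))
  sp <- system$species
  jsonlite::write_json(list(
    temperature_K = system$temperature_K,
    voltage_convention = system$voltage_convention,
    species = data.frame(name = sp$name, z = sp$z, P = sp$P,
                         c_cis_M = sp$c_cis, c_trans_M = sp$c_trans)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
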