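#' @name liposome_assay
#' @title Liposome indicator-displacement (tandem) assay kinetics
#'
#' @description
#' Liposomes encapsulate a reporter pair — a calixarene receptor (CX4) that
#' quenches the dye lucigenin (LCG) when bound. A cationic peptide entering
#' through a membrane channel competes for CX4, displaces LCG and turns
#' fluorescence on. The model couples three pieces:
#'
#' 1. a 1:1 two-ligand competitive binding equilibrium inside the liposome
#'    ([competitive_equilibrium()]),
#' 2. a saturable per-channel flux law
#'    \eqn{j(C) = k_{exit} k_{entry} C / (k_{entry} C + k_{exit})}
#'    — entry to the pore is concentration-dependent, escape into the lumen
#'    is not, so once entry saturates the influx is exit-limited and
#'    independent of the outside concentration,
#' 3. an ODE for the total internal peptide, with efflux through the same
#'    law evaluated at the free internal concentration (symmetric channel).
#'
#' The inverse estimator [flux_per_channel()] converts a measured initial
#' fluorescence rate into molecules per second per channel through the
#' binding-curve derivative and the liposome volume.
NULL

#' Tandem-assay composition
#'
#' @param cx4_total encapsulated calixarene, mol/L (default 700 uM).
#' @param lcg_total encapsulated dye, mol/L (default 500 uM).
#' @param K_CL CX4-dye association constant, L/mol.
#' @param K_CP CX4-peptide association constant, L/mol; must exceed `K_CL`
#'   for displacement to be favourable.
#' @param liposome_diameter inner diameter, m (default 100 nm).
#' @param channels_per_liposome reconstituted channels per liposome
#'   (default 1).
#' @param f_floor,f_ceiling relative fluorescence of the fully quenched and
#'   fully displaced states.
#' @return an object of class `assay_config`.
#' @export
assay_config <- function(cx4_total = 700e-6, lcg_total = 500e-6,
                         K_CL = 1e5, K_CP = 1e7,
                         liposome_diameter = 100e-9,
                         channels_per_liposome = 1L,
                         f_floor = 0, f_ceiling = 1) {
  .check_number(cx4_total, "cx4_total", lower = 0, allow_zero = FALSE)
  .check_number(lcg_total, "lcg_total", lower = 0, allow_zero = FALSE)
  .check_number(K_CL, "K_CL", lower = 0, allow_zero = FALSE)
  .check_number(K_CP, "K_CP", lower = 0, allow_zero = FALSE)
  if (K_CP <= K_CL) {
    stop("K_CP must exceed K_CL: displacement must be favourable",
         call. = FALSE)
  }
  .check_number(liposome_diameter, "liposome_diameter", lower = 0,
                allow_zero = FALSE)
  .check_number(channels_per_liposome, "channels_per_liposome", lower = 0)
  if (f_floor >= f_ceiling) stop("f_floor must be below f_ceiling",
                                 call. = FALSE)
  structure(list(cx4_total = cx4_total, lcg_total = lcg_total,
                 K_CL = K_CL, K_CP = K_CP,
                 liposome_diameter = liposome_diameter,
                 channels_per_liposome = channels_per_liposome,
                 f_floor = f_floor, f_ceiling = f_ceiling),
            class = "assay_config")
}

#' Saturable per-channel transport model
#'
#' @param k_entry channel association rate, per second per micromolar.
#' @param k_exit rate-limiting escape from the channel, per second.
#' @return an object of class `transport_model`.
#' @export
transport_model <- function(k_entry, k_exit) {
  .check_number(k_entry, "k_entry", lower = 0, allow_zero = FALSE)
  .check_number(k_exit, "k_exit", lower = 0, allow_zero = FALSE)
  structure(list(k_entry = k_entry, k_exit = k_exit),
            class = "transport_model")
}

#' @rdname transport_model
#' @param transport a `transport_model`.
#' @param conc_M free peptide concentration on the entry side, mol/L.
#' @return `channel_flux()`: molecules per second per channel; monotone in
#'   the concentration and bounded by `k_exit`.
#' @export
channel_flux <- function(transport, conc_M) {
  stopifnot(inherits(transport, "transport_model"))
  c_uM <- conc_M * 1e6
  with(transport, k_exit * k_entry * c_uM / (k_entry * c_uM + k_exit))
}

#' Two-ligand one-receptor competitive binding equilibrium
#'
#' Solves the 1:1 competitive equilibrium of a receptor (CX4) with two
#' ligands (dye LCG and peptide) from the mass-action and conservation
#' relations, by monotone root-finding in the free receptor concentration
#' followed by Newton polishing to a relative residual below 1e-12.
#'
#' @param cx4_total,lcg_total,ptm_total total concentrations, mol/L.
#' @param K_CL,K_CP association constants, L/mol.
#' @return list with free concentrations `cx4_free`, `lcg_free`, `ptm_free`
#'   and complexes `cx4_lcg`, `cx4_ptm` (mol/L), plus `residual` (largest
#'   relative conservation error).
#' @export
competitive_equilibrium <- function(cx4_total, lcg_total, ptm_total,
                                    K_CL, K_CP) {
  .check_number(cx4_total, "cx4_total", lower = 0)
  .check_number(lcg_total, "lcg_total", lower = 0)
  .check_number(ptm_total, "ptm_total", lower = 0)
  .check_number(K_CL, "K_CL", lower = 0, allow_zero = FALSE)
  .check_number(K_CP, "K_CP", lower = 0, allow_zero = FALSE)
  if (cx4_total == 0) {
    return(list(cx4_free = 0, lcg_free = lcg_total, ptm_free = ptm_total,
                cx4_lcg = 0, cx4_ptm = 0, residual = 0))
  }
  # g(x) = x + x*K_CL*L_tot/(1+K_CL*x) + x*K_CP*P_tot/(1+K_CP*x) - C_tot
  # is strictly increasing in x = free receptor; root lies in (0, C_tot].
  g <- function(x) {
    x * (1 + K_CL * lcg_total / (1 + K_CL * x) +
           K_CP * ptm_total / (1 + K_CP * x)) - cx4_total
  }
  gp <- function(x) {
    1 + K_CL * lcg_total / (1 + K_CL * x)^2 +
      K_CP * ptm_total / (1 + K_CP * x)^2
  }
  x <- uniroot(g, c(0, cx4_total), tol = .Machine$double.eps * cx4_total)$root
  for (i in 1:5) { # Newton polish to machine accuracy
    step <- g(x) / gp(x)
    x_new <- x - step
    if (x_new <= 0) x_new <- x / 2
    x <- x_new
    if (abs(step) < 1e-16 * max(x, cx4_total)) break
  }
  lcg_free <- lcg_total / (1 + K_CL * x)
  ptm_free <- ptm_total / (1 + K_CP * x)
  cl <- K_CL * x * lcg_free
  cp <- K_CP * x * ptm_free
  res <- max(abs(x + cl + cp - cx4_total) / cx4_total,
             if (lcg_total > 0) abs(lcg_free + cl - lcg_total) / lcg_total else 0,
             if (ptm_total > 0) abs(ptm_free + cp - ptm_total) / ptm_total else 0)
  if (res > 1e-10) {
    stop(sprintf("competitive equilibrium failed to converge (residual %g)",
                 res), call. = FALSE)
  }
  list(cx4_free = x, lcg_free = lcg_free, ptm_free = ptm_free,
       cx4_lcg = cl, cx4_ptm = cp, residual = res)
}

# relative fluorescence for a given total internal peptide concentration:
# linear in the free-dye fraction
.f_rel_of_ptm <- function(ptm_total, assay) {
  eq <- competitive_equilibrium(assay$cx4_total, assay$lcg_total, ptm_total,
                                assay$K_CL, assay$K_CP)
  phi <- eq$lcg_free / assay$lcg_total
  list(f_rel = assay$f_floor + (assay$f_ceiling - assay$f_floor) * phi,
       ptm_free = eq$ptm_free, residual = eq$residual)
}

#' Liposome inner volume, litres
#'
#' @param assay an [assay_config()].
#' @return `(pi/6) d^3` converted to litres.
#' @export
liposome_volume_L <- function(assay) {
  (pi / 6) * assay$liposome_diameter^3 * 1e3 # m^3 -> L
}

#' Simulate peptide influx and the resulting fluorescence curve
#'
#' Integrates the total internal peptide concentration
#' \deqn{dP_{tot}/dt = n_{ch} [j(c_{out}) - j(P_{free,in})] / (N_A V_{lip})}
#' (mol/L per second) with [deSolve::lsoda()] at relative tolerance 1e-8,
#' where the free internal concentration comes from the competitive binding
#' equilibrium at every step — the encapsulated receptor buffers the
#' incoming peptide, which is what slows the fluorescence rise. Each state
#' is mapped to relative fluorescence through the free-dye fraction.
#'
#' @param assay an [assay_config()].
#' @param transport a [transport_model()].
#' @param c_out outside peptide concentration, mol/L (constant; zero before
#'   `t_add`).
#' @param t_grid increasing time grid starting at 0, seconds.
#' @param t_add time at which peptide is added outside, seconds (default 0);
#'   points before `t_add` form the pre-addition baseline.
#' @return a `fluorescence_curve`: data frame `time_s`, `f_rel`,
#'   `c_in_total_M`, `c_in_free_M`, with attributes `assay`, `transport`,
#'   `c_out`, `t_add`, `max_residual` (worst conservation residual seen).
#' @export
simulate_influx <- function(assay, transport, c_out, t_grid, t_add = 0) {
  stopifnot(inherits(assay, "assay_config"),
            inherits(transport, "transport_model"))
  .check_number(c_out, "c_out", lower = 0)
  if (length(t_grid) < 2L || t_grid[1] < 0 || any(diff(t_grid) <= 0)) {
    stop("t_grid must be increasing and start at or after 0", call. = FALSE)
  }
  vol_factor <- .AVOGADRO * liposome_volume_L(assay) # molecules per (mol/L)
  nch <- assay$channels_per_liposome
  worst <- 0
  deriv <- function(t, y, parms) {
    m <- .f_rel_of_ptm(max(y[1], 0), assay)
    influx <- if (t >= t_add) channel_flux(transport, c_out) else 0
    efflux <- channel_flux(transport, m$ptm_free)
    list(nch * (influx - efflux) / vol_factor)
  }
  times <- sort(unique(c(0, t_add[t_add <= max(t_grid)], t_grid)))
  sol <- deSolve::lsoda(c(P = 0), times, deriv, parms = NULL,
                        rtol = 1e-8, atol = 1e-16)
  keep <- match(t_grid, sol[, "time"])
  ptot <- pmax(sol[keep, "P"], 0)
  mapped <- lapply(ptot, .f_rel_of_ptm, assay = assay)
  worst <- max(vapply(mapped, `[[`, numeric(1), "residual"))
  out <- data.frame(time_s = t_grid,
                    f_rel = vapply(mapped, `[[`, numeric(1), "f_rel"),
                    c_in_total_M = ptot,
                    c_in_free_M = vapply(mapped, `[[`, numeric(1), "ptm_free"))
  structure(out, assay = assay, transport = transport, c_out = c_out,
            t_add = t_add, max_residual = worst,
            class = c("fluorescence_curve", "data.frame"))
}

#' Initial rate of a fluorescence curve
#'
#' Least-squares slope of f_rel over a window that starts at the first point
#' where the signal exceeds the pre-addition baseline by three baseline
#' standard deviations (lag handling); with no pre-addition segment the
#' window starts at the first grid point.
#'
#' @param curve a `fluorescence_curve` (or data frame with `time_s`,
#'   `f_rel`).
#' @param window window length, seconds; needs at least 5 curve points.
#' @param t_add addition time (taken from the curve's attribute when
#'   present).
#' @return slope in f_rel units per second.
#' @export
initial_rate <- function(curve, window, t_add = NULL) {
  stopifnot(all(c("time_s", "f_rel") %in% names(curve)))
  .check_number(window, "window", lower = 0, allow_zero = FALSE)
  if (is.null(t_add)) t_add <- attr(curve, "t_add")
  if (is.null(t_add)) t_add <- 0
  pre <- curve$f_rel[curve$time_s < t_add]
  base_mean <- if (length(pre)) mean(pre) else curve$f_rel[1]
  base_sd <- if (length(pre) > 1) sd(pre) else 0
  thresh <- base_mean + 3 * base_sd + 1e-12 * max(abs(base_mean), 1)
  onset_idx <- which(curve$f_rel > thresh & curve$time_s >= t_add)[1]
  if (is.na(onset_idx)) return(0) # flat curve: nothing ever rises
  t0 <- curve$time_s[onset_idx]
  in_win <- curve$time_s >= t0 & curve$time_s <= t0 + window
  if (sum(in_win) < 5L) {
    stop("fewer than 5 curve points in the rate window", call. = FALSE)
  }
  unname(coef(lm(f_rel ~ time_s, data = curve[in_win, ]))[2])
}

#' Convert an initial fluorescence rate to molecules per second per channel
#'
#' Inverts the fluorescence mapping at the quenched baseline:
#' `dC_tot/dt = rate / (df_rel/dC_tot at 0)`, with the derivative computed
#' from the competitive equilibrium by central difference, then scales by
#' the liposome volume and channel count:
#' `flux = dC_tot/dt * N_A * V_lip / n_channels`.
#'
#' @param rate initial fluorescence slope, per second (>= 0).
#' @param assay an [assay_config()].
#' @return molecules per second per channel.
#' @export
flux_per_channel <- function(rate, assay) {
  stopifnot(inherits(assay, "assay_config"))
  .check_number(rate, "rate", lower = 0)
  if (rate == 0) return(0)
  h <- 1e-4 * assay$lcg_total
  d <- (.f_rel_of_ptm(2 * h, assay)$f_rel - .f_rel_of_ptm(0, assay)$f_rel) /
    (2 * h)
  if (abs(d) < .Machine$double.eps) {
    stop("binding curve is flat at baseline: assay saturated", call. = FALSE)
  }
  (rate / d) * .AVOGADRO * liposome_volume_L(assay) /
    assay$channels_per_liposome
}

#' Write a fluorescence curve as CSV (time_s, f_rel)
#'
#' @param curve a `fluorescence_curve`.
#' @param path CSV path.
#' @export
write_curve_csv <- function(curve, path) {
  write.csv(data.frame(time_s = curve$time_s, f_rel = curve$f_rel),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("curve file not found: %s", path),
                               call. = FALSE)
  d <- read.csv(path)
  stopifnot(all(c("time_s", "f_rel") %in% names(d)))
  structure(d, class = c("fluorescence_curve", "data.frame"))
}
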