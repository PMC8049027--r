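test_that("competitive binding conserves all three totals to 1e-12", {
  set.seed(13)
  for (i in 1:1000) {
    cx4 <- 10^runif(1, -7, -2)
    lcg <- 10^runif(1, -7, -2)
    ptm <- if (runif(1) < 0.1) 0 else 10^runif(1, -9, -2)
    K_CL <- 10^runif(1, 3, 7)
    K_CP <- K_CL * 10^runif(1, 0.5, 3)
    eq <- competitive_equilibrium(cx4, lcg, ptm, K_CL, K_CP)
    expect_lt(abs(eq$cx4_free + eq$cx4_lcg + eq$cx4_ptm - cx4) / cx4, 1e-12)
    expect_lt(abs(eq$lcg_free + eq$cx4_lcg - lcg) / lcg, 1e-12)
    if (ptm > 0) {
      expect_lt(abs(eq$ptm_free + eq$cx4_ptm - ptm) / ptm, 1e-12)
    }
    expect_true(all(unlist(eq[1:5]) >= 0))
  }
})

test_that("the quenched baseline and the displacement limit behave", {
  a <- assay_config()
  base <- competitive_equilibrium(a$cx4_total, a$lcg_total, 0, a$K_CL, a$K_CP)
  expect_lt(base$lcg_free / a$lcg_total, 0.1) # dye mostly bound: quenched
  sat <- competitive_equilibrium(a$cx4_total, a$lcg_total, 1, a$K_CL, a$K_CP)
  expect_gt(sat$lcg_free / a$lcg_total, 0.99) # peptide displaces the dye
  expect_gt(sat$cx4_ptm / a$cx4_total, 0.99)
  none <- competitive_equilibrium(0, a$lcg_total, 1e-6, a$K_CL, a$K_CP)
  expect_equal(none$lcg_free, a$lcg_total)
})

test_that("no peptide outside or no channels gives a flat baseline", {
  a <- assay_config()
  tr <- transport_model(1000, 2)
  grid <- seq(0, 5, by = 0.05)
  flat1 <- simulate_influx(a, tr, 0, grid)
  expect_equal(diff(range(flat1$f_rel)), 0)
  expect_equal(initial_rate(flat1, window = 1), 0)
  a0 <- assay_config(channels_per_liposome = 0)
  flat2 <- simulate_influx(a0, tr, 1e-6, grid)
  expect_equal(diff(range(flat2$f_rel)), 0)
})

test_that("in the exit-limited regime the initial rate is independent of
           the outside concentration", {
  a <- assay_config()
  tr <- transport_model(k_entry = 1000, k_exit = 2)
  grid <- seq(0, 1, by = 0.002)
  rates <- vapply(c(0.1, 0.5, 1.0) * 1e-6, function(co) {
    initial_rate(simulate_influx(a, tr, co, grid), window = 0.1)
  }, numeric(1))
  expect_lt((max(rates) - min(rates)) / min(rates), 0.10)
})

test_that("in the linear regime the initial rate is proportional to the
           outside concentration", {
  a <- assay_config()
  tr <- transport_model(k_entry = 0.005, k_exit = 2) # entry-limited
  grid <- seq(0, 1, by = 0.002)
  concs <- c(0.1, 1.0) * 1e-6
  rates <- vapply(concs, function(co) {
    initial_rate(simulate_influx(a, tr, co, grid), window = 0.1)
  }, numeric(1))
  loglog_slope <- diff(log(rates)) / diff(log(concs))
  expect_lt(abs(loglog_slope - 1), 0.05)
})

test_that("the measured initial slope matches the chain-rule prediction", {
  a <- assay_config()
  tr <- transport_model(k_entry = 1000, k_exit = 2)
  co <- 1e-6
  curve <- simulate_influx(a, tr, co, seq(0, 0.2, by = 5e-4))
  rate <- initial_rate(curve, window = 0.02)
  dcdt <- a$channels_per_liposome * channel_flux(tr, co) /
    (6.02214076e23 * liposome_volume_L(a))
  h <- 1e-9
  eq0 <- competitive_equilibrium(a$cx4_total, a$lcg_total, 0, a$K_CL, a$K_CP)
  eqh <- competitive_equilibrium(a$cx4_total, a$lcg_total, h, a$K_CL, a$K_CP)
  dfdc <- ((eqh$lcg_free - eq0$lcg_free) / a$lcg_total) / h
  expect_lt(abs(rate - dcdt * dfdc) / (dcdt * dfdc), 0.05)
})

test_that("flux_per_channel inverts the simulator round trip", {
  a <- assay_config()
  tr <- transport_model(k_entry = 1000, k_exit = 2)
  curve <- simulate_influx(a, tr, 1e-6, seq(0, 2, by = 0.002))
  flux <- flux_per_channel(initial_rate(curve, window = 0.1), a)
  expect_lt(abs(flux - 2) / 2, 0.15)
  expect_equal(flux_per_channel(0, a), 0)
  # per-channel flux halves when the same signal comes from twice the pores
  a2 <- assay_config(channels_per_liposome = 2)
  r <- 1e-3
  expect_equal(flux_per_channel(r, a2), flux_per_channel(r, a) / 2)
})

test_that("fluorescence rises monotonically while the gradient is inward
           and totals are conserved along the integration", {
  a <- assay_config()
  tr <- transport_model(1000, 2)
  curve <- simulate_influx(a, tr, 1e-6, seq(0, 30, by = 0.1))
  expect_true(all(curve$c_in_free_M <= 1e-6 + 1e-12))
  expect_true(all(diff(curve$f_rel) > -1e-12))
  expect_true(all(curve$f_rel >= a$f_floor & curve$f_rel <= a$f_ceiling))
  expect_lt(attr(curve, "max_residual"), 1e-10)
})

test_that("fluorescence curves round-trip through CSV", {
  a <- assay_config()
  curve <- simulate_influx(a, transport_model(1000, 2), 1e-6,
                           seq(0, 1, by = 0.01))
  f <- tempfile(fileext = ".csv")
  write_curve_csv(curve, f)
  back <- read_curve_csv(f)
  expect_equal(back$f_rel, curve$f_rel)
})

test_that("assay configurations are validated", {
  expect_error(assay_config(K_CL = 1e7, K_CP = 1e5), "displacement")
  expect_error(assay_config(f_floor = 1, f_ceiling = 0), "f_floor")
  expect_error(transport_model(0, 2), "outside its allowed range")
  expect_error(simulate_influx(assay_config(), transport_model(1, 1), 1e-6,
                               c(0, 0, 1)), "increasing")
})
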