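test_that("on a noiseless trace the detector reproduces the ledger exactly", {
  g <- gating_model(5, 0, 0.02, 0)
  cfg <- noiseless_config(duration = 30, seed = 17L)
  s <- simulate_trace(g, cfg, 1, -50)
  tab <- detect_events(s$trace, detection_config(min_dwell = 0),
                       V_mv = -50, conc_uM = 1)
  truth <- s$ledger[s$ledger$onset + s$ledger$dwell < cfg$duration - 1e-9, ]
  expect_equal(nrow(tab), nrow(truth))
  dt <- 1 / cfg$sampling_rate
  expect_true(all(abs(tab$onset_s - truth$onset) <= dt + 1e-12))
  expect_true(all(abs(tab$dwell_s - truth$dwell) <= 2 * dt + 1e-12))
  expect_true(all(tab$mean_blocked_pA == 0))
})

test_that("with realistic noise and filtering, millisecond events are
           recovered with no false positives", {
  g <- gating_model(5, 0, 0.02, 0) # tau 20 ms, ~4.8 events/s
  cfg <- trace_config(duration = 60, i_open = 50, i_blocked = 0,
                      noise_sd = 2.5, sampling_rate = 50000,
                      filter_cutoff = 2500, seed = 8L)
  s <- simulate_trace(g, cfg, 1, -50)
  tab <- detect_events(s$trace, V_mv = -50, conc_uM = 1)
  truth <- s$ledger[s$ledger$onset + s$ledger$dwell < cfg$duration, ]
  long_truth <- truth[truth$dwell >= 1e-3, ]
  tol <- 5e-4
  recovered <- vapply(seq_len(nrow(long_truth)), function(i) {
    any(abs(tab$onset_s - long_truth$onset[i]) < tol)
  }, logical(1))
  expect_gte(mean(recovered), 0.99)
  false_pos <- vapply(seq_len(nrow(tab)), function(i) {
    !any(abs(truth$onset - tab$onset_s[i]) < tol)
  }, logical(1))
  expect_equal(sum(false_pos), 0L)
})

test_that("an empty trace yields an empty event table", {
  g <- gating_model(5, 0, 0.02, 0)
  s <- simulate_trace(g, noiseless_config(1), 0, -50)
  tab <- detect_events(s$trace, detection_config())
  expect_equal(nrow(tab), 0L)
  expect_equal(event_rate(tab)$rate, 0)
})

test_that("event rates carry exact Poisson confidence intervals", {
  tab120 <- ledger_as_table(data.frame(onset = seq_len(120), dwell = 1e-3),
                            duration = 60)
  er <- event_rate(tab120)
  expect_equal(er$rate, 2.0)
  expect_lt(er$ci_low, 2); expect_gt(er$ci_high, 2)

  none <- ledger_as_table(data.frame(onset = numeric(0), dwell = numeric(0)),
                          duration = 60)
  er0 <- event_rate(none)
  expect_equal(er0$rate, 0)
  expect_equal(er0$ci_low, 0)
  expect_equal(er0$ci_high, -log(0.025) / 60, tolerance = 1e-10)

  # rate estimate is Poisson-consistent on a long simulation
  g <- gating_model(5, 0, 0.001, 0)
  s <- simulate_trace(g, noiseless_config(200, seed = 12L), 1, -50)
  er_sim <- event_rate(ledger_as_table(s$ledger, 200))
  expect_lt(abs(er_sim$rate - 5), 3 * sqrt(1000) / 200)
})

test_that("the censored-exponential dwell fit is consistent and unbiased
           above a censoring bound", {
  tau <- 5e-3
  set.seed(99)
  d <- rexp(10000, 1 / tau)
  fit <- fit_dwell(d)
  expect_lt(abs(fit$tau_d - tau), 3 * tau / sqrt(10000))
  expect_lte(fit$ci_low, fit$tau_d); expect_gte(fit$ci_high, fit$tau_d)
  expect_gt(fit$ci_low, tau - 4 * tau / sqrt(10000))

  # memorylessness: censoring at t_min = tau leaves the estimator unbiased
  fit_c <- fit_dwell(d, t_min = tau)
  n_kept <- sum(d >= tau)
  expect_lt(abs(fit_c$tau_d - tau), 3 * tau / sqrt(n_kept))

  expect_error(fit_dwell(rexp(10, 1)), "too few events")
  expect_error(fit_dwell(rep(1e-3, 100)), "degenerate")
})

test_that("bootstrap dwell intervals are deterministic for a fixed seed", {
  set.seed(5); d <- rexp(500, 100)
  f1 <- fit_dwell(d, seed = 7L)
  f2 <- fit_dwell(d, seed = 7L)
  expect_identical(f1, f2)
})

test_that("zero-voltage extrapolation is exact on noiseless log-linear data", {
  v <- c(-20, -40, -60, -80)
  tr <- extrapolate_zero_voltage(
    data.frame(V_mv = v, value = 2 * exp(0.02 * abs(v))), "event_rate")
  expect_equal(tr$intercept_at_zero, 2, tolerance = 1e-10)
  expect_equal(tr$slope_per_mv, 0.02, tolerance = 1e-10)
  expect_equal(tr$r_squared, 1, tolerance = 1e-10)

  expect_error(extrapolate_zero_voltage(
    data.frame(V_mv = v, value = c(1, 2, 0, 4))), "positive")
  expect_error(extrapolate_zero_voltage(
    data.frame(V_mv = c(-20, -40), value = c(1, 2))), "at least 3")
  expect_error(extrapolate_zero_voltage(
    data.frame(V_mv = c(-20, 40, -60), value = c(1, 2, 3))), "one sign")
})

test_that("event statistics are invariant to trace amplitude rescaling", {
  g <- gating_model(5, 0, 0.02, 0)
  cfg <- trace_config(duration = 20, i_open = 50, noise_sd = 2,
                      sampling_rate = 10000, filter_cutoff = 2500, seed = 21L)
  s <- simulate_trace(g, cfg, 1, -50)
  scaled <- s$trace
  scaled$samples <- scaled$samples * 3.7
  t1 <- detect_events(s$trace)
  t2 <- detect_events(scaled)
  expect_equal(t1$onset_s, t2$onset_s)
  expect_equal(t1$dwell_s, t2$dwell_s)
  expect_equal(event_rate(t1)$rate, event_rate(t2)$rate)
  expect_equal(fit_dwell(t1)$tau_d, fit_dwell(t2)$tau_d)
})

test_that("the full pipeline recovers the gating parameters and the
           voltage trends", {
  g <- gating_model(1.0, 0.03, 0.1, 0.02)
  cfg <- trace_config(duration = 100, i_open = 50, noise_sd = 2.5,
                      sampling_rate = 25000, filter_cutoff = 2500, seed = 1L)
  rec <- recover_gating(g, cfg, conc_uM = 1,
                        voltages_mv = c(-20, -40, -60, -80, -100))
  expect_lt(abs(rec$recovered$k_on0_C - 1.0), 0.15)
  expect_lt(abs(rec$recovered$tau0 - 0.1) / 0.1, 0.15)
  expect_lt(abs(rec$recovered$alpha_on - 0.03) / 0.03, 0.20)
  expect_lt(abs(rec$recovered$alpha_off - 0.02) / 0.02, 0.20)
  expect_true(all(diff(rec$per_voltage$f_e) > 0))
  expect_true(all(diff(rec$per_voltage$tau_d) < 0))
})

test_that("flat or indistinguishable traces are rejected", {
  flat <- structure(list(sampling_rate = 1000, samples = rep(5, 1000)),
                    class = "current_trace")
  expect_error(detect_events(flat, detection_config(blocked_level = 5)),
               "flat trace")
  noisy <- structure(list(sampling_rate = 1000,
                          samples = rnorm(1000, 1, 10)),
                     class = "current_trace")
  expect_error(detect_events(noisy), "not distinguishable")
  short <- structure(list(sampling_rate = 1000, samples = rnorm(50)),
                     class = "current_trace")
  expect_error(detect_events(short), "too short")
})
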