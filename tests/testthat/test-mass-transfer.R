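test_that("windowed regression differentiates exactly where it should", {
  t10 <- seq(0, 2000, by = 10)
  ## linear inventory: slope recovered exactly, zero standard error
  fw_lin <- {
    N <- 9 - 0.002 * t10
    (N * 0.018) / (N * 0.018 + 0.331)
  }
  r <- drying_rate(t10, fw_lin, 0.331, half_window = 36)
  expect_equal(r$Ndot_w, rep(0.002, length(t10)), tolerance = 1e-10)
  expect_lt(max(r$slope_se), 1e-12)
  expect_true(all(r$edge[1:36]) && !any(r$edge[37:(length(t10) - 36)]))

  ## quadratic inventory: centred slope equals the analytic derivative
  Nq <- 9 - 0.002 * t10 + 2e-7 * t10^2
  fwq <- (Nq * 0.018) / (Nq * 0.018 + 0.331)
  rq <- drying_rate(t10, fwq, 0.331, half_window = 36)
  mid <- !rq$edge
  expect_equal(rq$Ndot_w[mid], (0.002 - 4e-7 * t10)[mid], tolerance = 1e-6)

  expect_error(drying_rate(t10[1:50], fw_lin[1:50], 0.331), "points")
  expect_error(drying_rate(c(0, 10, 30), fw_lin[1:3], 0.331, half_window = 1),
               "uniform")
})

test_that("rate fraction and resistance inversion are mutually consistent", {
  expect_equal(mtr_fraction(0.5, 1), 0.5, ignore_attr = TRUE)
  f0 <- mtr_fraction(0, 1)
  expect_equal(f0, 1e-6, ignore_attr = TRUE)
  expect_true(attr(f0, "clipped"))
  expect_equal((1 - 0.3) * 0.9598 * 0.01, 0.006719, tolerance = 1e-3) # Ndot_inf anchor
  expect_error(mtr_fraction(0.1, 0), "Ndot_inf")

  om <- omega_total(0.8402, 0.33, 0.4, 1500, 0.01)
  expect_equal(om, 0.0300, tolerance = 1e-3)
  ## algebraic inverse round trip
  for (f in c(0.05, 0.3, 0.8402, 0.99)) {
    om_f <- omega_total(f, 0.33, 0.4, 1500, 0.01)
    back <- 1 - exp(-0.33 / (om_f * 0.4 * 1500 * 0.01))
    expect_equal(back, f, tolerance = 1e-12)
  }
  expect_gt(omega_total(0.9, 0.33, 0.4, 1500, 0.01),
            omega_total(0.999, 0.33, 0.4, 1500, 0.01))  # f -> 1 drives omega -> 0
  expect_lt(omega_total(1 - 1e-9, 0.33, 0.4, 1500, 0.01), 1e-2)
  expect_error(omega_total(1, 0.33, 0.4, 1500, 0.01), "strictly")
})

test_that("the two-term resistance model refits its own curve exactly", {
  truth <- resistance_fit(0.028, 0.58, 0.10, 0.05)
  F_w <- seq(0.05, 1.4, by = 0.02)
  om <- omega_model(F_w, truth)
  fit <- fit_resistance(F_w, om, f_w_end = 0.05)
  expect_equal(fit$omega_ext, truth$omega_ext, tolerance = 1e-6)
  expect_equal(fit$omega_max, truth$omega_max, tolerance = 1e-6)
  expect_equal(fit$f_w_crit, truth$f_w_crit, tolerance = 1e-6)
  ## at the anchor the curve passes through ext + max
  expect_equal(omega_model(0.05, truth), 0.028 + 0.58, tolerance = 1e-12)
  ## residual internal resistance at F_w = 0.5 for a batch ending at
  ## F_w = 0.1: exp(-(0.5 - 0.1)/0.1) = exp(-4), about 2%
  t2 <- resistance_fit(0.028, 0.58, 0.10, 0.10)
  rel <- (omega_model(0.5, t2) - t2$omega_ext) / t2$omega_max
  expect_equal(rel, exp(-4), tolerance = 1e-12)
  expect_error(fit_resistance(c(0.1, 0.5), c(0.6, 0.03)), "10 valid points")
})

test_that("inlet-concentration estimation works when the outlet saturates", {
  iso <- agg_iso()
  c_in_true <- equilibrium_concentration(25, 0.30)
  ## near-zero external resistance: the outlet leaves essentially saturated
  bed <- bed_config(inlet_water_conc = c_in_true)
  run <- simulate_drying(bed, resistance_fit(omega_ext = 0.002), iso,
                         duration = 3000)
  tg <- seq(10, max(run$time), by = 10)
  st <- granudry:::run_state_at(run, tg)
  r <- drying_rate(tg, st$f_w, bed$solids_mass)
  cs <- equilibrium_concentration(st$T_bed, water_activity(st$F_w, iso))
  est <- estimate_inlet_concentration(tg, r$Ndot_w, cs, bed$phi_g)
  expect_lt(abs(est$c_g_in - c_in_true) / c_in_true, 0.10)

  ## dry inlet: the estimate must stay close to zero
  bed0 <- bed_config(inlet_water_conc = 0)
  run0 <- simulate_drying(bed0, resistance_fit(omega_ext = 0.002), iso,
                          duration = 3000)
  st0 <- granudry:::run_state_at(run0, tg)
  r0 <- drying_rate(tg, st0$f_w, bed0$solids_mass)
  cs0 <- equilibrium_concentration(st0$T_bed, water_activity(st0$F_w, iso))
  est0 <- estimate_inlet_concentration(tg, r0$Ndot_w, cs0, bed0$phi_g)
  expect_gte(est0$c_g_in, 0)
  expect_lte(est0$c_g_in, 0.05 * cs0[est0$index])

  ## a rate above saturation is clamped with a warning
  expect_warning(
    clamped <- estimate_inlet_concentration(tg, rep(1, length(tg)), cs, bed$phi_g),
    "clamped")
  expect_identical(clamped$c_g_in, 0)
})

test_that("the full analysis recovers the generating resistance curve", {
  run <- ref_run()
  out <- analyze_run(run, isotherm = agg_iso())
  expect_equal(out$inlet_method, "known")
  expect_lt(abs(out$fit$omega_ext / 0.028 - 1), 0.05)
  expect_lt(abs(out$fit$f_w_crit / 0.10 - 1), 0.10)
  ## omega trace reproduces the generating model on the clean points
  ok <- !out$trace$clipped & !out$trace$edge
  om_true <- omega_model(out$trace$F_w[ok], run$truth)
  expect_lt(median(abs(out$trace$Omega_tot[ok] / om_true - 1)), 0.05)
})

test_that("a constant-resistance batch yields a negligible internal term", {
  bed <- bed_config(inlet_water_conc = equilibrium_concentration(25, 0.30))
  run <- simulate_drying(bed, resistance_fit(omega_ext = 0.028, omega_max = 0,
                                             f_w_crit = 0.1, f_w_end = 0),
                         agg_iso(), duration = 5000)
  ## this batch ends abruptly (no internal resistance slows the tail), so a
  ## 720 s differentiation window would straddle the stop; a 240 s window
  ## resolves it
  out <- analyze_run(run, isotherm = agg_iso(), half_window = 12)
  expect_lte(out$fit$omega_max, 0.05 * out$fit$omega_ext)
  expect_lt(abs(out$fit$omega_ext / 0.028 - 1), 0.05)
})

test_that("resistance falls as the rate fraction rises, at fixed geometry", {
  f <- seq(0.05, 0.95, by = 0.05)
  om <- omega_total(f, 0.33, 0.4, 1500, 0.01)
  expect_true(all(diff(om) < 0))
})
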