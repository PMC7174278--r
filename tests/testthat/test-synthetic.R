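test_that("default 600 L/min batch matches the observed drying envelope", {
  run <- ref_run()
  expect_equal(run$f_w[1], 0.34, tolerance = 1e-3)
  i26 <- which(run$f_w < 0.026)[1]
  expect_lt(run$time[i26], 120 * 60)                  # below 2.6% within 2 h
  depression <- run$bed$inlet_temp - min(run$T_bed)
  expect_gt(depression, 7)                            # ~10 degC evaporative
  expect_lt(depression, 13)                           # cooling at the plateau
  expect_true(all(diff(run$f_w) <= 0))                # monotone drying
  ## F_w = (m_s/m_adsorb) f_w/(1-f_w) holds identically
  expect_equal(run$F_w,
               run$bed$solids_mass / run$bed$adsorbing_mass *
                 run$f_w / (1 - run$f_w), tolerance = 1e-12)
})

test_that("with constant driving force the inventory decays linearly", {
  ## Omega_max = 0, dry inlet, zero latent heat: T_bed = T_in, a_w = 1 in
  ## the free-water regime, so dN/dt = -f_MTR * C_S* * phi is constant.
  bed <- bed_config(inlet_water_conc = 0)
  tr <- resistance_fit(omega_ext = 0.028, omega_max = 0, f_w_crit = 0.1, f_w_end = 0)
  run <- simulate_drying(bed, tr, agg_iso(), duration = 1500, latent_heat = 0)
  kfm <- bed$solids_mass / (bed$solids_fraction * bed$skeletal_density * bed$phi_g)
  f_mtr <- 1 - exp(-kfm / tr$omega_ext)
  k <- f_mtr * equilibrium_concentration(bed$inlet_temp, 1) * bed$phi_g
  N0 <- moles_of_water(0.34, bed$solids_mass)
  free <- run$a_w == 1
  N_t <- moles_of_water(run$f_w[free], bed$solids_mass)
  expect_equal(N_t, N0 - k * run$time[free], tolerance = 1e-3)
  expect_equal(run$T_bed[free], rep(bed$inlet_temp, sum(free)), tolerance = 1e-9)
})

test_that("saturated inlet means no drying and no temperature depression", {
  run <- static_run(f_w0 = 0.25, duration = 60)
  expect_equal(run$f_w, rep(0.25, length(run$f_w)), tolerance = 1e-12)
  expect_equal(run$T_bed, run$T_in, tolerance = 1e-9)
})

test_that("water leaving the granules balances the integrated drying rate", {
  run <- ref_run()
  removed <- moles_of_water(run$f_w[1], run$bed$solids_mass) -
    moles_of_water(run$f_w[length(run$f_w)], run$bed$solids_mass)
  carried <- sum(run$Ndot_w) * run$params$dt
  expect_equal(carried / removed, 1, tolerance = 5e-3)
})

test_that("drying slows with external resistance and speeds with gas flow", {
  iso <- agg_iso()
  mk <- function(ext, flow, duration) {
    simulate_drying(bed_config(gas_flow = flow, inlet_water_conc = 0.38),
                    resistance_fit(omega_ext = ext), iso, duration = duration)
  }
  base <- mk(0.028, 600, 2500)             # both inside the free-water regime
  slow <- mk(0.056, 600, 2500)
  expect_true(all(slow$Ndot_w < base$Ndot_w))
  t5 <- function(run) run$time[which(run$f_w < 0.05)[1]]
  fast <- mk(0.028, 850, 4500)
  expect_lt(t5(fast), t5(mk(0.028, 600, 4500)))
})

test_that("plateau temperature depression satisfies the energy balance", {
  run <- ref_run()
  i <- which(run$F_w > 0.6)                # constant-rate region
  dT <- run$T_in[i] - run$T_bed[i]
  pred <- run$Ndot_w[i] * run$params$latent_heat /
    (run$bed$phi_g * run$params$air_heat_capacity)
  expect_equal(dT, pred, tolerance = 1e-4)
})

test_that("spectra generation is seed-reproducible and obeys the optics model", {
  run <- static_run(duration = 120)
  opt <- optics_config(rng_seed = 7L)
  s1 <- generate_spectra(run, opt)
  s2 <- generate_spectra(run, opt)
  expect_identical(s1$values, s2$values)

  ## dry material: no water band, only the baseline
  opt0 <- quiet_optics()
  a0 <- granudry:::true_absorbance(0, 25, opt0)
  base <- opt0$baseline_offset + opt0$baseline_slope *
    (opt0$wavelength_grid - opt0$wavelength_grid[1])
  expect_equal(drop(a0), base, tolerance = 1e-14)
})

test_that("averaging strictly improves the water-band signal-to-noise", {
  run <- static_run(f_w0 = 0.30, duration = 2000)
  sp <- generate_spectra(run, optics_config(rng_seed = 21L, airgap_prob = 0,
                                            fouling_magnitude = 0))
  band <- which(sp$wavelengths == 1940)
  shoulder <- which(sp$wavelengths == 1760)
  amp <- function(series) {
    a <- to_absorbance(series)
    a$values[, band] - a$values[, shoulder]
  }
  sd_single <- sd(amp(sp))
  sd_block <- sd(amp(block_average(sp, 10)))
  ma <- moving_average(to_absorbance(block_average(sp, 10)), 75)
  sd_ma <- sd((ma$values[, band] - ma$values[, shoulder])[-(1:74)])
  expect_gt(sd_single, sd_block)
  expect_gt(sd_block, sd_ma)
})

test_that("LOD sampling hits the schedule and the stated noise level", {
  run <- ref_run()
  clean <- sample_lod(run, interval = 400, rel_noise_sd = 0)
  expect_equal(nrow(clean), 18)                       # floor(7200/400)
  expect_equal(clean$f_w_obs,
               approx(run$time, run$f_w, clean$time)$y, tolerance = 1e-12)

  set.seed(8)
  eps <- replicate(60, {
    s <- sample_lod(run, interval = 400, rel_noise_sd = 0.02)
    s$f_w_obs / clean$f_w_obs - 1
  })
  expect_equal(sd(eps), 0.02, tolerance = 0.1)
  expect_error(sample_lod(run, interval = 0), "interval")
})

test_that("a complete synthetic batch is reproducible end to end", {
  b1 <- synthetic_batch(seed = 5, duration = 1200, isotherm = agg_iso())
  b2 <- synthetic_batch(seed = 5, duration = 1200, isotherm = agg_iso())
  expect_identical(b1$spectra$values, b2$spectra$values)
  expect_identical(b1$lod, b2$lod)
  expect_identical(b1$run$f_w, b2$run$f_w)
})
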