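#' Fluidised-bed configuration
#'
#' @param gas_flow fluidising gas flowrate, L/min (volumetric, at inlet
#'   conditions); > 0.
#' @param inlet_temp inlet gas temperature, degC.
#' @param solids_mass dry solids mass m_s, kg.
#' @param adsorbing_mass mass of the water-adsorbing excipients m_adsorb,
#'   kg; <= solids_mass. Denominator of the dry-basis moisture F_w.
#' @param solids_fraction volume fraction of solids in the bed f_s, in (0,1).
#' @param skeletal_density solids skeletal density rho_s, kg/m^3.
#' @param inlet_water_conc water concentration of the inlet gas C_g_in,
#'   mol/m^3; `NULL` when unknown (it can then be estimated from the data
#'   by [estimate_inlet_concentration()]).
#' @return object of class `bed_config`. The element `phi_g` carries the
#'   flow converted to m^3/s.
#' @export
bed_config <- function(gas_flow = 600, inlet_temp = 25,
                       solids_mass = 0.331, adsorbing_mass = 0.118,
                       solids_fraction = 0.40, skeletal_density = 1500,
                       inlet_water_conc = NULL) {
  if (gas_flow <= 0) stop("bed_config: gas_flow must be > 0")
  if (solids_fraction <= 0 || solids_fraction >= 1) {
    stop("bed_config: solids_fraction must lie in (0, 1)")
  }
  if (skeletal_density <= 0) stop("bed_config: skeletal_density must be > 0")
  if (adsorbing_mass > solids_mass) {
    stop("bed_config: adsorbing_mass cannot exceed solids_mass")
  }
  if (!is.null(inlet_water_conc) && inlet_water_conc < 0) {
    stop("bed_config: inlet_water_conc must be >= 0")
  }
  structure(list(gas_flow = gas_flow, phi_g = gas_flow / 1000 / 60,
                 inlet_temp = inlet_temp, solids_mass = solids_mass,
                 adsorbing_mass = adsorbing_mass,
                 solids_fraction = solids_fraction,
                 skeletal_density = skeletal_density,
                 inlet_water_conc = inlet_water_conc),
            class = "bed_config")
}

#' Mass-transfer-resistance parametrisation
#'
#' Total resistance as a constant external term plus an internal term that
#' grows exponentially as the granule dries:
#' \deqn{\Omega_{tot}(F_w) = \Omega_{ext} + \Omega_{max}
#'   e^{-(F_w - F_{w,end})/F_{w,crit}}.}
#'
#' @param omega_ext external (gas-film) resistance, s; >= 0.
#' @param omega_max internal resistance at the end of drying, s; >= 0.
#' @param f_w_crit critical dry-basis moisture scale; > 0.
#' @param f_w_end final dry-basis moisture, the anchor of the exponential.
#' @return object of class `resistance_fit`.
#' @export
resistance_fit <- function(omega_ext = 0.028, omega_max = 0.58,
                           f_w_crit = 0.10, f_w_end = 0.05) {
  if (omega_ext < 0 || omega_max < 0 || f_w_end < 0) {
    stop("resistance_fit: resistances and f_w_end must be >= 0")
  }
  if (f_w_crit <= 0) stop("resistance_fit: f_w_crit must be > 0")
  structure(list(omega_ext = omega_ext, omega_max = omega_max,
                 f_w_crit = f_w_crit, f_w_end = f_w_end),
            class = "resistance_fit")
}

#' @export
print.resistance_fit <- function(x, ...) {
  cat(sprintf("resistance_fit: omega_ext = %.4g s, omega_max = %.4g s, F_w.crit = %.4g, F_w.end = %.4g\n",
              x$omega_ext, x$omega_max, x$f_w_crit, x$f_w_end))
  if (!is.null(attr(x, "std_errors"))) {
    se <- attr(x, "std_errors")
    cat("  std. errors: ", paste(sprintf("%s = %.3g", names(se), se), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Evaluate the resistance model at given moisture contents
#'
#' @param F_w dry-basis moisture content(s).
#' @param fit a [resistance_fit].
#' @return total resistance Omega_tot in seconds.
#' @export
omega_model <- function(F_w, fit) {
  stopifnot(inherits(fit, "resistance_fit"))
  fit$omega_ext + fit$omega_max * exp(-(F_w - fit$f_w_end) / fit$f_w_crit)
}

#' Optical and noise model of the in-line NIR sensor
#'
#' Defines how a moisture state maps to a measured intensity scan. The
#' true absorbance is a water band (Gaussian in wavelength) on a linear
#' baseline. The band amplitude saturates with moisture,
#' `absorbance_per_moisture * response_gamma * ln(1 + f_w/response_gamma)`,
#' emulating the nonlinearity of diffuse-reflectance measurements at high
#' water loadings (for `response_gamma -> Inf` the amplitude is linear in
#' f_w). The band centre shifts with bed temperature
#' (`temp_shift` nm/K about 25 degC), as the water -OH band does.
#' Measurement artefacts: per-scan lognormal gain, additive detector
#' noise, air-gap dropout scans, and transient window fouling that decays
#' exponentially (self-cleaning by particle collisions).
#'
#' @param wavelength_grid nm; default 1750..2150 step 1 (401 points).
#' @param dark_level,bright_level detector counts; dark < bright.
#' @param water_band_center,water_band_width nm.
#' @param absorbance_per_moisture AU per unit f_w (small-f_w slope of the
#'   band amplitude).
#' @param response_gamma moisture scale of the saturating band response.
#' @param temp_shift band-centre shift, nm per K of bed temperature.
#' @param baseline_offset AU; `baseline_slope` AU/nm (about the grid start).
#' @param scan_noise_sd additive detector noise, counts.
#' @param gain_sd log-scale sd of the per-scan gain.
#' @param airgap_prob per-scan probability of a dropout (air-gap) scan.
#' @param fouling_magnitude AU of an initial fouling event;
#'   `fouling_decay` 1/s; `fouling_rate` events per second while the
#'   granules are wet enough to stick (f_w > 0.2).
#' @param rng_seed integer seed making generation reproducible; `NULL`
#'   uses the session RNG stream.
#' @return object of class `optics_config`.
#' @export
optics_config <- function(wavelength_grid = seq(1750, 2150, by = 1),
                          dark_level = 500, bright_level = 20000,
                          water_band_center = 1940, water_band_width = 35,
                          absorbance_per_moisture = 2.0, response_gamma = 0.01,
                          temp_shift = 0.5,
                          baseline_offset = 0.1, baseline_slope = 2e-4,
                          scan_noise_sd = 50, gain_sd = 0.05,
                          airgap_prob = 0.01,
                          fouling_magnitude = 0.05, fouling_decay = 1 / 120,
                          fouling_rate = 1 / 600,
                          rng_seed = NULL) {
  if (any(diff(wavelength_grid) <= 0)) {
    stop("optics_config: wavelength_grid must be strictly increasing")
  }
  if (dark_level >= bright_level) stop("optics_config: dark_level must be < bright_level")
  if (airgap_prob < 0 || airgap_prob > 1) stop("optics_config: airgap_prob must lie in [0, 1]")
  if (water_band_width <= 0) stop("optics_config: water_band_width must be > 0")
  if (response_gamma <= 0) stop("optics_config: response_gamma must be > 0")
  structure(list(wavelength_grid = wavelength_grid, dark_level = dark_level,
                 bright_level = bright_level,
                 water_band_center = water_band_center,
                 water_band_width = water_band_width,
                 absorbance_per_moisture = absorbance_per_moisture,
                 response_gamma = response_gamma, temp_shift = temp_shift,
                 baseline_offset = baseline_offset, baseline_slope = baseline_slope,
                 scan_noise_sd = scan_noise_sd, gain_sd = gain_sd,
                 airgap_prob = airgap_prob,
                 fouling_magnitude = fouling_magnitude,
                 fouling_decay = fouling_decay, fouling_rate = fouling_rate,
                 rng_seed = rng_seed),
            class = "optics_config")
}

#' Forward-simulate a fluidised-bed drying batch
#'
#' Explicit Euler integration of the molar water inventory with the
#' resistance model supplying the drying rate and a quasi-steady energy
#' balance supplying the bed temperature. At each step:
#' the dry-basis moisture sets the water activity through the sorption
#' isotherm (clamped to 1 in the free-water regime, i.e. while the
#' inventory exceeds the isotherm's capacity); the total resistance
#' follows from [omega_model()]; the drying rate is
#' \eqn{\dot N_w = f_{MTR} (1 - S_{in}) C_S^*(T_{bed}, a_w) \varphi_g}
#' with \eqn{f_{MTR} = 1 - e^{-m_s/(\Omega_{tot} f_s \rho_s \varphi_g)}};
#' and the bed temperature solves
#' \eqn{\varphi_g c_{air} (T_{in} - T_{bed}) = \dot N_w \Delta H_{vap}}
#' by damped fixed-point iteration (tolerance 1e-6 degC; the undamped map
#' is oscillatory, so a relaxation factor of 0.5 is applied).
#'
#' @param bed a [bed_config]. If `inlet_water_conc` is `NULL`, a dry inlet
#'   (0 mol/m^3) is simulated.
#' @param truth a [resistance_fit] holding the generating parameters.
#' @param isotherm a [gab_params] aggregate isotherm (see
#'   [aggregate_isotherm()]).
#' @param duration simulated time, s.
#' @param dt Euler step, s; must be <= 1 (the dynamics are slow relative
#'   to 1 s, and larger steps degrade the energy balance).
#' @param f_w0 initial wet-basis moisture fraction.
#' @param latent_heat molar heat of vaporisation, J/mol.
#' @param air_heat_capacity volumetric heat capacity of the gas, J/(m^3 K).
#' @param min_rate drying rate (mol/s) below which the run is considered
#'   finished and integration stops; set to 0 to always run to `duration`.
#' @return object of class `drying_run`: uniform time grid with wet-basis
#'   `f_w`, dry-basis `F_w`, bed and inlet temperatures, the true drying
#'   rate `Ndot_w` (mol/s), water activity `a_w` and resistance
#'   `omega_tot`, plus the `bed`, `truth` and `isotherm` objects. The run
#'   stops early if the drying rate falls below 1e-9 mol/s.
#' @export
simulate_drying <- function(bed, truth, isotherm,
                            duration = 7200, dt = 1, f_w0 = 0.34,
                            latent_heat = 44000, air_heat_capacity = 1200,
                            min_rate = 1e-9) {
  stopifnot(inherits(bed, "bed_config"), inherits(truth, "resistance_fit"),
            inherits(isotherm, "gab_params"))
  if (dt <= 0 || dt > 1) stop("simulate_drying: dt must lie in (0, 1]")
  if (f_w0 <= 0 || f_w0 >= 1) stop("simulate_drying: f_w0 must lie in (0, 1)")
  if (duration <= dt) stop("simulate_drying: duration must exceed dt")
  c_in <- if (is.null(bed$inlet_water_conc)) 0 else bed$inlet_water_conc
  phi <- bed$phi_g
  kfm <- bed$solids_mass / (bed$solids_fraction * bed$skeletal_density * phi)
  n <- floor(duration / dt) + 1            # states at 0, dt, ..., duration
  N_w <- moles_of_water(f_w0, bed$solids_mass)
  t_out <- f_w <- F_w <- T_bed <- Ndot <- a_w_out <- om_out <- numeric(n)
  T_cur <- bed$inlet_temp
  for (i in seq_len(n)) {
    m_w <- N_w * 0.018
    Fw_i <- m_w / bed$adsorbing_mass
    fw_i <- m_w / (m_w + bed$solids_mass)
    aw_i <- water_activity(Fw_i, isotherm)
    om_i <- omega_model(Fw_i, truth)
    f_mtr <- 1 - exp(-kfm / om_i)
    nd <- NA_real_
    converged <- FALSE
    for (it in seq_len(100)) {
      cs <- equilibrium_concentration(T_cur, aw_i)
      s_in <- if (cs > 0) min(1, c_in / cs) else 1
      nd <- f_mtr * (1 - s_in) * cs * phi
      T_new <- bed$inlet_temp - nd * latent_heat / (phi * air_heat_capacity)
      if (abs(T_new - T_cur) < 1e-6) {
        T_cur <- T_new
        converged <- TRUE
        break
      }
      T_cur <- 0.5 * T_cur + 0.5 * T_new
    }
    if (!converged) {
      stop(sprintf("simulate_drying: bed-temperature iteration did not converge at step %d (t = %.0f s)",
                   i, i * dt))
    }
    t_out[i] <- (i - 1) * dt
    f_w[i] <- fw_i; F_w[i] <- Fw_i; T_bed[i] <- T_cur
    Ndot[i] <- nd; a_w_out[i] <- aw_i; om_out[i] <- om_i
    if (nd < min_rate && i < n) {
      n <- i
      break
    }
    N_w <- N_w - nd * dt
    if (N_w < 0) {
      warning("simulate_drying: water inventory went negative; clamped to equilibrium")
      N_w <- 0
    }
  }
  idx <- seq_len(n)
  structure(list(time = t_out[idx], f_w = f_w[idx], F_w = F_w[idx],
                 T_bed = T_bed[idx],
                 T_in = rep(bed$inlet_temp, n),
                 Ndot_w = Ndot[idx], a_w = a_w_out[idx],
                 omega_tot = om_out[idx],
                 bed = bed, truth = truth, isotherm = isotherm,
                 lod = NULL,
                 params = list(duration = duration, dt = dt, f_w0 = f_w0,
                               latent_heat = latent_heat,
                               air_heat_capacity = air_heat_capacity,
                               inlet_water_conc = c_in)),
            class = "drying_run")
}

#' @export
print.drying_run <- function(x, ...) {
  cat(sprintf("drying_run: %.0f min at %.0f L/min; f_w %.3f -> %.4f; T_bed %.1f..%.1f degC\n",
              max(x$time) / 60, x$bed$gas_flow, x$f_w[1], x$f_w[length(x$f_w)],
              min(x$T_bed), max(x$T_bed)))
  if (!is.null(x$lod)) cat(sprintf("  %d LOD samples attached\n", nrow(x$lod)))
  invisible(x)
}

## interpolate run state at arbitrary times
run_state_at <- function(run, times) {
  list(f_w = stats::approx(run$time, run$f_w, times, rule = 2)$y,
       T_bed = stats::approx(run$time, run$T_bed, times, rule = 2)$y,
       F_w = stats::approx(run$time, run$F_w, times, rule = 2)$y)
}

## noise-free absorbance surface of the optics model (n times x W)
true_absorbance <- function(f_w, T_bed, optics) {
  wl <- optics$wavelength_grid
  g <- optics$response_gamma
  amp <- optics$absorbance_per_moisture * g * log(1 + f_w / g)
  centers <- optics$water_band_center + optics$temp_shift * (T_bed - 25)
  baseline <- optics$baseline_offset + optics$baseline_slope * (wl - wl[1])
  band <- exp(-0.5 * (outer(centers, wl, "-") / optics$water_band_width)^2)
  sweep(band * amp, 2, baseline, "+")
}

#' Synthesize raw NIR intensity scans for a drying run
#'
#' One scan per second. The true absorbance surface from the optics model
#' is converted to intensity,
#' \eqn{I = dark + (bright - dark)\, 10^{-A g_t} + \epsilon}, with a
#' lognormal per-scan gain \eqn{g_t} and additive Gaussian detector noise.
#' With probability `airgap_prob` a scan is replaced by a low-signal
#' dropout artefact (an air pocket in front of the probe window). Window
#' fouling events (while f_w > 0.2) lower the apparent absorbance by an
#' exponentially decaying offset. Intensities at or below the dark level
#' are clipped at dark + 1 count with a warning. Generation is
#' reproducible for a fixed `optics$rng_seed`.
#'
#' @param run a [drying_run].
#' @param optics an [optics_config].
#' @return an intensity [spectra_series] with bright/dark references
#'   attached and the optics configuration in `meta$optics`.
#' @export
generate_spectra <- function(run, optics) {
  stopifnot(inherits(run, "drying_run"), inherits(optics, "optics_config"))
  if (!is.null(optics$rng_seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(optics$rng_seed)
  }
  times <- seq(1, floor(max(run$time)))
  st <- run_state_at(run, times)
  n <- length(times)
  wl <- optics$wavelength_grid
  W <- length(wl)
  A <- true_absorbance(st$f_w, st$T_bed, optics)
  ## transient fouling: sticky wet granules raise reflection, lowering A
  if (optics$fouling_magnitude > 0 && optics$fouling_rate > 0) {
    sticky <- st$f_w > 0.2
    events <- times[sticky & stats::runif(n) < optics$fouling_rate]
    if (length(events) > 0) {
      foul <- numeric(n)
      for (te in events) {
        after <- times >= te
        foul[after] <- foul[after] +
          optics$fouling_magnitude * exp(-optics$fouling_decay * (times[after] - te))
      }
      A <- A - foul
    }
  }
  gain <- exp(stats::rnorm(n, 0, optics$gain_sd))
  dark <- rep(optics$dark_level, W)
  bright <- rep(optics$bright_level, W)
  span <- optics$bright_level - optics$dark_level
  I <- optics$dark_level + span * 10^(-A * gain)
  dropout <- stats::runif(n) < optics$airgap_prob
  if (any(dropout)) {
    frac <- stats::runif(sum(dropout), 0.01, 0.10)
    I[dropout, ] <- optics$dark_level + span * frac
  }
  if (optics$scan_noise_sd > 0) {
    I <- I + matrix(stats::rnorm(n * W, 0, optics$scan_noise_sd), n, W)
  }
  n_clip <- sum(I <= optics$dark_level)
  if (n_clip > 0) {
    warning(sprintf("generate_spectra: %d intensity points at or below dark level clipped to dark + 1", n_clip))
    I[I <= optics$dark_level] <- optics$dark_level + 1
  }
  spectra_series(wl, times, I, "intensity", bright, dark,
                 meta = list(optics = optics, dropout_scans = sum(dropout)))
}

#' Draw sparse loss-on-drying reference samples from a run
#'
#' Emulates the manual sampling protocol: a small sample is withdrawn at
#' every multiple of `interval` seconds and its wet-basis moisture is
#' measured gravimetrically with multiplicative noise,
#' f_obs = f_w(t) (1 + e), e ~ N(0, rel_noise_sd). Observations are
#' clamped to (0, 1).
#'
#' @param run a [drying_run].
#' @param interval sampling interval, s; the in-line protocol samples
#'   every 6-7 min (default 400 s).
#' @param rel_noise_sd relative measurement noise (default 2%).
#' @return data.frame with columns `time` (s) and `f_w_obs`.
#' @export
sample_lod <- function(run, interval = 400, rel_noise_sd = 0.02) {
  stopifnot(inherits(run, "drying_run"))
  if (interval <= 0) stop("sample_lod: interval must be > 0")
  times <- seq(interval, max(run$time), by = interval)
  fw <- run_state_at(run, times)$f_w
  obs <- fw * (1 + stats::rnorm(length(fw), 0, rel_noise_sd))
  obs <- pmin(pmax(obs, .Machine$double.eps), 1 - .Machine$double.eps)
  data.frame(time = times, f_w_obs = obs)
}

#' Generate a complete synthetic drying batch
#'
#' Convenience wrapper producing everything a downstream analysis needs:
#' the noise-free trajectory, the raw intensity scans, and the sparse LOD
#' reference samples. With `vary = TRUE`, batch-to-batch variation is
#' emulated by drawing the initial moisture (33-38 wt%) and the ambient
#' inlet humidity (20-40% RH) at random, mirroring the spread observed
#' across real batches.
#'
#' @param seed integer seed controlling every random element of the batch.
#' @param bed,truth,isotherm,optics model components; defaults are the
#'   600 L/min reference conditions with the aggregate isotherm of the
#'   shipped placebo formulation.
#' @param duration,f_w0 passed to [simulate_drying()].
#' @param lod_interval,lod_noise passed to [sample_lod()].
#' @param inlet_rh inlet relative humidity (at the inlet temperature) used
#'   to set the inlet water concentration when `bed$inlet_water_conc` is
#'   `NULL`; default 30% RH.
#' @param vary draw f_w0 and inlet_rh at random for batch-to-batch spread.
#' @return list with elements `run` (a [drying_run] with `lod` attached),
#'   `spectra` (raw intensity [spectra_series]) and `lod` (data.frame).
#' @export
synthetic_batch <- function(seed = 1, bed = bed_config(), truth = resistance_fit(),
                            isotherm = NULL, optics = NULL,
                            duration = 6000, f_w0 = 0.34,
                            lod_interval = 400, lod_noise = 0.02,
                            inlet_rh = 0.30, vary = FALSE) {
  set.seed(seed)
  if (is.null(isotherm)) {
    isotherm <- aggregate_isotherm(placebo_formulation())$params
  }
  if (vary) {
    f_w0 <- stats::runif(1, 0.33, 0.38)
    inlet_rh <- stats::runif(1, 0.20, 0.40)
  }
  if (is.null(bed$inlet_water_conc)) {
    bed$inlet_water_conc <- equilibrium_concentration(bed$inlet_temp, inlet_rh)
  }
  run <- simulate_drying(bed, truth, isotherm, duration = duration, f_w0 = f_w0)
  if (is.null(optics)) optics <- optics_config(rng_seed = seed + 1L)
  spectra <- generate_spectra(run, optics)
  lod <- sample_lod(run, interval = lod_interval, rel_noise_sd = lod_noise)
  run$lod <- lod
  list(run = run, spectra = spectra, lod = lod)
}
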