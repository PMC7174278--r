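## Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## aggregate isotherm of the shipped formulation
agg_iso <- function() memo("agg_iso", aggregate_isotherm(placebo_formulation())$params)

## reference noise-free 600 L/min run with the default generating parameters
ref_run <- function() memo("ref_run", {
  bed <- bed_config(inlet_water_conc = equilibrium_concentration(25, 0.30))
  simulate_drying(bed, resistance_fit(), agg_iso(), duration = 7200)
})

## constant-moisture run (saturated inlet: no drying, no depression),
## handy for spectra round-trip identities
static_run <- function(f_w0 = 0.30, duration = 1200) {
  bed <- bed_config(inlet_water_conc = equilibrium_concentration(25, 1))
  simulate_drying(bed, resistance_fit(), agg_iso(),
                  duration = duration, f_w0 = f_w0, min_rate = 0)
}

## noise-free optics: every stochastic artefact switched off
quiet_optics <- function(...) {
  optics_config(scan_noise_sd = 0, gain_sd = 0, airgap_prob = 0,
                fouling_magnitude = 0, rng_seed = 42L, ...)
}

## small random spectra series for io tests
random_series <- function(n = 5, w = 7, kind = "intensity", seed = 99) {
  set.seed(seed)
  wl <- sort(1750 + cumsum(runif(w, 0.5, 2)))
  dark <- runif(w, 400, 600)
  bright <- dark + runif(w, 1e4, 2e4)
  vals <- matrix(runif(n * w, 1000, 15000), n, w)
  if (kind == "absorbance") {
    spectra_series(wl, seq_len(n), vals / 1e4, "absorbance")
  } else {
    spectra_series(wl, seq_len(n), vals, "intensity", bright, dark)
  }
}
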