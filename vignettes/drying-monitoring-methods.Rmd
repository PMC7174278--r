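---
title: "Monitoring fluidised-bed granule drying with an in-line NIR sensor: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring fluidised-bed granule drying: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Pharmaceutical granules leave wet granulation at roughly 34 wt% water and
are dried in a fluidised bed until they equilibrate with the ambient air at
1.5–2 wt%. Three questions matter during the batch: *how much water is left*
(moisture monitoring), *when to stop* (end-point detection), and *what
limits the drying rate* (mass-transfer analysis, the basis of scale-up).
`granudry` implements the complete analysis chain for an in-line
diffuse-reflectance NIR sensor sampling 401 wavelength points over
1750–2150 nm at one scan per second, together with a synthetic batch
generator so that every stage can be exercised and tested without
experimental data.

# Spectral preprocessing

Scans from a bubbling bed are dominated by particle motion: air gaps and
variable packing in front of the probe window change the collected
intensity from scan to scan. The fixed preprocessing chain is

1. `block_average()` — non-overlapping blocks of 10 intensity scans are
   averaged (one spectrum per ~10 s);
2. `to_absorbance()` — `A = -log10((I - dark)/(bright - dark))` with the
   per-batch bright and dark references; non-physical transmittances are
   clipped at 1e-6 and counted, never silently dropped;
3. `moving_average()` — a causal mean over the current and 74 prior
   spectra (a 750 s memory). The first 74 outputs use an expanding window
   and are flagged as warm-up rather than dropped, preserving alignment;
4. `snv()` — per-spectrum standardisation, applied only on the
   process-control branch. SNV does not improve the regression branch, so
   the moisture model uses the unstandardised absorbance.

Mean-centring is done inside the modelling functions, which store the mean
so that new spectra are centred identically at prediction time.

The 75-spectrum filter is matched to the default noise level. It has two
costs that matter downstream: a group delay of about 370 s, and a smearing
of any feature whose time scale is comparable to the window. Both are
discussed under *Known limitations*.

# Moisture regression

`fit_pls_nipals()` regresses the base-10 logarithm of the wet-basis
moisture fraction on the preprocessed spectra with the classical NIPALS
algorithm (deflation of both blocks; the weight iteration converges at
1e-10 or 500 iterations). The log transform makes the error budget
relative, which is the natural scale when moisture spans 1.5–38 wt%.
Predictions are back-transformed as `f_w = 10^(y + mean(log10 f_w))`;
base 10 is used consistently for the transform and back-transform.

Calibration pairs each loss-on-drying (LOD) reference sample with the
preprocessed spectrum nearest in time (at most 30 s away). The number of
latent variables is chosen by contiguous-block cross-validation with the
one-standard-error rule (`select_n_lv()`): contiguous blocks respect the
time ordering of the spectra and avoid leakage between strongly
autocorrelated neighbours, and the one-SE rule keeps the model from
chasing noise. The error metric is the root-mean-square relative
deviation, `relative_error()`, reported in percent.

The NIPALS implementation is verified in the test suite against an
independent SIMPLS oracle (a different algebra for the same projection) to
1e-8 on random problems.

# End-point detection

`build_mspc()` fits a PCA model (by SVD) to end-point spectra — all
preprocessed, SNV-treated spectra of normal-operating-condition (NOC)
batches whose reference moisture is below the 2% end-point criterion. The
model order is chosen by row-wise cross-validated PRESS with element-wise
deletion: held-out rows have interleaved coordinate groups predicted from
the remaining coordinates through the training loadings. (Plain projection
PRESS decreases monotonically with the order and cannot select anything;
element-wise deletion restores a minimum.)

A new spectrum is scored by its squared residual off the model plane
(`q_statistic()`), and control limits come from the Jackson–Mudholkar
closed form on the residual eigenvalues (`jm_limit()`). For heavily skewed
residual spectra the JM exponent `h0` can turn negative, where the formula
loses monotonicity in the confidence level; the limit then falls back to
the two-moment chi-square approximation `g·chi²_h` with `g = θ2/θ1`,
`h = θ1²/θ2`, which is exact for equal eigenvalues and always monotone.
Both routes are validated against Monte-Carlo quantiles in the tests, and
the 95% limit holds an empirical false-alarm rate of 5% ± 1% on Gaussian
nulls.

The end-point rule (`detect_endpoint()`) fires on the first run of 10
consecutive observations below the 95% limit. The reported time stamp is
the *first* observation of that run; the conservative alternative (the
observation completing the run) is available via `report = "last"`.

A practical observation reproduced by the synthetic studies: each batch
carries its own slowly varying residual structure (the moving average makes
the noise within a batch strongly autocorrelated), so an MSPC model built
from too few NOC batches puts the Q floor of a *fresh* batch above the
limit and never detects anything. Seven NOC batches — the package's
default study design — make detection reliable; a marginal batch whose
equilibrium moisture sits just under 2% can still legitimately go
undetected.

# Sorption thermodynamics

Water activity links the measured moisture to the vapour-phase driving
force. Each excipient follows a GAB isotherm (`gab_content()`), inverted
analytically through a quadratic in `k_w·a_w` (`water_activity()`); dry-basis
contents above the isotherm's capacity at `a_w = 1` map to `a_w = 1`, the
free-water regime, which reproduces the constant-rate/falling-rate
transition. Assuming the materials adsorb independently,
`aggregate_isotherm()` sums the mass-weighted component isotherms per unit
adsorbing mass (cellulose, hypromellose, croscarmellose — 118 g per batch;
mannitol contributes its small uptake to the numerator but not the
denominator) on an activity grid of 0.02–0.94, then refits one GAB curve so
the granule can be treated as a single pseudo-material. Saturated vapour
pressure uses an Antoine-type correlation anchored at 2339.1 Pa at 20 °C
(`vapor_pressure()`), within 1 Pa of the steam tables over the working
range, and `equilibrium_concentration()` applies the ideal-gas law with
R = 8.314 J/(mol·K) and temperatures in kelvin.

# Mass-transfer resistance analysis

The drying rate is obtained by converting the moisture trajectory to the
molar water inventory and differentiating with a 72-point (±36, 720 s)
windowed linear regression (`drying_rate()`), which also reports the
slope's standard error; edge points use truncated windows and are flagged.
The rate fraction

`f_MTR = Ndot_w / ((1 - S_in) · C_S*(T_bed, a_w) · φ_g)`

compares the measured rate with the thermodynamic maximum (outlet
saturated). Inverting the plug-flow bed balance gives the total resistance

`Ω_tot = -m_s / (ln(1 - f_MTR) · f_s · ρ_s · φ_g)`,

with solids volume fraction `f_s = 0.40` and skeletal density
`ρ_s = 1500 kg/m³` as defaults; the closed form is verified against direct
numerical integration of the bed balance in the tests. `f_MTR` is clipped
to (1e-6, 1−1e-6) before the logarithm and clipped points are excluded
from any fit.

`fit_resistance()` parametrises the observed curve as a constant external
(gas-film) resistance plus an internal resistance that decays
exponentially with dry-basis moisture:
`Ω_tot = Ω_ext + Ω_max·exp(-(F_w - F_w,end)/F_w,crit)`. The fit minimises
squared error in `log10 Ω` — the curve spans two orders of magnitude, and a
linear-space fit would ignore the external plateau — with `F_w,end` fixed
to the final observed moisture and a multi-start over the critical-moisture
scale.

## The inlet-humidity question

`f_MTR` needs the inlet water concentration. When the drying record
carries a measured value (the synthetic runs always do), `analyze_run()`
uses it. When it does not, `estimate_inlet_concentration()` anchors it by
assuming the outlet air is saturated at the time of the maximum smoothed
drying rate. That assumption deserves a warning: it forces the estimated
`f_MTR` to exactly 1 at that time point, so on a flat constant-rate
plateau — where the outlet is *not* truly saturated — every plateau point
clips at the `f_MTR` ceiling and the external resistance becomes
unidentifiable. The estimator is therefore reliable only when the bed
genuinely saturates the gas (small `Ω_ext`, low flow), which is what its
tests exercise; with a measured inlet humidity the full resistance curve is
identified. This is why `analyze_run()` prefers the known value.

# The synthetic batch generator

`simulate_drying()` integrates the molar water inventory with explicit
Euler steps (dt ≤ 1 s; the dynamics are minutes-scale) using the same
resistance model the analysis fits, so parameter recovery is a genuine
round trip. The bed temperature solves the quasi-steady energy balance
`φ_g·c_air·(T_in - T_bed) = Ndot_w·ΔH_vap` by damped fixed-point iteration
(relaxation 0.5, tolerance 1e-6 °C, at most 100 iterations — the undamped
map has slope < −1 at the operating point and oscillates). Latent heat
44,000 J/mol and volumetric air heat capacity 1,200 J/(m³·K) are standard
values; with the default parameters they reproduce the observed ~10 °C
evaporative bed-temperature depression, a ~0.17 mol/min plateau drying
rate, and a 600 L/min batch that reaches 5 wt% in just under an hour and
equilibrates below 2 wt% within 90 minutes.

`generate_spectra()` maps the moisture state to raw intensity scans. The
true absorbance is a Gaussian water band near 1940 nm on a linear
baseline. Two deliberate, physically motivated nonlinearities make the
spectra realistic for a *log-scale* regression target:

* the band amplitude saturates with moisture,
  `apm·γ·ln(1 + f_w/γ)` with γ = 0.01 (diffuse-reflectance response
  compresses at high water loadings; `γ → ∞` recovers a linear response);
* the band centre shifts with bed temperature by 0.5 nm/K (the water -OH
  combination band is temperature sensitive).

A strictly linear amplitude would make the noise-free spectra an exactly
rank-one linear manifold in `f_w`, and no linear PLS on `log10 f_w` could
track the trajectory to within a few percent — the measured floor is ~30%
with 2 latent variables. With the saturating response the same pipeline
reaches a 2–4% error floor, matching how log-moisture PLS behaves on real
reflectance data.

Measurement artefacts are each independently switchable: per-scan
lognormal gain (default sd 0.05), additive detector noise (50 counts
against a 500-count dark level and 20,000-count bright level), air-gap
dropout scans (probability 0.01/scan), and transient window fouling while
the granules are wet (`f_w > 0.2`), decaying exponentially by particle
self-cleaning. LOD sampling emulates the manual protocol: one sample every
400 s with 2% relative gravimetric noise. Batch-to-batch variation draws
the initial moisture from 33–38 wt% and the ambient inlet humidity from
20–40% RH.

What the generator does *not* emulate: particle-size change and attrition
fines, scattering drift with granule shrinkage, probe repositioning between
batches, and humidity drift within a batch. Passing tests therefore show
the algorithms are correct and well-calibrated for this noise model, not
that the accuracy figures transfer to any particular instrument.

# Numerical choices and degenerate inputs

* Bed-temperature solve: damped fixed point as above; non-convergence is an
  error naming the step.
* Negative water inventory (possible at dt = 1 s in extreme configurations)
  is clamped to zero with a warning; runs stop early once the rate falls
  below 1e-9 mol/s (configurable).
* `to_absorbance()` clips transmittance at 1e-6 and records the count;
  `snv()` refuses zero-variance spectra, naming the row.
* GAB fitting multi-starts over C ∈ {1, 10, 100} and k ∈ {0.5, 0.8, 0.95};
  the resistance fit multi-starts over F_w,crit ∈ {0.05, 0.1, 0.2}.
* Residual eigenvalues below 1e-12 of the leading eigenvalue are truncated
  before the limit moments θ_i are formed.
* Serialization uses CSV plus JSON sidecars with 17 significant digits, so
  every model and series round-trips to machine precision.

# Study sizes used by the tests

The test suite and acceptance script run entirely on synthetic batches:
120-minute runs at 1 s resolution (7,200 scans of 401 points), three
calibration batches for the regression studies, seven NOC batches for the
control-chart studies, five validation seeds for end-point detection, and
Monte-Carlo checks with 10⁵–10⁶ draws. The complete suite runs in a few
minutes on one CPU.

# Known limitations

* **Filter smearing of the falling-rate transition.** The 750 s moving
  average smears features on its own time scale. When the *NIR-predicted*
  moisture is pushed through the resistance analysis, the external
  resistance survives (recovered within twice the relative moisture error)
  but the critical-moisture scale `F_w,crit` is systematically stretched —
  an artefact of the preprocessing, not of the fit, and invisible on real
  data where no ground truth exists. Recovery from an unfiltered noisy
  moisture trace is tight (a few percent).
* **Windowed differentiation near abrupt endings.** A batch that ends
  abruptly (no internal resistance to slow the tail) violates the local
  linearity the 720 s regression window assumes; the analysis window is a
  parameter (`half_window`) and should be shortened for fast batches.
* **The saturated-outlet inlet estimator** is structurally degenerate on a
  flat plateau, as described above.
* The simulator has no bed hydrodynamics, no particle population balance,
  and no temperature dependence of the GAB parameters.
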