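#' Molar drying rate by windowed linear regression
#'
#' Converts the moisture trajectory to the molar water inventory
#' ([moles_of_water()]) and differentiates it by fitting a straight line
#' to the `half_window` points on either side of every time point (default
#' 36, i.e. 72 points spanning 720 s at the 10 s cadence of the
#' preprocessed signal). Edge points use truncated windows and are flagged
#' low-confidence.
#'
#' @param time uniform time grid, s.
#' @param f_w wet-basis moisture trajectory on that grid.
#' @param m_s dry solids mass, kg.
#' @param half_window points on each side of the centre.
#' @return data.frame with `time`, `N_w` (mol), `Ndot_w` (mol/s, the
#'   negated slope), `slope_se` (standard error of the slope, mol/s),
#'   `rel_se` (se relative to the rate) and `edge` (truncated-window flag).
#' @export
drying_rate <- function(time, f_w, m_s, half_window = 36) {
  n <- length(time)
  stopifnot(length(f_w) == n)
  if (n <= 2 * half_window) {
    stop(sprintf("drying_rate: need more than %d points, got %d", 2 * half_window, n))
  }
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-6 * dt[1])) stop("drying_rate: time grid must be uniform")
  N_w <- moles_of_water(f_w, m_s)
  slope <- se <- numeric(n)
  edge <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half_window)
    hi <- min(n, i + half_window)
    edge[i] <- (hi - lo) < 2 * half_window
    tt <- time[lo:hi] - time[i]
    yy <- N_w[lo:hi]
    sxx <- sum((tt - mean(tt))^2)
    b1 <- sum((tt - mean(tt)) * (yy - mean(yy))) / sxx
    res <- yy - mean(yy) - b1 * (tt - mean(tt))
    m <- length(tt)
    se[i] <- if (m > 2) sqrt(sum(res^2) / (m - 2) / sxx) else NA_real_
    slope[i] <- b1
  }
  data.frame(time = time, N_w = N_w, Ndot_w = -slope, slope_se = se,
             rel_se = ifelse(slope != 0, abs(se / slope), NA_real_),
             edge = edge)
}

#' Estimate the inlet water concentration from the rate maximum
#'
#' When the inlet humidity is not measured it is anchored by assuming the
#' outlet air is saturated at the beginning of the constant-rate period:
#' at the time t0 of the maximum smoothed drying rate (the first
#' `startup_exclude` seconds are ignored),
#' \eqn{C_{g,in} = \max(0,\; C_S^*(t_0) - \dot N_w(t_0)/\varphi_g)}.
#' The estimate is only meaningful when the outlet really is close to
#' saturation there; see the package vignette for the failure mode on a
#' flat rate plateau.
#'
#' @param time,Ndot_w,C_S_star aligned vectors: time (s), measured drying
#'   rate (mol/s), equilibrium concentration (mol/m^3).
#' @param phi_g gas flow, m^3/s.
#' @param startup_exclude seconds of startup transient to skip.
#' @param smooth_window running-mean length applied to the rate before
#'   locating its maximum.
#' @return list with `c_g_in` (mol/m^3), `t0`, `index`, and `clamped`
#'   (TRUE when the raw estimate was negative and clamped to 0, with a
#'   warning).
#' @export
estimate_inlet_concentration <- function(time, Ndot_w, C_S_star, phi_g,
                                         startup_exclude = 300,
                                         smooth_window = 11) {
  stopifnot(length(time) == length(Ndot_w), length(time) == length(C_S_star))
  ok <- time > startup_exclude
  if (!any(ok)) stop("estimate_inlet_concentration: no data after the startup window (empty constant-rate region)")
  sm <- stats::filter(Ndot_w, rep(1 / smooth_window, smooth_window), sides = 2)
  sm[is.na(sm)] <- Ndot_w[is.na(sm)]
  cand <- which(ok)
  i0 <- cand[which.max(sm[cand])]
  raw <- C_S_star[i0] - Ndot_w[i0] / phi_g
  clamped <- raw < 0
  if (clamped) {
    warning("estimate_inlet_concentration: rate exceeds the saturation rate at t0; inlet concentration clamped to 0")
  }
  list(c_g_in = max(0, raw), t0 = time[i0], index = i0, clamped = clamped)
}

#' Fraction of the maximum drying rate
#'
#' \eqn{f_{MTR} = \dot N_w / \dot N_w^\infty}, the extent to which mass
#' transfer limits drying (1 = the gas leaves saturated). Values are
#' clipped to (1e-6, 1 - 1e-6) so the downstream logarithm stays finite;
#' clipped entries are flagged in the `clipped` attribute and should be
#' excluded from resistance fitting.
#'
#' @param Ndot_w measured drying rate, mol/s.
#' @param Ndot_inf maximum (saturation) drying rate
#'   \eqn{(1 - S_{in}) C_S^* \varphi_g}, mol/s; > 0.
#' @return clipped ratio with attribute `clipped` (logical).
#' @export
mtr_fraction <- function(Ndot_w, Ndot_inf) {
  stopifnot(length(Ndot_w) == length(Ndot_inf))
  if (any(Ndot_inf <= 0)) stop("mtr_fraction: Ndot_inf must be > 0")
  f <- Ndot_w / Ndot_inf
  clipped <- f <= 1e-6 | f >= 1 - 1e-6
  f <- pmin(pmax(f, 1e-6), 1 - 1e-6)
  attr(f, "clipped") <- clipped
  f
}

#' Total mass-transfer resistance from the rate fraction
#'
#' Inverts the plug-flow bed balance:
#' \deqn{\Omega_{tot} = -\frac{m_s}{\ln(1 - f_{MTR})\, f_s \rho_s \varphi_g}.}
#'
#' @param f_mtr rate fraction(s) strictly inside (0, 1).
#' @param m_s dry solids mass, kg.
#' @param f_s solids volume fraction.
#' @param rho_s skeletal density, kg/m^3.
#' @param phi_g gas flow, m^3/s.
#' @return resistance(s) in seconds.
#' @export
omega_total <- function(f_mtr, m_s, f_s, rho_s, phi_g) {
  if (any(f_mtr <= 0 | f_mtr >= 1)) stop("omega_total: f_mtr must lie strictly in (0, 1)")
  -m_s / (log(1 - f_mtr) * f_s * rho_s * phi_g)
}

#' Fit the two-term resistance model to an observed resistance curve
#'
#' Nonlinear least squares of
#' \eqn{\Omega_{tot}(F_w) = \Omega_{ext} + \Omega_{max}
#' e^{-(F_w - F_{w,end})/F_{w,crit}}} minimising the squared error in
#' log10(Omega) — the observed resistances span two orders of magnitude,
#' and a linear-space fit would ignore the external-resistance plateau.
#' `F_w_end` is fixed to the final observed moisture, not co-estimated.
#' Multi-start over the critical-moisture scale guards against local
#' minima.
#'
#' @param F_w dry-basis moisture contents (>= 10 points spanning the
#'   plateau and the rise).
#' @param omega_tot observed total resistances, s; > 0.
#' @param f_w_end the final dry-basis moisture the exponential is
#'   anchored to (default: smallest observed F_w).
#' @return a [resistance_fit] with attributes `std_errors` (log-space fit)
#'   and `residual_sd` (log10 units).
#' @export
fit_resistance <- function(F_w, omega_tot, f_w_end = min(F_w)) {
  stopifnot(length(F_w) == length(omega_tot))
  keep <- is.finite(F_w) & is.finite(omega_tot) & omega_tot > 0
  F_w <- F_w[keep]; omega_tot <- omega_tot[keep]
  if (length(F_w) < 10) stop("fit_resistance: need at least 10 valid points")
  if (diff(range(F_w)) < 0.1) stop("fit_resistance: degenerate F_w range")
  dat <- data.frame(F = F_w, ly = log10(omega_tot))
  ext0 <- unname(stats::quantile(omega_tot, 0.1))
  max0 <- max(unname(stats::quantile(omega_tot, 0.95)) - ext0, 1e-4)
  best <- NULL
  for (fc0 in c(0.05, 0.10, 0.20)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        ly ~ log10(ext + mx * exp(-(F - f_w_end) / fc)), data = dat,
        start = list(ext = ext0, mx = max0, fc = fc0),
        lower = c(1e-8, 1e-8, 1e-4), upper = c(Inf, Inf, 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("fit_resistance: no start point converged")
  co <- stats::coef(best$fit)
  out <- resistance_fit(co[["ext"]], co[["mx"]], co[["fc"]], f_w_end)
  attr(out, "std_errors") <- tryCatch(
    summary(best$fit)$coefficients[, "Std. Error"], error = function(e) NULL)
  attr(out, "residual_sd") <- sqrt(best$rss / max(1, nrow(dat) - 3))
  out
}

#' Full mass-transfer analysis of a drying run
#'
#' Chains the monitoring steps: drying-rate estimation from the moisture
#' trajectory, water activity from the aggregate isotherm, vapour pressure
#' and equilibrium concentration at the measured bed temperature, inlet
#' saturation, rate fraction, total resistance, and the two-term
#' resistance fit. The moisture signal may be the run's own trajectory
#' (downsampled to `cadence`), or any externally supplied trace on the
#' same clock — e.g. NIR-predicted moisture — via `moisture`.
#'
#' The inlet water concentration is taken from the run record when it
#' carries one (`inlet = "known"`, the default resolution of `"auto"`);
#' otherwise it is estimated by [estimate_inlet_concentration()]
#' (`inlet = "estimate"`).
#'
#' @param run a [drying_run].
#' @param isotherm aggregate [gab_params]; defaults to the run's own, or
#'   to the shipped placebo formulation's aggregate.
#' @param moisture optional data.frame with `time` (s) and `f_w`
#'   overriding the run's trajectory.
#' @param cadence sampling period of the analysed trace, s.
#' @param half_window differentiation window half-width (points).
#' @param inlet `"auto"`, `"known"` or `"estimate"`.
#' @return list of class `mtr_analysis` with `trace` (data.frame: time,
#'   f_w, F_w, a_w, P_star, C_S_star, S_in, Ndot_w, Ndot_inf, f_MTR,
#'   Omega_tot, slope_se, clipped, edge), `fit` (a [resistance_fit]),
#'   `c_g_in` and `inlet_method`.
#' @export
analyze_run <- function(run, isotherm = NULL, moisture = NULL,
                        cadence = 10, half_window = 36,
                        inlet = c("auto", "known", "estimate")) {
  stopifnot(inherits(run, "drying_run"))
  inlet <- match.arg(inlet)
  if (is.null(isotherm)) {
    isotherm <- if (!is.null(run$isotherm)) run$isotherm else {
      aggregate_isotherm(placebo_formulation())$params
    }
  }
  bed <- run$bed
  if (is.null(moisture)) {
    tgrid <- seq(cadence, max(run$time), by = cadence)
    st <- run_state_at(run, tgrid)
    moisture <- data.frame(time = tgrid, f_w = st$f_w)
  }
  tgrid <- moisture$time
  f_w <- moisture$f_w
  T_bed <- stats::approx(run$time, run$T_bed, tgrid, rule = 2)$y
  rate <- drying_rate(tgrid, f_w, bed$solids_mass, half_window)
  m_w <- bed$solids_mass * f_w / (1 - f_w)
  F_w <- m_w / bed$adsorbing_mass
  a_w <- water_activity(F_w, isotherm)
  P_star <- vapor_pressure(T_bed)
  C_S_star <- equilibrium_concentration(T_bed, a_w)
  known_cin <- bed$inlet_water_conc
  if (inlet == "auto") inlet <- if (!is.null(known_cin)) "known" else "estimate"
  if (inlet == "known") {
    if (is.null(known_cin)) stop("analyze_run: inlet = 'known' but the run records no inlet concentration")
    c_g_in <- known_cin
  } else {
    est <- estimate_inlet_concentration(tgrid, rate$Ndot_w, C_S_star, bed$phi_g)
    c_g_in <- est$c_g_in
  }
  S_in <- pmin(1, ifelse(C_S_star > 0, c_g_in / C_S_star, 1))
  Ndot_inf <- (1 - S_in) * C_S_star * bed$phi_g
  usable <- Ndot_inf > 0
  f_mtr <- rep(NA_real_, length(tgrid))
  clipped <- rep(TRUE, length(tgrid))
  fm <- mtr_fraction(rate$Ndot_w[usable], Ndot_inf[usable])
  f_mtr[usable] <- fm
  clipped[usable] <- attr(fm, "clipped")
  omega <- rep(NA_real_, length(tgrid))
  ok <- usable & !clipped
  omega[ok] <- omega_total(f_mtr[ok], bed$solids_mass, bed$solids_fraction,
                           bed$skeletal_density, bed$phi_g)
  trace <- data.frame(time = tgrid, f_w = f_w, F_w = F_w, a_w = a_w,
                      P_star = P_star, C_S_star = C_S_star, S_in = S_in,
                      Ndot_w = rate$Ndot_w, Ndot_inf = Ndot_inf,
                      f_MTR = f_mtr, Omega_tot = omega,
                      slope_se = rate$rel_se, clipped = clipped,
                      edge = rate$edge)
  fit_pts <- ok & !rate$edge
  f_w_end <- min(F_w[fit_pts])
  fit <- fit_resistance(F_w[fit_pts], omega[fit_pts], f_w_end)
  structure(list(trace = trace, fit = fit, c_g_in = c_g_in,
                 inlet_method = inlet),
            class = "mtr_analysis")
}

#' @export
print.mtr_analysis <- function(x, ...) {
  cat(sprintf("mtr_analysis: %d time points (%d in the resistance fit), inlet %s (C_g,in = %.4g mol/m^3)\n",
              nrow(x$trace), sum(!x$trace$clipped & !x$trace$edge, na.rm = TRUE),
              x$inlet_method, x$c_g_in))
  print(x$fit)
  invisible(x)
}
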