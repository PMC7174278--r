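#' GAB sorption-isotherm parameters
#'
#' Container for the three Guggenheim-Andersen-de Boer parameters of one
#' material, plus its name and mass in the formulation. The GAB model is a
#' three-parameter extension of BET relating dry-basis water content to
#' water activity.
#'
#' @param m_o monolayer capacity, g water per g solid; > 0.
#' @param C_GAB dimensionless energy constant; > 0.
#' @param k_w dimensionless; in (0, 1] so the isotherm stays finite on
#'   a_w in \[0, 1).
#' @param name material name.
#' @param mass mass of the material in the formulation, g (optional).
#' @return an object of class `gab_params`.
#' @export
gab_params <- function(m_o, C_GAB, k_w, name = "material", mass = NA_real_) {
  stopifnot(is.numeric(m_o), is.numeric(C_GAB), is.numeric(k_w))
  if (m_o <= 0) stop("gab_params: m_o must be > 0")
  if (C_GAB <= 0) stop("gab_params: C_GAB must be > 0")
  if (k_w <= 0 || k_w > 1) stop("gab_params: k_w must lie in (0, 1]")
  structure(list(m_o = m_o, C_GAB = C_GAB, k_w = k_w,
                 name = name, mass = mass),
            class = "gab_params")
}

#' @export
print.gab_params <- function(x, ...) {
  cat(sprintf("GAB isotherm '%s': m_o = %.4g g/g, C = %.4g, k_w = %.4g",
              x$name, x$m_o, x$C_GAB, x$k_w))
  if (!is.na(x$mass)) cat(sprintf(", mass = %.4g g", x$mass))
  cat("\n")
  invisible(x)
}

#' Dry-basis water content from the GAB isotherm
#'
#' \deqn{F_w(a_w) = \frac{k a C m_o}{(1 - k a)(1 + (C - 1) k a)}}
#'
#' @param a_w water activity; must satisfy 0 <= a_w < 1/k_w.
#' @param p a [gab_params] object.
#' @return water content, g water / g solid (vectorised over `a_w`).
#' @export
gab_content <- function(a_w, p) {
  stopifnot(inherits(p, "gab_params"), is.numeric(a_w))
  if (any(a_w < 0) || any(a_w >= 1 / p$k_w)) {
    stop(sprintf("gab_content: a_w must lie in [0, %.4g) for k_w = %.4g",
                 1 / p$k_w, p$k_w))
  }
  u <- p$k_w * a_w
  u * p$C_GAB * p$m_o / ((1 - u) * (1 + (p$C_GAB - 1) * u))
}

#' Water activity from dry-basis water content (GAB inversion)
#'
#' Inverts [gab_content()] by solving the quadratic in u = k_w a_w:
#' \deqn{-F (C-1) u^2 + (F (C-2) - C m_o) u + F = 0.}
#' Contents above the isotherm's capacity at a_w = 1 are mapped to
#' a_w = 1 (free-water regime: liquid water present beyond what the
#' solids can adsorb).
#'
#' @param F_w dry-basis water content, g/g; >= 0.
#' @param p a [gab_params] object.
#' @return water activity in \[0, 1\] (vectorised over `F_w`).
#' @export
water_activity <- function(F_w, p) {
  stopifnot(inherits(p, "gab_params"), is.numeric(F_w))
  if (any(F_w < 0)) stop("water_activity: F_w must be >= 0")
  cap <- gab_content(1, p)
  vapply(F_w, function(F) {
    if (F == 0) return(0)
    if (F >= cap) return(1)
    qa <- -F * (p$C_GAB - 1)
    qb <- F * (p$C_GAB - 2) - p$C_GAB * p$m_o
    qc <- F
    disc <- qb^2 - 4 * qa * qc
    if (disc < 0) {
      stop(sprintf("water_activity: no real root for F_w = %.6g (m_o=%.4g, C=%.4g, k_w=%.4g)",
                   F, p$m_o, p$C_GAB, p$k_w))
    }
    u <- c((-qb + sqrt(disc)) / (2 * qa), (-qb - sqrt(disc)) / (2 * qa))
    u <- u[u > 0 & u < 1]
    if (length(u) == 0) {
      stop(sprintf("water_activity: no root in (0,1) for F_w = %.6g (m_o=%.4g, C=%.4g, k_w=%.4g)",
                   F, p$m_o, p$C_GAB, p$k_w))
    }
    u[1] / p$k_w
  }, numeric(1))
}

#' Fit GAB parameters to isotherm data
#'
#' Nonlinear least squares on the water content, with a multi-start over
#' C in \{1, 10, 100\} and k_w in \{0.5, 0.8, 0.95\} to avoid the local
#' minima the GAB surface is known for. Unweighted by default.
#'
#' @param a_grid water activities (< 1), at least 3 points.
#' @param F_values observed dry-basis water contents, same length.
#' @param weights optional nonnegative weights.
#' @return a [gab_params] object with attributes `residual_sd` and
#'   `std_errors` (named vector, when the fit provides them).
#' @export
fit_gab <- function(a_grid, F_values, weights = NULL) {
  stopifnot(is.numeric(a_grid), is.numeric(F_values),
            length(a_grid) == length(F_values))
  if (length(a_grid) < 3) stop("fit_gab: at least 3 points are required")
  if (any(a_grid >= 1) || any(a_grid < 0)) stop("fit_gab: a_grid must lie in [0, 1)")
  if (is.null(weights)) weights <- rep(1, length(a_grid))
  dat <- data.frame(a = a_grid, F = F_values, w = weights)
  gabfun <- function(a, m_o, C, k) {
    u <- k * a
    u * C * m_o / ((1 - u) * (1 + (C - 1) * u))
  }
  best <- NULL
  for (C0 in c(1, 10, 100)) for (k0 in c(0.5, 0.8, 0.95)) {
    m00 <- max(mean(F_values) / 2, 1e-4)
    fit <- tryCatch(
      minpack.lm::nlsLM(F ~ gabfun(a, m_o, C, k), data = dat, weights = dat$w,
                        start = list(m_o = m00, C = C0, k = k0),
                        lower = c(1e-8, 1e-6, 1e-6), upper = c(10, 1e5, 1),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2 * dat$w)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("fit_gab: no start point converged")
  co <- stats::coef(best$fit)
  out <- gab_params(co[["m_o"]], co[["C"]], min(co[["k"]], 1), name = "fitted")
  attr(out, "residual_sd") <- sqrt(best$rss / max(1, length(a_grid) - 3))
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  attr(out, "std_errors") <- se
  out
}

#' Granule formulation: components and their sorption behaviour
#'
#' @param components list of [gab_params] objects, each with a `mass` (g).
#' @param adsorbing character vector naming the components whose combined
#'   mass defines `m_adsorb`, the denominator of the dry-basis moisture
#'   F_w = m_w / m_adsorb. All components still contribute their uptake to
#'   the aggregate isotherm numerator.
#' @return object of class `formulation` with fields `components`,
#'   `adsorbing`, `m_adsorb` (g) and `m_total` (g).
#' @export
formulation <- function(components, adsorbing) {
  stopifnot(is.list(components), length(components) >= 1)
  nm <- vapply(components, function(p) p$name, character(1))
  masses <- vapply(components, function(p) p$mass, numeric(1))
  if (any(is.na(masses)) || any(masses <= 0)) {
    stop("formulation: every component needs a positive mass")
  }
  if (!all(adsorbing %in% nm)) {
    stop("formulation: adsorbing subset names unknown components: ",
         paste(setdiff(adsorbing, nm), collapse = ", "))
  }
  if (length(adsorbing) == 0) stop("formulation: adsorbing subset is empty")
  structure(list(components = components, adsorbing = adsorbing,
                 m_adsorb = sum(masses[nm %in% adsorbing]),
                 m_total = sum(masses)),
            class = "formulation")
}

#' @export
print.formulation <- function(x, ...) {
  cat(sprintf("Formulation: %d components, m_total = %.4g g, m_adsorb = %.4g g\n",
              length(x$components), x$m_total, x$m_adsorb))
  for (p in x$components) {
    cat(sprintf("  %-18s %6.4g g  (m_o=%.4g, C=%.4g, k_w=%.4g)%s\n",
                p$name, p$mass, p$m_o, p$C_GAB, p$k_w,
                if (p$name %in% x$adsorbing) "  [adsorbing]" else ""))
  }
  invisible(x)
}

#' The placebo granule formulation shipped with the package
#'
#' Loads the per-material GAB parameters and dry-basis masses of the
#' placebo formulation (mannitol, microcrystalline cellulose, hypromellose,
#' croscarmellose sodium) from the JSON file under `inst/extdata`. The
#' adsorbing subset (cellulose, hypromellose, croscarmellose) sums to
#' 118 g per batch.
#'
#' @param path optional path to an alternative formulation JSON file.
#' @return a [formulation] object.
#' @export
placebo_formulation <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "placebo_formulation.json", package = "granudry")
  }
  read_formulation(path)
}

#' Read a formulation from JSON
#'
#' @param path JSON file with fields `components` (array of objects with
#'   `name`, `mass_g`, `m_o`, `C_GAB`, `k_w`) and `adsorbing` (array of names).
#' @return a [formulation] object.
#' @export
read_formulation <- function(path) {
  if (!file.exists(path)) stop("read_formulation: file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  comps <- lapply(j$components, function(cj) {
    gab_params(cj$m_o, cj$C_GAB, cj$k_w, name = cj$name, mass = cj$mass_g)
  })
  formulation(comps, unlist(j$adsorbing))
}

#' Aggregate sorption isotherm of a formulation
#'
#' Assuming the materials adsorb independently, the water held by the
#' granule at a given activity is the mass-weighted sum of the component
#' isotherms. Expressed per mass of the adsorbing excipients:
#' \deqn{F_w(a) = \sum_i m_i\, F_{w,i}(a) / m_{adsorb}.}
#' A single GAB curve is then fitted to the tabulated aggregate so the
#' granule can be treated as one pseudo-material downstream.
#'
#' @param f a [formulation] object.
#' @param grid water activities to tabulate; default 0.02 to 0.94 step 0.02.
#' @return list with `table` (data.frame of a_w, F_w) and `params`
#'   (fitted [gab_params] for the aggregate).
#' @export
aggregate_isotherm <- function(f, grid = seq(0.02, 0.94, by = 0.02)) {
  stopifnot(inherits(f, "formulation"))
  if (any(grid < 0) || any(grid > 0.95)) {
    stop("aggregate_isotherm: grid must lie within [0, 0.95]")
  }
  Fw <- vapply(grid, function(a) {
    sum(vapply(f$components, function(p) p$mass * gab_content(a, p), numeric(1)))
  }, numeric(1)) / f$m_adsorb
  params <- fit_gab(grid, Fw)
  params$name <- "aggregate"
  params$mass <- f$m_adsorb
  list(table = data.frame(a_w = grid, F_w = Fw), params = params)
}
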