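#' Saturated vapour pressure of water
#'
#' Antoine-type correlation expressed relative to the vapour pressure at a
#' reference temperature of 20 degC, where it returns 2339.1 Pa exactly:
#' \deqn{P^*(T) = 2339.1\, e^{-4078.8 (1/(236.63+T) - 1/256.63)}}
#'
#' @param temp_c temperature in degrees Celsius; valid between -50 and 150.
#' @return saturated vapour pressure in Pa (vectorised over `temp_c`).
#' @examples
#' vapor_pressure(20)   # 2339.1
#' vapor_pressure(25)   # ~3169 Pa, the steam-table value
#' @export
vapor_pressure <- function(temp_c) {
  stopifnot(is.numeric(temp_c))
  if (any(temp_c <= -50 | temp_c >= 150)) {
    stop("vapor_pressure: temperature outside the correlation's validity range (-50, 150) degC")
  }
  2339.1 * exp(-4078.8 * (1 / (236.63 + temp_c) - 1 / 256.63))
}

#' Equilibrium water concentration in the gas phase
#'
#' Ideal-gas concentration in equilibrium with moist solids at water
#' activity `a_w` and bed temperature `temp_c`:
#' \eqn{C_S^* = a_w P^*(T) / (R T)} with T in kelvin and R = 8.314 J/(mol K).
#'
#' @param temp_c bed temperature, degC.
#' @param a_w water activity in \[0, 1\].
#' @return concentration in mol/m^3.
#' @export
equilibrium_concentration <- function(temp_c, a_w) {
  stopifnot(is.numeric(a_w))
  if (any(a_w < 0 | a_w > 1)) stop("equilibrium_concentration: a_w must lie in [0, 1]")
  a_w * vapor_pressure(temp_c) / (8.314 * (temp_c + 273.15))
}

#' Moles of water held by the bed
#'
#' Converts a wet-basis moisture fraction to the molar water inventory:
#' \eqn{N_w = m_s f_w / ((1 - f_w)\, 0.018)} with the dry solids mass
#' `m_s` in kg and the molar mass of water 0.018 kg/mol.
#'
#' @param f_w wet-basis moisture mass fraction, in \[0, 1).
#' @param m_s dry solids mass, kg.
#' @return moles of water (vectorised over `f_w`).
#' @export
moles_of_water <- function(f_w, m_s) {
  stopifnot(is.numeric(f_w), is.numeric(m_s), m_s > 0)
  if (any(f_w < 0 | f_w >= 1)) stop("moles_of_water: f_w must lie in [0, 1)")
  m_s * f_w / ((1 - f_w) * 0.018)
}
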