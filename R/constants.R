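# Physical constants (SI, CODATA 2018) used by the PRE and relaxation models.
.const <- list(
  mu0_over_4pi = 1e-7,              # T m / A
  gamma_h      = 2.6752218744e8,    # 1H gyromagnetic ratio, rad s^-1 T^-1
  gamma_n15    = 2.7116e7,          # |15N| gyromagnetic ratio, rad s^-1 T^-1
  g_e          = 2.00231930436,     # free-electron g factor
  mu_b         = 9.2740100783e-24,  # Bohr magneton, J T^-1
  hbar         = 1.054571817e-34,   # J s
  kb_si        = 1.380649e-23,      # J K^-1
  n_avogadro   = 6.02214076e23,     # mol^-1
  kb_kcal      = 1.987204259e-3     # kcal mol^-1 K^-1
)

# Dynamic viscosity of light water, mPa s, 0-100 C at 5 C steps (standard
# reference values).  Linear interpolation between entries.
.h2o_visc_table <- data.frame(
  temp_c = seq(0, 100, by = 5),
  eta    = c(1.792, 1.519, 1.307, 1.138, 1.002, 0.890, 0.797, 0.719, 0.653,
             0.596, 0.547, 0.504, 0.466, 0.433, 0.404, 0.378, 0.354, 0.334,
             0.315, 0.298, 0.282)
)

# Heavy-to-light water viscosity ratio anchors; D2O is more viscous and the
# ratio decays slowly with temperature.  Interpolated linearly.
.d2o_ratio_table <- data.frame(
  temp_c = c(5, 10, 20, 25, 30, 40, 50, 75, 100),
  ratio  = c(1.265, 1.256, 1.244, 1.230, 1.216, 1.204, 1.192, 1.170, 1.155)
)

#' Solvent viscosity lookup
#'
#' Dynamic viscosity of light or heavy water at a given temperature, from
#' embedded reference tables with linear interpolation (1 degree resolution is
#' ample for correlation-time rescaling).
#'
#' @param temperature_k temperature in Kelvin (scalar or vector); must lie in
#'   273.15-373.15 K for `"water"` and 278.15-373.15 K for `"heavy_water"`.
#' @param solvent `"water"` (H2O) or `"heavy_water"` (D2O).
#' @return viscosity in mPa s.
#' @export
#' @examples
#' solvent_viscosity(298.15)                 # ~0.89 mPa s
#' solvent_viscosity(298.15, "heavy_water")  # ~1.10 mPa s
solvent_viscosity <- function(temperature_k, solvent = c("water", "heavy_water")) {
  solvent <- match.arg(solvent)
  t_c <- temperature_k - 273.15
  lo <- if (solvent == "water") 0 else 5
  if (any(!is.finite(t_c)) || any(t_c < lo - 1e-9) || any(t_c > 100 + 1e-9))
    stop("temperature outside the tabulated range (", lo, "-100 C) for ", solvent)
  eta <- approx(.h2o_visc_table$temp_c, .h2o_visc_table$eta, xout = pmin(pmax(t_c, 0), 100))$y
  if (solvent == "heavy_water") {
    r <- approx(.d2o_ratio_table$temp_c, .d2o_ratio_table$ratio,
                xout = pmin(pmax(t_c, 5), 100))$y
    eta <- eta * r
  }
  eta
}
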