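# Rotational correlation times: TRACT rate differences, Stokes-Einstein-Debye
# hydrodynamics, and temperature/viscosity rescaling.

#' Amide spin parameters for TRACT
#'
#' Conventional constants for the 15N-1H cross-correlated relaxation model:
#' N-H bond length, 15N CSA magnitude and the angle between the CSA principal
#' axis and the dipolar vector.
#'
#' @param proton_frequency_mhz 1H Larmor frequency (MHz).
#' @param r_nh N-H bond length (A).
#' @param csa_n 15N chemical shift anisotropy (ppm).
#' @param csa_dipole_angle angle between CSA axis and N-H vector (degrees).
#' @return object of class `spin_params`.
#' @export
spin_params <- function(proton_frequency_mhz = 850, r_nh = 1.02,
                        csa_n = 160, csa_dipole_angle = 17) {
  stopifnot(proton_frequency_mhz > 0, r_nh > 0, csa_n > 0,
            csa_dipole_angle >= 0)
  structure(list(proton_frequency_mhz = proton_frequency_mhz, r_nh = r_nh,
                 csa_n = csa_n, csa_dipole_angle = csa_dipole_angle),
            class = "spin_params")
}

#' Correlation-time container
#'
#' @param tau_c_ns correlation time (ns), > 0.
#' @param temperature temperature (K).
#' @param viscosity solvent viscosity (mPa s) if known.
#' @param provenance `"tract"`, `"hydrodynamic"` or `"rescaled"`.
#' @return object of class `correlation_time`.
#' @export
correlation_time <- function(tau_c_ns, temperature = NA_real_,
                             viscosity = NA_real_,
                             provenance = c("tract", "hydrodynamic", "rescaled")) {
  provenance <- match.arg(provenance)
  stopifnot(is.finite(tau_c_ns), tau_c_ns > 0)
  structure(list(tau_c_ns = tau_c_ns, temperature = temperature,
                 viscosity = viscosity, provenance = provenance),
            class = "correlation_time")
}

#' @export
print.correlation_time <- function(x, ...) {
  cat(sprintf("<correlation_time> %.2f ns (%s", x$tau_c_ns, x$provenance))
  if (is.finite(x$temperature)) cat(sprintf(", %.1f K", x$temperature))
  cat(")\n")
  invisible(x)
}

#' Transverse N-H dipole / 15N-CSA cross-correlated rate
#'
#' Rigid isotropic rotor: eta_xy = p d (3 cos^2 theta - 1)/2
#' (4 J(0) + 3 J(omegaN)) with J(w) = (2/5) tau_c / (1 + w^2 tau_c^2),
#' p = mu0 gammaH gammaN hbar / (8 pi sqrt(2) r_NH^3) and
#' d = gammaN B0 Delta-sigma / (3 sqrt(2)).  The TROSY and anti-TROSY
#' linewidths differ by 2 eta_xy.
#'
#' @param tau_c_ns correlation time(s) in ns.
#' @param sp a [spin_params].
#' @return eta_xy in s^-1; strictly increasing in tau_c.
#' @export
eta_xy <- function(tau_c_ns, sp = spin_params()) {
  tau <- tau_c_ns * 1e-9
  b0 <- 2 * pi * sp$proton_frequency_mhz * 1e6 / .const$gamma_h
  omega_n <- .const$gamma_n15 * b0
  jw <- function(w) (2 / 5) * tau / (1 + (w * tau)^2)
  p <- 4 * pi * .const$mu0_over_4pi * .const$gamma_h * .const$gamma_n15 *
    .const$hbar / (8 * pi * sqrt(2) * (sp$r_nh * 1e-10)^3)
  d <- .const$gamma_n15 * b0 * sp$csa_n * 1e-6 / (3 * sqrt(2))
  th <- sp$csa_dipole_angle * pi / 180
  p * d * (3 * cos(th)^2 - 1) / 2 * (4 * jw(0) + 3 * jw(omega_n))
}

#' Fit TRACT decay rates
#'
#' Independent mono-exponential fits I(t) = I0 exp(-R t) to the TROSY
#' (slowly relaxing, alpha) and anti-TROSY (fast, beta) 1D decays.
#'
#' @param delays relaxation delays (s), >= 5 points each.
#' @param trosy,antitrosy intensity series.
#' @return list with `r_alpha`, `r_beta` (s^-1) and the two `nls` fits.
#' @export
fit_tract_rates <- function(delays, trosy, antitrosy) {
  if (length(delays) < 5) stop("need at least 5 delay points")
  fit1 <- .fit_monoexp(delays, trosy)
  fit2 <- .fit_monoexp(delays, antitrosy)
  list(r_alpha = fit1$r, r_beta = fit2$r, fit_alpha = fit1$fit,
       fit_beta = fit2$fit)
}

.fit_monoexp <- function(t, y) {
  stopifnot(length(t) == length(y))
  pos <- y > 0
  if (sum(pos) >= 2) {
    ll <- lm(log(y[pos]) ~ t[pos])
    r0 <- max(-coef(ll)[2], 1e-3)
    i0 <- exp(coef(ll)[1])
  } else {
    r0 <- 1 / max(t)
    i0 <- max(abs(y))
  }
  df <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ i0 * exp(-r * t), data = df,
                      start = list(i0 = i0, r = r0)),
    error = function(e) stop("mono-exponential fit failed: ",
                             conditionMessage(e)))
  list(r = unname(coef(fit)["r"]), i0 = unname(coef(fit)["i0"]), fit = fit)
}

#' Correlation time from a TRACT rate difference
#'
#' Solves Delta-R = R_beta - R_alpha = 2 eta_xy(tau_c) for tau_c by monotone
#' bracketing root-finding over 0.001-1000 ns.
#'
#' @param delta_r rate difference in s^-1, > 0.
#' @param sp a [spin_params].
#' @param temperature temperature (K) recorded on the result.
#' @return a [correlation_time] with provenance `"tract"`.
#' @export
rates_to_tauc <- function(delta_r, sp = spin_params(), temperature = 298.15) {
  if (!is.finite(delta_r) || delta_r <= 0) stop("delta_r must be positive")
  f <- function(tc_ns) 2 * eta_xy(tc_ns, sp) - delta_r
  lo <- 1e-3; hi <- 1e3
  if (f(hi) < 0) stop("delta_r outside the invertible range (too large)")
  root <- uniroot(f, c(lo, hi), tol = 1e-12)
  correlation_time(root$root, temperature = temperature, provenance = "tract")
}

#' Stokes-Einstein-Debye correlation time
#'
#' Hydrated-sphere estimate: r = (3 M vbar / (4 pi NA))^(1/3) + shell,
#' tau_c = 4 pi eta r^3 / (3 kB T).
#'
#' @param mw_kda molecular weight (kDa).
#' @param v_bar partial specific volume (cm^3/g).
#' @param hydration_shell hydration shell thickness (A).
#' @param temperature temperature (K).
#' @param viscosity solvent viscosity (mPa s); default from the light-water
#'   table at `temperature`.
#' @return a [correlation_time] with provenance `"hydrodynamic"`.
#' @export
#' @examples
#' sed_tauc(21)  # ~9 ns for a 21-kDa protein at 25 C in H2O
sed_tauc <- function(mw_kda, v_bar = 0.73, hydration_shell = 3.2,
                     temperature = 298.15,
                     viscosity = solvent_viscosity(temperature)) {
  stopifnot(mw_kda > 0, v_bar > 0, hydration_shell >= 0, temperature > 0,
            viscosity > 0)
  m_g <- mw_kda * 1000                                     # g/mol
  vol_m3 <- m_g * (v_bar * 1e-6) / .const$n_avogadro       # m^3 per molecule
  r_m <- (3 * vol_m3 / (4 * pi))^(1 / 3) + hydration_shell * 1e-10
  tau_s <- 4 * pi * (viscosity * 1e-3) * r_m^3 / (3 * .const$kb_si * temperature)
  correlation_time(tau_s * 1e9, temperature = temperature,
                   viscosity = viscosity, provenance = "hydrodynamic")
}

#' Rescale a correlation time across temperature and solvent viscosity
#'
#' tau_c(T2) = tau_c(T1) (eta(T2)/eta(T1)) (T1/T2), with viscosities from the
#' embedded light/heavy-water tables or supplied explicitly.
#'
#' @param tc a [correlation_time] or a tau_c value in ns.
#' @param t_from,t_to temperatures in K.
#' @param viscosity_model `"water"`, `"heavy_water"`, or a numeric pair
#'   `c(eta_from, eta_to)` in mPa s.
#' @return a [correlation_time] with provenance `"rescaled"`.
#' @export
#' @examples
#' rescale_tauc(34, 318.15, 298.15)  # ~54 ns: 34 ns at 45 C seen at 25 C
rescale_tauc <- function(tc, t_from, t_to, viscosity_model = "water") {
  tau <- if (inherits(tc, "correlation_time")) tc$tau_c_ns else tc
  stopifnot(is.finite(tau), tau > 0, t_from > 0, t_to > 0)
  if (is.numeric(viscosity_model)) {
    stopifnot(length(viscosity_model) == 2, all(viscosity_model > 0))
    eta_from <- viscosity_model[1]; eta_to <- viscosity_model[2]
  } else {
    eta_from <- solvent_viscosity(t_from, viscosity_model)
    eta_to <- solvent_viscosity(t_to, viscosity_model)
  }
  correlation_time(tau * (eta_to / eta_from) * (t_from / t_to),
                   temperature = t_to, viscosity = eta_to,
                   provenance = "rescaled")
}
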