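# Membrane PRE back-calculation: Solomon-Bloembergen r^-6 relaxation from a
# planar distribution of laterally mobile nitroxide labels, closed form and
# brute-force lattice-sum oracle, intensity ratios and Eq.-style errors.

#' Spin-label layer geometry
#'
#' Describes the planar distribution of nitroxide labels below the phosphate
#' plane.  With 5 mol% doxyl-PC at an area per lipid of 65 A^2 the default
#' area density is 0.05/65 ~ 7.7e-4 labels/A^2; the 5-doxyl position puts the
#' nitroxide midplane ~8 A below the phosphate plane.  The trans leaflet adds
#' a second label plane `bilayer_phosphate_separation - label_depth_d` below
#' the cis phosphate plane.
#'
#' @param label_depth_d depth (A) of the nitroxide midplane below the cis
#'   phosphate plane (positive = into the membrane).
#' @param area_density_sigma labels per A^2.
#' @param include_trans_leaflet add the mirror label plane of the far leaflet.
#' @param bilayer_phosphate_separation distance (A) between the two phosphate
#'   planes.
#' @return object of class `spin_label_layer`.
#' @export
spin_label_layer <- function(label_depth_d = 8,
                             area_density_sigma = 0.05 / 65,
                             include_trans_leaflet = TRUE,
                             bilayer_phosphate_separation = 38) {
  stopifnot(area_density_sigma >= 0, is.finite(label_depth_d))
  if (include_trans_leaflet && bilayer_phosphate_separation <= 0)
    stop("bilayer_phosphate_separation must be positive with a trans leaflet")
  structure(list(label_depth_d = label_depth_d,
                 area_density_sigma = area_density_sigma,
                 include_trans_leaflet = include_trans_leaflet,
                 bilayer_phosphate_separation = bilayer_phosphate_separation),
            class = "spin_label_layer")
}

#' PRE model parameters
#'
#' The Solomon-Bloembergen prefactor is recomputed from physical constants;
#' only the correlation time, field, diamagnetic rate and transfer delay are
#' user inputs.  `k_sb` (A^6 s^-1) is
#' (1/15) (mu0/4pi)^2 gammaH^2 ge^2 muB^2 S(S+1) [4 J(0) + 3 J(omegaH)] with
#' J(w) = tau / (1 + w^2 tau^2) and S = 1/2.
#'
#' @param tau_pre_ns effective electron-proton correlation time (ns).
#' @param proton_frequency_mhz 1H Larmor frequency (MHz).
#' @param r2_dia intrinsic methyl 1H transverse rate in the diamagnetic
#'   sample (s^-1).
#' @param transfer_delay_t total transverse evolution time of the transfer
#'   periods (s).
#' @return object of class `pre_params` with the derived `k_sb`.
#' @export
pre_params <- function(tau_pre_ns = 5, proton_frequency_mhz = 850,
                       r2_dia = 20, transfer_delay_t = 0.008) {
  stopifnot(tau_pre_ns > 0, proton_frequency_mhz > 0, r2_dia > 0,
            transfer_delay_t > 0)
  tau <- tau_pre_ns * 1e-9
  omega_h <- 2 * pi * proton_frequency_mhz * 1e6
  jw <- function(w) tau / (1 + (w * tau)^2)
  pref <- (1 / 15) * .const$mu0_over_4pi^2 * .const$gamma_h^2 * .const$g_e^2 *
    .const$mu_b^2 * 0.5 * 1.5                 # S(S+1), S = 1/2
  k_sb <- pref * 1e60 * (4 * jw(0) + 3 * jw(omega_h))   # m^6 -> A^6
  structure(list(tau_pre_ns = tau_pre_ns,
                 proton_frequency_mhz = proton_frequency_mhz,
                 r2_dia = r2_dia, transfer_delay_t = transfer_delay_t,
                 electron_spin = 0.5, k_sb = k_sb),
            class = "pre_params")
}

# distances (A) from a reporter at height z to the label plane(s); errors if
# the reporter sits at or below the cis label plane.
.label_deltas <- function(height_z, layer) {
  d1 <- height_z + layer$label_depth_d
  if (any(d1 <= 0))
    stop("reporter at or below the spin-label plane (height_z <= -label_depth_d)")
  if (layer$include_trans_leaflet) {
    d2 <- height_z + layer$bilayer_phosphate_separation - layer$label_depth_d
    if (any(d2 <= 0)) stop("reporter below the trans spin-label plane")
    list(d1, d2)
  } else list(d1)
}

#' Analytic PRE rate above a labelled plane
#'
#' Integrating the r^-6 dipolar interaction over a uniform plane of labels at
#' perpendicular distance Delta gives Gamma2 = k_sb sigma pi / (2 Delta^4).
#' With the trans leaflet included the same term is added at
#' Delta' = height_z + bilayer_phosphate_separation - label_depth_d.
#'
#' @param height_z reporter height(s) above the cis phosphate plane (A);
#'   vectorized.
#' @param layer a [spin_label_layer].
#' @param params a [pre_params].
#' @return Gamma2 in s^-1.
#' @export
#' @examples
#' gamma2_analytic(15, spin_label_layer(), pre_params())
gamma2_analytic <- function(height_z, layer = spin_label_layer(),
                            params = pre_params()) {
  stopifnot(inherits(layer, "spin_label_layer"), inherits(params, "pre_params"))
  deltas <- .label_deltas(height_z, layer)
  g <- 0
  for (d in deltas) g <- g + params$k_sb * layer$area_density_sigma * pi / (2 * d^4)
  g
}

#' Brute-force lattice-sum PRE rate (oracle for the plane integral)
#'
#' Sums k_sb sigma spacing^2 (rho^2 + Delta^2)^-3 over a square lattice of
#' point labels within `cutoff_radius`, one lattice per included leaflet.
#' Converges to [gamma2_analytic] as spacing shrinks and the cutoff grows.
#'
#' @inheritParams gamma2_analytic
#' @param lattice_spacing lattice constant (A).
#' @param cutoff_radius lateral cutoff (A); must exceed 10 Delta.
#' @return Gamma2 in s^-1.
#' @export
gamma2_discrete <- function(height_z, layer = spin_label_layer(),
                            params = pre_params(),
                            lattice_spacing = 0.5, cutoff_radius = NULL) {
  stopifnot(length(height_z) == 1, lattice_spacing > 0)
  deltas <- .label_deltas(height_z, layer)
  if (is.null(cutoff_radius)) cutoff_radius <- 100 * deltas[[1]]
  g <- 0
  for (d in deltas) {
    s <- lattice_sum_cpp(d, lattice_spacing, cutoff_radius)
    g <- g + params$k_sb * layer$area_density_sigma * lattice_spacing^2 * s
  }
  g
}

#' Intensity ratio from a PRE rate
#'
#' I/I0 = R2dia exp(-Gamma2 t) / (R2dia + Gamma2): the paramagnetic
#' broadening scales the steady-state peak height and the extra decay during
#' the transfer periods attenuates it further.  Strictly decreasing in
#' Gamma2, bounded in [0, 1].
#'
#' @param gamma2 PRE rate(s), s^-1, non-negative (Inf allowed: fully
#'   bleached).
#' @param params a [pre_params].
#' @return ratio(s) in [0, 1].
#' @export
intensity_ratio <- function(gamma2, params = pre_params()) {
  if (any(is.na(gamma2)) || any(gamma2 < 0)) stop("gamma2 must be non-negative")
  r <- params$r2_dia * exp(-gamma2 * params$transfer_delay_t) /
    (params$r2_dia + gamma2)
  r[is.infinite(gamma2)] <- 0
  r
}

#' Back-calculated PRE profile for one conformer
#'
#' Evaluates [gamma2_analytic] at each reporter's z and converts to I/I0.
#' Reporters at or below the cis label plane are flagged as bleached
#' (ratio 0, Gamma2 = Inf) with a warning rather than erroring, so deeply
#' inserted helix reporters remain representable.
#'
#' @param conf a [conformer].
#' @param layer a [spin_label_layer].
#' @param params a [pre_params].
#' @return data.frame of class `pre_prediction` with columns `reporter_id`,
#'   `z_height_A`, `gamma2_s1`, `ratio`, `bleached`.
#' @export
predict_profile <- function(conf, layer = spin_label_layer(),
                            params = pre_params()) {
  stopifnot(inherits(conf, "conformer"))
  z <- conf$xyz[, 3]
  bleach <- z <= -layer$label_depth_d
  g <- rep(Inf, length(z))
  if (any(!bleach)) g[!bleach] <- gamma2_analytic(z[!bleach], layer, params)
  if (any(bleach))
    warning(sum(bleach), " reporter(s) at or below the label plane; ratio set to 0")
  out <- data.frame(reporter_id = rownames(conf$xyz), z_height_A = z,
                    gamma2_s1 = g, ratio = intensity_ratio(g, params),
                    bleached = bleach, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("pre_prediction", "data.frame")
  out
}

#' Ensemble-averaged PRE profile
#'
#' Under fast exchange between conformations the PRE rates (not intensities)
#' average: Gamma2 is weight-averaged per reporter before one intensity-ratio
#' conversion.  `"intensity_average"` averages the per-member ratios instead
#' (slow-exchange bound, kept for sensitivity analysis); by Jensen's
#' inequality the fast-exchange ratio never exceeds it.
#'
#' @param conformers list of [conformer]s sharing one reporter set.
#' @param weights non-negative weights summing to 1 (tolerance 1e-9);
#'   default uniform.
#' @param regime `"fast_exchange"` (default) or `"intensity_average"`.
#' @param layer,params model settings as in [predict_profile].
#' @return a `pre_prediction` data.frame (z is the weighted mean height).
#' @export
ensemble_profile <- function(conformers, weights = NULL,
                             regime = c("fast_exchange", "intensity_average"),
                             layer = spin_label_layer(), params = pre_params()) {
  regime <- match.arg(regime)
  n <- length(conformers)
  stopifnot(n >= 1)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  ids <- rownames(conformers[[1]]$xyz)
  preds <- lapply(conformers, function(cf) {
    if (!identical(sort(rownames(cf$xyz)), sort(ids)))
      stop("conformers have mismatched reporter sets")
    p <- suppressWarnings(predict_profile(cf, layer, params))
    p[match(ids, p$reporter_id), ]
  })
  gmat <- vapply(preds, function(p) p$gamma2_s1, numeric(length(ids)))
  zmat <- vapply(preds, function(p) p$z_height_A, numeric(length(ids)))
  gmat <- matrix(gmat, nrow = length(ids))
  zmat <- matrix(zmat, nrow = length(ids))
  if (regime == "fast_exchange") {
    gbar <- as.numeric(gmat %*% weights)
    ratio <- intensity_ratio(gbar, params)
  } else {
    rmat <- matrix(vapply(preds, function(p) p$ratio, numeric(length(ids))),
                   nrow = length(ids))
    ratio <- as.numeric(rmat %*% weights)
    gbar <- as.numeric(gmat %*% weights)
  }
  out <- data.frame(reporter_id = ids,
                    z_height_A = as.numeric(zmat %*% weights),
                    gamma2_s1 = gbar, ratio = ratio,
                    bleached = !is.finite(gbar), row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("pre_prediction", "data.frame")
  out
}

#' PRE measurement error from signal-to-noise
#'
#' Error = (Ipara/Idia) sqrt((1/SNpara)^2 + (1/SNdia)^2): the intensity-ratio
#' uncertainty propagated from the spectral signal-to-noise of the
#' paramagnetic and diamagnetic spectra.
#'
#' @param i_para,i_dia peak intensities (arbitrary units, `i_dia` > 0).
#' @param sn_para,sn_dia signal-to-noise ratios (> 0).
#' @return error value(s), >= 0.
#' @export
#' @examples
#' measurement_error(0.5, 1, 10, 20)  # 0.055902
measurement_error <- function(i_para, i_dia, sn_para, sn_dia) {
  if (any(i_dia <= 0)) stop("i_dia must be positive")
  if (any(sn_para <= 0) || any(sn_dia <= 0)) stop("S/N values must be positive")
  (i_para / i_dia) * sqrt(1 / sn_para^2 + 1 / sn_dia^2)
}

#' Construct a PRE measurement table
#'
#' Ratios and their errors are always computed, never supplied: ratio =
#' Ipara/Idia and the error follows [measurement_error].
#'
#' @param df data.frame with columns `reporter_id`, `i_para`, `i_dia`,
#'   `sn_para`, `sn_dia` (optional `residue`, `atom` are carried through).
#' @return data.frame of class `pre_measurement` with added `ratio`, `error`.
#' @export
pre_measurement <- function(df) {
  req <- c("reporter_id", "i_para", "i_dia", "sn_para", "sn_dia")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$reporter_id))
    stop("duplicated reporter_id: ",
         paste(unique(df$reporter_id[duplicated(df$reporter_id)]), collapse = ", "))
  bad <- which(df$i_dia <= 0 | df$sn_para <= 0 | df$sn_dia <= 0)
  if (length(bad))
    stop("non-positive i_dia or S/N at row(s) ", paste(bad, collapse = ", "))
  df$ratio <- df$i_para / df$i_dia
  df$error <- measurement_error(df$i_para, df$i_dia, df$sn_para, df$sn_dia)
  class(df) <- c("pre_measurement", "data.frame")
  df
}
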