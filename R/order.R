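# Deuterium NMR chain-order analytics: Pake splittings to |S_CD|, smoothed
# profiles, mean-torque chain extension, Zeeman-order relaxation fits,
# square-law tables, and order parameters from trajectory C-H vectors.

#' Quadrupolar coupling conventions
#'
#' The 90-degree-edge separation of a Pake doublet relates to the segmental
#' order parameter as dv = (3/4) chi_q |S_CD|; the fast C3 rotation of a
#' terminal methyl scales its splitting down by a further factor of 3.
#'
#' @param chi_q static quadrupolar coupling constant (kHz).
#' @param powder_edge_factor 90-degree-edge factor (3/4).
#' @param methyl_reduction methyl C3 reduction factor (1/3).
#' @return object of class `quadrupole_params`.
#' @export
quadrupole_params <- function(chi_q = 167, powder_edge_factor = 3 / 4,
                              methyl_reduction = 1 / 3) {
  stopifnot(chi_q > 0, powder_edge_factor > 0, methyl_reduction > 0)
  structure(list(chi_q = chi_q, powder_edge_factor = powder_edge_factor,
                 methyl_reduction = methyl_reduction),
            class = "quadrupole_params")
}

#' Segmental order parameter from a quadrupolar splitting
#'
#' |S| = dv / (edge_factor * chi_q) for methylenes; methyl splittings are
#' additionally divided by the C3 reduction, |S| = dv /
#' (edge_factor * chi_q * methyl_reduction).
#'
#' @param dv splitting(s) in kHz (>= 0); vectorized.
#' @param group `"CH2"` or `"CH3"`, recycled against `dv`.
#' @param qp a [quadrupole_params].
#' @return |S_CD| in [0, 0.5]; values above 0.5 are unphysical and error.
#' @export
#' @examples
#' splitting_to_order(25.05, "CH2")  # 0.200
splitting_to_order <- function(dv, group = "CH2", qp = quadrupole_params()) {
  if (any(dv < 0)) stop("splittings must be non-negative")
  if (!all(group %in% c("CH2", "CH3"))) stop("group must be CH2 or CH3")
  group <- rep_len(group, length(dv))
  s <- dv / (qp$powder_edge_factor * qp$chi_q)
  s[group == "CH3"] <- s[group == "CH3"] / qp$methyl_reduction
  if (any(s > 0.5 + 1e-12)) stop("|S_CD| > 0.5 is unphysical; check inputs")
  pmin(s, 0.5)
}

#' Forward conversion: order parameter to splitting
#'
#' Inverse of [splitting_to_order]; used by the synthetic generator.
#'
#' @param s |S_CD| value(s) in [0, 0.5].
#' @inheritParams splitting_to_order
#' @return splitting(s) in kHz.
#' @export
order_to_splitting <- function(s, group = "CH2", qp = quadrupole_params()) {
  if (any(s < 0 | s > 0.5)) stop("|S_CD| must lie in [0, 0.5]")
  group <- rep_len(group, length(s))
  dv <- s * qp$powder_edge_factor * qp$chi_q
  dv[group == "CH3"] <- dv[group == "CH3"] * qp$methyl_reduction
  dv
}

#' Smoothed order parameter profile from resolved splittings
#'
#' Converts the resolved splittings to |S|, sorts them in descending order
#' and reassigns them monotonically from the upper chain (the plateau) toward
#' the terminal methyl at the resolved carbon positions; unresolved positions
#' are filled by shape-preserving monotone interpolation (carbons outside the
#' resolved range take the nearest resolved value).  The result is
#' non-increasing toward the chain end.
#'
#' @param splittings data.frame with columns `carbon_index` (2..N, 1-based
#'   from the carbonyl), `splitting_khz`, `group` ("CH2"/"CH3").
#' @param chain_length N (14 for myristoyl, 16 for palmitoyl).
#' @param qp a [quadrupole_params].
#' @return data.frame of class `order_profile` with columns `carbon_index`,
#'   `s_cd`, `resolved`; attribute `smoothed = TRUE`.
#' @export
smooth_profile <- function(splittings, chain_length, qp = quadrupole_params()) {
  stopifnot(all(c("carbon_index", "splitting_khz", "group") %in% names(splittings)))
  if (nrow(splittings) < 2) stop("need at least 2 resolved splittings")
  if (chain_length < max(splittings$carbon_index) ||
      chain_length < nrow(splittings) + 1)
    stop("chain_length smaller than the resolved positions")
  s_vals <- splitting_to_order(splittings$splitting_khz, splittings$group, qp)
  idx <- sort(unique(splittings$carbon_index))
  if (length(idx) != nrow(splittings)) stop("duplicate carbon_index in splittings")
  s_sorted <- sort(s_vals, decreasing = TRUE)      # plateau first
  carbons <- 2:chain_length
  if (length(idx) >= 3) {
    f <- splinefun(idx, s_sorted, method = "hyman")
    s_all <- f(pmin(pmax(carbons, min(idx)), max(idx)))
  } else {
    s_all <- approx(idx, s_sorted, xout = pmin(pmax(carbons, min(idx)), max(idx)))$y
  }
  s_all <- rev(cummax(rev(s_all)))                 # enforce monotone non-increasing
  out <- data.frame(carbon_index = carbons, s_cd = s_all,
                    resolved = carbons %in% idx)
  class(out) <- c("order_profile", "data.frame")
  attr(out, "smoothed") <- TRUE
  out
}

#' Build an order profile directly from |S| values
#'
#' @param carbon_index carbon positions (2..N).
#' @param s_cd |S_CD| values in [0, 0.5].
#' @param smoothed logical flag carried in the attribute.
#' @return an `order_profile` data.frame.
#' @export
order_profile <- function(carbon_index, s_cd, smoothed = FALSE) {
  stopifnot(length(carbon_index) == length(s_cd), all(s_cd >= 0 & s_cd <= 0.5))
  out <- data.frame(carbon_index = as.integer(carbon_index), s_cd = s_cd,
                    resolved = TRUE)
  class(out) <- c("order_profile", "data.frame")
  attr(out, "smoothed") <- smoothed
  out
}

#' Mean-torque chain extension profile
#'
#' First-order mean-torque model: each segment's mean travel along the
#' membrane normal is D <cos beta_i> with
#' <cos beta_i> = (1 + sqrt((8 |S_i| - 1) / 3)) / 2 for |S_i| >= 1/8 (the
#' closed form's domain); below 1/8 the model is outside its domain and the
#' fallback <cos beta_i> = 1/2 is applied and flagged.  Cumulative extension
#' is measured from the terminal methyl, which sits at 0 by convention.
#'
#' @param profile an `order_profile` (carbon 2..N with the terminal methyl at
#'   index N).
#' @param segment_projection projected C-C length per carbon (A), default
#'   1.27.
#' @return data.frame of class `extension_profile` with `carbon_index`,
#'   `s_cd`, `cos_beta`, `travel_A`, `extension_A`, `sub_eighth`.
#' @export
#' @examples
#' p <- order_profile(2:14, rep(0.25, 13))
#' chain_extension(p)$travel_A[1]  # 1.00162
chain_extension <- function(profile, segment_projection = 1.27) {
  stopifnot(inherits(profile, "order_profile"), all(profile$s_cd <= 0.5))
  p <- profile[order(profile$carbon_index), ]
  s <- p$s_cd
  sub <- s < 1 / 8
  cosb <- ifelse(sub, 0.5, (1 + sqrt(pmax(8 * s - 1, 0) / 3)) / 2)
  travel <- segment_projection * cosb
  # distance of carbon i from the terminal methyl: sum of travels of the
  # segments between i and the chain end
  n <- nrow(p)
  ext <- rev(cumsum(rev(c(travel[-1], 0))))
  out <- data.frame(carbon_index = p$carbon_index, s_cd = s, cos_beta = cosb,
                    travel_A = travel, extension_A = ext, sub_eighth = sub)
  class(out) <- c("extension_profile", "data.frame")
  out
}

#' Fit a Zeeman-order inversion-recovery decay
#'
#' Least-squares fit of I(t) = I_inf (1 - 2 f exp(-R1Z t)) to an intensity
#' series, returning the relaxation rate with a 95% confidence interval.
#'
#' @param delays recovery delays in seconds, strictly increasing, >= 5
#'   points.
#' @param intensities measured intensities (arbitrary units).
#' @return object of class `relaxation_fit`: `r1z`, `f`, `i_inf`, `ci`
#'   (95% CI on `r1z`), and the `nls` fit.
#' @export
fit_inversion_recovery <- function(delays, intensities) {
  stopifnot(length(delays) == length(intensities))
  if (length(delays) < 5) stop("need at least 5 delay points")
  if (any(diff(delays) <= 0)) stop("delays must be strictly increasing")
  i_inf0 <- intensities[length(intensities)]
  if (i_inf0 <= 0) i_inf0 <- max(abs(intensities))
  f0 <- min(max((1 - intensities[1] / i_inf0) / 2, 0.3), 1.2)
  r0 <- 1 / max(stats::median(delays), 1e-6)
  df <- data.frame(t = delays, y = intensities)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ i_inf * (1 - 2 * f * exp(-r * t)), data = df,
                      start = list(i_inf = i_inf0, f = f0, r = r0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("inversion-recovery fit failed to converge: ",
                             conditionMessage(e)))
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))["r"]
  q <- qt(0.975, df = length(delays) - 3)
  structure(list(r1z = unname(cf["r"]), f = unname(cf["f"]),
                 i_inf = unname(cf["i_inf"]),
                 ci = unname(cf["r"] + c(-1, 1) * q * se), fit = fit),
            class = "relaxation_fit")
}

#' Square-law table of R1Z versus S^2
#'
#' Pairs relaxation rates with the square of the order parameter at shared
#' carbon positions, sorted by S^2.  No line is fitted: in such plots the
#' curvature itself is the diagnostic of membrane elasticity.
#'
#' @param profile an `order_profile`.
#' @param rates data.frame with columns `carbon_index`, `r1z`.
#' @return data.frame with `carbon_index`, `s_cd`, `s_squared`, `r1z`,
#'   ascending in `s_squared`.
#' @export
square_law_table <- function(profile, rates) {
  stopifnot(inherits(profile, "order_profile"),
            all(c("carbon_index", "r1z") %in% names(rates)))
  ids <- intersect(profile$carbon_index, rates$carbon_index)
  if (length(ids) == 0) stop("no shared carbon indices")
  s <- profile$s_cd[match(ids, profile$carbon_index)]
  out <- data.frame(carbon_index = ids, s_cd = s, s_squared = s^2,
                    r1z = rates$r1z[match(ids, rates$carbon_index)])
  out[order(out$s_squared), , drop = FALSE]
}

#' Order parameters from C-H bond vectors of trajectory frames
#'
#' S_CD(i) = <(3 cos^2 theta - 1)/2> over frames, theta the angle between the
#' unit C-H vector and the membrane normal (+z).  The signed value is kept in
#' the `signed_s` attribute; the profile reports |S| (values above the 0.5
#' methylene ceiling, e.g. rigid vectors along z, are flagged via the sign
#' attribute and capped in the profile).
#'
#' @param ch_unit_vectors named list: carbon index -> (frames x 3) matrix of
#'   unit vectors (tolerance 1e-6 on the norm).
#' @return an `order_profile` with attribute `signed_s`.
#' @export
order_from_vectors <- function(ch_unit_vectors) {
  stopifnot(is.list(ch_unit_vectors), length(ch_unit_vectors) >= 1)
  idx <- as.integer(names(ch_unit_vectors))
  if (any(is.na(idx))) stop("list names must be carbon indices")
  s_signed <- vapply(ch_unit_vectors, function(v) {
    stopifnot(is.matrix(v), ncol(v) == 3)
    nrm <- sqrt(rowSums(v^2))
    if (any(abs(nrm - 1) > 1e-6)) stop("C-H vectors must be unit length")
    mean((3 * v[, 3]^2 - 1) / 2)
  }, 0)
  out <- data.frame(carbon_index = idx, s_cd = pmin(abs(s_signed), 0.5),
                    resolved = TRUE)
  out <- out[order(out$carbon_index), ]
  class(out) <- c("order_profile", "data.frame")
  attr(out, "smoothed") <- FALSE
  attr(out, "signed_s") <- unname(s_signed[order(idx)])
  out
}
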