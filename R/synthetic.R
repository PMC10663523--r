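# Synthetic-data generators: every input the pipeline consumes, with known
# ground truth.  All generators are pure functions of (spec, seed).

#' Toy reporter geometry specification
#'
#' A rigid stand-in for a G domain carrying methyl reporters, tethered above
#' the membrane by a surface-embedded amphipathic helix: 41 G-domain
#' reporters on a slightly anisotropic shell (so the principal body axes are
#' well defined) plus 3 helix reporters on a line below the phosphate plane
#' (default depth -6.5 A, the mean helix insertion depth).
#'
#' @param n_gdomain_reporters number of G-domain reporters (default 41, for
#'   44 reporters in total).
#' @param n_helix_reporters number of helix reporters (default 3).
#' @param gdomain_radius mean shell radius (A).
#' @param helix_depth helix reporter z (A, negative = inserted).
#' @param center_height z of the G-domain centre (A).
#' @param seed integer; rotates the deterministic low-discrepancy point set.
#' @return object of class `toy_domain_spec`.
#' @export
toy_domain_spec <- function(n_gdomain_reporters = 41, n_helix_reporters = 3,
                            gdomain_radius = 12, helix_depth = -6.5,
                            center_height = 23, seed = 1) {
  stopifnot(n_gdomain_reporters >= 1, n_helix_reporters >= 1,
            gdomain_radius > 0)
  structure(list(n_gdomain_reporters = as.integer(n_gdomain_reporters),
                 n_helix_reporters = as.integer(n_helix_reporters),
                 gdomain_radius = gdomain_radius, helix_depth = helix_depth,
                 center_height = center_height, seed = as.integer(seed)),
            class = "toy_domain_spec")
}

#' Build the toy reference conformer
#'
#' G-domain reporters are placed on a low-discrepancy (golden-angle) octant
#' shell replicated through all eight sign combinations, with per-axis
#' spreads rescaled to (0.55, 0.45, 0.72) x radius; leftover reporters sit
#' on the z axis (the odd one at the centre).  The sign symmetry makes the
#' covariance of the point set exactly diagonal and the prescribed spreads
#' order it, so in the reference pose the principal body axes coincide
#' exactly with the membrane axes (body z = membrane normal, the largest
#' variance; body x = membrane x) and the centroid equals the configured
#' centre to machine precision.  Helix
#' reporters sit on a line at `helix_depth` with 5-A spacing.  Reporter ids
#' carry residue numbers spread over the G-domain range (g17, g21, ...) and
#' the helix positions (h4, h8, h12), from which roles derive.
#'
#' @param spec a [toy_domain_spec].
#' @return a reference [conformer].
#' @export
make_toy_domain <- function(spec = toy_domain_spec()) {
  stopifnot(inherits(spec, "toy_domain_spec"))
  n <- spec$n_gdomain_reporters
  k <- n %/% 8L
  r <- n %% 8L
  golden <- pi * (3 - sqrt(5))
  pts <- matrix(0, 0, 3)
  if (k > 0) {
    i <- seq_len(k) - 1
    z <- (i + 0.5) / (k + 0.5)                 # octant: z in (0, 1)
    phi <- (i * golden + spec$seed * 0.1) %% (pi / 2)
    rho <- sqrt(pmax(1 - z^2, 0))
    base <- cbind(cos(phi) * rho, sin(phi) * rho, z)
    signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
    pts <- do.call(rbind, lapply(seq_len(8), function(s)
      sweep(base, 2, signs[s, ], `*`)))
  }
  if (r > 0) {                                 # axial leftovers, sign-paired
    zr <- c(if (r %% 2L == 1L) 0,
            if (r > 1) c(outer(c(1, -1), 0.25 * seq_len(r %/% 2L))))
    pts <- rbind(pts, cbind(0, 0, zr))
  }
  # prescribe the per-axis spread exactly (z > x > y) so the principal body
  # axes of the reference are the membrane axes with a safe eigenvalue gap
  target_sd <- spec$gdomain_radius * c(0.55, 0.45, 0.72)
  for (ax in 1:3) {
    s <- sqrt(mean(pts[, ax]^2))
    if (s > 0) pts[, ax] <- pts[, ax] * (target_sd[ax] / s)
  }
  pts <- sweep(pts, 2, c(0, 0, spec$center_height), `+`)
  g_res <- round(seq(17, 181, length.out = n))
  g_ids <- paste0("g", g_res)
  nh <- spec$n_helix_reporters
  h_res <- c(4, 8, 12, seq(13, by = 1, length.out = max(0, nh - 3)))[seq_len(nh)]
  h_ids <- paste0("h", h_res)
  h_pts <- cbind((seq_len(nh) - (nh + 1) / 2) * 5, 0, spec$helix_depth)
  xyz <- rbind(pts, h_pts)
  rownames(xyz) <- c(g_ids, h_ids)
  roles <- c(rep("g_domain", n), rep("n_helix", nh))
  names(roles) <- rownames(xyz)
  conformer("reference", xyz, roles)
}

#' Three-state truth ensemble specification
#'
#' Ground-truth mixture over the orientational states: per-state fractions,
#' per-state G-domain height distributions (means 18/22/26 A by default, SD
#' 1.5 A, so the states are separable in their PRE signatures but overlap),
#' and uniform orientation sampling within each state's (beta, gamma) bins.
#'
#' @param fractions named simplex over the states (sums to 1).
#' @param height_mean,height_sd per-state height mean/SD (A), recycled.
#' @param seed integer seed.
#' @return object of class `truth_ensemble`.
#' @export
truth_ensemble <- function(fractions = c(S1 = 0.2, S2 = 0.3, S3 = 0.5),
                           height_mean = c(S1 = 18, S2 = 22, S3 = 26),
                           height_sd = 1.5, seed = 1) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, all(fractions >= 0))
  height_sd <- rep_len(height_sd, length(fractions))
  names(height_sd) <- names(fractions)
  structure(list(fractions = fractions,
                 height_mean = height_mean[names(fractions)],
                 height_sd = height_sd, seed = as.integer(seed)),
            class = "truth_ensemble")
}

# rotation about z by g degrees then composed as Rz(gamma) Ry(beta)
.rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
.rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

# rotation whose orientation under compute_orientation's convention is
# (beta, gamma): R = Rz(gamma) Ry(beta) t(B), B the reference body frame
.orientation_rotation <- function(beta, gamma, bf) {
  .rot_z(gamma) %*% .rot_y(beta) %*% t(bf)
}

sample_gamma_in <- function(rng) {
  # uniform draw on a circular interval possibly wrapping 360
  if (rng[1] <= rng[2]) runif(1, rng[1], rng[2])
  else (runif(1, rng[1], rng[2] + 360)) %% 360
}

#' Sample a state-structured conformer library
#'
#' Each conformer draws a state from the truth fractions, an orientation
#' uniform within that state's (beta, gamma) bins, and a height from the
#' state's Gaussian; the reference G domain is rigidly rotated about its
#' centroid (rotation built in the reference body frame, so the extracted
#' orientation recovers the sampled angles exactly) and translated to the
#' sampled COM height.  Helix reporters stay at their membrane-embedded
#' reference positions.  Heights violating the spin-label-plane constraint
#' are resampled (up to 100 tries, then error).
#'
#' @param reference a reference [conformer] (see [make_toy_domain]).
#' @param truth a [truth_ensemble].
#' @param n_conformers library size.
#' @param states list of [state_definition]s matching the truth fractions.
#' @param layer a [spin_label_layer] (for the height constraint).
#' @return list with `conformers` (list of [conformer]) and `labels`
#'   (character vector of true states).
#' @export
sample_library <- function(reference, truth, n_conformers,
                           states = default_states(),
                           layer = spin_label_layer()) {
  stopifnot(inherits(reference, "conformer"), inherits(truth, "truth_ensemble"),
            n_conformers >= 1)
  validate_states(states)
  state_names <- vapply(states, `[[`, "", "name")
  stopifnot(setequal(names(truth$fractions), state_names))
  bf <- body_frame(reference)
  gmask <- reference$roles == "g_domain"
  gref <- reference$xyz[gmask, , drop = FALSE]
  gctr <- colMeans(gref)
  gref0 <- sweep(gref, 2, gctr)
  set.seed(truth$seed)
  labels <- sample(names(truth$fractions), n_conformers, replace = TRUE,
                   prob = truth$fractions)
  conformers <- vector("list", n_conformers)
  for (k in seq_len(n_conformers)) {
    st <- states[[match(labels[k], state_names)]]
    beta <- runif(1, st$beta_range[1], st$beta_range[2])
    gamma <- sample_gamma_in(st$gamma_range)
    rot <- .orientation_rotation(beta, gamma, bf)
    gnew <- gref0 %*% t(rot)
    h <- NA
    for (try in seq_len(100)) {
      h <- rnorm(1, truth$height_mean[labels[k]], truth$height_sd[labels[k]])
      if (min(gnew[, 3]) + h > -layer$label_depth_d + 1e-6) break
      h <- NA
    }
    if (is.na(h))
      stop("could not sample a height keeping all G-domain reporters above ",
           "the label plane for state ", labels[k])
    xyz <- reference$xyz
    xyz[gmask, ] <- sweep(gnew, 2, c(gctr[1], gctr[2], h), `+`)
    conformers[[k]] <- conformer(sprintf("conf_%04d", k), xyz,
                                 reference$roles, reference$g_domain_range)
  }
  list(conformers = conformers, labels = labels)
}

#' Simulate a PRE measurement from a truth conformer multiset
#'
#' Fast-exchange ensemble ratios with uniform weights, perturbed by
#' multiplicative Gaussian noise (SD = `noise_fraction` x ratio, clipped to
#' [0, 1]); I_dia is fixed at 1000 a.u., I_para = ratio x I_dia, and the S/N
#' columns are populated so the propagated errors are well defined.
#'
#' @param truth_conformers list of [conformer]s (the generating multiset).
#' @param layer,params PRE model settings.
#' @param noise_fraction multiplicative noise SD fraction (default 0.15).
#' @param sn signal-to-noise assigned to both spectra (default 50).
#' @param seed integer seed.
#' @param reporters optional character vector restricting the measured
#'   reporters (e.g. the 30 well-resolved of 44).
#' @return a `pre_measurement` data.frame.
#' @export
simulate_pre_measurement <- function(truth_conformers,
                                     layer = spin_label_layer(),
                                     params = pre_params(),
                                     noise_fraction = 0.15, sn = 50,
                                     seed = 1, reporters = NULL) {
  prof <- ensemble_profile(truth_conformers, layer = layer, params = params)
  if (!is.null(reporters)) {
    prof <- prof[prof$reporter_id %in% reporters, , drop = FALSE]
    if (nrow(prof) == 0) stop("no requested reporters in the profile")
  }
  set.seed(seed)
  ratio <- prof$ratio
  if (noise_fraction > 0)
    ratio <- pmin(pmax(ratio * (1 + rnorm(length(ratio), 0, noise_fraction)), 0), 1)
  pre_measurement(data.frame(reporter_id = prof$reporter_id,
                             i_para = ratio * 1000, i_dia = 1000,
                             sn_para = sn, sn_dia = sn,
                             stringsAsFactors = FALSE))
}

#' Simulate a splitting table from a truth order profile
#'
#' Forward conversion of |S| to quadrupolar splittings plus Gaussian noise in
#' kHz; positions listed in `mask` are dropped to emulate unresolved peaks.
#' The terminal carbon is a CH3, all others CH2.
#'
#' @param truth_profile an `order_profile` (monotone non-increasing).
#' @param qp a [quadrupole_params].
#' @param noise_khz Gaussian noise SD on the splittings (kHz).
#' @param seed integer seed.
#' @param mask integer carbon indices to drop.
#' @return data.frame with `carbon_index`, `splitting_khz`, `group`.
#' @export
simulate_splittings <- function(truth_profile, qp = quadrupole_params(),
                                noise_khz = 0, seed = 1, mask = integer(0)) {
  stopifnot(inherits(truth_profile, "order_profile"))
  p <- truth_profile[order(truth_profile$carbon_index), ]
  group <- ifelse(p$carbon_index == max(p$carbon_index), "CH3", "CH2")
  dv <- order_to_splitting(p$s_cd, group, qp)
  set.seed(seed)
  if (noise_khz > 0) dv <- pmax(dv + rnorm(length(dv), 0, noise_khz), 0)
  out <- data.frame(carbon_index = p$carbon_index, splitting_khz = dv,
                    group = group, stringsAsFactors = FALSE)
  out[!(out$carbon_index %in% mask), , drop = FALSE]
}

#' Default inversion-recovery delay schedule (seconds)
#' @export
ir_schedule <- function() c(0.001, 0.007, 0.014, 0.023, 0.035, 0.07, 0.1,
                            0.2, 0.4, 1, 1.8)

#' Simulate an inversion-recovery intensity series
#'
#' I(t) = i_inf (1 - 2 f exp(-r1z t)) plus Gaussian noise.
#'
#' @param r1z Zeeman-order relaxation rate (s^-1), > 0.
#' @param f inversion efficiency.
#' @param i_inf equilibrium intensity.
#' @param schedule delay schedule (s).
#' @param noise Gaussian noise SD in intensity units.
#' @param seed integer seed.
#' @return list with `delays` and `intensities`.
#' @export
simulate_inversion_recovery <- function(r1z, f = 1, i_inf = 100,
                                        schedule = ir_schedule(),
                                        noise = 0, seed = 1) {
  stopifnot(r1z > 0)
  y <- i_inf * (1 - 2 * f * exp(-r1z * schedule))
  set.seed(seed)
  if (noise > 0) y <- y + rnorm(length(y), 0, noise)
  list(delays = schedule, intensities = y)
}

#' Simulate a TRACT decay pair
#'
#' Forward model: R_alpha = r_common - eta_xy(tau_c), R_beta = r_common +
#' eta_xy(tau_c); both mono-exponential decays receive Gaussian noise
#' expressed as a fraction of the initial intensity.
#'
#' @param tau_c_ns correlation time (ns).
#' @param sp a [spin_params].
#' @param schedule delay schedule (s).
#' @param noise noise SD as a fraction of i0.
#' @param seed integer seed.
#' @param r_common common (auto-relaxation) rate, s^-1; must exceed eta_xy.
#' @param i0 initial intensity.
#' @return list with `delays`, `trosy`, `antitrosy`, `r_alpha`, `r_beta`.
#' @export
simulate_tract <- function(tau_c_ns, sp = spin_params(),
                           schedule = seq(0.002, 0.1, length.out = 12),
                           noise = 0, seed = 1, r_common = 40, i0 = 100) {
  stopifnot(tau_c_ns > 0)
  eta <- eta_xy(tau_c_ns, sp)
  if (r_common <= eta) stop("r_common must exceed eta_xy for a positive R_alpha")
  r_a <- r_common - eta
  r_b <- r_common + eta
  set.seed(seed)
  tr <- i0 * exp(-r_a * schedule)
  at <- i0 * exp(-r_b * schedule)
  if (noise > 0) {
    tr <- tr + rnorm(length(schedule), 0, noise * i0)
    at <- at + rnorm(length(schedule), 0, noise * i0)
  }
  list(delays = schedule, trosy = tr, antitrosy = at,
       r_alpha = r_a, r_beta = r_b)
}
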