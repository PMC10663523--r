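# Conformer geometry: membrane frame, rigid-body orientation extraction,
# orientational state assignment, and PMF surfaces over (beta, gamma).

#' Membrane frame
#'
#' Fixes the coordinate convention shared by all geometry and PRE routines:
#' the membrane normal is +z, and z = 0 is the phosphate plane of the leaflet
#' the protein sits on, so heights are reported relative to the phosphorus
#' plane of the cis leaflet.
#'
#' @param phosphate_plane_z z-offset (Angstrom) of the cis phosphate plane in
#'   the raw coordinates; coordinates are shifted so this plane becomes z = 0.
#' @return an object of class `membrane_frame`.
#' @export
membrane_frame <- function(phosphate_plane_z = 0) {
  stopifnot(is.numeric(phosphate_plane_z), length(phosphate_plane_z) == 1,
            is.finite(phosphate_plane_z))
  structure(list(phosphate_plane_z = phosphate_plane_z,
                 normal_axis = c(0, 0, 1), leaflet_sign = +1),
            class = "membrane_frame")
}

#' Conformer: one rigid snapshot in the membrane frame
#'
#' @param id conformer identifier (string).
#' @param xyz numeric matrix (n_reporters x 3) of reporter coordinates in
#'   Angstrom, membrane frame (z = 0 at the cis phosphate plane); rownames are
#'   the reporter ids.
#' @param roles named character vector mapping reporter id to `"g_domain"` or
#'   `"n_helix"`.
#' @param g_domain_range integer pair of residue numbers delimiting the G
#'   domain (default 17-181).
#' @return an object of class `conformer`.
#' @export
conformer <- function(id, xyz, roles, g_domain_range = c(17L, 181L)) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3, !is.null(rownames(xyz)))
  if (anyDuplicated(rownames(xyz))) stop("reporter ids must be unique")
  if (!all(is.finite(xyz))) stop("all reporter coordinates must be finite")
  roles <- roles[rownames(xyz)]
  if (any(is.na(roles)) || !all(roles %in% c("g_domain", "n_helix")))
    stop("every reporter needs a role in {g_domain, n_helix}")
  if (!any(roles == "g_domain")) stop("at least one g_domain reporter required")
  structure(list(id = as.character(id), xyz = xyz, roles = roles,
                 g_domain_range = as.integer(g_domain_range)),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat("<conformer>", x$id, ":", nrow(x$xyz), "reporters (",
      sum(x$roles == "g_domain"), "G-domain,", sum(x$roles == "n_helix"),
      "helix ), COM z =", round(com_height(x), 2), "A\n")
  invisible(x)
}

#' Centre-of-mass height of a reporter group
#'
#' Unweighted centroid z of the reporters with the requested role, relative to
#' the phosphate plane (z = 0).  Negative values mean insertion below the
#' phosphate plane.
#'
#' @param conf a [conformer].
#' @param role `"g_domain"` (default) or `"n_helix"`.
#' @return height in Angstrom.
#' @export
com_height <- function(conf, role = "g_domain") {
  stopifnot(inherits(conf, "conformer"))
  keep <- conf$roles == role
  if (!any(keep)) stop("no reporters with role '", role, "'")
  mean(conf$xyz[keep, 3])
}

# Principal-axes body frame of a conformer's G-domain reporters.
# Columns are unit vectors (x, y, z); body z is the largest-variance axis,
# sign-fixed toward the membrane normal, body x the second axis sign-fixed
# toward the membrane x axis, body y completes a right-handed frame.
# Ties in eigenvalue ordering resolve by eigen()'s descending order then the
# lexicographic axis preference implied by the sign fixes.
body_frame <- function(conf) {
  pts <- g_domain_xyz(conf)
  ctr <- sweep(pts, 2, colMeans(pts))
  ev <- eigen(crossprod(ctr) / nrow(ctr), symmetric = TRUE)
  if (ev$values[2] < 1e-9 * max(ev$values[1], 1e-300))
    stop("degenerate (collinear) reporter geometry in conformer '", conf$id, "'")
  bz <- ev$vectors[, 1]
  if (bz[3] < 0 || (bz[3] == 0 && bz[which.max(abs(bz))] < 0)) bz <- -bz
  bx <- ev$vectors[, 2]
  bx <- bx - sum(bx * bz) * bz          # numerical re-orthogonalization
  bx <- bx / sqrt(sum(bx^2))
  if (bx[1] < 0 || (bx[1] == 0 && bx[which.max(abs(bx))] < 0)) bx <- -bx
  by <- c(bz[2] * bx[3] - bz[3] * bx[2],
          bz[3] * bx[1] - bz[1] * bx[3],
          bz[1] * bx[2] - bz[2] * bx[1])
  cbind(x = bx, y = by, z = bz)
}

g_domain_xyz <- function(conf) conf$xyz[conf$roles == "g_domain", , drop = FALSE]

# Kabsch: optimal rotation R (3x3) such that conf_pts ~ ref_pts %*% t(R),
# translations removed.  Both inputs are matrices with matching rows.
kabsch_rotation <- function(ref_pts, conf_pts) {
  p <- sweep(ref_pts, 2, colMeans(ref_pts))
  q <- sweep(conf_pts, 2, colMeans(conf_pts))
  h <- crossprod(p, q)                  # t(p) %*% q
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

#' Orientation (tilt/spin angles) of a conformer relative to a reference
#'
#' Extracts the optimal rigid rotation (least-squares superposition of the
#' shared G-domain reporters, translation removed) mapping the reference onto
#' the conformer, then reports beta as the polar angle between the rotated
#' reference body z-axis and the membrane normal, and gamma as the azimuth of
#' the rotated reference body x-axis about the membrane normal, measured from
#' the membrane x axis, in [0, 360).  The reference body frame is its
#' principal-axes frame (largest-variance axis = body z, tie-broken toward the
#' membrane normal).
#'
#' The absolute gamma origin is a convention; [orientation_offset] arguments
#' let you calibrate against an external collective-variable definition.
#'
#' @param conf,reference [conformer] objects sharing at least 3 non-collinear
#'   G-domain reporters.
#' @param beta_offset,gamma_offset calibration offsets in degrees added to the
#'   extracted angles (gamma modulo 360).
#' @return list with elements `beta` (degrees, 0-180) and `gamma`
#'   (degrees, [0, 360)), class `orientation`.
#' @export
#' @examples
#' ref <- make_toy_domain()
#' compute_orientation(ref, ref)  # beta = 0, gamma = 0
compute_orientation <- function(conf, reference, beta_offset = 0, gamma_offset = 0) {
  stopifnot(inherits(conf, "conformer"), inherits(reference, "conformer"))
  ids <- intersect(rownames(g_domain_xyz(reference)), rownames(g_domain_xyz(conf)))
  if (length(ids) < 3)
    stop("conformer '", conf$id, "': fewer than 3 shared G-domain reporters")
  rot <- kabsch_rotation(reference$xyz[ids, , drop = FALSE],
                         conf$xyz[ids, , drop = FALSE])
  bf <- body_frame(reference)
  v <- as.numeric(rot %*% bf[, "z"])
  u <- as.numeric(rot %*% bf[, "x"])
  beta <- acos(max(-1, min(1, v[3]))) * 180 / pi + beta_offset
  gamma <- (atan2(u[2], u[1]) * 180 / pi + gamma_offset) %% 360
  orientation(beta, gamma)
}

#' @rdname compute_orientation
#' @param beta,gamma angles in degrees.
#' @export
orientation <- function(beta, gamma) {
  stopifnot(is.finite(beta), is.finite(gamma))
  if (beta < -1e-9 || beta > 180 + 1e-9) stop("beta must lie in [0, 180]")
  structure(list(beta = min(max(beta, 0), 180), gamma = gamma %% 360),
            class = "orientation")
}

#' Orientational state definition
#'
#' A rectangular bin in (beta, gamma) space.  The gamma interval lives on the
#' circle: `gamma_range = c(300, 20)` wraps through 360/0, and printed ranges
#' exceeding 180 degrees (e.g. 115-187) are honoured without clipping.
#'
#' @param name state name.
#' @param beta_range,gamma_range numeric length-2 intervals in degrees.
#' @return object of class `state_definition`.
#' @export
state_definition <- function(name, beta_range, gamma_range) {
  stopifnot(length(beta_range) == 2, length(gamma_range) == 2,
            beta_range[1] < beta_range[2])
  structure(list(name = as.character(name), beta_range = as.numeric(beta_range),
                 gamma_range = as.numeric(gamma_range) %% 360),
            class = "state_definition")
}

#' Default three-state definitions
#'
#' The S1/S2/S3 orientational clusters of the G domain: S1 (beta 57-73,
#' gamma 115-187) with the switch-I face toward the bilayer, S2 (beta 8-20,
#' gamma 64-118), and S3 (beta 20-30, gamma 0-50) with both switches solvent
#' exposed.
#'
#' @return list of three [state_definition] objects.
#' @export
default_states <- function() {
  list(state_definition("S1", c(57, 73), c(115, 187)),
       state_definition("S2", c(8, 20), c(64, 118)),
       state_definition("S3", c(20, 30), c(0, 50)))
}

gamma_in_range <- function(gamma, rng) {
  gamma <- gamma %% 360
  if (rng[1] <= rng[2]) gamma >= rng[1] & gamma <= rng[2]
  else gamma >= rng[1] | gamma <= rng[2]
}

# circular interval overlap (closed)
.gamma_overlap <- function(a, b) {
  any(gamma_in_range(c(b[1], b[2]), a)) || any(gamma_in_range(c(a[1], a[2]), b))
}

validate_states <- function(states) {
  stopifnot(length(states) >= 1, all(vapply(states, inherits, TRUE, "state_definition")))
  if (anyDuplicated(vapply(states, `[[`, "", "name"))) stop("duplicate state names")
  if (length(states) > 1) {
    for (i in seq_len(length(states) - 1)) for (j in (i + 1):length(states)) {
      a <- states[[i]]; b <- states[[j]]
      beta_ov <- max(a$beta_range[1], b$beta_range[1]) <
        min(a$beta_range[2], b$beta_range[2])
      if (beta_ov && .gamma_overlap(a$gamma_range, b$gamma_range))
        stop("state definitions '", a$name, "' and '", b$name, "' overlap")
    }
  }
  invisible(states)
}

#' Assign an orientation to a state
#'
#' @param o an [orientation].
#' @param states list of pairwise-disjoint [state_definition]s (overlapping
#'   definitions are rejected).
#' @return the name of the unique containing state, or `"unassigned"`.
#' @export
#' @examples
#' assign_state(orientation(65, 150), default_states())  # "S1"
assign_state <- function(o, states = default_states()) {
  stopifnot(inherits(o, "orientation"))
  validate_states(states)
  for (s in states) {
    if (o$beta >= s$beta_range[1] && o$beta <= s$beta_range[2] &&
        gamma_in_range(o$gamma, s$gamma_range)) return(s$name)
  }
  "unassigned"
}

#' Potential of mean force over orientation space
#'
#' Histograms a set of orientations on a regular (beta, gamma) grid and
#' converts counts to free energies, F(bin) = -kB T log(count / max count),
#' so the most populated bin sits at exactly 0 and all occupied bins are
#' non-negative.  Empty bins are flagged `NA` ("unvisited"), never 0 or
#' infinite, so surfaces serialize losslessly.
#'
#' @param orientations list of [orientation] objects.
#' @param bin_width_beta,bin_width_gamma bin widths in degrees; must divide
#'   180 and 360 respectively.
#' @param temperature temperature in K.
#' @return object of class `pmf_surface`: list with `beta_edges`,
#'   `gamma_edges`, `counts` and `free_energy` (kcal/mol) matrices.
#' @export
pmf_from_orientations <- function(orientations, bin_width_beta = 5,
                                  bin_width_gamma = 5, temperature = 298.15) {
  if (length(orientations) == 0) stop("empty orientation list")
  if (!is.finite(temperature) || temperature <= 0) stop("temperature must be positive")
  nb <- 180 / bin_width_beta
  ng <- 360 / bin_width_gamma
  if (abs(nb - round(nb)) > 1e-9 || abs(ng - round(ng)) > 1e-9)
    stop("bin widths must divide 180 (beta) and 360 (gamma) degrees")
  nb <- round(nb); ng <- round(ng)
  beta <- vapply(orientations, `[[`, 0, "beta")
  gamma <- vapply(orientations, `[[`, 0, "gamma") %% 360
  ib <- pmin(floor(beta / bin_width_beta) + 1, nb)
  ig <- pmin(floor(gamma / bin_width_gamma) + 1, ng)
  counts <- matrix(0L, nb, ng)
  for (k in seq_along(ib)) counts[ib[k], ig[k]] <- counts[ib[k], ig[k]] + 1L
  kbt <- .const$kb_kcal * temperature
  fe <- matrix(NA_real_, nb, ng)
  occ <- counts > 0
  fe[occ] <- -kbt * log(counts[occ] / max(counts))
  structure(list(beta_edges = seq(0, 180, by = bin_width_beta),
                 gamma_edges = seq(0, 360, by = bin_width_gamma),
                 counts = counts, free_energy = fe, temperature = temperature),
            class = "pmf_surface")
}

#' Write a PMF surface as TSV
#'
#' One row per bin: `beta_low, beta_high, gamma_low, gamma_high, count,
#' free_energy_kcal_mol`.  Unvisited bins carry `NA` free energy.
#'
#' @param pmf a [pmf_from_orientations] result.
#' @param path output file.
#' @export
write_pmf <- function(pmf, path) {
  stopifnot(inherits(pmf, "pmf_surface"))
  nb <- nrow(pmf$counts); ng <- ncol(pmf$counts)
  df <- data.frame(
    beta_low = rep(pmf$beta_edges[seq_len(nb)], times = ng),
    beta_high = rep(pmf$beta_edges[-1], times = ng),
    gamma_low = rep(pmf$gamma_edges[seq_len(ng)], each = nb),
    gamma_high = rep(pmf$gamma_edges[-1], each = nb),
    count = as.vector(pmf$counts),
    free_energy_kcal_mol = as.vector(pmf$free_energy))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @importFrom utils write.table
NULL
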