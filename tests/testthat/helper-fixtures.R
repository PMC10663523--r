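# Shared fixtures, built once per test run.  Everything derives from the
# synthetic-data module with fixed seeds.

fx <- new.env()

fx_reference <- function() {
  if (is.null(fx$reference)) fx$reference <- make_toy_domain()
  fx$reference
}

# small state-structured library (n = 200) used by several files
fx_library <- function() {
  if (is.null(fx$lib)) {
    samp <- sample_library(fx_reference(), truth_ensemble(seed = 42), 200)
    fx$lib <- list(samp = samp,
                   clib = conformer_library(samp$conformers, fx_reference()))
  }
  fx$lib
}

# rotation matrices used to build known-orientation conformers
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

# apply a rotation to the G-domain reporters of a conformer, about their
# centroid, leaving helix reporters in place
rotate_conformer <- function(conf, rot, id = "rotated") {
  g <- conf$roles == "g_domain"
  ctr <- colMeans(conf$xyz[g, , drop = FALSE])
  xyz <- conf$xyz
  xyz[g, ] <- sweep(sweep(xyz[g, , drop = FALSE], 2, ctr) %*% t(rot), 2, ctr, `+`)
  conformer(id, xyz, conf$roles, conf$g_domain_range)
}
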