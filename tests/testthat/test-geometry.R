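# Conformer geometry: orientation extraction, state assignment, PMF.

test_that("orientation of the reference against itself is the identity", {
  ref <- fx_reference()
  o <- compute_orientation(ref, ref)
  expect_lt(o$beta, 1e-6)
  expect_lt(min(o$gamma, 360 - o$gamma), 1e-6)
})

test_that("known rigid rotations are recovered exactly", {
  ref <- fx_reference()
  # 30 degrees about the membrane x axis tilts the body z axis by 30
  o <- compute_orientation(rotate_conformer(ref, rot_x(30)), ref)
  expect_equal(o$beta, 30, tolerance = 1e-6)
  # a full turn about the membrane normal changes nothing
  conf <- rotate_conformer(ref, rot_x(30))
  o2 <- compute_orientation(rotate_conformer(conf, rot_z(360)), ref)
  expect_equal(o2$beta, o$beta, tolerance = 1e-9)
  expect_equal(o2$gamma, o$gamma, tolerance = 1e-6)
})

test_that("rotation extraction round-trips over random rotations", {
  ref <- fx_reference()
  set.seed(99)
  for (i in 1:100) {
    beta <- runif(1, 1, 179)
    gamma <- runif(1, 0, 360)
    rot <- rot_z(gamma) %*% rot_y(beta)
    o <- compute_orientation(rotate_conformer(ref, rot), ref)
    expect_equal(o$beta, beta, tolerance = 1e-6)
    # the azimuth convention flips by 180 when the body z points downward
    gamma_expect <- if (beta < 90) gamma else (gamma + 180) %% 360
    dg <- abs(o$gamma - gamma_expect) %% 360
    expect_lt(min(dg, 360 - dg), 1e-6)
  }
})

test_that("degenerate reporter geometry is rejected", {
  xyz <- cbind(1:5, 2 * (1:5), 3 * (1:5))  # collinear
  rownames(xyz) <- paste0("g", 21:25)
  roles <- setNames(rep("g_domain", 5), rownames(xyz))
  line <- conformer("line", xyz, roles)
  expect_error(compute_orientation(line, line), "collinear|degenerate")
  ref <- fx_reference()
  small <- conformer("two", ref$xyz[1:2, ], ref$roles[1:2])
  expect_error(compute_orientation(ref, small), "fewer than 3")
})

test_that("com_height is the role centroid and errors on missing roles", {
  xyz <- rbind(c(0, 0, 10), c(0, 0, 30), c(1, 1, 23))
  rownames(xyz) <- c("g20", "g30", "h4")
  roles <- setNames(c("g_domain", "g_domain", "n_helix"), rownames(xyz))
  cf <- conformer("c", xyz, roles)
  expect_equal(com_height(cf, "g_domain"), 20)
  expect_equal(com_height(cf, "n_helix"), 23)
  cf2 <- conformer("c2", xyz[1:2, ], roles[1:2])
  expect_error(com_height(cf2, "n_helix"), "no reporters")
})

test_that("state assignment honours the published bins and wraparound", {
  states <- default_states()
  expect_equal(assign_state(orientation(65, 150), states), "S1")
  expect_equal(assign_state(orientation(25, 30), states), "S3")
  expect_equal(assign_state(orientation(0, 0), states), "unassigned")
  # the S1 gamma interval extends past 180 without clipping
  expect_equal(assign_state(orientation(65, 185), states), "S1")
  # wrapping interval through 0
  wrap <- list(state_definition("W", c(10, 20), c(350, 10)))
  expect_equal(assign_state(orientation(15, 5), wrap), "W")
  expect_equal(assign_state(orientation(15, 355), wrap), "W")
  expect_equal(assign_state(orientation(15, 180), wrap), "unassigned")
})

test_that("overlapping state definitions are rejected at validation", {
  bad <- list(state_definition("A", c(10, 30), c(0, 50)),
              state_definition("B", c(20, 40), c(40, 90)))
  expect_error(assign_state(orientation(15, 20), bad), "overlap")
  # shared beta edge with disjoint gamma is allowed (the default S2/S3 case)
  expect_silent(assign_state(orientation(15, 80), default_states()))
})

test_that("PMF matches the closed form and its invariances", {
  # two bins with probabilities 0.8/0.2 at 298.15 K: dF = kB T ln 4
  ors <- c(replicate(8, orientation(10, 10), simplify = FALSE),
           replicate(2, orientation(100, 200), simplify = FALSE))
  pmf <- pmf_from_orientations(ors, 20, 20, 298.15)
  expect_equal(min(pmf$free_energy, na.rm = TRUE), 0)
  expect_equal(max(pmf$free_energy, na.rm = TRUE), 0.8214,
               tolerance = 1e-3)
  # duplicating every orientation leaves F unchanged
  pmf2 <- pmf_from_orientations(c(ors, ors), 20, 20, 298.15)
  expect_equal(pmf2$free_energy, pmf$free_energy)
  # uniform counts give F = 0 everywhere occupied
  u <- lapply(seq(5, 175, by = 10), function(b) orientation(b, 10))
  pmfu <- pmf_from_orientations(u, 10, 360, 298.15)
  expect_true(all(pmfu$free_energy[!is.na(pmfu$free_energy)] == 0))
  # empty bins are NA, not zero or infinite
  expect_true(anyNA(pmf$free_energy))
  expect_false(any(is.infinite(pmf$free_energy)))
})

test_that("PMF rejects bad inputs", {
  expect_error(pmf_from_orientations(list()), "empty")
  expect_error(pmf_from_orientations(list(orientation(1, 1)), temperature = -1),
               "positive")
  expect_error(pmf_from_orientations(list(orientation(1, 1)), bin_width_beta = 7),
               "divide")
})

test_that("PMF surfaces serialize as TSV with unvisited markers", {
  ors <- list(orientation(10, 10), orientation(10, 12), orientation(100, 200))
  pmf <- pmf_from_orientations(ors, 30, 60)
  path <- tempfile(fileext = ".tsv")
  write_pmf(pmf, path)
  df <- read.delim(path)
  expect_equal(nrow(df), 6 * 6)
  expect_equal(sum(df$count), 3)
  expect_true(all(is.na(df$free_energy_kcal_mol[df$count == 0])))
})
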