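# Membrane PRE back-calculation and measurement errors.

test_that("analytic plane integral agrees with the brute-force lattice sum", {
  params <- pre_params()
  layer <- spin_label_layer(include_trans_leaflet = FALSE)
  for (delta in c(10, 15, 20, 30)) {
    z <- delta - layer$label_depth_d
    a <- gamma2_analytic(z, layer, params)
    d <- gamma2_discrete(z, layer, params, lattice_spacing = 0.5,
                         cutoff_radius = 100 * delta)
    expect_lt(abs(d - a) / a, 0.005)
  }
})

test_that("lattice sum truncation bounds and monotone refinement hold", {
  params <- pre_params()
  layer <- spin_label_layer(include_trans_leaflet = FALSE)
  z <- 12  # delta = 20
  a <- gamma2_analytic(z, layer, params)
  small <- gamma2_discrete(z, layer, params, 0.5, 15)
  expect_lt(small, a)
  cuts <- c(50, 100, 400, 2000)
  vals <- vapply(cuts, function(co) gamma2_discrete(z, layer, params, 0.5, co), 0)
  expect_true(all(diff(vals) >= 0))
})

test_that("gamma2 scales linearly in density and as delta^-4", {
  params <- pre_params()
  l1 <- spin_label_layer(area_density_sigma = 5e-4, include_trans_leaflet = FALSE)
  l2 <- spin_label_layer(area_density_sigma = 1e-3, include_trans_leaflet = FALSE)
  expect_equal(gamma2_analytic(7, l2, params), 2 * gamma2_analytic(7, l1, params))
  l0 <- spin_label_layer(area_density_sigma = 0, include_trans_leaflet = FALSE)
  expect_equal(gamma2_analytic(7, l0, params), 0)
  # halving delta multiplies the single-leaflet term by 16
  expect_equal(gamma2_analytic(2, l1, params),
               16 * gamma2_analytic(12, l1, params))
  expect_error(gamma2_analytic(-10, l1, params), "below")
})

test_that("intensity ratio matches the closed form and is monotone in [0,1]", {
  params <- pre_params(r2_dia = 20, transfer_delay_t = 0.008)
  expect_equal(intensity_ratio(0, params), 1)
  expect_equal(intensity_ratio(20, params), 0.5 * exp(-0.16), tolerance = 1e-12)
  expect_equal(intensity_ratio(Inf, params), 0)
  g <- c(0, 10^(seq(-2, 3.5, by = 0.25)))
  r <- intensity_ratio(g, params)
  expect_true(all(diff(r) < 0))
  expect_true(all(r >= 0 & r <= 1))
  expect_lt(intensity_ratio(1e6, params), 1e-12)
  expect_error(intensity_ratio(-1, params), "non-negative")
})

test_that("measurement error reproduces hand-evaluated cases exactly", {
  expect_equal(measurement_error(0.5, 1, 10, 20), 0.5 * sqrt(0.01 + 0.0025),
               tolerance = 1e-12)
  expect_equal(measurement_error(1, 1, 10, 10), sqrt(2) / 10, tolerance = 1e-12)
  expect_equal(measurement_error(0, 1, 10, 10), 0)
  # homogeneous of degree 1 in the ratio, decreasing in each S/N
  expect_equal(measurement_error(0.8, 1, 15, 25),
               2 * measurement_error(0.4, 1, 15, 25))
  expect_lt(measurement_error(0.5, 1, 20, 20), measurement_error(0.5, 1, 10, 20))
  expect_error(measurement_error(1, 1, 0, 10), "positive")
  expect_error(measurement_error(1, 0, 10, 10), "positive")
})

test_that("predicted profiles depend only on reporter heights", {
  ref <- fx_reference()
  prof <- predict_profile(ref)
  shifted <- ref
  shifted$xyz[, 1] <- shifted$xyz[, 1] + 50
  shifted$xyz[, 2] <- shifted$xyz[, 2] - 20
  expect_equal(predict_profile(shifted)$ratio, prof$ratio)
  # far limit: everything at z = 100 relaxes to ratio ~ 1
  far <- ref
  far$xyz[, 3] <- 100
  expect_true(all(predict_profile(far)$ratio > 0.99))
  # reporters sorted by height have ratios sorted the same way
  ord <- order(prof$z_height_A)
  expect_true(all(diff(prof$ratio[ord]) >= 0))
})

test_that("reporters below the label plane bleach with a warning", {
  ref <- fx_reference()
  deep <- ref
  deep$xyz[1, 3] <- -12   # below the 8-A label plane
  expect_warning(p <- predict_profile(deep), "label plane")
  expect_equal(p$ratio[1], 0)
  expect_true(p$bleached[1])
  # 1 A above the label plane: essentially fully bleached but computable
  near <- ref
  near$xyz[1, 3] <- -7
  expect_lt(predict_profile(near)$ratio[1], 0.05)
})

test_that("ensemble averaging follows the fast-exchange convention", {
  lib <- fx_library()$samp$conformers[1:4]
  single <- ensemble_profile(lib[1], weights = 1)
  expect_equal(single$ratio, suppressWarnings(predict_profile(lib[[1]]))$ratio)
  twin <- ensemble_profile(lib[c(1, 1)], weights = c(0.5, 0.5))
  expect_equal(twin$ratio, single$ratio)
  # Jensen: fast-exchange ratio never exceeds the intensity average
  set.seed(7)
  for (i in 1:20) {
    w <- runif(4); w <- w / sum(w)
    fe <- ensemble_profile(lib, w, "fast_exchange")
    ia <- ensemble_profile(lib, w, "intensity_average")
    expect_true(all(fe$ratio <= ia$ratio + 1e-12))
  }
  expect_error(ensemble_profile(lib, c(1, 1, 1, 1)), "sum to 1")
  mism <- lib
  rownames(mism[[2]]$xyz)[1] <- "g999"
  expect_error(ensemble_profile(mism), "mismatched")
})
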