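# Deuterium order parameters, chain extension, relaxation fits.

test_that("splitting-order conversion inverts exactly for both group types", {
  expect_equal(splitting_to_order(0), 0)
  expect_equal(splitting_to_order(25.05, "CH2"), 0.2, tolerance = 1e-12)
  # a methyl with the same splitting reports a 3x larger order parameter
  expect_equal(splitting_to_order(10, "CH3"), 3 * splitting_to_order(10, "CH2"))
  s <- seq(0.01, 0.45, by = 0.02)
  for (g in c("CH2", "CH3"))
    expect_equal(splitting_to_order(order_to_splitting(s, g), g), s,
                 tolerance = 1e-12)
  expect_error(splitting_to_order(200, "CH2"), "unphysical")
  expect_error(splitting_to_order(-1), "non-negative")
})

test_that("smoothed profiles are monotone and insensitive to input order", {
  truth <- order_profile(2:16, 0.22 * pmin(1, exp(-(0:14) / 8)))
  sp <- simulate_splittings(truth, noise_khz = 0, seed = 1)
  prof <- smooth_profile(sp, 16)
  expect_true(all(diff(prof$s_cd) <= 1e-12))
  expect_equal(prof$s_cd, truth$s_cd, tolerance = 1e-9)
  # permuting rows changes nothing
  prof2 <- smooth_profile(sp[sample(nrow(sp)), ], 16)
  expect_equal(prof2$s_cd, prof$s_cd)
  # masking positions: interpolation stays close to the truth
  spm <- simulate_splittings(truth, noise_khz = 0, seed = 1, mask = c(5, 9, 12))
  profm <- smooth_profile(spm, 16)
  expect_lt(max(abs(profm$s_cd - truth$s_cd)), 0.02)
  expect_error(smooth_profile(sp, 10), "chain_length")
})

test_that("mean-torque travel matches closed-form limits", {
  p <- order_profile(2:4, c(0.5, 0.25, 0.125))
  ext <- chain_extension(p)
  expect_equal(ext$cos_beta, c(1, (1 + sqrt(1 / 3)) / 2, 0.5), tolerance = 1e-9)
  expect_equal(ext$travel_A, c(1.27, 1.00162, 0.635), tolerance = 1e-5)
  # below |S| = 1/8 the closed form leaves its domain and the fallback flags
  p2 <- order_profile(2:3, c(0.2, 0.05))
  ext2 <- chain_extension(p2)
  expect_true(ext2$sub_eighth[2])
  expect_equal(ext2$cos_beta[2], 0.5)
})

test_that("chain extension is cumulative from the terminal methyl", {
  p <- order_profile(2:14, rep(0.5, 13))  # all-trans: 1.27 A per segment
  ext <- chain_extension(p)
  expect_equal(ext$extension_A[ext$carbon_index == 14], 0)
  expect_equal(ext$extension_A[ext$carbon_index == 2], 12 * 1.27)
  expect_true(all(diff(ext$extension_A) <= 0))  # decreasing toward CH3
  # pointwise larger order gives pointwise larger extension
  lo <- chain_extension(order_profile(2:14, rep(0.15, 13)))
  expect_true(all(ext$extension_A >= lo$extension_A))
})

test_that("inversion-recovery fits recover the rate on the printed schedule", {
  expect_length(ir_schedule(), 11)
  sim <- simulate_inversion_recovery(2, f = 1, i_inf = 100)
  fit <- fit_inversion_recovery(sim$delays, sim$intensities)
  expect_equal(fit$r1z, 2, tolerance = 1e-6)
  expect_equal(fit$f, 1, tolerance = 1e-6)
  # zero crossing at ln(2)/R for full inversion
  t0 <- log(2) / fit$r1z
  expect_lt(abs(fit$i_inf * (1 - 2 * fit$f * exp(-fit$r1z * t0))), 1e-6)
  # intensity scale invariance
  fit10 <- fit_inversion_recovery(sim$delays, 10 * sim$intensities)
  expect_equal(fit10$r1z, fit$r1z, tolerance = 1e-9)
  expect_error(fit_inversion_recovery(c(0.1, 0.2, 0.1, 0.4, 0.5), rep(1, 5)),
               "increasing")
  expect_error(fit_inversion_recovery(c(0.1, 0.2), c(1, 2)), "at least 5")
})

test_that("inversion-recovery fits are nearly unbiased under 5% noise", {
  rates <- replicate(100, {
    s <- simulate_inversion_recovery(2, f = 1, i_inf = 100, noise = 5,
                                     seed = sample.int(1e6, 1))
    fit_inversion_recovery(s$delays, s$intensities)$r1z
  })
  expect_lt(abs(mean(rates) - 2) / 2, 0.02)
  # the 95% CI brackets the rate in a noiseless fit
  s0 <- simulate_inversion_recovery(2)
  ci <- fit_inversion_recovery(s0$delays, s0$intensities)$ci
  expect_true(ci[1] <= 2 && 2 <= ci[2])
})

test_that("square-law tables pair S^2 with rates, sorted ascending", {
  prof <- order_profile(2:6, c(0.2, 0.18, 0.15, 0.1, 0.05))
  rates <- data.frame(carbon_index = c(4, 2, 6), r1z = c(9, 4, 25))
  tab <- square_law_table(prof, rates)
  expect_equal(tab$s_squared, sort(c(0.2, 0.15, 0.05)^2))
  expect_equal(tab$r1z[tab$carbon_index == 2], 4)
  # CSV round trip preserves the pairs
  path <- tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  expect_equal(read.csv(path)$r1z, tab$r1z)
  expect_error(square_law_table(prof, data.frame(carbon_index = 99, r1z = 1)),
               "shared")
})

test_that("order parameters from C-H vectors follow the P2 average", {
  along_z <- list(`2` = matrix(rep(c(0, 0, 1), 10), ncol = 3, byrow = TRUE))
  p <- order_from_vectors(along_z)
  expect_equal(attr(p, "signed_s"), 1)
  magic <- 54.7356103 * pi / 180
  v <- c(sin(magic), 0, cos(magic))
  pm <- order_from_vectors(list(`3` = matrix(rep(v, 5), ncol = 3, byrow = TRUE)))
  expect_lt(abs(attr(pm, "signed_s")), 1e-6)
  # isotropic vectors average to zero order
  set.seed(12)
  g <- matrix(rnorm(3e5 * 3), ncol = 3)
  g <- g / sqrt(rowSums(g^2))
  pi0 <- order_from_vectors(list(`4` = g))
  expect_lt(abs(attr(pi0, "signed_s")), 0.005)
  expect_error(order_from_vectors(list(`2` = matrix(1:6, 2))), "unit length")
})
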