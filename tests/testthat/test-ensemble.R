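# Ensemble selection against PRE profiles.

test_that("chi-square matches hand evaluation and scales with sigma", {
  meas <- pre_measurement(data.frame(
    reporter_id = c("g20", "g30"), i_para = c(500, 600), i_dia = c(1000, 1000),
    sn_para = 50, sn_dia = 50))
  pred <- data.frame(reporter_id = c("g20", "g30"),
                     ratio = meas$ratio + c(0.1, 0.2))
  meas$error <- c(0.1, 0.1)
  expect_equal(chi_square(pred, meas, sigma_floor = 1e-6), 1 + 4)
  meas$error <- c(0.2, 0.2)
  expect_equal(chi_square(pred, meas, sigma_floor = 1e-6), 5 / 4)
  expect_equal(chi_square(data.frame(reporter_id = meas$reporter_id,
                                     ratio = meas$ratio), meas), 0)
  expect_error(chi_square(data.frame(reporter_id = "zz", ratio = 1), meas),
               "shared")
})

test_that("a planted single conformer is recovered exactly at N = 1", {
  fx <- fx_library()
  meas <- simulate_pre_measurement(fx$samp$conformers[17], noise_fraction = 0,
                                   seed = 3)
  fit <- select_ensemble(fx$clib, meas, fit_config(ensemble_size = 1,
                                                   restarts = 5, seed = 1))
  expect_equal(fit$member_ids, 17)
  expect_lt(fit$chi2, 1e-10)
})

test_that("selection is deterministic given the seed", {
  fx <- fx_library()
  meas <- simulate_pre_measurement(fx$samp$conformers[c(3, 9, 9, 40)],
                                   noise_fraction = 0.15, seed = 5)
  cfg <- fit_config(ensemble_size = 4, restarts = 5, seed = 11)
  f1 <- select_ensemble(fx$clib, meas, cfg)
  f2 <- select_ensemble(fx$clib, meas, cfg)
  expect_identical(f1, f2)
  s1 <- repeat_selection(fx$clib, meas, fit_config(ensemble_size = 4,
                                                   restarts = 3, repeats = 5,
                                                   seed = 2))
  s2 <- repeat_selection(fx$clib, meas, fit_config(ensemble_size = 4,
                                                   restarts = 3, repeats = 5,
                                                   seed = 2))
  expect_identical(s1, s2)
})

test_that("best chi-square never increases with ensemble size on clean data", {
  fx <- fx_library()
  meas <- simulate_pre_measurement(fx$samp$conformers[c(2, 5, 8, 11, 20, 33)],
                                   noise_fraction = 0, seed = 9)
  chis <- vapply(c(1, 2, 4, 8, 16), function(n)
    select_ensemble(fx$clib, meas,
                    fit_config(ensemble_size = n, restarts = 5, seed = 4))$chi2,
    0)
  expect_true(all(diff(chis) <= 1e-8))
})

test_that("the proposal-based climber also reduces chi-square", {
  fx <- fx_library()
  meas <- simulate_pre_measurement(fx$samp$conformers[c(3, 14)],
                                   noise_fraction = 0, seed = 2)
  cfg <- fit_config(ensemble_size = 4, search_method = "proposals",
                    restarts = 5, iterations = 2000, seed = 8)
  fit <- select_ensemble(fx$clib, meas, cfg)
  # compare against a random multiset baseline
  set.seed(8)
  base <- replicate(20, {
    ids <- sample(length(fx$clib$conformers), 4, replace = TRUE)
    chi_square(ensemble_profile(fx$clib$conformers[ids]), meas)
  })
  expect_lt(fit$chi2, min(base) + 1e-9)
})

test_that("ensemble COM is the multiplicity-weighted member mean", {
  fx <- fx_library()
  fit <- list(member_ids = c(1, 1, 2), chi2 = 0,
              state_counts = c(), com_mean = NA)
  class(fit) <- "ensemble_fit"
  h <- fx$clib$heights
  expect_equal(ensemble_com(fit, fx$clib), (2 * h[1] + h[2]) / 3)
  fit$member_ids <- c(1, 10^6)
  expect_error(ensemble_com(fit, fx$clib), "unknown member")
})

test_that("repeat fractions have 1/N granularity and zero noise gives SD 0", {
  fx <- fx_library()
  meas <- simulate_pre_measurement(fx$samp$conformers[c(2, 7, 19, 25)],
                                   noise_fraction = 0, seed = 1)
  cfg <- fit_config(ensemble_size = 16, repeats = 4, noise_fraction = 0,
                    restarts = 3, seed = 6)
  summ <- repeat_selection(fx$clib, meas, cfg)
  expect_true(all(abs(summ$per_repeat %% 6.25) < 1e-9))
  expect_true(all(summ$sd_pct == 0))
  expect_true(all(abs(colSums(t(summ$per_repeat)) - 100) < 1e-9))
})

test_that("population comparison is a two-sided Welch test", {
  mk <- function(mat) {
    structure(list(per_repeat = mat, states = colnames(mat)),
              class = "population_summary")
  }
  set.seed(4)
  a <- mk(matrix(rnorm(100, 10, 5), ncol = 1, dimnames = list(NULL, "S2")))
  b <- mk(matrix(rnorm(100, 50, 5), ncol = 1, dimnames = list(NULL, "S2")))
  res <- compare_populations(a, b, "S2")
  expect_lt(res$p_value, 1e-4)
  swapped <- compare_populations(b, a, "S2")
  expect_equal(swapped$t_statistic, -res$t_statistic)
  expect_equal(swapped$p_value, res$p_value)
  same <- compare_populations(a, a, "S2")
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_populations(a, b, "S9"), "absent")
})
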