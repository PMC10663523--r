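# Fixed-size ensemble selection against measured PRE profiles, repeated
# fitting under noise perturbation, population statistics.

#' Conformer library with precomputed PRE responses
#'
#' Bundles a conformer list with its per-reporter back-calculated Gamma2
#' matrix (recomputable via [predict_profile]), per-conformer orientational
#' state labels and G-domain COM heights, ready for ensemble fitting.
#'
#' @param conformers list of [conformer]s sharing one reporter set.
#' @param reference reference [conformer] for orientation extraction.
#' @param states list of [state_definition]s for labelling.
#' @param layer,params PRE model settings.
#' @return object of class `conformer_library`.
#' @export
conformer_library <- function(conformers, reference, states = default_states(),
                              layer = spin_label_layer(), params = pre_params()) {
  stopifnot(length(conformers) >= 1)
  ids <- rownames(conformers[[1]]$xyz)
  preds <- lapply(conformers, function(cf) {
    p <- suppressWarnings(predict_profile(cf, layer, params))
    p[match(ids, p$reporter_id), ]
  })
  gamma2 <- t(vapply(preds, function(p) p$gamma2_s1, numeric(length(ids))))
  colnames(gamma2) <- ids
  orients <- lapply(conformers, compute_orientation, reference = reference)
  labels <- vapply(orients, assign_state, "", states = states)
  heights <- vapply(conformers, com_height, 0, role = "g_domain")
  structure(list(conformers = conformers, reference = reference,
                 response_matrix = gamma2, orientations = orients,
                 state_labels = labels, heights = heights,
                 states = states, layer = layer, params = params),
            class = "conformer_library")
}

#' @export
print.conformer_library <- function(x, ...) {
  cat("<conformer_library>", length(x$conformers), "conformers,",
      ncol(x$response_matrix), "reporters\n")
  print(table(x$state_labels))
  invisible(x)
}

#' Ensemble fit configuration
#'
#' @param ensemble_size number of members N (multiset, repetition allowed).
#' @param repeats number of noise-perturbed refits for population statistics.
#' @param noise_fraction multiplicative Gaussian noise SD as a fraction of
#'   each measured ratio.
#' @param seed integer seed; every source of randomness derives from it.
#' @param restarts independent search starts per fit.
#' @param iterations for `"sweep"`, the maximum number of full coordinate
#'   sweeps; for `"proposals"`, the number of random swap proposals.
#' @param search_method `"sweep"` (exhaustive best-single-swap coordinate
#'   descent; default) or `"proposals"` (random single-swap hill climb).
#' @param perturb what the repeats perturb: the measured data (default), only
#'   the search start, or both.
#' @param sigma_floor lower bound applied to measured errors in the chi^2
#'   weights.
#' @param polish_threshold chi^2-per-reporter level below which the exact
#'   polish phase runs (low-support enumeration plus pair repairs).  Fits in
#'   the noise-free regime sit orders of magnitude below it, noise-limited
#'   fits orders of magnitude above; set to `Inf` to always polish or `0` to
#'   never.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(ensemble_size = 16, repeats = 100, noise_fraction = 0.15,
                       seed = 1, restarts = 20, iterations = 2000,
                       search_method = c("sweep", "proposals"),
                       perturb = c("data", "start", "both"),
                       sigma_floor = 0.01, polish_threshold = 0.01) {
  search_method <- match.arg(search_method)
  perturb <- match.arg(perturb)
  stopifnot(ensemble_size >= 1, repeats >= 1, noise_fraction >= 0,
            restarts >= 1, iterations >= 1, sigma_floor > 0,
            polish_threshold >= 0)
  if (search_method == "sweep" && iterations == 2000) iterations <- 50
  structure(list(ensemble_size = as.integer(ensemble_size),
                 repeats = as.integer(repeats),
                 noise_fraction = noise_fraction, seed = as.integer(seed),
                 restarts = as.integer(restarts),
                 iterations = as.integer(iterations),
                 search_method = search_method, perturb = perturb,
                 sigma_floor = sigma_floor, polish_threshold = polish_threshold),
            class = "fit_config")
}

# shared reporters + floored sigma between a gamma2 response matrix and a
# measurement table
.match_measurement <- function(lib, measured, sigma_floor) {
  ids <- intersect(colnames(lib$response_matrix), measured$reporter_id)
  if (length(ids) == 0) stop("no shared reporters between library and measurement")
  i <- match(ids, measured$reporter_id)
  list(ids = ids,
       gamma2 = lib$response_matrix[, ids, drop = FALSE],
       ratio = measured$ratio[i],
       sigma = pmax(measured$error[i], sigma_floor))
}

#' Weighted chi-square between predicted and measured PRE ratios
#'
#' Sum over shared reporters of ((ratio_calc - ratio_meas) / sigma)^2, with
#' sigma the measurement error floored at `sigma_floor`.
#'
#' @param predicted a `pre_prediction` (e.g. from [ensemble_profile]).
#' @param measured a `pre_measurement`.
#' @param sigma_floor error floor (default 0.01).
#' @return chi-square value.
#' @export
chi_square <- function(predicted, measured, sigma_floor = 0.01) {
  stopifnot(inherits(measured, "pre_measurement"))
  ids <- intersect(predicted$reporter_id, measured$reporter_id)
  if (length(ids) == 0) stop("no shared reporters")
  p <- predicted$ratio[match(ids, predicted$reporter_id)]
  i <- match(ids, measured$reporter_id)
  sig <- pmax(measured$error[i], sigma_floor)
  sum(((p - measured$ratio[i]) / sig)^2)
}

#' Select a fixed-size conformer ensemble fitting a PRE profile
#'
#' Searches over multisets of `ensemble_size` library members (uniform
#' weights 1/N, fast-exchange averaging of Gamma2) for the minimum weighted
#' chi-square against the measured ratios.  The default search runs
#' exhaustive best-single-swap coordinate descent to a local minimum from
#' `restarts` starts (the first start is a greedy forward construction, the
#' rest random); `"proposals"` instead accepts random single-member
#' replacements on strict decrease.  Deterministic given `cfg$seed`.
#'
#' @param lib a [conformer_library].
#' @param measured a `pre_measurement` table; fitting uses only the reporters
#'   present in it.
#' @param cfg a [fit_config].
#' @param seed optional override of `cfg$seed` (used by [repeat_selection]).
#' @return object of class `ensemble_fit`: `member_ids` (multiset of row
#'   indices), `chi2`, `state_counts`, `com_mean`.
#' @export
select_ensemble <- function(lib, measured, cfg = fit_config(), seed = cfg$seed) {
  stopifnot(inherits(lib, "conformer_library"), inherits(measured, "pre_measurement"),
            inherits(cfg, "fit_config"))
  if (cfg$ensemble_size > length(lib$conformers) * 1000L)
    stop("ensemble size too large for library")
  mm <- .match_measurement(lib, measured, cfg$sigma_floor)
  res <- ensemble_search_cpp(mm$gamma2, mm$ratio, mm$sigma,
                             cfg$ensemble_size, lib$params$r2_dia,
                             lib$params$transfer_delay_t, cfg$restarts,
                             cfg$iterations, as.integer(seed),
                             cfg$search_method, cfg$polish_threshold)
  members <- sort(res$members)
  labels <- lib$state_labels[members]
  state_names <- vapply(lib$states, `[[`, "", "name")
  counts <- vapply(c(state_names, "unassigned"),
                   function(s) sum(labels == s), 0L)
  structure(list(member_ids = members, chi2 = res$chi2,
                 state_counts = counts,
                 com_mean = mean(lib$heights[members]),
                 n_reporters = length(mm$ids)),
            class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat("<ensemble_fit> N =", length(x$member_ids), " chi2 =",
      format(x$chi2, digits = 4), " COM =", round(x$com_mean, 1), "A\n")
  print(x$state_counts)
  invisible(x)
}

#' Multiplicity-weighted mean G-domain COM height of an ensemble
#'
#' @param fit an [ensemble_fit].
#' @param lib the [conformer_library] it was fitted from.
#' @return height in Angstrom.
#' @export
ensemble_com <- function(fit, lib) {
  stopifnot(inherits(fit, "ensemble_fit"), inherits(lib, "conformer_library"))
  if (any(fit$member_ids < 1 | fit$member_ids > length(lib$conformers)))
    stop("unknown member id in fit")
  mean(lib$heights[fit$member_ids])
}

# per-repeat RNG stream: a deterministic integer derived from (seed, repeat)
.repeat_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(r) * 16807) %% 2147483647)
}

#' Repeat ensemble selection under noise perturbation
#'
#' For each repeat the measured ratios are perturbed by independent Gaussian
#' noise with SD = `noise_fraction` x ratio, the ensemble is refit with a
#' seed derived from (`cfg$seed`, repeat index), and the per-state member
#' fractions and ensemble COM are recorded.  Reported populations are the
#' mean and SD over repeats; per-repeat fractions (always multiples of 1/N)
#' are retained for significance testing.
#'
#' Two details matter for unbiased populations.  Perturbed ratios are
#' clipped only at 0: intensity ratios above 1 arise from noise in real
#' spectra, and truncating them at 1 would push every high reporter
#' systematically down and drag the refit ensembles toward the membrane.
#' And the chi-square weights during the refits include the injected noise,
#' sigma_eff^2 = sigma_meas^2 + (noise_fraction x ratio)^2: the refit data
#' carry that error by construction, and weighting them by the much smaller
#' spectral error alone would make every refit chase individual noise
#' excursions.
#'
#' @inheritParams select_ensemble
#' @return object of class `population_summary`: `states`, `mean_pct`,
#'   `sd_pct`, `per_repeat` (repeats x states matrix of fractions in
#'   percent), `com_per_repeat`, `com_mean`, `com_sd`, `chi2`.
#' @export
repeat_selection <- function(lib, measured, cfg = fit_config()) {
  stopifnot(cfg$repeats >= 2)
  state_names <- c(vapply(lib$states, `[[`, "", "name"), "unassigned")
  n_states <- length(state_names)
  frac <- matrix(NA_real_, cfg$repeats, n_states,
                 dimnames = list(NULL, state_names))
  coms <- numeric(cfg$repeats)
  chi2s <- numeric(cfg$repeats)
  for (r in seq_len(cfg$repeats)) {
    sr <- .repeat_seed(cfg$seed, r)
    m_r <- measured
    if (cfg$perturb %in% c("data", "both") && cfg$noise_fraction > 0) {
      set.seed(sr)
      noisy <- m_r$ratio * (1 + rnorm(nrow(m_r), 0, cfg$noise_fraction))
      m_r$ratio <- pmax(noisy, 0)
      m_r$error <- sqrt(measured$error^2 +
                          (cfg$noise_fraction * measured$ratio)^2)
    }
    search_seed <- if (cfg$perturb == "data") cfg$seed else sr
    fit <- select_ensemble(lib, m_r, cfg, seed = search_seed)
    frac[r, ] <- 100 * fit$state_counts / cfg$ensemble_size
    coms[r] <- fit$com_mean
    chi2s[r] <- fit$chi2
  }
  structure(list(states = state_names,
                 mean_pct = colMeans(frac),
                 sd_pct = apply(frac, 2, sd),
                 per_repeat = frac,
                 com_per_repeat = coms,
                 com_mean = mean(coms), com_sd = sd(coms),
                 chi2 = chi2s, cfg = cfg),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat("<population_summary>", nrow(x$per_repeat), "repeats\n")
  for (s in x$states)
    cat(sprintf("  %-10s %5.1f%% +/- %.1f\n", s, x$mean_pct[s], x$sd_pct[s]))
  cat(sprintf("  ensemble COM %.1f +/- %.1f A; median chi2 %.2f\n",
              x$com_mean, x$com_sd, stats::median(x$chi2)))
  invisible(x)
}

#' Compare a state's population between two summaries
#'
#' Two-sided Welch two-sample t-test on the per-repeat state fractions.
#'
#' @param a,b [repeat_selection] results retaining per-repeat fractions.
#' @param state state name present in both.
#' @return list with `t_statistic` and `p_value`.
#' @export
compare_populations <- function(a, b, state) {
  stopifnot(inherits(a, "population_summary"), inherits(b, "population_summary"))
  if (!(state %in% colnames(a$per_repeat)) || !(state %in% colnames(b$per_repeat)))
    stop("state '", state, "' absent from a summary")
  x <- a$per_repeat[, state]
  y <- b$per_repeat[, state]
  if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y))
    return(list(t_statistic = 0, p_value = 1))
  tt <- t.test(x, y, alternative = "two.sided", var.equal = FALSE)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value)
}
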