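test_that("PSTH rates and standard errors follow the binning arithmetic", {
  rec <- unit_recording("u1", list(c(0.0125)))
  p <- compute_psth(rec, t_range = c(0, 0.05))
  expect_equal(p$rate[p$bin_centers == 0.0125], 200)
  expect_equal(sum(p$rate > 0), 1)
  # duplicating trials keeps the rate, shrinks the sem
  rec2 <- unit_recording("u2", list(c(0.01, 0.02), c(0.012)))
  rec4 <- unit_recording("u4", rep(rec2$trials, 2))
  p2 <- compute_psth(rec2, t_range = c(0, 0.05))
  p4 <- compute_psth(rec4, t_range = c(0, 0.05))
  expect_equal(p4$rate, p2$rate)
  nz <- p2$sem > 0
  expect_true(all(p4$sem[nz] < p2$sem[nz]))
  # homogeneous Poisson: mean bin rate near the true rate
  rec_p <- constant_recording(40, n_trials = 200, seed = 5, t_range = c(0, 1))
  pp <- compute_psth(rec_p, t_range = c(0, 1))
  expect_equal(mean(pp$rate), 40, tolerance = 0.05)
})

test_that("inclusion filter applies the 100-spike threshold inclusively", {
  mk <- function(n) unit_recording("u", list(seq_len(n) * 1e-3))
  recs <- list(mk(99), mk(100), mk(150))
  kept <- inclusion_filter_units(recs)
  expect_length(kept, 2)
  expect_equal(vapply(kept, function(r) sum(lengths(r$trials)), 1), c(100, 150))
})

test_that("onset delay estimator finds steps and demands overrides otherwise", {
  # noise-free step at exactly 30 ms
  edges <- seq(-0.1, 0.2, by = 0.005)
  centers <- edges[-length(edges)] + 0.0025
  rate <- ifelse(centers > 0.03, 80, 10)
  psth <- structure(list(bin_centers = centers, rate = rate,
                         sem = rep(1, length(rate)), bin_width = 0.005,
                         n_trials = 10), class = "psth")
  expect_equal(estimate_onset_delay(psth), 0.03)
  expect_equal(estimate_onset_delay(psth, override = 0.042), 0.042)
  flat <- structure(list(bin_centers = centers, rate = rep(10, length(rate)),
                         sem = rep(1, length(rate)), bin_width = 0.005,
                         n_trials = 10), class = "psth")
  expect_error(estimate_onset_delay(flat), "override")
  # Poisson data with a known 31 ms delay: recovered within 5 ms
  rec <- onset_recording(10, 60, 80, 0.012, 0.05, delay = 0.031,
                         n_trials = 200, seed = 9)
  est <- estimate_onset_delay(compute_psth(rec, t_range = c(-0.4, 0.7)))
  expect_lt(abs(est - 0.031), 0.005)
})

test_that("sustained levels are window means of the PSTH", {
  edges <- seq(-0.2, 0.6, by = 0.005)
  centers <- edges[-length(edges)] + 0.0025
  rate <- ifelse(centers < 0, 20, 80)
  psth <- structure(list(bin_centers = centers, rate = rate,
                         sem = rep(1, length(rate)), bin_width = 0.005,
                         n_trials = 10), class = "psth")
  lv <- estimate_sustained_levels(psth)
  expect_equal(lv$A_pre, 20)
  expect_equal(lv$A_post, 80)
  expect_error(estimate_sustained_levels(psth, post_window = c(2, 3)),
               "outside")
})

test_that("chi-square error is zero at truth and one at a one-sem offset", {
  r <- reduced_params(20, 60, 90, 0.012, 0.05)
  tc <- reduced_response(r, seq(-0.1, 0.4, by = 2.5e-4))
  psth <- psth_from_rate(tc)
  psth$sem <- rep(4, length(psth$rate))
  model <- reduced_response(r, seq(0, 0.25, by = 2.5e-4))
  # residual error reflects only the model-downsampling approximation
  expect_lt(chi_square_fit_error(model, psth, delta_tau = 0), 0.02)
  shifted <- psth
  shifted$rate <- shifted$rate + 4   # one sem everywhere
  expect_equal(chi_square_fit_error(model, shifted, delta_tau = 0), 1,
               tolerance = 0.05)
  # unsquared variant for the same offset gives sem, not 1
  expect_equal(chi_square_fit_error(model, shifted, delta_tau = 0,
                                    denominator = "sem"), 4, tolerance = 0.05)
  expect_error(chi_square_fit_error(model, psth, delta_tau = 5), "no PSTH bins")
})

test_that("grid search recovers a noise-free unit and is deterministic", {
  r <- reduced_params(45, 60, 100, 0.015, 0.060, t_change = 0)
  tc <- reduced_response(r, seq(-0.4, 0.7, by = 2.5e-4))
  psth <- psth_from_rate(tc)
  f <- grid_search_fit(psth, 45, 60, delta_tau = 0)
  # the chi-square valley is shallow along a (tau_e, tau_i, A_max) ridge:
  # the rate curve is recovered essentially exactly, the parameters to
  # within the ridge width rather than the final grid spacing
  expect_lt(f$chi2_per_bin, 1e-3)
  expect_lt(abs(f$tau_e - 0.015) / 0.015, 0.15)
  expect_lt(abs(f$tau_i - 0.060) / 0.060, 0.15)
  expect_lt(abs(f$A_max - 100) / 100, 0.15)
  expect_true(f$converged)
  f2 <- grid_search_fit(psth, 45, 60, delta_tau = 0)
  expect_identical(f, f2)
  # degenerate flat input is flagged
  flat <- psth
  flat$rate <- rep(50, length(flat$rate))
  fd <- grid_search_fit(flat, 50, 50, delta_tau = 0)
  expect_true(fd$degenerate)
  expect_false(fd$converged)
})

test_that("grid refinement reaches the documented resolution", {
  cfg <- fit_config()
  r <- reduced_params(30, 70, 95, 0.02, 0.07, t_change = 0)
  tc <- reduced_response(r, seq(-0.4, 0.7, by = 2.5e-4))
  f <- grid_search_fit(psth_from_rate(tc), 30, 70, 0, cfg)
  init_spacing <- diff(cfg$range_tau_i) / (cfg$bins_tau - 1)
  bound <- init_spacing * (2 / cfg$bins_tau)^(cfg$iterations - 1)
  expect_lte(f$resolution[["tau_i"]], bound)
})

test_that("global-parameter population fits cost accuracy as expected", {
  # small synthetic population sharing a common tau_e / tau_i ratio
  set.seed(31)
  cfg <- fit_config(bins_Amax = 10, bins_tau = 8, iterations = 2)
  recs <- list()
  delays <- c(0.030, 0.030, 0.030)
  taui <- c(0.035, 0.06, 0.09)
  for (k in 1:3) {
    recs[[k]] <- onset_recording(12, 55 + 10 * k, (55 + 10 * k) / 0.75,
                                 0.4 * taui[k], taui[k], delay = delays[k],
                                 n_trials = 30, seed = 40 + k)
  }
  free <- population_fit_global(recs, character(), cfg, delta_tau = delays)
  expect_equal(free$percent_error_increase, 0)
  fix_ratio <- population_fit_global(recs, "tau_ratio", cfg,
                                     delta_tau = delays,
                                     outer_bins = 7, outer_iterations = 2)
  fix_taue <- population_fit_global(recs, "tau_e", cfg, delta_tau = delays,
                                    outer_bins = 7, outer_iterations = 2)
  # fixing the shared ratio hurts less than fixing tau_e itself
  expect_lt(fix_ratio$percent_error_increase, fix_taue$percent_error_increase)
  # fixing two parameters hurts at least as much as fixing one
  fix_two <- population_fit_global(recs, c("tau_e", "A_max"), cfg,
                                   delta_tau = delays,
                                   outer_bins = 5, outer_iterations = 1)
  expect_gte(fix_two$percent_error_increase,
             fix_taue$percent_error_increase - 1e-8)
  expect_error(population_fit_global(recs[1], "tau_e", cfg), "two units")
})

test_that("surrogate chi-square distribution is calibrated and reproducible", {
  fits <- data.frame(tau_e = c(0.012, 0.02), tau_i = c(0.05, 0.04),
                     A_max = c(90, 110), A_pre = c(12, 9),
                     A_post = c(65, 80))
  cfg <- fit_config(bins_Amax = 12, bins_tau = 8, iterations = 2)
  chi <- surrogate_chi2_distribution(fits, n_units = 12, n_trials = 10,
                                     seed = 77, cfg = cfg)
  chi_again <- surrogate_chi2_distribution(fits, n_units = 12, n_trials = 10,
                                           seed = 77, cfg = cfg)
  expect_identical(chi, chi_again)
  # a correctly specified model fits its own surrogates at chi2 near 1
  expect_gt(mean(chi), 0.6)
  expect_lt(mean(chi), 1.6)
})
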