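test_that("Poisson rate-change test reproduces exact tail probabilities", {
  # build a recording whose baseline fixes lambda = 4 in a 20 ms window:
  # baseline rate 40 spikes/s in one trial over [-0.4, 0.055] and a chosen
  # number of spikes in the test window
  mk <- function(n_test) {
    base <- seq(-0.399, 0.054, length.out = 91)  # 91 / 0.455 s = 200 spikes/s
    test_spikes <- if (n_test > 0) seq(0.1401, 0.1599, length.out = n_test)
    else numeric(0)
    unit_recording("u", list(sort(c(base, test_spikes))))
  }
  lam <- 91 / 0.455 * 0.02   # expected count 4 in the 20 ms window
  up <- poisson_rate_change_test(mk(10), tail = "up")
  expect_equal(up$expected, lam)
  expect_equal(up$p_value, ppois(9, lam, lower.tail = FALSE))
  expect_true(up$significant)
  down <- poisson_rate_change_test(mk(0), tail = "down")
  expect_equal(down$p_value, exp(-lam), tolerance = 1e-12)
  expect_true(down$significant)
  # observed equal to the expectation: not significant
  at_mean <- poisson_rate_change_test(mk(4), tail = "up")
  expect_false(at_mean$significant)
})

test_that("attention index is normalized and antisymmetric", {
  expect_equal(attention_index(50, 50), 0)
  expect_equal(attention_index(60, 40), 0.2)
  expect_equal(attention_index(7, 0), 1)
  expect_equal(attention_index(40, 60), -attention_index(60, 40))
  expect_error(attention_index(0, 0), "undefined")
})

test_that("spike-count dispersion matches Poisson statistics", {
  rec <- constant_recording(40, n_trials = 2000, seed = 13)
  mv <- mean_variance_by_bin(rec)
  expect_equal(nrow(mv), 24)   # [-0.4, 0.2] in 25 ms intervals
  expect_equal(mean(mv$variance / mv$mean), 1, tolerance = 0.1)
  # identical trials have zero variance
  rec_id <- unit_recording("u", rep(list(c(-0.3, -0.1, 0.05)), 5))
  mv_id <- mean_variance_by_bin(rec_id)
  expect_true(all(mv_id$variance == 0))
})

test_that("excess cumulative count implements the pre-rate subtraction", {
  cfg <- analysis_config()
  # no post-change spikes: ec(t) = -F_pre (t - t_change)
  base <- seq(-0.39, 0.05, by = 0.01)
  rec <- unit_recording("u", list(base))
  ec <- excess_cumulative_count(rec, cfg)
  F_pre <- sum(base >= -0.4 & base < 0.055) / 0.455
  expect_equal(ec$F_pre, F_pre)
  expect_equal(ec$ec, -F_pre * (ec$t - cfg$t_change_delay))
  expect_equal(ec$ec[1], 0)
  # linearity: trace of a trial set equals the sum of per-trial traces
  rec2 <- constant_recording(50, n_trials = 4, seed = 3)
  total <- excess_cumulative_count(rec2, cfg)
  parts <- lapply(rec2$trials, function(tr)
    excess_cumulative_count(unit_recording("u", list(tr)), cfg))
  expect_equal(total$ec, Reduce(`+`, lapply(parts, `[[`, "ec")))
  expect_equal(total$F_pre, sum(vapply(parts, `[[`, 1, "F_pre")))
})

test_that("rate doubling yields the expected excess-count growth", {
  cfg <- analysis_config()
  step_tc <- structure(list(t = c(-0.45, cfg$t_change_delay,
                                  cfg$t_change_delay + 1e-9, 0.3),
                            A_e = c(50, 50, 100, 100)),
                       class = "rate_timecourse")
  rec <- unit_recording("u", poisson_spikes_from_rate(step_tc, 2000, seed = 8))
  ec <- excess_cumulative_count(rec, cfg)
  i <- which.min(abs(ec$t - 0.25))
  expected <- 50 * 2000 * (ec$t[i] - cfg$t_change_delay)
  expect_equal(ec$ec[i], expected, tolerance = 0.05)
})

test_that("excess difference threshold follows the Poisson envelope", {
  cfg <- analysis_config()
  tgrid <- seq(cfg$t_change_delay, 0.3, by = 0.001)
  mk_ec <- function(F_pre) structure(list(t = tgrid,
                                          ec = rep(0, length(tgrid)),
                                          F_pre = F_pre,
                                          t_change = cfg$t_change_delay,
                                          n_trials = 10),
                                     class = "excess_count")
  res <- excess_difference_test(mk_ec(60), mk_ec(40), cfg)
  i <- which.min(abs(tgrid - cfg$t_change_delay - 0.04))
  expect_equal(res$threshold[i], 2.32 * sqrt(100 * 0.04), tolerance = 1e-6)
  expect_false(any(res$significant))
  # literal (no square root) variant
  cfg_lit <- analysis_config(literal_threshold = TRUE)
  res_lit <- excess_difference_test(mk_ec(60), mk_ec(40), cfg_lit)
  expect_equal(res_lit$threshold[i], 2.32 * 100 * 0.04, tolerance = 1e-6)
})

test_that("null excess-difference comparisons rarely cross the envelope", {
  cfg <- analysis_config()
  set.seed(19)
  n_rep <- 150
  hits <- logical(n_rep)
  t_eval <- 0.105   # 50 ms after the response delay
  for (k in seq_len(n_rep)) {
    A <- constant_recording(60, n_trials = 15, seed = 2000 + 2 * k)
    N <- constant_recording(60, n_trials = 15, seed = 2001 + 2 * k)
    d <- excess_difference_test(excess_cumulative_count(A, cfg),
                                excess_cumulative_count(N, cfg), cfg)
    hits[k] <- d$significant[which.min(abs(d$t - t_eval))]
  }
  # two-sided rate at z = 2.32 should be ~2%; allow broad binomial slack
  expect_lt(mean(hits), 0.08)
})

test_that("interval count changes flag the attended transient early", {
  cfg <- analysis_config()
  # substitution check of the threshold: variance sum 4 -> threshold 2
  tr_A <- rep(list(c(-0.2, 0.06)), 4)
  tr_N <- rep(list(c(-0.25, 0.19)), 4)
  res0 <- interval_count_change(unit_recording("a", tr_A),
                                unit_recording("n", tr_N), cfg)
  expect_equal(res0$threshold, rep(0, 6))  # identical trials: zero variance
  expect_equal(nrow(res0), 6)
  # model-generated attended vs unattended transients, speed-up
  tun <- speed_tuning(A0 = 0, A_pref = 60, v_pref = 8, sigma_v = log(2^2.5))
  spec <- change_paradigm_spec(tun, v_pre = 4, alpha = 1.2, A_max = 84,
                               n_trials = 60, seed = 5)
  ex <- make_change_experiment(spec)
  res <- interval_count_change(ex$recordings[["attend-in/speed-up"]],
                               ex$recordings[["attend-out/speed-up"]], cfg)
  expect_true(all(abs(res$contrast[res$significant]) >
                    res$threshold[res$significant]))
  # no change in speed: contrasts stay small relative to threshold
  spec0 <- change_paradigm_spec(tun, v_pre = 4, change_factor = 1,
                                alpha = 1, A_max = 84, n_trials = 40,
                                seed = 6)
  ex0 <- make_change_experiment(spec0)
  res_flat <- interval_count_change(ex0$recordings[["attend-in/speed-up"]],
                                    ex0$recordings[["attend-out/speed-up"]],
                                    cfg)
  expect_lt(mean(res_flat$significant), 0.5)
})

test_that("time advantage detects pure latency shifts", {
  set.seed(41)
  cfg <- analysis_config()
  # steps placed so both crossings fall clearly after the response delay
  step_at <- function(t0) structure(list(t = c(-0.45, t0, t0 + 1e-9, 0.3),
                                         A_e = c(30, 30, 90, 90)),
                                    class = "rate_timecourse")
  trials_A <- poisson_spikes_from_rate(step_at(0.10), 400, seed = 51)
  rec_A <- unit_recording("a", trials_A)
  # identical data: advantage 0 at every threshold
  adv0 <- time_advantage(rec_A, rec_A, thresholds = c(10, 25), cfg)
  expect_equal(adv0$advantage, c(0, 0))
  # the same trains shifted 10 ms later: advantage +10 ms
  rec_N <- unit_recording("n", lapply(trials_A, function(x) x + 0.010))
  adv <- time_advantage(rec_A, rec_N, thresholds = c(10, 25, 40), cfg)
  expect_equal(adv$advantage, rep(0.010, 3), tolerance = 1e-9)
  # unreachable thresholds are reported missing
  advm <- time_advantage(rec_A, rec_N, thresholds = c(500), cfg)
  expect_true(is.na(advm$advantage))
})

test_that("deceleration-acceleration regression and its resampling errors", {
  x <- c(-3, -1, 0.5, 2, 4, 6)
  y <- -0.2 * x
  r <- accel_decel_regression(x, y)
  expect_equal(r$slope, -0.2)
  expect_equal(r$offset, 0)
  expect_equal(r$slope_sd, 0)
  expect_equal(r$offset_sd, 0)
  # duplicated points leave the slope unchanged
  r2 <- accel_decel_regression(c(x, x), c(y, y))
  expect_equal(r2$slope, -0.2)
  # noisy recovery within a few resampling SDs
  set.seed(3)
  xn <- rnorm(40, 0, 5)
  yn <- -0.2 * xn + rnorm(40, 0, 0.4)
  rn <- accel_decel_regression(xn, yn)
  expect_lt(abs(rn$slope + 0.2), 4 * max(rn$slope_sd, 0.01))
  expect_error(accel_decel_regression(c(1, 1, 1), c(1, 2, 3)), "degenerate")
})

test_that("paired rank test behaves at its conventions and detects shifts", {
  a <- rnorm(20)
  expect_equal(paired_rank_test(a, a), 1)
  expect_lt(paired_rank_test(a + 1, a), 0.01)
  # sign-flip symmetry of the two-sided p-value
  b <- a + rnorm(20, 0.3)
  expect_equal(paired_rank_test(a, b), paired_rank_test(b, a))
})
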