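#' Counter-based substream seed
#'
#' Derives a reproducible per-stream seed from a master seed and a stream
#' counter, so any (unit, trial) subset can be regenerated independently of
#' generation order. Kept below 2^31 to stay a valid R integer.
#'
#' @param seed Master integer seed.
#' @param id Non-negative stream counter.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, id) {
  as.integer((as.double(seed) * 69069 + as.double(id) * 1013904223) %% 2147483647)
}

# truncated-positive normal draw
rtnorm_pos <- function(n, mean, sd, lower = .Machine$double.eps) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  guard <- 0L
  while (length(bad) > 0 && guard < 1000L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
    guard <- guard + 1L
  }
  pmax(x, lower)
}

#' Inhomogeneous Poisson spike trains from a rate time course
#'
#' Generates spikes by thinning: candidate events are drawn from a
#' homogeneous Poisson process at the maximum rate and accepted with
#' probability rate(t)/max-rate (rate linearly interpolated between grid
#' points), which is exact at any rate resolution. Each trial uses its own
#' counter-based substream so trial subsets are reproducible.
#'
#' @param rate_tc A `"rate_timecourse"` (list with `t`, `A_e`), rate in
#'   spikes/s, non-negative.
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @return A list of `n_trials` sorted spike-time vectors spanning
#'   `range(rate_tc$t)`.
#' @export
poisson_spikes_from_rate <- function(rate_tc, n_trials, seed) {
  if (any(rate_tc$A_e < 0)) stop("rate must be non-negative")
  t0 <- min(rate_tc$t); t1 <- max(rate_tc$t)
  rmax <- max(rate_tc$A_e)
  lapply(seq_len(n_trials), function(j) {
    set.seed(substream_seed(seed, j))
    if (rmax == 0) return(numeric(0))
    n <- stats::rpois(1, rmax * (t1 - t0))
    if (n == 0) return(numeric(0))
    cand <- sort(stats::runif(n, t0, t1))
    r <- stats::approx(rate_tc$t, rate_tc$A_e, xout = cand, rule = 2)$y
    cand[stats::runif(n) < r / rmax]
  })
}

#' Population specification for the onset-transient paradigm
#'
#' Distributions (mean/SD, truncated positive) of the generating parameters
#' of a heterogeneous population of units. Defaults follow the fitted-model
#' population statistics of macaque MT onset transients: excitatory time
#' constant 17 +/- 16 ms, inhibitory 45 +/- 30 ms, maximum sustained rate
#' 87 +/- 54 spikes/s, with 5-10 trial repetitions per unit. Pre-change
#' (spontaneous) and post-change sustained rates have no published population
#' moments; by default the spontaneous rate is 10 +/- 5 spikes/s and the
#' sustained driven rate is drawn as a fraction `post_frac` (0.75 +/- 0.08,
#' truncated to `[0.4, 0.92]`) of the unit's `A_max`, which reproduces the
#' pronounced onset transients (peak several times the sustained level) seen
#' in well-driven MT units; both are constrained to `A_post < A_max / 1.05`
#' so the fit's maximum-rate range always brackets the truth.
#'
#' @param n_units Number of units.
#' @param tau_e,tau_i,A_max,A_pre Two-element `c(mean, sd)` vectors (seconds
#'   for the time constants, spikes/s for the rates).
#' @param A_post Either NULL (default: draw as `post_frac * A_max`) or a
#'   `c(mean, sd)` vector of absolute rates, spikes/s.
#' @param post_frac `c(mean, sd)` of `A_post / A_max` used when `A_post` is
#'   NULL.
#' @param trials_per_unit Two-element inclusive range of trial counts.
#' @param onset_delay True response onset delay, seconds (mean, sd); default
#'   31 +/- 12 ms.
#' @param seed Integer seed.
#' @return An object of class `"population_spec"`.
#' @export
population_spec <- function(n_units = 50,
                            tau_e = c(0.017, 0.016),
                            tau_i = c(0.045, 0.030),
                            A_max = c(87, 54),
                            A_pre = c(10, 5),
                            A_post = NULL,
                            post_frac = c(0.75, 0.08),
                            trials_per_unit = c(5, 10),
                            onset_delay = c(0.031, 0.012),
                            seed = 1) {
  stopifnot(n_units >= 1, all(trials_per_unit >= 1),
            tau_e[1] > 0, tau_i[1] > 0, A_max[1] > 0)
  structure(list(n_units = n_units, tau_e = tau_e, tau_i = tau_i,
                 A_max = A_max, A_pre = A_pre, A_post = A_post,
                 post_frac = post_frac,
                 trials_per_unit = trials_per_unit,
                 onset_delay = onset_delay, seed = as.integer(seed)),
            class = "population_spec")
}

#' Synthetic onset-transient experiment with known ground truth
#'
#' Draws per-unit parameters from the population distributions, builds each
#' unit's onset rate time course (baseline at the pre-change rate until the
#' unit's onset delay, then the reduced-model transient), and generates
#' Poisson trials. Deterministic given the spec's seed.
#'
#' @param spec A [population_spec()].
#' @param t_range Time span of each trial, seconds relative to stimulus
#'   onset; default `[-0.4, 0.7]`.
#' @return A list with `recordings` (list of [unit_recording()]) and `truth`
#'   (data frame of the generating parameters per unit).
#' @export
make_onset_experiment <- function(spec, t_range = c(-0.4, 0.7)) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  n <- spec$n_units
  tau_e <- rtnorm_pos(n, spec$tau_e[1], spec$tau_e[2], lower = 0.001)
  tau_i <- rtnorm_pos(n, spec$tau_i[1], spec$tau_i[2], lower = 0.002)
  # excitatory time scales are much faster than inhibitory ones in the
  # fitted population; resample pairs violating tau_e < tau_i
  bad <- which(tau_e >= tau_i)
  guard <- 0L
  while (length(bad) > 0 && guard < 1000L) {
    tau_e[bad] <- rtnorm_pos(length(bad), spec$tau_e[1], spec$tau_e[2],
                             lower = 0.001)
    tau_i[bad] <- rtnorm_pos(length(bad), spec$tau_i[1], spec$tau_i[2],
                             lower = 0.002)
    bad <- bad[tau_e[bad] >= tau_i[bad]]
    guard <- guard + 1L
  }
  A_max <- rtnorm_pos(n, spec$A_max[1], spec$A_max[2], lower = 20)
  A_pre <- rtnorm_pos(n, spec$A_pre[1], spec$A_pre[2], lower = 2)
  A_post <- if (is.null(spec$A_post)) {
    frac <- pmin(pmax(stats::rnorm(n, spec$post_frac[1], spec$post_frac[2]),
                      0.4), 0.92)
    frac * A_max
  } else {
    rtnorm_pos(n, spec$A_post[1], spec$A_post[2], lower = 5)
  }
  delay <- rtnorm_pos(n, spec$onset_delay[1], spec$onset_delay[2],
                      lower = 0.005)
  # keep the generating parameters inside the fit's admissible region
  A_post <- pmin(A_post, A_max / 1.05)
  A_pre <- pmin(A_pre, pmin(A_post, A_max) * 0.8)
  trial_choices <- seq(spec$trials_per_unit[1], spec$trials_per_unit[2])
  n_trials <- if (length(trial_choices) == 1) rep(trial_choices, n)
              else sample(trial_choices, n, replace = TRUE)
  tg <- seq(t_range[1], t_range[2], by = 0.001)
  recordings <- vector("list", n)
  for (k in seq_len(n)) {
    r <- reduced_params(A_pre[k], A_post[k], A_max[k], tau_e[k], tau_i[k],
                        t_change = delay[k])
    tc <- reduced_response(r, tg)
    trials <- poisson_spikes_from_rate(tc, n_trials[k],
                                       seed = substream_seed(spec$seed, k))
    recordings[[k]] <- unit_recording(sprintf("unit-%03d", k), trials)
  }
  truth <- data.frame(unit_id = sprintf("unit-%03d", seq_len(n)),
                      tau_e = tau_e, tau_i = tau_i, A_max = A_max,
                      A_pre = A_pre, A_post = A_post, delta_tau = delay,
                      n_trials = n_trials, stringsAsFactors = FALSE)
  list(recordings = recordings, truth = truth)
}

#' Specification of the four-condition speed-change paradigm
#'
#' Emulates the attend-in/attend-out x speed-up/speed-down change-detection
#' paradigm: a stimulus moving at a base speed changes speed by a factor of
#' about 2 (acceleration block) or about 0.5 (deceleration block) at a time
#' jittered uniformly within 0.66-5.5 s after motion onset, while attention
#' is directed into or out of the receptive field. Attention acts as a
#' multiplicative input gain `alpha` on the attended conditions.
#'
#' @param tuning A [speed_tuning()] object.
#' @param v_pre Base speed, deg/s.
#' @param change_factor Acceleration factor (the deceleration block uses its
#'   reciprocal); default 2.
#' @param alpha Attention gain; default 1.2.
#' @param A_max Circuit maximum sustained rate, spikes/s; must exceed the
#'   tuning rates at all used speeds.
#' @param tau_e,tau_i Time constants, seconds.
#' @param change_time_range Jitter range of the change time after motion
#'   onset, seconds; default `[0.66, 5.5]`.
#' @param t_change_delay Response delay of the transient after the change,
#'   seconds; default 0.055.
#' @param n_trials Trials per condition.
#' @param seed Integer seed.
#' @return An object of class `"change_paradigm_spec"`.
#' @export
change_paradigm_spec <- function(tuning, v_pre, change_factor = 2,
                                 alpha = 1.2, A_max, tau_e = 0.017,
                                 tau_i = 0.045,
                                 change_time_range = c(0.66, 5.5),
                                 t_change_delay = 0.055,
                                 n_trials = 40, seed = 1) {
  stopifnot(inherits(tuning, "speed_tuning"), change_factor > 0, alpha >= 1,
            v_pre > 0, A_max > 0, n_trials >= 1)
  structure(list(tuning = tuning, v_pre = v_pre,
                 change_factor = change_factor, alpha = alpha,
                 A_max = A_max, tau_e = tau_e, tau_i = tau_i,
                 change_time_range = change_time_range,
                 t_change_delay = t_change_delay,
                 n_trials = n_trials, seed = as.integer(seed)),
            class = "change_paradigm_spec")
}

#' Synthetic four-condition speed-change experiment
#'
#' Builds the rate time course of each condition from the tuning curve
#' (sustained rates at the base and changed speed), the reduced transient
#' model, and the attention gain (attended conditions use attention-mapped
#' normalized activations and the attended transient dynamics), then
#' generates Poisson trials. The change time is jittered per trial within the
#' configured range but output spike times are re-aligned so t = 0 is the
#' change; the transient begins at the response delay.
#'
#' @param spec A [change_paradigm_spec()].
#' @param t_range Output span relative to the change, seconds; default
#'   `[-0.45, 0.3]`.
#' @return A list with `recordings` (named list of four [unit_recording()]s
#'   with conditions `attend-in/speed-up`, `attend-out/speed-up`,
#'   `attend-in/speed-down`, `attend-out/speed-down`) and `truth` (data frame
#'   of generating rates per condition).
#' @export
make_change_experiment <- function(spec, t_range = c(-0.45, 0.3)) {
  stopifnot(inherits(spec, "change_paradigm_spec"))
  v_pre <- spec$v_pre
  speeds <- c("speed-up" = v_pre * spec$change_factor,
              "speed-down" = v_pre / spec$change_factor)
  A_pre <- speed_tuning_rate(v_pre, spec$tuning)
  if (A_pre >= spec$A_max) stop("tuning rate at the base speed reaches A_max")
  tg <- seq(t_range[1], t_range[2], by = 0.001)
  recordings <- list()
  truth <- NULL
  cond_i <- 0L
  for (chg in names(speeds)) {
    A_post <- speed_tuning_rate(speeds[[chg]], spec$tuning)
    if (A_post >= spec$A_max) stop("tuning rate after the change reaches A_max")
    for (att in c("attend-in", "attend-out")) {
      cond_i <- cond_i + 1L
      gains <- attention_gains(if (att == "attend-in") spec$alpha else 1)
      r <- reduced_params(A_pre, A_post, spec$A_max, spec$tau_e, spec$tau_i,
                          t_change = spec$t_change_delay)
      tc <- reduced_response(r, tg, gains = gains)
      cond <- paste(att, chg, sep = "/")
      # per-trial change-time jitter: with a stationary pre-change rate the
      # re-aligned trains are statistically identical, so the jitter enters
      # only through the bookkeeping of absolute event times
      set.seed(substream_seed(spec$seed, cond_i * 1000L))
      t_events <- stats::runif(spec$n_trials, spec$change_time_range[1],
                               spec$change_time_range[2])
      trials <- poisson_spikes_from_rate(tc, spec$n_trials,
                                         seed = substream_seed(spec$seed, cond_i))
      rec <- unit_recording(cond, trials, condition = cond)
      rec$t_events <- t_events
      recordings[[cond]] <- rec
      truth <- rbind(truth, data.frame(
        condition = cond, A_pre = A_pre * if (att == "attend-in")
          attention_map(A_pre / spec$A_max, spec$alpha) / (A_pre / spec$A_max) else 1,
        A_post_unattended = A_post, alpha = gains$alpha_e,
        stringsAsFactors = FALSE))
    }
  }
  list(recordings = recordings, truth = truth)
}

#' Parameter-recovery report for the onset paradigm
#'
#' Generates a synthetic onset experiment, runs the full preparation and
#' grid-search fit on every unit, and scores the recovered `(tau_e, tau_i,
#' A_max)` against the generating truth. Deterministic given the spec seed.
#'
#' @param spec A [population_spec()].
#' @param cfg A [fit_config()].
#' @param use_true_delay Use the generating onset delay instead of the
#'   automated estimator (isolates fit error from latency error); default
#'   TRUE.
#' @return A list with `per_unit` (truth and fits side by side), and
#'   `summary` (per-parameter bias, RMSE and median relative error).
#' @export
parameter_recovery_report <- function(spec, cfg = fit_config(),
                                      use_true_delay = TRUE) {
  exper <- make_onset_experiment(spec)
  n <- length(exper$recordings)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    rec <- exper$recordings[[k]]
    tru <- exper$truth[k, ]
    psth <- compute_psth(rec, t_range = c(-0.4, 0.7))
    lv <- estimate_sustained_levels(psth)
    A_pre <- max(lv$A_pre, 0.5 / (rec$n_trials * 0.1))  # half-spike floor
    dtau <- if (use_true_delay) tru$delta_tau else
      tryCatch(estimate_onset_delay(psth), error = function(e) tru$delta_tau)
    f <- grid_search_fit(psth, A_pre, lv$A_post, dtau, cfg)
    rows[[k]] <- data.frame(
      unit_id = tru$unit_id, n_trials = tru$n_trials,
      tau_e_true = tru$tau_e, tau_e_fit = f$tau_e,
      tau_i_true = tru$tau_i, tau_i_fit = f$tau_i,
      A_max_true = tru$A_max, A_max_fit = f$A_max,
      chi2_per_bin = f$chi2_per_bin, converged = f$converged,
      stringsAsFactors = FALSE)
  }
  per_unit <- do.call(rbind, rows)
  score <- function(fit, true) {
    rel <- abs(fit - true) / true
    c(bias = mean(fit - true), rmse = sqrt(mean((fit - true)^2)),
      median_rel_error = stats::median(rel))
  }
  summary <- rbind(
    tau_e = score(per_unit$tau_e_fit, per_unit$tau_e_true),
    tau_i = score(per_unit$tau_i_fit, per_unit$tau_i_true),
    A_max = score(per_unit$A_max_fit, per_unit$A_max_true))
  list(per_unit = per_unit, summary = as.data.frame(summary))
}
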