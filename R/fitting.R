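#' Grid-search fit configuration
#'
#' Search ranges, grid resolutions, and iteration count of the iterative
#' grid-search fit. Defaults: the maximum-rate range is `[1.03, 3]` times the
#' sustained post-change rate (40 bins); time-constant ranges are
#' `[1, 100] ms` for excitation and `[1, 500] ms` for inhibition (15 bins
#' each); four iterations with subsequently refined grids; the fit is
#' evaluated over a 200 ms window after response onset.
#'
#' @param range_Amax Two multiples of `A_post` bounding the `A_max` search.
#' @param bins_Amax Number of `A_max` grid points.
#' @param range_tau_e,range_tau_i Time-constant search ranges, seconds.
#' @param bins_tau Number of grid points per time-constant axis.
#' @param iterations Total grid iterations (initial + refinements).
#' @param fit_window Chi-square averaging window after response onset, s.
#' @param denominator `"sem2"` for the conventional chi-square (squared
#'   standard error in the denominator) or `"sem"` for the unsquared variant.
#' @param range_tau_ratio Search range for the derived `tau_e / tau_i` ratio
#'   when it is fixed globally across a population.
#' @return An object of class `"fit_config"`.
#' @export
fit_config <- function(range_Amax = c(1.03, 3), bins_Amax = 40,
                       range_tau_e = c(0.001, 0.1),
                       range_tau_i = c(0.001, 0.5), bins_tau = 15,
                       iterations = 4, fit_window = 0.2,
                       denominator = c("sem2", "sem"),
                       range_tau_ratio = c(0.01, 10)) {
  denominator <- match.arg(denominator)
  stopifnot(range_Amax[1] > 1, range_Amax[2] > range_Amax[1],
            all(range_tau_e > 0), all(range_tau_i > 0),
            bins_Amax >= 2, bins_tau >= 2, iterations >= 1, fit_window > 0)
  structure(list(range_Amax = range_Amax, bins_Amax = bins_Amax,
                 range_tau_e = range_tau_e, range_tau_i = range_tau_i,
                 bins_tau = bins_tau, iterations = iterations,
                 fit_window = fit_window, denominator = denominator,
                 range_tau_ratio = range_tau_ratio),
            class = "fit_config")
}

#' Keep units with enough spikes for a well-shaped PSTH
#'
#' Units whose spike count summed over all trials is below `min_spikes`
#' provide too little data for a stable trial-averaged rate and are excluded
#' from fitting.
#'
#' @param recs List of [unit_recording()] objects.
#' @param min_spikes Inclusion threshold on the total spike count; default
#'   100 (kept when the total is at least this).
#' @return The surviving subset of `recs`.
#' @export
inclusion_filter_units <- function(recs, min_spikes = 100) {
  keep <- vapply(recs, function(r) sum(lengths(r$trials)) >= min_spikes,
                 logical(1))
  recs[keep]
}

# per-bin sem with the zero-variance floor of one spike per (n_trials * bin)
floored_sem <- function(psth) {
  floor_rate <- 1 / (psth$n_trials * psth$bin_width)
  pmax(psth$sem, ifelse(psth$sem == 0, floor_rate, 0))
}

#' Chi-square error between a model time course and a PSTH
#'
#' The model (time 0 = response onset) is downsampled to the PSTH's temporal
#' resolution by averaging within each bin, and the squared deviation from
#' the delay-compensated experimental rate is divided by the per-bin standard
#' error (squared, by default) and averaged over the fit window. Bins with
#' zero variance get a standard-error floor of one spike per
#' `n_trials * bin_width`.
#'
#' @param model A `"rate_timecourse"` whose time axis starts at the response
#'   onset (t = 0), e.g. a [reduced_response()] with `t_change = 0`.
#' @param psth A [compute_psth()] result, time relative to stimulus onset.
#' @param delta_tau Response onset delay, seconds.
#' @param window Averaging window length after response onset, seconds.
#' @param denominator `"sem2"` (conventional chi-square) or `"sem"`.
#' @return Chi-square per bin (dimensionless).
#' @export
chi_square_fit_error <- function(model, psth, delta_tau, window = 0.2,
                                 denominator = c("sem2", "sem")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(psth, "psth"))
  sel <- psth$bin_centers >= delta_tau &
    psth$bin_centers < delta_tau + window
  if (!any(sel)) stop("fit window contains no PSTH bins")
  centers <- psth$bin_centers[sel] - delta_tau   # model time
  hw <- psth$bin_width / 2
  model_bin <- vapply(centers, function(tc) {
    ts <- seq(max(tc - hw, min(model$t)), min(tc + hw, max(model$t)),
              length.out = 5)
    mean(stats::approx(model$t, model$A_e, xout = ts, rule = 2)$y)
  }, numeric(1))
  sem <- floored_sem(psth)[sel]
  dev2 <- (model_bin - psth$rate[sel])^2
  if (denominator == "sem2") mean(dev2 / sem^2) else mean(dev2 / sem)
}

# chi2 over an explicit (tau_e, tau_i, A_max) grid for one prepared unit;
# grids may be length-1 for fixed axes. Returns list(chi2 array, dims).
eval_grid <- function(prep, taue, taui, amax) {
  v <- cpp_grid_chi2(prep$A_pre, prep$A_post, taue, taui, amax,
                     prep$rate, prep$sem2, prep$bin_lo, prep$bin_hi,
                     prep$min_substeps)
  array(v, dim = c(length(taue), length(taui), length(amax)))
}

# precompute the binned target for the grid search (model time axis)
prepare_fit_target <- function(psth, A_pre, A_post, delta_tau, cfg) {
  sel <- psth$bin_centers >= delta_tau &
    psth$bin_centers < delta_tau + cfg$fit_window
  if (!any(sel)) stop("fit window contains no PSTH bins")
  centers <- psth$bin_centers[sel] - delta_tau
  hw <- psth$bin_width / 2
  sem <- floored_sem(psth)[sel]
  sem2 <- if (cfg$denominator == "sem2") sem^2 else sem
  list(A_pre = A_pre, A_post = A_post,
       rate = psth$rate[sel], sem2 = sem2,
       bin_lo = pmax(centers - hw, 0), bin_hi = centers + hw,
       min_substeps = 50L)
}

# evaluation points are cell centers: bins cells over the range, so the
# spacing shrinks by exactly 2/bins per refinement
grid_centers <- function(range, bins) {
  w <- diff(range) / bins
  seq(range[1] + w / 2, range[2] - w / 2, length.out = bins)
}

# new range spans one cell on either side of the best center, clamped
refine_range <- function(range, bins, best, outer_range) {
  w <- diff(range) / bins
  c(max(best - w, outer_range[1]), min(best + w, outer_range[2]))
}

#' Fit the reduced transient model to a PSTH by iterative grid search
#'
#' Exhaustively evaluates the reduced response over a 3-D grid of
#' `(tau_e, tau_i, A_max)`, then re-centers the grid on the best cell
#' (spanning one previous cell on either side, with the same number of bins)
#' and repeats for the configured number of iterations. The fit is
#' deterministic given its inputs.
#'
#' @param psth A [compute_psth()] result (time relative to stimulus onset).
#' @param A_pre,A_post Sustained rates, spikes/s (see
#'   [estimate_sustained_levels()]).
#' @param delta_tau Response onset delay, seconds (see
#'   [estimate_onset_delay()]).
#' @param cfg A [fit_config()].
#' @return An object of class `"fit_result"`: fitted `tau_e`, `tau_i`,
#'   `A_max`, the inputs `A_pre`, `A_post`, `delta_tau`, the achieved
#'   `chi2_per_bin`, logical flags `converged` (not on a range boundary,
#'   non-degenerate) and `degenerate`, and `resolution` (final grid spacing
#'   per axis).
#' @export
grid_search_fit <- function(psth, A_pre, A_post, delta_tau, cfg = fit_config()) {
  stopifnot(inherits(cfg, "fit_config"))
  if (A_post * cfg$range_Amax[1] <= A_post)
    stop("A_max search range must start above A_post")
  degenerate <- isTRUE(all.equal(A_pre, A_post, tolerance = 1e-6))
  prep <- prepare_fit_target(psth, A_pre, A_post, delta_tau, cfg)
  re <- cfg$range_tau_e; ri <- cfg$range_tau_i
  ra <- cfg$range_Amax * A_post
  # A_pre must also stay below the smallest A_max on the grid
  ra[1] <- max(ra[1], A_pre * 1.001)
  if (ra[1] >= ra[2]) ra[2] <- ra[1] * 1.5
  outer <- list(e = re, i = ri, a = ra)
  best <- NULL
  for (it in seq_len(cfg$iterations)) {
    taue <- grid_centers(re, cfg$bins_tau)
    taui <- grid_centers(ri, cfg$bins_tau)
    amax <- grid_centers(ra, cfg$bins_Amax)
    chi2 <- eval_grid(prep, taue, taui, amax)
    i <- arrayInd(which.min(chi2), dim(chi2))
    best <- list(tau_e = taue[i[1]], tau_i = taui[i[2]], A_max = amax[i[3]],
                 chi2 = chi2[i[1], i[2], i[3]],
                 resolution = c(tau_e = diff(re) / cfg$bins_tau,
                                tau_i = diff(ri) / cfg$bins_tau,
                                A_max = diff(ra) / cfg$bins_Amax))
    re <- refine_range(re, cfg$bins_tau, best$tau_e, outer$e)
    ri <- refine_range(ri, cfg$bins_tau, best$tau_i, outer$i)
    ra <- refine_range(ra, cfg$bins_Amax, best$A_max, outer$a)
  }
  res <- best$resolution
  on_boundary <-
    best$tau_e <= outer$e[1] + res[1] || best$tau_e >= outer$e[2] - res[1] ||
    best$tau_i <= outer$i[1] + res[2] || best$tau_i >= outer$i[2] - res[2] ||
    best$A_max <= outer$a[1] + res[3] || best$A_max >= outer$a[2] - res[3]
  structure(list(tau_e = best$tau_e, tau_i = best$tau_i, A_max = best$A_max,
                 A_pre = A_pre, A_post = A_post, delta_tau = delta_tau,
                 chi2_per_bin = best$chi2,
                 converged = !on_boundary && !degenerate,
                 degenerate = degenerate, on_boundary = on_boundary,
                 resolution = best$resolution),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Transient model fit: tau_e = %.1f ms, tau_i = %.1f ms, A_max = %.1f spikes/s\n",
              1000 * x$tau_e, 1000 * x$tau_i, x$A_max))
  cat(sprintf("  A_pre = %.1f, A_post = %.1f spikes/s, delay = %.0f ms, chi2/N = %.3f%s\n",
              x$A_pre, x$A_post, 1000 * x$delta_tau, x$chi2_per_bin,
              if (!x$converged) " (flagged)" else ""))
  invisible(x)
}

# prepare one recording for fitting: psth, onset delay, sustained levels
prepare_unit <- function(rec, cfg, bin_width = 0.005, t_range = c(-0.4, 0.7),
                         delta_tau = NULL) {
  psth <- compute_psth(rec, bin_width = bin_width, t_range = t_range)
  lv <- estimate_sustained_levels(psth)
  if (is.null(delta_tau))
    delta_tau <- estimate_onset_delay(psth, override = NULL)
  list(psth = psth, A_pre = lv$A_pre, A_post = lv$A_post,
       delta_tau = delta_tau, unit_id = rec$unit_id)
}

#' Fit a population of onset recordings
#'
#' Convenience wrapper: PSTH, sustained levels, onset delay and grid-search
#' fit for each recording, returning one row per unit.
#'
#' @param recs List of [unit_recording()] objects.
#' @param cfg A [fit_config()].
#' @param delta_tau Optional vector of manual onset delays (recycled).
#' @param bin_width,t_range PSTH construction parameters.
#' @return A data frame with the fitted parameters and diagnostics.
#' @export
fit_population <- function(recs, cfg = fit_config(), delta_tau = NULL,
                           bin_width = 0.005, t_range = c(-0.4, 0.7)) {
  if (!is.null(delta_tau)) delta_tau <- rep_len(delta_tau, length(recs))
  rows <- lapply(seq_along(recs), function(k) {
    prep <- prepare_unit(recs[[k]], cfg, bin_width, t_range,
                         delta_tau = if (is.null(delta_tau)) NULL else delta_tau[k])
    f <- grid_search_fit(prep$psth, prep$A_pre, prep$A_post, prep$delta_tau, cfg)
    data.frame(unit_id = prep$unit_id, tau_e = f$tau_e, tau_i = f$tau_i,
               A_max = f$A_max, A_pre = f$A_pre, A_post = f$A_post,
               delta_tau = f$delta_tau, chi2_per_bin = f$chi2_per_bin,
               converged = f$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# inner fit with some axes fixed; fixed = named list, may contain tau_ratio
fit_unit_fixed <- function(prep, cfg, fixed) {
  re <- cfg$range_tau_e; ri <- cfg$range_tau_i
  ra <- cfg$range_Amax * prep$A_post
  ra[1] <- max(ra[1], prep$A_pre * 1.001)
  if (ra[1] >= ra[2]) ra[2] <- ra[1] * 1.5
  has_ratio <- !is.null(fixed$tau_ratio)
  outer <- list(e = re, i = ri, a = ra)
  best <- NULL
  for (it in seq_len(cfg$iterations)) {
    taue <- if (!is.null(fixed$tau_e)) fixed$tau_e
            else grid_centers(re, cfg$bins_tau)
    taui <- if (!is.null(fixed$tau_i)) fixed$tau_i
            else grid_centers(ri, cfg$bins_tau)
    amax <- if (!is.null(fixed$A_max)) fixed$A_max
            else grid_centers(ra, cfg$bins_Amax)
    if (has_ratio) {
      # tau_e is slaved to tau_i through the fixed ratio
      chi2 <- array(Inf, dim = c(1, length(taui), length(amax)))
      for (ii in seq_along(taui)) {
        te <- fixed$tau_ratio * taui[ii]
        te <- min(max(te, 1e-5), 10)
        chi2[1, ii, ] <- eval_grid(prep, te, taui[ii], amax)[1, 1, ]
      }
      i <- arrayInd(which.min(chi2), dim(chi2))
      best <- list(tau_e = fixed$tau_ratio * taui[i[2]], tau_i = taui[i[2]],
                   A_max = amax[i[3]], chi2 = chi2[i[1], i[2], i[3]])
      i_e <- 1L
    } else {
      chi2 <- eval_grid(prep, taue, taui, amax)
      i <- arrayInd(which.min(chi2), dim(chi2))
      best <- list(tau_e = taue[i[1]], tau_i = taui[i[2]], A_max = amax[i[3]],
                   chi2 = chi2[i[1], i[2], i[3]])
      i_e <- i[1]
    }
    if (is.null(fixed$tau_e) && !has_ratio && length(taue) > 1)
      re <- refine_range(re, cfg$bins_tau, best$tau_e, outer$e)
    if (is.null(fixed$tau_i) && length(taui) > 1)
      ri <- refine_range(ri, cfg$bins_tau, best$tau_i, outer$i)
    if (is.null(fixed$A_max) && length(amax) > 1)
      ra <- refine_range(ra, cfg$bins_Amax, best$A_max, outer$a)
  }
  best
}

#' Population fits with one or more globally fixed parameters
#'
#' Repeats the grid-search fit with a subset of `{tau_e, tau_i, A_max,
#' tau_ratio}` held at a single value shared by all units, searching the
#' shared value(s) by the same iterative grid scheme in an outer loop (the
#' derived ratio `tau_ratio = tau_e / tau_i` slaves `tau_e` to the per-unit
#' `tau_i`). Reports the increase of the mean chi-square relative to the
#' all-free fit, in percent.
#'
#' @param recs List of at least two [unit_recording()] objects.
#' @param fixed Character vector naming the globally fixed parameter(s); any
#'   of `"tau_e"`, `"tau_i"`, `"A_max"`, `"tau_ratio"`. Empty means the
#'   all-free fit (0% increase by construction).
#' @param cfg A [fit_config()].
#' @param delta_tau Optional manual onset delays (recycled over units).
#' @param outer_bins,outer_iterations Grid resolution and refinement count of
#'   the outer search over the global value(s).
#' @param bin_width,t_range PSTH construction parameters.
#' @return A list with `fits` (per-unit data frame), `global` (named fixed
#'   values), `mean_chi2`, `mean_chi2_free`, and `percent_error_increase`.
#' @export
population_fit_global <- function(recs, fixed = character(),
                                  cfg = fit_config(), delta_tau = NULL,
                                  outer_bins = 9, outer_iterations = 2,
                                  bin_width = 0.005, t_range = c(-0.4, 0.7)) {
  if (length(recs) < 2) stop("population fit needs at least two units")
  bad <- setdiff(fixed, c("tau_e", "tau_i", "A_max", "tau_ratio"))
  if (length(bad)) stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "))
  if (!is.null(delta_tau)) delta_tau <- rep_len(delta_tau, length(recs))
  units <- lapply(seq_along(recs), function(k)
    prepare_unit(recs[[k]], cfg, bin_width, t_range,
                 delta_tau = if (is.null(delta_tau)) NULL else delta_tau[k]))
  preps <- lapply(units, function(u) {
    tg <- prepare_fit_target(u$psth, u$A_pre, u$A_post, u$delta_tau, cfg)
    tg$unit_id <- u$unit_id
    tg
  })
  fit_all <- function(fixed_values) {
    res <- lapply(preps, fit_unit_fixed, cfg = cfg, fixed = fixed_values)
    list(mean_chi2 = mean(vapply(res, `[[`, numeric(1), "chi2")), fits = res)
  }
  free <- fit_all(list())
  if (length(fixed) == 0) {
    global <- numeric(0)
    final <- free
  } else {
    posts <- vapply(preps, function(p) p$A_post, numeric(1))
    ranges <- list(tau_e = cfg$range_tau_e, tau_i = cfg$range_tau_i,
                   A_max = c(min(posts) * cfg$range_Amax[1],
                             max(posts) * cfg$range_Amax[2]),
                   tau_ratio = cfg$range_tau_ratio)[fixed]
    grids <- lapply(ranges, function(r) seq(r[1], r[2], length.out = outer_bins))
    best_vals <- NULL; best_obj <- Inf; best_fit <- NULL
    for (it in seq_len(outer_iterations)) {
      combos <- do.call(expand.grid, grids)
      for (ci in seq_len(nrow(combos))) {
        vals <- as.list(combos[ci, , drop = FALSE])
        names(vals) <- fixed
        f <- fit_all(vals)
        if (f$mean_chi2 < best_obj) {
          best_obj <- f$mean_chi2; best_vals <- vals; best_fit <- f
        }
      }
      grids <- lapply(seq_along(grids), function(g) {
        gr <- grids[[g]]
        i <- which.min(abs(gr - best_vals[[fixed[g]]]))
        seq(gr[max(1, i - 1)], gr[min(length(gr), i + 1)],
            length.out = outer_bins)
      })
      names(grids) <- fixed
    }
    global <- unlist(best_vals)
    final <- best_fit
  }
  fits <- do.call(rbind, lapply(seq_along(preps), function(k) {
    f <- final$fits[[k]]
    data.frame(unit_id = preps[[k]]$unit_id, tau_e = f$tau_e, tau_i = f$tau_i,
               A_max = f$A_max, chi2_per_bin = f$chi2,
               stringsAsFactors = FALSE)
  }))
  list(fits = fits, global = global,
       mean_chi2 = final$mean_chi2, mean_chi2_free = free$mean_chi2,
       percent_error_increase =
         100 * (final$mean_chi2 - free$mean_chi2) / free$mean_chi2)
}

#' Surrogate chi-square distribution for goodness-of-fit calibration
#'
#' Draws model parameters from the empirical distribution of fitted
#' parameters, generates Poisson spike trains with matched trial counts from
#' the corresponding model responses, refits each surrogate unit, and returns
#' the resulting chi-square-per-bin values. If the model class is adequate,
#' this distribution overlays the empirical one.
#'
#' @param fits A data frame of fits as returned by [fit_population()] (needs
#'   columns `tau_e`, `tau_i`, `A_max`, `A_pre`, `A_post`).
#' @param n_units Number of surrogate units to generate.
#' @param n_trials Trials per surrogate unit.
#' @param seed Integer seed; the output is reproducible given the seed.
#' @param cfg A [fit_config()].
#' @param delta_tau Onset delay used for generation and refitting, seconds.
#' @return Numeric vector of `n_units` chi-square-per-bin values.
#' @export
surrogate_chi2_distribution <- function(fits, n_units, n_trials, seed,
                                        cfg = fit_config(), delta_tau = 0.03) {
  stopifnot(nrow(fits) >= 1)
  set.seed(as.integer(seed))
  rows <- sample.int(nrow(fits), n_units, replace = TRUE)
  out <- numeric(n_units)
  for (k in seq_len(n_units)) {
    f <- fits[rows[k], ]
    r <- reduced_params(f$A_pre, f$A_post, f$A_max, f$tau_e, f$tau_i,
                        t_change = delta_tau)
    tg <- seq(-0.4, 0.7, by = 0.001)
    tc <- reduced_response(r, tg)
    trials <- poisson_spikes_from_rate(tc, n_trials,
                                       seed = substream_seed(seed, k))
    rec <- unit_recording(sprintf("surrogate-%d", k), trials)
    psth <- compute_psth(rec, t_range = c(-0.4, 0.7))
    lv <- estimate_sustained_levels(psth)
    fit <- grid_search_fit(psth, lv$A_pre, lv$A_post, delta_tau, cfg)
    out[k] <- fit$chi2_per_bin
  }
  out
}
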