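#' Construct a unit recording
#'
#' The raw-data unit of the pipeline: spike times per trial, aligned to a
#' common event (stimulus onset for the onset paradigm, the speed change for
#' the change paradigm), with an optional condition label.
#'
#' @param unit_id Unit label.
#' @param trials List of numeric vectors of spike times, seconds, relative to
#'   the alignment event; each is sorted on construction.
#' @param condition Optional condition label (e.g. `"attend-in/speed-up"`).
#' @return An object of class `"unit_recording"`.
#' @export
unit_recording <- function(unit_id, trials, condition = NA_character_) {
  if (!is.list(trials) || length(trials) < 1)
    stop("trials must be a non-empty list of spike-time vectors")
  trials <- lapply(trials, function(x) {
    x <- as.numeric(x)
    if (any(!is.finite(x))) stop("spike times must be finite")
    sort(x)
  })
  structure(list(unit_id = as.character(unit_id), trials = trials,
                 n_trials = length(trials), condition = condition),
            class = "unit_recording")
}

#' Trial-averaged PSTH with per-bin standard error
#'
#' Bins spike times into fixed-width bins and returns the trial-averaged rate
#' per bin together with the standard error of the per-trial bin rates.
#'
#' @param rec A [unit_recording()].
#' @param bin_width Bin width, seconds; default 0.005.
#' @param t_range Two-element time range covered by the bins, seconds relative
#'   to the alignment event; defaults to the span of the spike times, snapped
#'   to bin edges.
#' @return An object of class `"psth"`: list with `bin_centers`, `rate`
#'   (spikes/s), `sem` (spikes/s), `bin_width`, `n_trials`.
#' @examples
#' rec <- unit_recording("u1", list(c(0.0125)))
#' p <- compute_psth(rec, t_range = c(0, 0.05))
#' p$rate[p$bin_centers == 0.0125]  # 200 spikes/s
#' @export
compute_psth <- function(rec, bin_width = 0.005, t_range = NULL) {
  stopifnot(inherits(rec, "unit_recording"))
  if (bin_width <= 0) stop("bin_width must be positive")
  all_t <- unlist(rec$trials)
  if (is.null(t_range)) {
    if (length(all_t) == 0) stop("no spikes and no explicit t_range")
    t_range <- c(floor(min(all_t) / bin_width), ceiling(max(all_t) / bin_width) + 1e-9) * bin_width
  }
  edges <- seq(t_range[1], t_range[2], by = bin_width)
  if (length(edges) < 2) stop("t_range spans no complete bin")
  nb <- length(edges) - 1
  n <- rec$n_trials
  counts <- matrix(0L, n, nb)
  for (j in seq_len(n)) {
    x <- rec$trials[[j]]
    x <- x[x >= edges[1] & x < edges[nb + 1]]
    if (length(x))
      counts[j, ] <- tabulate(findInterval(x, edges), nbins = nb)
  }
  rates <- counts / bin_width
  rate <- colSums(counts) / (n * bin_width)
  sem <- if (n > 1) apply(rates, 2, stats::sd) / sqrt(n) else rep(0, nb)
  structure(list(bin_centers = edges[-(nb + 1)] + bin_width / 2,
                 rate = rate, sem = sem,
                 bin_width = bin_width, n_trials = n),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("PSTH: %d bins of %g ms, %d trials, rate %g-%g spikes/s\n",
              length(x$rate), 1000 * x$bin_width, x$n_trials,
              round(min(x$rate), 2), round(max(x$rate), 2)))
  invisible(x)
}

#' Estimate the response onset delay from a PSTH
#'
#' Automated replacement for by-eye latency estimation: the baseline mean rate
#' and a noise scale (the average per-bin standard error over the baseline
#' window) are computed, and the onset is the left edge of the first run of at
#' least `min_run` consecutive post-onset bins whose rate deviates from the
#' baseline mean by more than `n_se` times that noise scale. A manual
#' `override` value, when given, is returned verbatim.
#'
#' @param psth A [compute_psth()] result; times relative to stimulus onset.
#' @param baseline_window Two-element window preceding stimulus onset.
#' @param n_se Deviation threshold in multiples of the baseline standard
#'   error; default 3.
#' @param min_run Required consecutive deviating bins; default 2.
#' @param override Optional manual delay, seconds, used verbatim.
#' @return Onset delay, seconds (relative to stimulus onset).
#' @export
estimate_onset_delay <- function(psth, baseline_window = c(-0.1, 0),
                                 n_se = 3, min_run = 2, override = NULL) {
  if (!is.null(override)) return(override)
  stopifnot(inherits(psth, "psth"))
  if (baseline_window[1] >= baseline_window[2] || baseline_window[2] > 0)
    stop("baseline window must precede stimulus onset")
  bl <- psth$bin_centers >= baseline_window[1] & psth$bin_centers < baseline_window[2]
  if (!any(bl)) stop("baseline window outside PSTH support")
  mu <- mean(psth$rate[bl])
  se <- mean(psth$sem[bl])
  if (se == 0) se <- stats::sd(psth$rate[bl])
  if (!is.finite(se) || se == 0) se <- .Machine$double.eps
  post <- which(psth$bin_centers > 0)
  dev <- abs(psth$rate[post] - mu) > n_se * se
  run <- 0L
  for (k in seq_along(dev)) {
    run <- if (dev[k]) run + 1L else 0L
    if (run >= min_run) {
      i <- post[k - min_run + 1L]
      return(psth$bin_centers[i] - psth$bin_width / 2)
    }
  }
  stop("no sustained deviation from baseline found; supply a manual override")
}

#' Sustained pre- and post-change rates from a PSTH
#'
#' Average rate over fixed windows before and after the stimulus change
#' (defaults: `[-100 ms, 0]` and `[200 ms, 500 ms]` relative to onset).
#'
#' @param psth A [compute_psth()] result.
#' @param pre_window,post_window Two-element windows, seconds.
#' @return A list with `A_pre` and `A_post`, spikes/s.
#' @export
estimate_sustained_levels <- function(psth, pre_window = c(-0.1, 0),
                                      post_window = c(0.2, 0.5)) {
  stopifnot(inherits(psth, "psth"))
  sel <- function(w) {
    i <- psth$bin_centers >= w[1] & psth$bin_centers < w[2]
    if (!any(i)) stop(sprintf("window [%g, %g] s outside PSTH support", w[1], w[2]))
    mean(psth$rate[i])
  }
  list(A_pre = sel(pre_window), A_post = sel(post_window))
}
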