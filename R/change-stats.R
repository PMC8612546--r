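#' Analysis configuration for the speed-change statistics
#'
#' @param t_change_delay Average response delay of the population transient
#'   after the stimulus change, seconds; default 0.055.
#' @param baseline_window Window for pre-change rate estimation, seconds
#'   relative to the change; default `[-0.4, t_change_delay]`.
#' @param z_threshold Significance threshold on the excess-count difference,
#'   chosen to give p < 0.01 one-sided; default 2.32.
#' @param interval_width Width of the spike-count intervals, seconds; 0.025.
#' @param transient_span Interval span of the transient analysis after the
#'   change, seconds; default `[0.05, 0.2]`.
#' @param smoothing_rms RMS width of the Gaussian PSTH smoothing kernel,
#'   seconds; default 0.010.
#' @param literal_threshold Use the literal (non-square-root) significance
#'   thresholds instead of the Poisson count-variance reading; default FALSE.
#' @return An object of class `"analysis_config"`.
#' @export
analysis_config <- function(t_change_delay = 0.055,
                            baseline_window = c(-0.4, t_change_delay),
                            z_threshold = 2.32, interval_width = 0.025,
                            transient_span = c(0.05, 0.2),
                            smoothing_rms = 0.010,
                            literal_threshold = FALSE) {
  stopifnot(t_change_delay >= 0, baseline_window[1] < baseline_window[2],
            z_threshold > 0, interval_width > 0, smoothing_rms > 0)
  structure(list(t_change_delay = t_change_delay,
                 baseline_window = baseline_window,
                 z_threshold = z_threshold, interval_width = interval_width,
                 transient_span = transient_span,
                 smoothing_rms = smoothing_rms,
                 literal_threshold = literal_threshold),
            class = "analysis_config")
}

count_in_window <- function(rec, w) {
  sum(vapply(rec$trials, function(x) sum(x >= w[1] & x < w[2]), numeric(1)))
}

#' One-tailed Poisson test for a firing-rate change
#'
#' Tests whether the spike count in a post-change window deviates from the
#' count expected if the unit kept firing at its pre-change baseline rate,
#' using the exact Poisson tail probability (counts pooled over trials; the
#' real-valued expected count is used, not rounded).
#'
#' @param rec A [unit_recording()], spike times aligned to the change (t = 0).
#' @param window Test window, seconds after the change; default
#'   `[0.140, 0.160]`.
#' @param tail `"up"` to test for an increase, `"down"` for a decrease.
#' @param baseline_window Baseline window, seconds; default `[-0.4, 0.055]`.
#' @param p Significance level; default 0.05.
#' @return A list with `significant`, `p_value`, `observed`, `expected`.
#' @examples
#' # exact tails: P(X >= 10 | lambda = 4) ~ 0.0081
#' @export
poisson_rate_change_test <- function(rec, window = c(0.140, 0.160),
                                     tail = c("up", "down"),
                                     baseline_window = c(-0.4, 0.055),
                                     p = 0.05) {
  tail <- match.arg(tail)
  stopifnot(inherits(rec, "unit_recording"))
  if (window[1] >= window[2]) stop("empty test window")
  nbl <- count_in_window(rec, baseline_window)
  lambda <- nbl / diff(baseline_window) * diff(window)
  obs <- count_in_window(rec, window)
  p_value <- if (tail == "up") {
    stats::ppois(obs - 1, lambda, lower.tail = FALSE)
  } else {
    stats::ppois(obs, lambda)
  }
  list(significant = p_value < p, p_value = p_value,
       observed = obs, expected = lambda)
}

#' Attentional modulation index
#'
#' Normalized difference of attended and non-attended pre-change rates,
#' `(A - N) / (A + N)`, in `[-1, 1]` and antisymmetric under swapping.
#'
#' @param A_attended,A_nonattended Pre-change rates, spikes/s, non-negative
#'   and not both zero.
#' @return Attention index.
#' @examples
#' attention_index(60, 40)  # 0.2
#' @export
attention_index <- function(A_attended, A_nonattended) {
  if (any(A_attended < 0) || any(A_nonattended < 0))
    stop("rates must be non-negative")
  if (any(A_attended + A_nonattended == 0))
    stop("attention index undefined when both rates are zero")
  (A_attended - A_nonattended) / (A_attended + A_nonattended)
}

#' Per-interval spike-count mean and variance across trials
#'
#' Dispersion check against Poisson statistics: in fixed-width intervals, the
#' sample mean and unbiased variance of per-trial spike counts; for a Poisson
#' process the two are equal.
#'
#' @param rec A [unit_recording()] with at least two trials.
#' @param bin_width Interval width, seconds; default 0.025.
#' @param span Two-element analysis span, seconds; default `[-0.4, 0.2]`.
#' @return A data frame with `t` (interval centers), `mean`, `variance`.
#' @export
mean_variance_by_bin <- function(rec, bin_width = 0.025, span = c(-0.4, 0.2)) {
  stopifnot(inherits(rec, "unit_recording"))
  if (rec$n_trials < 2) stop("need at least two trials for a variance")
  edges <- seq(span[1], span[2], by = bin_width)
  nb <- length(edges) - 1
  counts <- t(vapply(rec$trials, function(x) {
    x <- x[x >= edges[1] & x < edges[nb + 1]]
    tabulate(findInterval(x, edges), nbins = nb)
  }, numeric(nb)))
  data.frame(t = edges[-(nb + 1)] + bin_width / 2,
             mean = colMeans(counts),
             variance = apply(counts, 2, stats::var))
}

#' Excess cumulative spike count after a stimulus change
#'
#' The number of spikes (summed over trials) exceeding the count expected if
#' the unit had kept firing at its observed pre-change rate: `ec(t)` is the
#' cumulative post-change spike count minus `F_pre * (t - t_change)`, where
#' `F_pre` is the firing rate summed over all trials in the baseline window.
#' A larger (smaller) excess count reflects a steeper positive (negative)
#' initial slope of the transient.
#'
#' @param rec A [unit_recording()] aligned to the change (t = 0).
#' @param cfg An [analysis_config()]; `t_change_delay` is the start of the
#'   accumulation and `baseline_window` defines `F_pre`.
#' @param t_grid Evaluation times, seconds; default 1 ms steps from the
#'   response delay to 0.3 s.
#' @return An object of class `"excess_count"`: list with `t`, `ec` (spikes),
#'   `F_pre` (spikes/s summed over trials), `n_trials`.
#' @export
excess_cumulative_count <- function(rec, cfg = analysis_config(),
                                    t_grid = NULL) {
  stopifnot(inherits(rec, "unit_recording"), inherits(cfg, "analysis_config"))
  tc <- cfg$t_change_delay
  if (is.null(t_grid)) t_grid <- seq(tc, 0.3, by = 0.001)
  if (any(t_grid < tc)) stop("t_grid must start at or after the response delay")
  F_pre <- count_in_window(rec, cfg$baseline_window) / diff(cfg$baseline_window)
  spikes <- sort(unlist(lapply(rec$trials, function(x) x[x > tc])))
  cum <- findInterval(t_grid, spikes)
  structure(list(t = t_grid, ec = cum - F_pre * (t_grid - tc),
                 F_pre = F_pre, t_change = tc, n_trials = rec$n_trials),
            class = "excess_count")
}

#' Attention difference of excess counts with Poisson significance envelope
#'
#' Difference of the attended and non-attended excess cumulative counts,
#' together with the time-dependent significance threshold
#' `z * sqrt((F_A_pre + F_N_pre) * (t - t_change))` derived from the Poisson
#' count variance of the two baselines (with `z = 2.32`, one-sided p < 0.01).
#' Setting `literal_threshold` in the config drops the square root.
#'
#' @param ec_A,ec_N [excess_cumulative_count()] traces of the attended and
#'   non-attended condition, on a common time grid.
#' @param cfg An [analysis_config()].
#' @return A list with `t`, `delta_ec`, `threshold`, and logical
#'   `significant` (`|delta_ec| > threshold`).
#' @export
excess_difference_test <- function(ec_A, ec_N, cfg = analysis_config()) {
  stopifnot(inherits(ec_A, "excess_count"), inherits(ec_N, "excess_count"))
  if (length(ec_A$t) != length(ec_N$t) || any(ec_A$t != ec_N$t))
    stop("excess-count traces are on different time grids")
  dt <- ec_A$t - ec_A$t_change
  base <- (ec_A$F_pre + ec_N$F_pre) * dt
  thr <- cfg$z_threshold * if (cfg$literal_threshold) base else sqrt(base)
  delta <- ec_A$ec - ec_N$ec
  list(t = ec_A$t, delta_ec = delta, threshold = thr,
       significant = abs(delta) > thr)
}

interval_counts <- function(rec, edges) {
  nb <- length(edges) - 1
  counts <- t(vapply(rec$trials, function(x) {
    x <- x[x >= edges[1] & x < edges[nb + 1]]
    tabulate(findInterval(x, edges), nbins = nb)
  }, numeric(nb)))
  if (nb == 1) counts <- matrix(counts, ncol = 1)
  counts
}

# summed count, its variance (sum over independent trials), per interval
count_stats <- function(rec, edges) {
  counts <- interval_counts(rec, edges)
  list(total = colSums(counts),
       var = rec$n_trials * apply(counts, 2, stats::var))
}

#' Interval spike-count changes and their attentional contrast
#'
#' For each interval of `interval_width` within the transient span, computes
#' the change in summed spike count relative to the pre-change baseline
#' (scaled to the interval length), separately for the attended and
#' non-attended condition, and tests the attentional contrast against the
#' threshold `sqrt(var_A_pre + var_A_post + var_N_pre + var_N_post)` (spike
#' count variances across trials, summed over trials).
#'
#' @param rec_A,rec_N Attended / non-attended [unit_recording()]s aligned to
#'   the change.
#' @param cfg An [analysis_config()]; the baseline runs from the start of the
#'   baseline window to the response-delay estimate.
#' @return A data frame with one row per interval: `t_lo`, `t_hi`,
#'   `delta_ac_A`, `delta_ac_N`, `contrast` (A minus N), `threshold`,
#'   `significant`.
#' @export
interval_count_change <- function(rec_A, rec_N, cfg = analysis_config()) {
  stopifnot(inherits(cfg, "analysis_config"))
  iv <- cfg$interval_width
  edges <- seq(cfg$transient_span[1], cfg$transient_span[2], by = iv)
  if (length(edges) < 2) stop("transient span shorter than one interval")
  bl <- c(cfg$baseline_window[1], cfg$t_change_delay)
  scale <- iv / diff(bl)
  one <- function(rec) {
    post <- count_stats(rec, edges)
    pre <- count_stats(rec, bl)
    list(delta = post$total - pre$total * scale,
         var = post$var + pre$var * scale^2)
  }
  A <- one(rec_A); N <- one(rec_N)
  var_sum <- A$var + N$var
  thr <- if (cfg$literal_threshold) var_sum else sqrt(var_sum)
  contrast <- A$delta - N$delta
  data.frame(t_lo = edges[-length(edges)], t_hi = edges[-1],
             delta_ac_A = A$delta, delta_ac_N = N$delta,
             contrast = contrast, threshold = thr,
             significant = abs(contrast) > thr)
}

# Gaussian-smoothed PSTH rate on the PSTH's own bin grid
smooth_psth_rate <- function(psth, rms) {
  hw <- ceiling(4 * rms / psth$bin_width)
  k <- stats::dnorm(seq(-hw, hw) * psth$bin_width, sd = rms)
  k <- k / sum(k)
  n <- length(psth$rate)
  padded <- c(rep(psth$rate[1], hw), psth$rate, rep(psth$rate[n], hw))
  as.numeric(stats::filter(padded, k, sides = 2))[hw + seq_len(n)]
}

#' Attention-induced time advantage at rate-change thresholds
#'
#' Smooths the condition PSTHs with a Gaussian kernel (RMS width
#' `smoothing_rms`, truncated at four RMS widths and renormalized), and for
#' each requested rate change extracts the first post-change time at which the
#' smoothed rate deviates from its pre-change mean by the threshold. The time
#' advantage is the non-attended minus the attended crossing time; positive
#' values mean attention reaches the criterion earlier.
#'
#' @param rec_A,rec_N Attended / non-attended [unit_recording()]s aligned to
#'   the change.
#' @param thresholds Rate changes, spikes/s; positive for increases, negative
#'   for decreases.
#' @param cfg An [analysis_config()].
#' @param bin_width PSTH bin width for the smoothed estimate, seconds.
#' @param t_range PSTH range, seconds.
#' @return A data frame with `threshold`, `t_A`, `t_N`, `advantage`
#'   (`t_N - t_A`, NA where a threshold is never reached).
#' @export
time_advantage <- function(rec_A, rec_N, thresholds,
                           cfg = analysis_config(), bin_width = 0.001,
                           t_range = c(-0.4, 0.3)) {
  stopifnot(inherits(cfg, "analysis_config"))
  crossing <- function(rec, thr) {
    psth <- compute_psth(rec, bin_width = bin_width, t_range = t_range)
    sm <- smooth_psth_rate(psth, cfg$smoothing_rms)
    bl <- psth$bin_centers >= cfg$baseline_window[1] &
      psth$bin_centers < cfg$baseline_window[2]
    base <- mean(sm[bl])
    post <- which(psth$bin_centers >= cfg$t_change_delay)
    hit <- if (thr >= 0) sm[post] - base >= thr else sm[post] - base <= thr
    if (!any(hit)) return(NA_real_)
    psth$bin_centers[post[which(hit)[1]]]
  }
  rows <- lapply(thresholds, function(thr) {
    tA <- crossing(rec_A, thr); tN <- crossing(rec_N, thr)
    data.frame(threshold = thr, t_A = tA, t_N = tN, advantage = tN - tA)
  })
  do.call(rbind, rows)
}

#' Deceleration-versus-acceleration regression with leave-one-out errors
#'
#' Ordinary least squares of per-unit deceleration excess counts on the
#' corresponding acceleration excess counts; parameter variability is
#' assessed by leave-one-out resampling (the SD of the estimates obtained by
#' refitting with each unit dropped in turn).
#'
#' @param excess_up,excess_down Per-unit excess-count values (equal length,
#'   at least 3 units).
#' @return A list with `slope`, `offset`, `slope_sd`, `offset_sd`, `n`.
#' @export
accel_decel_regression <- function(excess_up, excess_down) {
  n <- length(excess_up)
  if (length(excess_down) != n) stop("per-unit vectors differ in length")
  if (n < 3) stop("need at least three units")
  if (stats::var(excess_up) == 0) stop("degenerate regressor: zero variance")
  fit <- stats::lm(excess_down ~ excess_up)
  loo <- vapply(seq_len(n), function(i) {
    stats::coef(stats::lm(excess_down[-i] ~ excess_up[-i]))
  }, numeric(2))
  list(slope = unname(stats::coef(fit)[2]),
       offset = unname(stats::coef(fit)[1]),
       slope_sd = stats::sd(loo[2, ]),
       offset_sd = stats::sd(loo[1, ]),
       n = n)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank p-value for paired per-unit samples; all-zero
#' differences return p = 1 by convention.
#'
#' @param values_a,values_b Equal-length paired samples.
#' @return The p-value.
#' @export
paired_rank_test <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("samples must be paired")
  d <- values_a - values_b
  if (all(d == 0)) return(1)
  suppressWarnings(
    stats::wilcox.test(values_a, values_b, paired = TRUE)$p.value)
}
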