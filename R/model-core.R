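#' Threshold-linear (rectified) gain function
#'
#' Returns `m * (x - theta)` where the input exceeds the threshold, and 0
#' otherwise; continuous and non-decreasing in `x`.
#'
#' @param x Input (vectorized).
#' @param m Gain factor, must be non-negative.
#' @param theta Threshold, same units as `x`.
#' @return Drive, same length as `x`.
#' @examples
#' gain_rectified(4, m = 2, theta = 1)  # 6
#' gain_rectified(0.5, m = 3, theta = 1)  # 0
#' @export
gain_rectified <- function(x, m, theta = 0) {
  if (!is.numeric(m) || length(m) != 1 || m < 0)
    stop("gain m must be a single non-negative number")
  ifelse(x > theta, m * (x - theta), 0)
}

#' Steady-state activations under constant input
#'
#' The fixed point of the circuit dynamics under constant suprathreshold input
#' is the standard static divisive-normalization model: the inhibitory
#' activation is the rectified input, and the excitatory rate is the rectified
#' drive input / (inhibition + sigma), scaled by the excitatory gain.
#'
#' @param I0 Constant input value.
#' @param p A [circuit_params()] object.
#' @return A list with components `A_e` (spikes/s) and `A_i`.
#' @examples
#' p <- circuit_params(0.01, 0.04, m_e = 2, m_i = 1, sigma = 1)
#' steady_state(1, p)  # A_i = 1, A_e = 1
#' @export
steady_state <- function(I0, p) {
  stopifnot(inherits(p, "circuit_params"))
  A_i <- gain_rectified(I0, p$m_i, p$theta_i)
  A_e <- gain_rectified(I0 / (A_i + p$sigma), p$m_e, p$theta_e)
  list(A_e = pmax(A_e, 0), A_i = A_i)
}

#' Integrate the full circuit under a piecewise-constant input
#'
#' Advances the two-unit dynamics on a time grid. The inhibitory equation is
#' linear on each constant-input segment and is propagated by its exact
#' exponential relaxation; the excitatory equation (the only nonlinear one) is
#' advanced with a fixed-step classical 4th-order Runge-Kutta scheme with step
#' at most `min(tau_e, tau_i) / 20`.
#'
#' @param p A [circuit_params()] object.
#' @param input A piecewise-constant input: either a single number (constant
#'   input) or a list with components `t` (segment start times, the first equal
#'   to `t_grid[1]`) and `I` (input value on each segment).
#' @param t_grid Strictly increasing vector of output times, seconds.
#' @param init Optional list with initial `A_e`, `A_i` at `t_grid[1]`; defaults
#'   to the steady state for the first segment's input.
#' @param step Integration step, seconds. Defaults to
#'   `min(tau_e, tau_i) / 20`; larger values are an error.
#' @return A `"rate_timecourse"`: list with `t`, `A_e` (spikes/s, floored at
#'   0), `A_i`.
#' @export
integrate_circuit <- function(p, input, t_grid, init = NULL, step = NULL) {
  stopifnot(inherits(p, "circuit_params"))
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing with at least two points")
  if (is.numeric(input) && length(input) == 1)
    input <- list(t = t_grid[1], I = input)
  if (!is.list(input) || is.null(input$t) || is.null(input$I) ||
      length(input$t) != length(input$I))
    stop("input must be a number or list(t = segment starts, I = values)")
  max_step <- min(p$tau_e, p$tau_i) / 20
  if (is.null(step)) step <- max_step
  if (step > max_step * (1 + 1e-9))
    stop(sprintf("integration step %g s exceeds required min(tau_e, tau_i)/20 = %g s",
                 step, max_step))
  if (is.null(init)) {
    ss <- steady_state(input$I[1], p)
    init <- list(A_e = ss$A_e, A_i = ss$A_i)
  }
  res <- cpp_full_circuit(p$tau_e, p$tau_i, p$m_e, p$m_i, p$sigma,
                          p$theta_e, p$theta_i,
                          as.numeric(input$t), as.numeric(input$I),
                          init$A_e, init$A_i, as.numeric(t_grid), step)
  structure(list(t = as.numeric(t_grid), A_e = pmax(res$A_e, 0),
                 A_i = res$A_i), class = "rate_timecourse")
}

# invert the zero-threshold steady state: input producing sustained rate A
# (normalized circuit algebra; used to map reduced parameters onto inputs)
input_for_rate <- function(A, A_max, m_e = 1, sigma = 1) {
  sigma / (m_e * (1 / A - 1 / A_max))
}

#' Post-change rate time course from the reduced parameterization
#'
#' Integrates the scalar excitatory equation in which the inhibitory
#' relaxation appears in closed form inside the divisive drive. The system is
#' assumed to be in its pre-change steady state at `t_change`; the rate starts
#' at `A_pre` and converges to `A_post`, with the transient excursion governed
#' by the time-constant separation.
#'
#' @param r A [reduced_params()] object.
#' @param t_grid Output times, seconds; values before `t_change` are reported
#'   at the pre-change steady level.
#' @param gains Optional [attention_gains()]; when supplied, `A_pre`/`A_post`
#'   are interpreted as unattended sustained rates and the attended time course
#'   is returned.
#' @return A `"rate_timecourse"` (list with `t`, `A_e`).
#' @examples
#' r <- reduced_params(50, 100, 120, tau_e = 0.010, tau_i = 0.040)
#' tc <- reduced_response(r, seq(0, 1, by = 0.001))
#' max(tc$A_e)  # transient overshoot above 100 spikes/s
#' @export
reduced_response <- function(r, t_grid, gains = attention_gains(1)) {
  stopifnot(inherits(r, "reduced_params"), inherits(gains, "attention_gains"))
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  p <- r$A_pre / r$A_max
  q <- r$A_post / r$A_max
  rel <- t_grid - r$t_change
  post <- rel >= 0
  dt <- min(r$tau_e, r$tau_i) / 20
  a <- numeric(length(t_grid))
  if (any(post))
    a[post] <- cpp_reduced_ae(p, q, r$tau_e, r$tau_i,
                              gains$alpha_e, gains$alpha_i, rel[post], dt)
  if (any(!post)) {
    I <- p / (1 - p)
    a[!post] <- gains$alpha_e * I / (gains$alpha_i * I + 1)
  }
  structure(list(t = as.numeric(t_grid), A_e = pmax(r$A_max * a, 0)),
            class = "rate_timecourse")
}

#' Transient peak in the fast-excitation limit
#'
#' When excitation reacts much faster than inhibition (`tau_e << tau_i`), the
#' excitatory rate tracks its drive instantaneously while inhibition is still
#' at its pre-change level, and the transient peak has the closed form
#' `A_post * (A_max - A_pre) / (A_max - A_post)`. The value exceeds `A_post`
#' exactly when the change is an increment (`A_post > A_pre`), and is a trough
#' below `A_post` for decrements.
#'
#' @param A_pre,A_post,A_max Sustained rates, spikes/s, with
#'   `0 < A_pre, A_post < A_max`.
#' @return Peak (or trough) rate, spikes/s.
#' @examples
#' peak_fast_excitation(50, 100, 120)   # 350
#' peak_fast_excitation(100, 50, 120)   # ~14.29
#' @export
peak_fast_excitation <- function(A_pre, A_post, A_max) {
  if (any(A_post >= A_max)) stop("A_post must be below A_max")
  if (any(A_pre <= 0) || any(A_pre >= A_max) || any(A_post <= 0))
    stop("rates must lie strictly between 0 and A_max")
  A_post * (A_max - A_pre) / (A_max - A_post)
}

#' Log-Gaussian speed tuning
#'
#' Sustained rate as a function of stimulus speed, Gaussian in natural log
#' speed around the preferred speed, on top of a spontaneous rate.
#'
#' @param v Speed, deg/s, strictly positive (vectorized).
#' @param tuning A [speed_tuning()] object.
#' @return Rate, spikes/s.
#' @examples
#' tun <- speed_tuning(0, 60, v_pref = 8, sigma_v = log(2^2.5))
#' speed_tuning_rate(8, tun)  # peak: A0 + A_pref
#' @export
speed_tuning_rate <- function(v, tuning) {
  stopifnot(inherits(tuning, "speed_tuning"))
  if (any(v <= 0)) stop("speed v must be strictly positive")
  tuning$A0 + tuning$A_pref *
    exp(-(log(tuning$v_pref) - log(v))^2 / (2 * tuning$sigma_v^2))
}

#' Predicted transient and sustained response to a speed change
#'
#' Maps the pre- and post-change speeds through the tuning curve to sustained
#' rates, applies the fast-excitation peak formula, and reports the transient
#' and sustained rate changes relative to the pre-change rate (the ratios
#' `A_peak / A_pre` and `A_post / A_peak` used to compare against population
#' change-transient data).
#'
#' @param v_pre,v_post Speeds before and after the change, deg/s.
#' @param tuning A [speed_tuning()] object.
#' @param A_max Theoretical maximum sustained rate; must exceed the tuning
#'   rates at both speeds.
#' @param tau_e,tau_i Optional time constants; when supplied, the peak is also
#'   computed from the integrated reduced response rather than the
#'   fast-excitation limit alone (returned as `A_peak_ode`).
#' @return A list with `A_pre`, `A_post`, `A_peak`, `transient_change`
#'   (`A_peak / A_pre`) and `sustained_change` (`A_post / A_peak`).
#' @export
predict_change_response <- function(v_pre, v_post, tuning, A_max,
                                    tau_e = NULL, tau_i = NULL) {
  A_pre <- speed_tuning_rate(v_pre, tuning)
  A_post <- speed_tuning_rate(v_post, tuning)
  if (any(A_pre >= A_max) || any(A_post >= A_max))
    stop("tuning rates reach A_max; increase A_max or reduce A_pref")
  if (any(A_pre <= 0) || any(A_post <= 0))
    stop("tuning rates must be positive; use A0 > 0 or speeds nearer v_pref")
  A_peak <- peak_fast_excitation(A_pre, A_post, A_max)
  out <- list(A_pre = A_pre, A_post = A_post, A_peak = A_peak,
              transient_change = A_peak / A_pre,
              sustained_change = A_post / A_peak)
  if (!is.null(tau_e) && !is.null(tau_i)) {
    stopifnot(length(v_pre) == 1, length(v_post) == 1)
    r <- reduced_params(A_pre, A_post, A_max, tau_e, tau_i)
    tc <- reduced_response(r, seq(0, 10 * tau_i, length.out = 2001))
    out$A_peak_ode <- if (A_post >= A_pre) max(tc$A_e) else min(tc$A_e)
  }
  out
}

#' @export
print.rate_timecourse <- function(x, ...) {
  cat(sprintf("Rate time course: %d samples, t in [%g, %g] s, A_e in [%g, %g] spikes/s\n",
              length(x$t), min(x$t), max(x$t), min(x$A_e), max(x$A_e)))
  invisible(x)
}
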