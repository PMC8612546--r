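#' Circuit parameters for the excitatory-inhibitory normalization model
#'
#' Container for the full parameterization of the two-unit rate circuit: an
#' excitatory unit whose drive is the external input divided by the inhibitory
#' activation plus a positive offset, and an inhibitory unit tracking the
#' input, each with threshold-linear gain and first-order relaxation dynamics.
#'
#' @param tau_e Excitatory time constant, seconds.
#' @param tau_i Inhibitory time constant, seconds.
#' @param m_e Excitatory gain (spikes/s per unit drive).
#' @param m_i Inhibitory gain (dimensionless per unit input); `m_i >= 0`.
#' @param sigma Positive offset in the divisive denominator.
#' @param theta_e,theta_i Input thresholds of the two rectified gains.
#' @return An object of class `"circuit_params"`.
#' @examples
#' circuit_params(tau_e = 0.010, tau_i = 0.040, m_e = 2, m_i = 1, sigma = 1)
#' @export
circuit_params <- function(tau_e, tau_i, m_e, m_i, sigma,
                           theta_e = 0, theta_i = 0) {
  stopifnot(is.numeric(tau_e), is.numeric(tau_i))
  if (tau_e <= 0 || tau_i <= 0) stop("time constants must be positive")
  if (sigma <= 0) stop("sigma must be positive")
  if (m_e <= 0) stop("m_e must be positive")
  if (m_i < 0) stop("m_i must be non-negative")
  structure(list(tau_e = tau_e, tau_i = tau_i, m_e = m_e, m_i = m_i,
                 sigma = sigma, theta_e = theta_e, theta_i = theta_i),
            class = "circuit_params")
}

#' Reduced (observable) parameterization of the change transient
#'
#' Parameterizes the post-change excitatory dynamics by quantities accessible
#' in a recording: the sustained rate before the change (`A_pre`), the
#' sustained rate after the transient has decayed (`A_post`), the theoretical
#' maximum sustained rate of the circuit (`A_max`, the ratio of excitatory to
#' inhibitory gain), and the two time constants. The underlying inputs are
#' recovered by inverting the steady-state relation, so the time course is
#' fully determined without knowing the circuit gains individually.
#'
#' @param A_pre,A_post Sustained pre-/post-change rates, spikes/s; both must
#'   lie strictly between 0 and `A_max`.
#' @param A_max Theoretical maximum sustained rate, spikes/s.
#' @param tau_e,tau_i Time constants, seconds.
#' @param t_change Time of the input step, seconds (default 0).
#' @return An object of class `"reduced_params"`.
#' @examples
#' reduced_params(A_pre = 50, A_post = 100, A_max = 120,
#'                tau_e = 0.010, tau_i = 0.040)
#' @export
reduced_params <- function(A_pre, A_post, A_max, tau_e, tau_i, t_change = 0) {
  if (A_max <= 0) stop("A_max must be positive")
  if (A_pre <= 0 || A_pre >= A_max)
    stop("A_pre must lie strictly between 0 and A_max (drive inversion undefined otherwise)")
  if (A_post <= 0 || A_post >= A_max)
    stop("A_post must lie strictly between 0 and A_max (drive inversion undefined otherwise)")
  if (tau_e <= 0 || tau_i <= 0) stop("time constants must be positive")
  structure(list(A_pre = A_pre, A_post = A_post, A_max = A_max,
                 tau_e = tau_e, tau_i = tau_i, t_change = t_change),
            class = "reduced_params")
}

#' Log-Gaussian speed tuning curve parameters
#'
#' @param A0 Spontaneous rate, spikes/s (>= 0).
#' @param A_pref Amplitude at the preferred speed, spikes/s.
#' @param v_pref Preferred speed, deg/s.
#' @param sigma_v Tuning width in natural-log-speed units.
#' @return An object of class `"speed_tuning"`.
#' @examples
#' speed_tuning(A0 = 0, A_pref = 60, v_pref = 8, sigma_v = log(2^2.5))
#' @export
speed_tuning <- function(A0, A_pref, v_pref, sigma_v) {
  if (A0 < 0) stop("A0 must be non-negative")
  if (A_pref <= 0) stop("A_pref must be positive")
  if (v_pref <= 0) stop("v_pref must be positive")
  if (sigma_v <= 0) stop("sigma_v must be positive")
  structure(list(A0 = A0, A_pref = A_pref, v_pref = v_pref, sigma_v = sigma_v),
            class = "speed_tuning")
}

#' Attentional input gains
#'
#' Multiplicative gains applied to the external input of the excitatory
#' (`alpha_e`) and inhibitory (`alpha_i`) units. The single-gain attention
#' model corresponds to `alpha_e == alpha_i`.
#'
#' @param alpha_e,alpha_i Positive gains; both default to 1 (no attention).
#' @return An object of class `"attention_gains"`.
#' @export
attention_gains <- function(alpha_e = 1, alpha_i = alpha_e) {
  if (alpha_e <= 0 || alpha_i <= 0) stop("attention gains must be positive")
  structure(list(alpha_e = alpha_e, alpha_i = alpha_i),
            class = "attention_gains")
}

# validate a normalized activation (rate relative to A_max), open interval
check_activation <- function(a, name = deparse(substitute(a))) {
  if (any(!is.finite(a)) || any(a <= 0) || any(a >= 1))
    stop(sprintf("%s must lie strictly inside (0, 1)", name))
  invisible(a)
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Divisive-normalization circuit parameters\n")
  cat(sprintf("  tau_e = %g ms, tau_i = %g ms\n", 1000 * x$tau_e, 1000 * x$tau_i))
  cat(sprintf("  m_e = %g, m_i = %g, sigma = %g, theta_e = %g, theta_i = %g\n",
              x$m_e, x$m_i, x$sigma, x$theta_e, x$theta_i))
  if (x$m_i > 0)
    cat(sprintf("  A_max = m_e/m_i = %g spikes/s\n", x$m_e / x$m_i))
  invisible(x)
}

#' @export
print.reduced_params <- function(x, ...) {
  cat("Reduced transient parameters\n")
  cat(sprintf("  A_pre = %g, A_post = %g, A_max = %g spikes/s\n",
              x$A_pre, x$A_post, x$A_max))
  cat(sprintf("  tau_e = %g ms, tau_i = %g ms, t_change = %g s\n",
              1000 * x$tau_e, 1000 * x$tau_i, x$t_change))
  invisible(x)
}
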