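#' Attentional scaling of a normalized sustained activation
#'
#' Scaling the circuit's input by a gain `alpha` maps the normalized sustained
#' activation `a` (rate relative to `A_max`) through the Naka-Rushton-like
#' form `alpha * a / ((alpha - 1) * a + 1)`: the identity at `alpha = 1`,
#' strictly increasing in `a`, and saturating at 1.
#'
#' @param a Normalized activation(s) in (0, 1); the closed-interval endpoints
#'   are allowed here since the map is continuous at 0 and 1.
#' @param alpha Positive input gain.
#' @return Attended normalized activation(s).
#' @examples
#' attention_map(0.5, 2)  # 2/3
#' @export
attention_map <- function(a, alpha) {
  if (any(a < 0) || any(a > 1)) stop("a must lie in [0, 1]")
  if (any(alpha <= 0)) stop("alpha must be positive")
  alpha * a / ((alpha - 1) * a + 1)
}

#' Initial slope of the normalized transient under attention
#'
#' The slope of the normalized rate immediately after the change,
#' `(1/tau_e) * (a_post - a_pre) / (1 - a_post) * alpha / (a_pre*(alpha-1) + 1)`.
#' Its sign equals the sign of the input change, and for `alpha > 1` its
#' magnitude exceeds the unattended value for every pre-change activation:
#' attention makes both rises and decays steeper.
#'
#' @param a_pre,a_post Normalized sustained activations, strictly in (0, 1).
#' @param alpha Attention gain.
#' @param tau_e Excitatory time constant, seconds.
#' @return Slope in units of normalized rate per second.
#' @examples
#' rise_slope(0.25, 0.5, alpha = 1, tau_e = 0.01)  # 50
#' @export
rise_slope <- function(a_pre, a_post, alpha = 1, tau_e) {
  check_activation(a_pre)
  if (any(a_post <= 0) || any(a_post >= 1))
    stop("a_post must lie strictly inside (0, 1)")
  if (any(alpha <= 0)) stop("alpha must be positive")
  (1 / tau_e) * (a_post - a_pre) / (1 - a_post) *
    alpha / (a_pre * (alpha - 1) + 1)
}

#' Sustained activation change under attention
#'
#' The attended post- minus pre-change sustained level, i.e. the difference of
#' the attention-mapped activations:
#' `alpha/(alpha - 1 + 1/a_post) - alpha/(alpha - 1 + 1/a_pre)`.
#'
#' @inheritParams rise_slope
#' @return Dimensionless sustained change.
#' @examples
#' sustained_change(0.25, 0.5, alpha = 2)  # 2/3 - 2/5
#' @export
sustained_change <- function(a_pre, a_post, alpha = 1) {
  attention_map(a_post, alpha) - attention_map(a_pre, alpha)
}

# attended normalized steady state with separate excitatory/inhibitory gains
steady_norm_gains <- function(a, alpha_e, alpha_i) {
  I <- a / (1 - a)
  alpha_e * I / (alpha_i * I + 1)
}

#' Attention-induced changes in slope, sustained level, and peak
#'
#' Computes the differences between attended and unattended response features
#' of a change transient, for generally unequal input gains on the excitatory
#' and inhibitory units. The slope and sustained changes are closed-form:
#' \deqn{\Delta F^{rise} = \frac{(q-p)\,(\alpha_e - 1 - p(\alpha_i - 1))}
#'   {\tau_e (1-q)\,(p(\alpha_i-1)+1)},\qquad
#'   \Delta F^{sus} = (q-p)\left(\frac{\alpha_e}
#'   {(q(\alpha_i-1)+1)(p(\alpha_i-1)+1)} - 1\right)}
#' with `p = a_pre`, `q = a_post`. The peak change has no closed form: the
#' reduced response is integrated with and without attention and the peak is
#' taken as the extremal deviation from the (attended) pre-change level within
#' 0.5 s of the change — peak and sustained features are quantified relative
#' to the pre-change activation.
#'
#' @param a_pre,a_post Normalized sustained activations, strictly in (0, 1).
#' @param gains An [attention_gains()] object.
#' @param tau_e,tau_i Time constants, seconds (needed for `dF_peak`).
#' @param peak_window Search window after the change for the peak, seconds.
#' @return A list with `dF_rise` (1/s), `dF_sus` (dimensionless) and `dF_peak`
#'   (dimensionless, normalized rate units).
#' @export
attention_deltas <- function(a_pre, a_post, gains, tau_e, tau_i,
                             peak_window = 0.5) {
  stopifnot(inherits(gains, "attention_gains"))
  check_activation(a_pre)
  check_activation(a_post)
  p <- a_pre; q <- a_post
  ae <- gains$alpha_e; ai <- gains$alpha_i
  dF_rise <- (q - p) * (ae - 1 - p * (ai - 1)) /
    (tau_e * (1 - q) * (p * (ai - 1) + 1))
  dF_sus <- (q - p) * (ae / ((q * (ai - 1) + 1) * (p * (ai - 1) + 1)) - 1)
  dt <- min(tau_e, tau_i) / 20
  t_out <- seq(0, peak_window, by = max(dt, peak_window / 5000))
  peak_of <- function(alpha_e, alpha_i) {
    a <- cpp_reduced_ae(p, q, tau_e, tau_i, alpha_e, alpha_i, t_out, dt)
    dev <- a - steady_norm_gains(p, alpha_e, alpha_i)
    dev[which.max(abs(dev))]
  }
  dF_peak <- peak_of(ae, ai) - peak_of(1, 1)
  if (!is.finite(dF_rise) || !is.finite(dF_sus) || !is.finite(dF_peak))
    stop(sprintf("non-finite attention delta at a_pre=%g, a_post=%g, alpha_e=%g, alpha_i=%g",
                 p, q, ae, ai))
  list(dF_rise = dF_rise, dF_sus = dF_sus, dF_peak = dF_peak)
}

#' Attention-modulation surfaces over the activation plane
#'
#' Evaluates [attention_deltas()] on a square grid of pre-/post-change
#' normalized activations and returns the three modulation surfaces. For a
#' consistent modulation the surface sign depends only on the sign of the
#' activation change (positive above the `a_pre = a_post` diagonal, negative
#' below); the sustained surface is the canonical inconsistent case, changing
#' sign above the diagonal at a critical input strength.
#'
#' @param alpha Attention gain (single-gain model); default 1.2.
#' @param tau_ratio `tau_e / tau_i` used for the peak surface; `tau_i` is held
#'   at 0.05 s.
#' @param grid_step Grid spacing over (0.05, 0.95); must be in (0, 0.5).
#' @param peak Logical; set `FALSE` to skip the (numerical) peak surface.
#' @return A list with the grid vector `a` and matrices `dF_rise`, `dF_sus`,
#'   `dF_peak` (rows index `a_pre`, columns `a_post`).
#' @export
attention_surfaces <- function(alpha = 1.2, tau_ratio = 0.25, grid_step = 0.01,
                               peak = TRUE) {
  if (grid_step <= 0 || grid_step >= 0.5) stop("grid_step must be in (0, 0.5)")
  a <- seq(0.05, 0.95, by = grid_step)
  n <- length(a)
  tau_i <- 0.05
  tau_e <- tau_ratio * tau_i
  p <- matrix(a, n, n)          # rows: a_pre
  q <- matrix(a, n, n, byrow = TRUE)  # cols: a_post
  dF_rise <- (q - p) * (alpha - 1 - p * (alpha - 1)) /
    (tau_e * (1 - q) * (p * (alpha - 1) + 1))
  dF_sus <- (q - p) * (alpha / ((q * (alpha - 1) + 1) * (p * (alpha - 1) + 1)) - 1)
  dF_peak <- NULL
  if (peak) {
    dF_peak <- matrix(NA_real_, n, n)
    gains <- attention_gains(alpha)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      dF_peak[i, j] <- attention_deltas(a[i], a[j], gains, tau_e, tau_i,
                                        peak_window = 0.5)$dF_peak
    }
  }
  list(a = a, alpha = alpha, tau_ratio = tau_ratio,
       dF_rise = dF_rise, dF_sus = dF_sus, dF_peak = dF_peak)
}
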