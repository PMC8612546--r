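# shared fixture builders (everything is generated in code, no data files)

# noise-free "PSTH" taken directly from a model rate curve (sem floored later)
psth_from_rate <- function(tc, bin_width = 0.005, n_trials = 10) {
  edges <- seq(min(tc$t), max(tc$t), by = bin_width)
  nb <- length(edges) - 1
  centers <- edges[-(nb + 1)] + bin_width / 2
  rate <- vapply(centers, function(ct) {
    sel <- tc$t >= ct - bin_width / 2 & tc$t < ct + bin_width / 2
    mean(tc$A_e[sel])
  }, numeric(1))
  structure(list(bin_centers = centers, rate = rate,
                 sem = rep(0, nb), bin_width = bin_width,
                 n_trials = n_trials), class = "psth")
}

# Poisson-sampled recording of a reduced-model onset transient
onset_recording <- function(A_pre, A_post, A_max, tau_e, tau_i,
                            delay = 0.031, n_trials = 10, seed = 1,
                            t_range = c(-0.4, 0.7)) {
  r <- reduced_params(A_pre, A_post, A_max, tau_e, tau_i, t_change = delay)
  tc <- reduced_response(r, seq(t_range[1], t_range[2], by = 0.001))
  unit_recording("synthetic", poisson_spikes_from_rate(tc, n_trials, seed))
}

# constant-rate recording aligned to a nominal change at t = 0
constant_recording <- function(rate, n_trials, seed,
                               t_range = c(-0.45, 0.3)) {
  tc <- structure(list(t = t_range, A_e = c(rate, rate)),
                  class = "rate_timecourse")
  unit_recording("const", poisson_spikes_from_rate(tc, n_trials, seed))
}

# map reduced parameters onto an explicit circuit (the oracle's own algebra):
# I = sigma / (m_e (1/A - 1/A_max)), m_i = m_e / A_max
circuit_for_reduced <- function(r, m_e = 120, sigma = 1) {
  m_i <- m_e / r$A_max
  I_for <- function(A) sigma / (m_e * (1 / A - 1 / r$A_max))
  list(params = circuit_params(r$tau_e, r$tau_i, m_e, m_i, sigma),
       I_pre = I_for(r$A_pre), I_post = I_for(r$A_post))
}
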