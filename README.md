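# dntransient

Neurons in motion-selective cortical area MT respond to abrupt stimulus
changes — stimulus onset, speed increments, speed decrements — with brief
firing-rate transients that can far exceed anything their static tuning
curve predicts, and these transients carry the signal that behavioral
change detection relies on. `dntransient` is an R package for scientists
modeling such responses: it implements a two-unit excitatory–inhibitory
rate circuit in which divisive inhibition acts on a slower time scale than
excitation, the closed-form results that follow from it, and the complete
analysis pipeline around it — grid-search fitting of the model to spike
trains, change-transient statistics with Poisson significance envelopes,
and a synthetic-data generator so everything can be validated end to end
against known ground truth.

## The model

The circuit obeys

```
tau_e dA_e/dt = -A_e + g_e( I / (A_i + sigma) )
tau_i dA_i/dt = -A_i + g_i( I )
```

with threshold-linear gains `g_e(x) = m_e (x - theta_e)+`,
`g_i(x) = m_i (x - theta_i)+`. Its fixed point is a static
divisive-normalization model; its dynamics produce transients because
excitation (time scale `tau_e`, ~10–20 ms) outruns the divisive term
(`tau_i`, ~40–70 ms). Post-change dynamics are fully determined by
observable quantities — the sustained rates `A_pre`, `A_post`, the maximum
sustained rate `A_max = m_e / m_i`, and the two time constants — and in the
fast-excitation limit the transient peak is

```
A_peak ≈ A_post (A_max - A_pre) / (A_max - A_post)
```

Attention enters as a multiplicative input gain `alpha`, which maps
normalized activations `a = A / A_max` through
`alpha a / ((alpha - 1) a + 1)`. The model's central prediction: the
*initial slope* of a transient is modulated consistently by attention
(steeper rises for increments, steeper decays for decrements, regardless of
pre-change activation), while the *sustained* response is modulated
inconsistently; the *peak* interpolates between the two as `tau_e / tau_i`
grows. The methods vignette
(`vignettes/divisive-normalization-transients.Rmd`) derives and discusses
all of this in detail.

## Worked example

Simulate the canonical step response — pre-change rate 50 spikes/s rising
to a sustained 100 spikes/s with `A_max` = 120, `tau_e` = 10 ms,
`tau_i` = 40 ms:

```r
library(dntransient)
r  <- reduced_params(A_pre = 50, A_post = 100, A_max = 120,
                     tau_e = 0.010, tau_i = 0.040)
tc <- reduced_response(r, seq(0, 0.5, by = 5e-4))
c(peak = max(tc$A_e), fast_excitation_limit = peak_fast_excitation(50, 100, 120),
  sustained = tail(tc$A_e, 1))
#>        peak fast_excitation_limit   sustained
#>       195.4                 350.0       100.0
```

The response overshoots to 195 spikes/s — nearly double the sustained
change — before divisive inhibition catches up; the closed-form 350 is the
idealized peak if excitation were infinitely fast. Now generate a synthetic
onset recording with known parameters and fit it:

```r
spec <- population_spec(n_units = 1, trials_per_unit = c(40, 40), seed = 8)
ex   <- make_onset_experiment(spec)        # truth: tau_e 15.6 ms, tau_i 70.2 ms, A_max 62.0
psth <- compute_psth(ex$recordings[[1]], t_range = c(-0.4, 0.7))
lv   <- estimate_sustained_levels(psth)
grid_search_fit(psth, lv$A_pre, lv$A_post, delta_tau = ex$truth$delta_tau[1])
#> Transient model fit: tau_e = 26.5 ms, tau_i = 45.3 ms, A_max = 51.2 spikes/s
#>   A_pre = 6.5, A_post = 47.6 spikes/s, delay = 30 ms, chi2/N = 1.836
```

The fitted curve matches the PSTH at roughly the trial-to-trial noise level
(`chi2/N` near 1), while the individual parameters land on the shallow
ridge along which `(tau_e, tau_i, A_max)` trade off — see the vignette's
identifiability section before interpreting single-unit time constants.
Finally, the attention algebra at a modest gain:

```r
attention_deltas(a_pre = 0.3, a_post = 0.6, attention_gains(1.2),
                 tau_e = 0.017, tau_i = 0.045)
#> $dF_rise  5.8269     # steeper rise (1/s, normalized units)
#> $dF_sus   0.0032     # barely changed sustained level
#> $dF_peak  0.0387     # higher relative peak
```

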