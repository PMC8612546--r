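---
title: "A dynamic divisive-normalization model of change transients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamic divisive-normalization model of change transients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dntransient)
```

## The model

Neurons in motion-selective cortex (area MT) respond to sudden stimulus
changes — stimulus onset, speed increments, speed decrements — with brief,
pronounced firing-rate transients that far exceed what their static tuning
curves predict. `dntransient` implements a minimal circuit that produces
these transients from the interplay of fast excitation and slower divisive
inhibition, together with the analysis pipeline needed to fit the circuit to
spike trains and to test its predictions about attention.

The circuit has one excitatory and one inhibitory unit, both driven by the
external input $I(t)$:

$$\tau_e \dot A_e = -A_e + g_e\!\left(\frac{I}{A_i + \sigma}\right), \qquad
  \tau_i \dot A_i = -A_i + g_i(I),$$

with threshold-linear gains $g_e(x) = m_e (x - \theta_e)^+$ and
$g_i(x) = m_i (x - \theta_i)^+$. The inhibitory activation divides the
excitatory drive, so the fixed point under constant input is a standard
static divisive-normalization model; the dynamics add the transient. Because
$\tau_e < \tau_i$ in the fitted populations, the excitatory unit tracks an
input step almost immediately while the divisive term catches up on the
slower time scale $\tau_i$, producing an overshoot (for increments) or an
undershoot (for decrements) that relaxes to the new sustained level.

With zero thresholds and positive input the steady state can be inverted:
the input producing sustained rate $A$ is
$I = \sigma / \big(m_e(1/A - 1/A_{max})\big)$ with
$A_{max} = m_e/m_i$, the theoretical maximum sustained rate. This inversion
is what makes the *reduced parameterization* possible: the post-change
dynamics are fully determined by the observable quantities
$(A^{pre}, A^{post}, A_{max}, \tau_e, \tau_i)$, without knowing the gains or
the inputs individually. `reduced_params()` + `reduced_response()` implement
this form; `circuit_params()` + `integrate_circuit()` implement the explicit
circuit, and the equivalence of the two is a standing test of the package
(sup-norm below 0.5% on randomized parameter sets; in practice it holds to
machine-level accuracy of the integrator).

In the limit of fast excitation ($\tau_e \ll \tau_i$) the transient peak has
the closed form

$$A^{peak} \approx A^{post}\,\frac{A_{max}-A^{pre}}{A_{max}-A^{post}},$$

implemented by `peak_fast_excitation()`. The sign of the excursion always
equals the sign of $A^{post}-A^{pre}$, and the overshoot grows without bound
as $A^{post} \to A_{max}$ — the mechanism behind transients that dwarf the
sustained change. Convergence of the integrated peak to this formula is
slow for strong increments (the relative gap scales like
$(\tau_e/\tau_i)\ln(\tau_i/\tau_e)$ times the relative drive decay rate, about
1.4% at a time-scale ratio of $10^{-3}$ for the worked example below and
0.2% at $10^{-4}$); the tests therefore check the decrement case at
$10^{-3}$ and the increment case at $10^{-4}$, both at 1%.

```{r}
r <- reduced_params(A_pre = 50, A_post = 100, A_max = 120,
                    tau_e = 0.010, tau_i = 0.040)
tc <- reduced_response(r, seq(0, 0.5, by = 5e-4))
c(peak = max(tc$A_e), closed_form = peak_fast_excitation(50, 100, 120),
  sustained = tail(tc$A_e, 1))
```

Speed enters through a log-Gaussian tuning curve
(`speed_tuning_rate()`): sustained rates before and after a speed change are
read off the tuning curve and pushed through the peak formula
(`predict_change_response()`), which reproduces the characteristic
over- and undershooting of change transients relative to the static tuning
prediction, on both tuning flanks.

## Attention

Attention is modeled as a multiplicative gain $\alpha > 1$ on the input,
$I \to \alpha I$. On normalized activations $a = A/A_{max} \in (0,1)$ the
steady state maps through the saturating form
$a \mapsto \alpha a / ((\alpha - 1) a + 1)$ (`attention_map()`). Three
response features are analyzed (all relative to the pre-change level):

* **initial slope** (`rise_slope()`):
  $F^{rise} = \frac{1}{\tau_e}\,\frac{a^{post}-a^{pre}}{1-a^{post}}\,
  \frac{\alpha}{a^{pre}(\alpha-1)+1}$. A variant of this expression with
  $1-a^{pre}$ in the denominator is sometimes written down; differentiating
  the reduced drive at the change time yields $1-a^{post}$, and the
  finite-difference oracle in the test suite confirms it, so that is what
  the package implements.
* **sustained change** (`sustained_change()`): the difference of the mapped
  activations.
* **peak** (numeric only): the extremal deviation of the integrated
  response from the attended pre-change level within 0.5 s of the change —
  transients decay well within 200 ms for physiological time constants, so
  the window is generous.

The central structural result, visible in `attention_surfaces()`: the
attention-induced change in slope, $\Delta F^{rise}$, is *consistent* — its
sign equals the sign of the activation change everywhere in the
$(a^{pre}, a^{post})$ plane — whereas $\Delta F^{sus}$ is *inconsistent*,
reversing sign at a critical input strength because the attended
Naka-Rushton curve crosses the unattended one. $\Delta F^{peak}$
interpolates between the two patterns as $\tau_e/\tau_i$ goes from 0 to
$\infty$; since the three features carry different units, the limits are
checked as sign-pattern agreement on an activation grid, not as numeric
equality. The generalized two-gain model (separate gains $\alpha_e$,
$\alpha_i$ on the two units, `attention_gains()`) has closed forms whose
grouping was fixed by re-deriving them from the circuit and matching the
numeric oracle:
$\Delta F^{sus} = (a^{post}-a^{pre})\big(\alpha_e/[(a^{post}(\alpha_i-1)+1)
(a^{pre}(\alpha_i-1)+1)] - 1\big)$, and analogously for the slope.

The surfaces default to $\alpha = 1.2$ — a modest gain producing
pre-change rate increases of 10–20% at mid-range activations, in line with
typical attentional modulation in MT — with the gain exposed as an argument
everywhere.

## Numerical choices

* The inhibitory equation is linear on any constant-input segment and is
  propagated by its exact exponential relaxation; only the excitatory
  equation is integrated, with a fixed-step classical Runge-Kutta scheme at
  step $\min(\tau_e,\tau_i)/20$ (halving the step changes the solution by
  far less than 0.1%). Requested output times are linearly interpolated
  between internal steps. Coarser user-supplied steps are an error, not a
  warning.
* Rectification floors rates at zero on output.
* The peak search for $\Delta F^{peak}$ uses at most 5000 output samples in
  the 0.5 s window; with the internal step tied to $\tau_e$ the peak is
  resolved at time-scale ratios from $10^{-3}$ to $10^{3}$.

## Fitting

`grid_search_fit()` fits $(\tau_e, \tau_i, A_{max})$ to a 5-ms-binned PSTH
by exhaustive evaluation over a 3-D grid, followed by three refinements:
after each pass the grid re-centers on the best cell, spanning one cell on
either side with the same bin counts, so each axis's spacing shrinks by
$2/\mathrm{bins}$ per iteration. Defaults: $A_{max}$ over
$[1.03, 3] \times A^{post}$ with 40 bins, $\tau_e$ over $[1, 100]$ ms and
$\tau_i$ over $[1, 500]$ ms with 15 bins each, four iterations, giving a
final resolution of about 0.01–0.1% of the initial ranges. Evaluation points
are cell centers, so boundary values are flagged rather than silently
returned. The fit is a pure function of its inputs.

The error is a chi-square per bin: the model, downsampled to the PSTH bins
by within-bin averaging, is compared to the delay-compensated rate, the
squared deviation divided by the squared per-bin standard error and averaged
over a 200 ms window after response onset. Dividing by the *squared*
standard error makes "chi-square near 1" mean deviations comparable to the
trial-to-trial variability; an unsquared variant is available behind the
`denominator` switch for comparison with conventions that divide by the
standard error itself. Bins with zero variance receive a standard-error
floor of one spike per (trials × bin width). Sustained levels are estimated
over $[-100, 0]$ ms and $[200, 500]$ ms around stimulus onset; the response
onset delay is estimated automatically (first run of at least two
consecutive bins deviating from the baseline mean by more than three
baseline standard errors) with a manual override — an automated,
reproducible stand-in for latency estimation by eye.

Two accompanying diagnostics: `population_fit_global()` refits a population
with one or more parameters (including the derived ratio
$\tau_e/\tau_i$) held at a globally searched value and reports the mean
chi-square increase in percent; `surrogate_chi2_distribution()` refits
Poisson surrogates drawn from the fitted parameter distribution, giving the
chi-square distribution expected if the model class is exactly right.

### Identifiability

The three fit parameters are *sloppy* over a 200 ms window: there is a
ridge along which trading $\tau_e$ up, $\tau_i$ down and $A_{max}$ down
changes the rate curve by under 10% while the parameters move by tens of
percent. Consequences, measured on synthetic data and stated as package
behavior rather than hidden: a noise-free fit recovers the *curve*
essentially exactly (chi-square near 0) but the parameters only to within a
few percent; at 10 Poisson trials per unit the median relative error across
a synthetic population is roughly 20–25% for $A_{max}$ but 40–60% for the
two time constants, shrinking steadily with trial count. Fitted time
constants from few-trial data should therefore be read as ridge
coordinates — their ratio and the implied curve are far better determined
than either constant alone.

## Synthetic data

The generators exist so every stage of the pipeline can run against known
ground truth without any recorded data.

`make_onset_experiment()` emulates onset-transient recordings from a
heterogeneous population: per-unit parameters are drawn from truncated
normal distributions whose defaults follow the fitted population statistics
of macaque MT onset responses ($\tau_e$ 17 ± 16 ms, $\tau_i$ 45 ± 30 ms,
$A_{max}$ 87 ± 54 spikes/s, 5–10 trials per unit, onset delay 31 ± 12 ms).
Two structural constraints reflect that population rather than the marginal
moments alone: $(\tau_e, \tau_i)$ pairs are resampled until
$\tau_e < \tau_i$ (excitatory time scales are much faster than inhibitory
ones in the fitted units, with a mean ratio near 0.4), and the driven
sustained rate is drawn as a fraction $0.75 \pm 0.08$ (truncated to
$[0.4, 0.92]$) of the unit's $A_{max}$, reproducing the pronounced onset
transients — peaks several times the sustained level — that well-driven
units show. Spontaneous pre-change rates default to 10 ± 5 spikes/s.

`make_change_experiment()` emulates the four-condition speed-change
paradigm (attend-in/attend-out × speed-up/speed-down): sustained rates come
from the tuning curve at the base and changed speed (factors of about 2 and
0.5), attended conditions are generated with the gain applied to the
circuit, the change time is jittered uniformly within 0.66–5.5 s per trial,
and output spikes are re-aligned to the change with the population response
delay at 55 ms.

Spikes are inhomogeneous Poisson, generated by thinning against the maximum
rate (exact at any rate resolution), with counter-based per-trial
substreams so any subset of trials is reproducible independently of
generation order. What the generator deliberately does **not** emulate:
refractoriness, bursting, trial-to-trial gain correlations, unit-to-unit
noise correlations, or adaptation of the tuning curve. Passing tests
therefore demonstrate correctness of the algorithms under Poisson
statistics, not robustness to every property of real spike trains — though
the mean–variance equality that the Poisson model assumes is the same
dispersion property observed in the recorded counts this paradigm emulates.

## Change-transient statistics

Analyses of the four-condition data, aligned to the change at $t=0$ with the
transient beginning at the response delay $t_{change} = 55$ ms:

* `excess_cumulative_count()`: cumulative post-change spike count (summed
  over trials) minus the count expected from the pre-change rate
  ($F^{pre}$, summed over trials, estimated over $[-400\,\mathrm{ms},
  t_{change}]$). Because integration attenuates rather than amplifies
  noise, the excess count is the slope proxy of choice and needs no
  smoothing.
* `excess_difference_test()`: the attended-minus-unattended excess
  difference against the envelope $\pm z\sqrt{(F_A^{pre}+F_N^{pre})\,
  (t-t_{change})}$ with $z = 2.32$ (one-sided $p<0.01$). The radical
  follows from the Poisson count variance — without it the threshold is
  dimensionally inconsistent — and a literal no-radical variant is kept
  behind the `literal_threshold` flag. The same reasoning gives the
  interval test's threshold $\sqrt{\sum \mathrm{var}}$ in
  `interval_count_change()` (25 ms intervals between 50 and 200 ms).
* `poisson_rate_change_test()`: exact one-tailed Poisson test of the count
  in a post-change window (default 140–160 ms) against the baseline
  expectation, using the real-valued expected count rather than a rounded
  one — the exact tail is well defined for non-integer means and rounding
  would only coarsen it.
* `time_advantage()`: first crossing times of rate-change thresholds in
  Gaussian-smoothed PSTHs (RMS 10 ms, kernel truncated at ±4 RMS and
  renormalized), attended minus non-attended.
* `attention_index()`, `mean_variance_by_bin()`,
  `accel_decel_regression()` (leave-one-out SDs), and
  `paired_rank_test()` complete the set. Units missing one of a pair of
  conditions are dropped from paired analyses.

The interval-test baseline window ends at the same 55 ms delay used
everywhere else; the two delay symbols that sometimes appear in descriptions
of this analysis are not separately defined, so the package uses one value.

## Study conditions used by the automated checks

The acceptance script and the acceptance-style tests regenerate everything
they measure. Problem sizes, chosen to make every check sharp at a scale a
single CPU handles in about a minute: 50 random parameter sets for the
oracle-equivalence bound; 91 × 91 activation grids for the closed-form
attention surfaces and 19 × 19 grids for the numeric peak surface; 1000
null repetitions for each false-positive calibration (20 trials at
60 spikes/s, and 15 trials at 50 spikes/s, evaluated 25 ms after the
response delay); 50 units × 10 trials for parameter recovery; and, for the
end-to-end attention check, a four-condition experiment at $\alpha = 1.2$
with a 1.5-octave-wide tuning curve ($A^{pref} = 60$ spikes/s at
8 deg/s, $A_{max} = 1.4\,A^{pref}$), base speed 2 deg/s doubling or halving
— an operating point on the tuning flank with low pre-change activation and
a strong transient, where the modulation the model predicts is several
noise standard deviations at 4000 trials per condition (the pooled-trial
analogue of averaging a few dozen recorded sites). At operating points near
the tuning peak the predicted modulation, while present, is small relative
to Poisson noise at any realistic trial count; the flank operating point is
where change detection is informative, for the model as for the neurons.

## Known limitations

* The time-constant recovery limits described under *Identifiability*.
* The reduced form assumes zero thresholds and suprathreshold input;
  threshold effects are only available through the explicit circuit.
* Attention enters as a stationary input gain; dynamic or feature-tuned
  gain fields are out of scope, as are recurrent (ring-network)
  implementations of the divisive pool and conductance-based dynamics.
* The grid search is deliberately exhaustive-plus-refinement for
  determinism; it is not a general-purpose optimizer and inherits the
  ridge behavior above.
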