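---
title: "Pupil dilation, depressive symptoms, and correlation under measurement error"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pupil dilation, depressive symptoms, and correlation under measurement error}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

During reward anticipation, healthy participants sustain elevated arousal
between a reward-predicting cue and the opportunity to respond; the pupil
dilates over that interval, driven largely by noradrenergic tone. In
depression, part of the clinical picture — anhedonia, loss of energy — is
hypothesized to reflect a failure to upregulate this anticipatory arousal.
The readout `pupilcorr` works with is deliberately simple: the *rate* of
pupil dilation (the mean first derivative of the z-scored pupil trace, in
z-units per second) over a 6-s anticipation window, contrasted between a
monetary-reward cue and a control cue, and correlated with the number of
depressive symptoms a participant reports for the preceding two weeks.

Both sides of that correlation are noisy instruments. The pupil contrast is
an average over ten trials per condition with substantial trial-to-trial
variability; the symptom count comes from a structured clinical interview
with imperfect test–retest reliability. A raw Pearson correlation between
the two is therefore attenuated, and its uncertainty understated. The core
of this package is a Bayesian bivariate-Gaussian latent-variable model that
treats the observed scores as noisy measurements of latent true scores and
estimates the correlation between the *latent* variables.

## The model

For participant $i$, let $x_i$ be the differential dilation score and
$y_i$ the symptom count. The model is

$$
(\xi_i, \eta_i) \sim \mathcal{N}_2\!\left(
  \begin{pmatrix}\mu_x\\ \mu_y\end{pmatrix},
  \begin{pmatrix}\sigma_x^2 & \rho\,\sigma_x\sigma_y\\
                 \rho\,\sigma_x\sigma_y & \sigma_y^2\end{pmatrix}\right),
\qquad
x_i \sim \mathcal{N}(\xi_i, s_x^2), \quad y_i \sim \mathcal{N}(\eta_i, s_y^2),
$$

with fixed measurement SDs $s_x = \mathrm{SD}(x)\sqrt{1 - R_x}$ and
$s_y = \mathrm{SD}(y)\sqrt{1 - R_y}$, where $R_x$ is the split-half
reliability of the pupil score (plug-in 0.87, with 0.70 as a conservative
alternative) and $R_y$ the published test–retest reliability of the
symptom interview (0.78). All five parameters carry uniform priors:
$\mu_x \sim U(-2, 2)$, $\sigma_x \sim U(0, 2)$, $\mu_y \sim U(0, 20)$,
$\sigma_y \sim U(0, 10)$, $\rho \sim U(-1, 1)$. With $s_x = s_y = 0$ the
model collapses to the standard Bayesian Pearson correlation under the same
priors; `pupilcorr` treats that as a degenerate special case, not an error.

Evidence for a negative correlation is summarized by the directional Bayes
factor computed directly from posterior draws:
$\mathrm{BF}_{(-)} = \#\{\rho^{(s)} < 0\}/\#\{\rho^{(s)} > 0\}$, which under
the symmetric uniform prior is the posterior-odds form of the one-sided
Bayes factor. When no draw falls on the disfavoured side, the total draw
count is reported and flagged as a lower bound. Two further "default"
Bayes factors support the extension analyses: the two-sided Pearson BF
under a stretched-beta prior on $\rho$ (width `kappa`, default 1, i.e.
uniform), and the JZS two-sample BF (Cauchy prior with scale
$\sqrt{2}/2$ on the standardized effect), both computed by numerical
integration of their exact likelihoods. Evidence bands follow the usual
convention (BF 3–10 moderate, 10–30 strong, >100 extreme).

A note on the item screen: the width of the stretched-beta prior used by
point-and-click software has varied across versions, and published item
tables are not always reproducible from their printed $(r, n)$ pairs under
any single width. `kappa` is therefore an explicit argument; the package's
correctness claims are against quadrature oracles, not against any printed
Bayes-factor table.

### Posterior computation

The per-participant latents $(\xi_i, \eta_i)$ are integrated out
analytically — marginally the observed pairs are bivariate normal with
covariance $\Sigma + \mathrm{diag}(s_x^2, s_y^2)$ — leaving a
five-parameter posterior. Sampling works on logit-transformed coordinates
(each parameter mapped from its uniform support to the real line, with the
Jacobian included), where the posterior is close to Gaussian. Each chain
runs a short component-wise random-walk warm-up, then a joint random walk
whose proposal covariance adapts to the warm-up history; the sampling phase
uses a frozen 50/50 mixture of that random walk and an independence
proposal — a multivariate $t_4$ centred on a deterministic Laplace
approximation (mode and Hessian of the transformed posterior), slightly
overdispersed. The independence component yields near-iid draws when the
Gaussian approximation is good; the random-walk component guarantees
correctness when it is not. Defaults are 4 chains, 1,000 warm-up and 5,000
kept draws each. Convergence is policed, not warned about: any parameter
with split-chain $\hat R$ above 1.01 raises an error carrying the full
diagnostic vector ($\hat R$ and effective sample sizes per parameter).

The test suite validates this machinery against three independent routes:
a brute-force two-pass grid integration of the marginalized posterior, an
importance-free JAGS fit of the non-marginalized latent model, and (for the
zero-noise case) iid sampling from the grid's $\rho$ marginal.

## Preprocessing and quality control

The cleaning chain is fixed: blink interpolation, then smoothing, then the
session z-transform, with QC computed from the pre-smoothing flags.

* **Blink interpolation.** Any contiguous run of invalid samples counts as
  a blink. The pupil trace is replaced by the straight line between the
  last valid sample at least 100 ms before the run and the first valid
  sample at least 100 ms after it; all replaced samples are marked
  `interpolated`. Runs whose padding reaches the session edge stay missing.
* **Smoothing.** A 200 ms sliding mean (100 ms each side), truncated at the
  series edges, missing samples excluded from the mean. Note that smoothing
  blurs the analysis-window endpoints into the neighbouring flat and decay
  segments, shrinking measured window slopes by a few percent; the factor
  is common to all conditions and participants and cancels from every
  correlation-based readout.
* **z-transform.** Centre and scale over all usable samples of the session
  (sample SD, $n-1$), so dilation is in z-units per second.
* **Missingness rules.** A trial is dropped when *strictly more than* 50%
  of its 6-s anticipation window is missing; a session when strictly more
  than 15% of all its samples are. Interpolated samples count as missing
  for both fractions by default.
* **Gaze window.** Per participant, the centre is the median gaze over all
  anticipation-window samples; the rectangle half-widths are shared across
  the cohort: 3.3 times the cohort mean of the per-participant gaze SDs.
  Trials with more than one second of (valid-sample) gaze outside the
  rectangle are dropped.

Three readings of the conventional rules are genuinely ambiguous, so they are
switches on `preprocess_params()` with documented defaults: whether
interpolated samples count as missing (default yes — interpolation recovers
plausible values, not information); whether the trial missingness fraction
is computed on the anticipation window or the whole trial (default
anticipation window — it is the analysis window); and whether out-of-window
gaze time is cumulative or longest-consecutive (default cumulative — the
stricter and simpler reading). The derivative itself uses per-sample first
differences of the smoothed, z-scored trace; a filtered derivative would be
a defensible alternative, and the telescoping identity
(mean derivative = endpoint difference over elapsed time) is asserted in
the tests to make the choice transparent.

## The synthetic-study generator

No public dataset accompanies this design, so `simulate_study()` is the
canonical input source and is itself first-class, tested code. It emulates:

* a continuous 250 Hz recording per participant covering 30 trials
  (10 per condition) in a balanced pseudo-random order with no run of three
  equal conditions; fixation jitter uniform on 2–4 s (the task description
  does not state it), a 6-s cue window, a 0.5-s flash/response gap, 1.5-s
  feedback, and a 1-s inter-trial interval — the latter three are exposed
  as configuration because only the cue and feedback durations are fixed by
  the design;
* a pupil trace built from a tonic baseline with per-trial offsets
  (constant within a trial, so planted within-window slopes stay exact),
  a linear anticipation ramp whose slope is
  `base_slope[condition] + trait_gain[condition] * trait + jitter`,
  a return to baseline during the flash gap, an independent small
  consumption-phase ramp, and white sensor noise;
* blinks as a Poisson process of invalid runs (100–400 ms), planted long
  missing runs (55% of the window) for the missingness rule, and planted
  gaze excursions of configurable length for the gaze rule — each recorded
  in a ground-truth sidecar so QC tests can demand exact set equality;
* clinical records: a per-participant arousal trait (standard normal), a
  latent symptom burden correlated with the trait at `true_rho`, an
  observed 0–20 symptom count, and 21 BDI-II items (0–3).

Two calibrations make the generator's knobs quantitative rather than
decorative. First, the trial-slope jitter is derived from
`reliability_target` by the Spearman–Brown relation for 5-trial halves, so
the split-half reliability of the differential score converges to the
target; blink interpolation and QC losses in the full pipeline shave a few
hundredths off the realized value, which stays within the generator's
stated ±0.05 band. Second, symptom counts come from a Gaussian copula:
the count is a monotone discretization of
$\beta\,\mathrm{burden} + \sqrt{1-\beta^2}\,\varepsilon$, where the margin
places $1-\mathrm{prop\_depressed}$ of its mass at zero (those rows are the
healthy controls, who by construction report no symptoms) and geometrically
decaying mass on 1–20. Discretizing a Gaussian attenuates any correlation
by a computable factor $\lambda$ (about 0.89 for the default margin), so
$\beta$ is set to $\sqrt{R_y}/\lambda$: the observed count then behaves as
a reliability-$R_y$ measurement of the burden, which is precisely what the
inference stage assumes. A margin too coarse to carry the requested
reliability is reported, not silently accepted. BDI items load on the
burden (0.45) and — for items 4, 15 and 21, the anhedonia/energy items the
field's item analyses single out — additionally on the negative trait
(0.30), so item screens on synthetic cohorts reproduce the qualitative
pattern: trait-loaded items cross BF 3, burden-only items mostly do not,
though with 17 of them an occasional false bold is statistically inevitable.

What the generator does **not** emulate, deliberately: the pupillary light
reflex, saccade- or foreshortening artifacts, luminance effects, realistic
blink-edge dynamics, or any fMRI signal. Passing tests on synthetic data
therefore demonstrate that the *pipeline* is correct and calibrated — that
it recovers planted correlations without bias and rejects exactly the
trials its rules say it should — not that real eye-tracking data meet the
generator's assumptions.

## Numerical choices and degenerate inputs

* Strict inequalities at every QC threshold (50%, 15%, 1 s), matching the
  "more than"/"exceeded" phrasing; fractions are computed as sample-count
  ratios so threshold cases are exact, not float-dependent.
* Sample SD ($n-1$) throughout.
* Window membership is half-open $[\mathrm{on}, \mathrm{off})$ on the
  sample grid, giving exactly 1,500 samples per 6-s window at 250 Hz.
* Zero-variance sessions, all-invalid series, fully-failed feedback cells,
  constant BDI items and $|r| = 1$ inputs each have a defined behaviour
  (error, `NA` cell, not-computable flag, or capped Bayes factor with a
  flag) asserted in the tests.
* The latent-model location priors widen, with a warning, when data fall
  outside them; the alternative — silently truncating the likelihood — can
  bias $\rho$.

## Problem sizes in the test suite

The suite runs the grid-oracle comparison at $n = 10$ pairs (two-pass grid,
$25^4 \times 121$ fine resolution), parameter recovery over 100 simulated
studies of 70 participants at reduced MCMC settings (4 chains × 1,000 kept
draws), 20 end-to-end sign-recovery runs, and 8 specificity replicates at
$n = 136$. These sizes were chosen so the full suite exercises every claim
at meaningful precision while remaining comfortable to run as a routine
check; reduced-chain fits occasionally trip the 1.01 $\hat R$ guard by
estimation noise, and replicate loops retry such fits once with a longer
run rather than loosening the guard.

## Known limitations

* Symptom counts are discrete and zero-inflated but enter the Gaussian
  latent model as continuous scores, as the analysis convention dictates;
  the recovery tests show the induced bias at the study's conditions is
  well under the tolerances, but heavier zero-inflation (small
  `prop_depressed`) would stress the approximation.
* The split-half coefficient (0.87) is plugged in uncorrected. Spearman–
  Brown would assign the 10-trial score a slightly higher reliability, so
  the plug-in over-corrects by a few percent; this is the convention the
  analysis replicates, and the recovery tests absorb it.
* One uncertainty value per instrument: the data structures carry
  per-observation SDs, so heteroscedastic extensions are free, but nothing
  in the pipeline estimates them.
* The directional Bayes factor from count ratios cannot exceed the draw
  count; genuinely extreme evidence saturates at a lower bound, which the
  reporting flags rather than extrapolates.
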