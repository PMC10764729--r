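# pupilcorr

Pupillometry analysis of reward-anticipatory arousal and depressive
symptoms: trial-structured preprocessing and quality control for 250 Hz
pupil/gaze recordings, derivative-based dilation features, and a Bayesian
latent-correlation model that propagates measurement uncertainty into the
dilation–symptom association.

## Who this is for

Researchers analysing reward-anticipation eye-tracking tasks in clinical
samples — specifically the design in which each trial presents a fixation
cross, a 6-s condition cue (monetary reward, verbal-feedback neutral, or
no-response control), a light flash requiring a speeded response, and 1.5 s
of feedback — and relating the pupil response to symptom scales such as an
M-CIDI symptom count or BDI-II items. Because raw data for this design are
typically not deposited, the package ships a fully tested synthetic-study
generator with known ground truth; real data enter through plain TSV
contracts (`samples.tsv`, `events.tsv`, `clinical.tsv`) at any stage.

## The statistical core

The pupil readout is **dilation**: the mean first derivative of the
z-scored pupil trace over the 6-s anticipation window (z/s), averaged over
surviving trials, contrasted reward-minus-control per participant. Both the
pupil contrast `x` and the symptom count `y` are noisy measurements, so the
correlation is estimated with a bivariate Gaussian latent-variable model

    (xi_i, eta_i) ~ N2( (mu_x, mu_y), Sigma(sigma_x, sigma_y, rho) )
    x_i ~ N(xi_i, s_x^2),   y_i ~ N(eta_i, s_y^2)
    s_x = SD(x) * sqrt(1 - R_pupil),   s_y = SD(y) * sqrt(1 - R_symptoms)

with uniform priors mu_x ~ U(-2, 2), sigma_x ~ U(0, 2), mu_y ~ U(0, 20),
sigma_y ~ U(0, 10), rho ~ U(-1, 1), with R_pupil the split-half
reliability of the dilation score (plug-in 0.87; 0.70 as a conservative
check) and R_symptoms = 0.78. The latents are marginalized analytically
and the five-parameter posterior is sampled by an adaptive MCMC scheme
(logit-transformed coordinates; adaptive random walk mixed with a
Laplace-matched independence proposal; split-R-hat > 1.01 is an error, not
a warning). Evidence is reported as the directional Bayes factor
`BF(-) = #(rho < 0) / #(rho > 0)` over posterior draws, alongside default
Bayes factors (stretched-beta Pearson BF10 and JZS two-sample BF10,
computed by numerical integration) for item screens, phase-specificity
checks and group comparisons.

Preprocessing implements a fixed cleaning chain: linear
blink interpolation with 100 ms padding, 200 ms sliding-mean smoothing,
session z-transform; trials are dropped above 50% missing data in the
anticipation window, sessions above 15% overall, and trials with more than
1 s of gaze outside a rectangular window of 3.3 cohort-mean SDs around each
participant's median gaze.

## Worked example

```r
library(pupilcorr)

cfg   <- sim_config(n_participants = 24, true_rho = -0.5, seed = 7)
study <- simulate_study(cfg)
study
#> <pupil_study>
#>   24 participants, 30 trials each, 250 Hz
#>   groups: 11 MDD / 13 HC; true latent rho -0.50

clean <- preprocess_study(study$samples, study$events)
clean
#> <pupil_clean>
#>   24 sessions (0 dropped), 720 trials (34 dropped: 16 missing, 18 gaze)

features <- aggregate_features(clean, study$events)
clinical <- derive_clinical(study$clinical)
fit <- correlate_dilation_symptoms(features, clinical, subset = "all",
                                   chains = 4, iter = 2500, warmup = 600,
                                   seed = 1)
fit
#> <latent_corr> bivariate Gaussian correlation with measurement error
#>   n = 24, 4 chains x 2500 draws (warmup 600)
#>   rho: mean -0.774, median -0.796, 95% CI [-0.964, -0.435]
#>   BF(-) = 3332
#>   max R-hat 1.0045, ESS(rho) 1747
attr(fit, "analysis")$raw_pearson_r
#> [1] -0.687
```

Reading the output: QC dropped 34 of 720 trials (16 for missing data, 18
for gaze excursions — the generator planted both artifact types). The raw
Pearson correlation between the differential dilation and the symptom
count is -0.687; the latent model, crediting both instruments with their
known unreliability, estimates the true correlation at -0.77 with a 95%
credible interval excluding zero and 3,332 posterior draws below zero for
every draw above — strong directional evidence, at this small n helped by
the deliberately strong planted correlation of -0.5.

The numbered drivers under `analysis/` run the same stages as a file-based
workflow (`01_simulate.R` ... `06_report.R`), writing each stage's TSV
outputs and a run manifest under `results/run/`:

```sh
Rscript analysis/01_simulate.R results/run 1
Rscript analysis/02_preprocess.R results/run
Rscript analysis/03_features.R results/run
Rscript analysis/04_correlate.R results/run
Rscript analysis/05_items.R results/run
Rscript analysis/06_report.R results/run
```

## Vignette

`vignettes/measurement-error-correlation.Rmd` documents the model and its
assumptions, every tunable threshold with its default and rationale, the
synthetic-data calibrations (Spearman–Brown trial noise, Gaussian-copula
symptom counts with discretization-attenuation correction), numerical
choices, and known limitations.
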