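Package: pupilcorr
Title: Pupillometry Preprocessing and Bayesian Latent Correlation for
    Reward-Anticipation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing trial-structured pupillometry from reward
    anticipation tasks in depression research. Simulates complete studies
    (250 Hz pupil/gaze streams, balanced three-condition event tables,
    clinical symptom scales) with a known latent correlation structure;
    implements a blink-interpolation, sliding-mean smoothing, session
    z-transform and missingness/gaze quality-control chain; extracts
    derivative-based pupil dilation features per task phase; and estimates
    the dilation-symptom correlation with a bivariate Gaussian latent-variable
    model that propagates SD*sqrt(1-reliability) measurement uncertainty,
    reporting directional Bayes factors from posterior mass ratios alongside
    default Bayes factors for Pearson correlations and two-sample
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rjags,
    jsonlite,
    withr
Config/testthat/edition: 3
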