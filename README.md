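# cvdstair

Adaptive confusion-line staircase engine for pediatric colour-vision
screening.

Congenital colour-vision deficiency (CVD) affects about 8% of boys, and
most children are never screened: plate tests need shape knowledge and a
trained administrator. A gamified tablet test sidesteps both — on each
trial a child taps one of eleven spots: three coloured targets lying on
the protan, deutan and tritan cone-confusion lines plus eight achromatic
distractors, with target saturations driven by adaptive staircases.
`cvdstair` is the computational core of such a test as an R package, for
vision scientists and test developers who want to study, extend or
re-validate the method without the app around it:

* **Colorimetry** — MacLeod-Boynton chromaticities (`l = L/(L+M)`,
  `s = S/(L+M)`), device RGB↔LMS calibration profiles with gamma,
  confusion-line target geometry, gamut limits, and audits of the residual
  cues a dichromat could exploit (`dichromat_luminance_signal()`,
  `audit_calibration_error()`).
* **Stimulus engine** — 11-item trials with uniform ±20% luminance noise
  and binary ±16% tritan noise masking those residual cues
  (`make_trial()`).
* **Staircase controller** — three interleaved staircases (×0.5 after a
  target tap, ×1.5 after a distractor tap, capped at saturation 0.9), two
  sets of 35 update events per axis, a 40-trial validity floor
  (`run_session()`, `apply_tap()`, `pool_observations()`).
* **Model-free psychometric fitting** — local-linear kernel logistic
  regression on log10 saturation (Gaussian kernel, bandwidth 0.70) with
  thresholds read off at performance level 0.21 (`fit_modelfree()`,
  `threshold_at()`, `optimize_fit_params()`).
* **Classifier** — the threshold ratio
  `r = min(t_tritan/t_protan, t_tritan/t_deutan)`, invariant under common
  rescaling of all three thresholds (non-visual factors cancel), with CVD
  called at `r < 0.59` (`threshold_ratio()`, `classify_ratio()`,
  `derive_criterion()`, `confusion_metrics()`).
* **Simulated observers** — parametric normal, anomalous-trichromat and
  dichromat observers with per-axis Weibull detection and a common lapse
  rate, plus cohort simulation for end-to-end validation with known
  ground truth (`observer_model()`, `simulate_cohort()`,
  `evaluate_cohort()`).

## Worked example

Simulate a mildly deuteranomalous child, run a complete session, fit the
three psychometric functions and classify:

```r
library(cvdstair)

obs <- observer_model("deuteranomalous",
                      sigma = c(protan = 0.12, deutan = 0.45, tritan = 0.05),
                      lapse = 0.04)
session <- run_session(obs, seed = 7)
session
#> Staircase session: 129 trials, set 2, complete
#>   saturation: protan=0.0834, deutan=0.2502, tritan=0.0278
#>   updates this set: protan=35, deutan=35, tritan=35

th <- session_thresholds(session)
round(th$thresholds, 4)
#> protan deutan tritan
#> 0.0307 0.1806 0.0156

r <- threshold_ratio(th$thresholds)
sprintf("ratio = %.3f -> %s", r, classify_ratio(r))
#> "ratio = 0.086 -> CVD"
```

The deutan threshold (0.18 of the maximum in-gamut saturation) sits an
order of magnitude above the tritan threshold (0.016), so the minimum
tritan:red-green ratio (0.086) falls far below the 0.59 criterion: the
observer's red-green deficit is detected even though its overall
performance (and lapse rate) would also have depressed raw thresholds for
a fully attentive normal observer.

A thin command-line front end over the same functions ships in
`inst/cli/cvdstair` (subcommands `simulate-session`, `fit`, `classify`,
`simulate-cohort`, `validate`, `derive-criterion`, `optimize-params`,
`audit-calibration`).

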