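---
title: "A confusion-line staircase engine for pediatric colour-vision screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A confusion-line staircase engine for pediatric colour-vision screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cvdstair is the computational core of a gamified tablet test for congenital
colour-vision deficiency (CVD) in young children, rebuilt as a desk-scale
engine: stimulus colorimetry, the adaptive staircase session controller,
model-free psychometric threshold estimation, and a threshold-ratio
classifier, all validated end-to-end against simulated observers. This
vignette explains the science behind each stage, the tunable parameters,
and the design decisions taken where the design was genuinely open.

## The task and its geometry

Congenital red-green CVD affects roughly 8% of boys. The test shows eleven
tappable spots per trial: one coloured target on each of the protan, deutan
and tritan cone-confusion lines, and eight achromatic distractors. A child
with normal colour vision can find the coloured targets; a child with a
red-green deficiency cannot distinguish low-saturation protan/deutan
targets from the grey distractors, and taps distractors instead.

All chromaticity arithmetic happens in the MacLeod-Boynton diagram, the
cone-based chromaticity plane with abscissa $l = L/(L+M)$ and ordinate
$s = S/(L+M)$ at constant luminance $L+M$:

* protan confusion lines converge on the copunctal point $(1, 0)$ (only L
  varies along them),
* deutan lines converge on the origin (only M varies),
* tritan lines are vertical (only S varies, so $l$ is constant).

A **device profile** carries everything needed to render these stimuli on a
calibrated display: an invertible linear-RGB-to-LMS matrix, per-channel
gamma exponents, the background white point, and the chromaticity of the
maximum in-gamut excursion ("saturation 1.0") on each axis. The reference
endpoints are protan $(l, s) = (0.6160, 0.0186)$, deutan
$(0.6160, 0.0157)$ and tritan $(0.6553, 0.0033)$. Target saturation is
always expressed as a fraction of that per-axis maximum, and
`target_chromaticity()` interpolates affinely between white and endpoint.

**White point.** The white's $l$ is fixed by the tritan endpoint (tritan
lines are vertical), and its $s$ is derived at profile load as the
intersection of the two red-green confusion lines through the stored
endpoints and their copunctal points; an explicitly supplied $s$ wins. For
the reference endpoints the two lines agree to within $10^{-5}$ at
$s \approx 0.0167$, a useful internal consistency check of the printed
geometry. The default profile's RGB-to-LMS matrix is synthetic — a
row-normalised Hunt-Pointer-Estevez-style transform rescaled so equal-RGB
grey maps exactly onto that white — because real per-device matrices are
measurement results, not constants; every computation that matters
downstream depends only on the chromaticity geometry.

## Why the stimuli carry masking noise

A dichromat's luminance channel is driven by the single remaining
red-green cone class (M for protanopes, L for deuteranopes), so a
nominally isoluminant red-green target still produces a luminance
increment or decrement for them. With the reference geometry the largest
such cue, at the top tested saturation 0.9, is

$$\frac{0.9\,(0.6553 - 0.6160)}{1 - 0.6553} \approx 0.103,$$

about 10% of the background luminance (`max_dichromat_luminance_cue()`).
To mask it, every item's luminance is drawn uniformly within ±20% of the
mean. Similarly, individual differences in cone fundamentals and residual
calibration error can leak an S-cone signal from the red-green targets of
up to about 8% of the background $s$; binary tritan noise of ±16% of
background $s$ (an equiprobable ±1 sign per item) buries it.
`audit_calibration_error()` quantifies both residual cues for a stimulus
rendered under one calibration and displayed under another.

One geometric consequence is worth knowing: the tritan endpoint *is* the
gamut edge, so a tritan target near saturation 0.9 cannot take the
negative tritan-noise offset — the required $s$ is unrenderable. Per the
out-of-gamut policy (redraw up to 100 times, then clip), such items end up
with predominantly positive offsets. This affects only the first few
trials of a session, before the tritan staircase descends.

## The staircase session

Each axis runs its own staircase starting at saturation 0.9 (the greatest
tested level). Tapping a target halves that axis's saturation; tapping a
distractor multiplies *every active* axis's saturation by 1.5, capped at
0.9. Either event is one *update* for the staircase(s) concerned. A
staircase that accumulates 35 updates in the current set deactivates and
its target is replaced by a distractor; when all three reach 35 the second
set begins, and the session completes at the end of set 2. Sessions must
reach 40 trials to count as valid — this floor is enforced independently
of completion.

Two readings of the counting rule were possible; we count *update events*
(own-target tap, or any distractor tap while active), because it is the
only reading under which per-axis counts can differ and the replacement
rule ("once a staircase has reached 35 trials, the target type is no
longer shown") becomes operative. Between sets we carry saturations over
and reset counts — restarting at 0.9 would waste the second set's trials
re-descending. The multiplicative asymmetry (×0.5 down, ×1.5 up) makes the
staircase equilibrate where the success probability satisfies
$p\log 0.5 + (1-p)\log 1.5 = 0$, i.e. $p = \log 1.5/\log 3 \approx 0.37$,
conveniently above the 0.21 threshold level so the fitted curve is
anchored from above.

**Pooling.** For fitting, each trial on which an axis was updated
contributes one Bernoulli observation at the presented saturation: success
if its own target was tapped, failure if a distractor was tapped; trials
resolved by tapping a *different* axis's target contribute nothing to this
axis. Both sets are pooled, giving exactly 70 observations per axis in a
complete session. Note what this conditioning means: the estimated curve
is $P(\text{own tap} \mid \text{own tap or distractor tap})$, which is the
quantity the simulator oracles in the test suite reproduce in closed form.

## Model-free threshold estimation

Psychometric functions are estimated without a parametric shape by
local-linear kernel logistic regression on the $\log_{10}$-saturation
axis: at each of 201 grid points spanning [lowest tested level, 0.9], a
degree-1 polynomial on the logit scale is fitted by maximising the
Gaussian-kernel-weighted binomial log-likelihood (a small damped
Fisher-scoring solver), and the fitted probability is the inverse logit of
the local intercept.

* **Bandwidth** defaults to 0.70 in $\log_{10}$-saturation units. The
  staircase levels are geometric (×0.5 spacing is 0.301 log units), so
  0.70 smooths over roughly two to three adjacent levels; on the raw
  saturation scale the same number would span the entire range.
* **Link**: logit. The fitted curve is monotone-equivalent under any
  sensible link for the purpose of threshold crossing.
* **Degenerate neighbourhoods** (all successes or all failures) are
  handled by clamping fitted probabilities to $[10^{-6}, 1-10^{-6}]$; the
  damped Newton steps simply walk the local intercept to the cap.
* A useful exact property anchors the machinery: as the bandwidth grows,
  the fit converges to the single global logistic regression, which the
  test suite verifies against `stats::glm()` to $10^{-3}$.

The **threshold** is read off where the fitted curve crosses the
performance level (default 0.21, well above the 1/11 ≈ 0.09 chance rate,
so no guessing-rate correction is built into the link) from below — the
*largest* such crossing, linearly interpolated between grid points. A
curve that never reaches the level returns the 0.9 ceiling flagged
`unresolved`; a curve already above the level at the grid minimum with no
later upward crossing returns the grid minimum flagged `floor`. An axis
whose 70 observations all sit at a single level (a dichromat pinned at the
ceiling for a whole session) cannot be fitted at all and is resolved
directly by its observed success rate.

`optimize_fit_params()` reproduces the parameter search that selected
(bandwidth, level): over a grid of candidate pairs it maximises the
separation margin between the highest CVD ratio and the lowest control
ratio, breaking ties toward the smaller bandwidth and lower level. The
default grids are bandwidth 0.10–2.00 by 0.05 and level 0.05–0.50 by 0.01.

## The threshold-ratio classifier

Raw thresholds confound colour vision with attention, motivation and
engagement — all of which depress performance on the three axes together.
The classifier therefore uses
$r = \min(t_{\text{tritan}}/t_{\text{protan}},\;
t_{\text{tritan}}/t_{\text{deutan}})$, which is exactly invariant under
any common rescaling of the three thresholds. Congenital tritan deficits
are rare enough that an elevated tritan threshold cancelling a red-green
deficit is not a practical concern. Ceiling-flagged thresholds enter the
ratio at 0.9, which keeps ratios finite and still leaves severe CVD far
below criterion (a normal tritan threshold of ≤0.35 against a 0.9 ceiling
gives $r \le 0.39$).

The criterion ratio (default 0.59) is derived from a discovery cohort as
the midpoint between the largest CVD ratio and the smallest control ratio;
$r < 0.59$ classifies as CVD, with the boundary itself counted normal.
Reference grouping by the plate test maps 0 errors to control, 1–2 to
inconclusive (excluded from accuracy metrics but reported), and ≥3 to CVD.
`power_bootstrap()` is a best-effort reconstruction of a design-stage
power computation — binomial draws of the estimated rate, with power the
probability of landing within a stated half-range of the truth — and is
documented as an interpretation, not a reproduction of the original
procedure.

## The simulated observer

The synthetic-data generator exists so the full pipeline can be exercised
with known ground truth. An observer detects each active target
independently with probability $1 - \exp\!\big(-(s/\sigma_a)^\beta\big)$
(Weibull-style, slope $\beta = 2$ by default; $\sigma_a = \infty$ encodes
a dead axis), taps one detected target uniformly at random, and otherwise
taps uniformly among all 11 items; with probability `lapse` the tap is
uniform regardless of the stimulus. This is deliberately not a cone-noise
ideal observer: it is the smallest model with per-axis monotone
psychometric functions, a common non-visual lapse factor, and closed-form
tap probabilities for oracle tests (a blind observer taps each target at
exactly 1/11).

Cohorts draw one base sensitivity scale per observer, uniform in
[0.03, 0.08] saturation units, applied to all three axes, plus a common
lapse uniform in [0, 0.1] — so between-child variation is deliberately
non-visual, and axis asymmetries encode deficiency alone. CVD types follow
the deutan-dominant mix (50% deuteranomalous, 25% protanomalous, 15%
deuteranope, 10% protanope); anomalous trichromats multiply the affected
axis's scale by uniform [5, 20] and the neighbouring red-green axis by
[2, 6] (the two red-green lines are close in colour space); dichromats
have an infinite affected scale and a neighbour factor of [8, 30].

One population parameter is calibrated rather than assumed:
`tritan_sigma_factor` (default 1.2) multiplies every observer's tritan
scale, making a unit of tritan saturation somewhat harder to detect than a
unit of red-green saturation. With perfectly symmetric axes the pipeline's
control-group ratio distribution centres near 0.88, because the minimum of
two noisy ratios is biased below 1; the reference cohorts' control groups
centre at 1.08. The factor was set, once, so that the simulated pipeline
reproduces that printed location, and was not adjusted afterwards.

What the generator does **not** emulate: spectral shifts of anomalous cone
fundamentals (deficits are scale factors, not rendered colour changes),
plate-test images (reference error counts are emulated directly), age- or
time-dependent attention, and — importantly — the steepness of real
children's psychometric functions, for which no trial-level data are
available. Passing end-to-end tests therefore demonstrates the internal
consistency of the engine under a plausible response model, not clinical
accuracy on real children.

## Numerical choices

* Gamut checks use a tolerance of $10^{-9}$ on linear RGB; the in-gamut
  set along a confusion axis is an interval (linear RGB is affine in
  saturation), so `max_in_gamut_saturation()` bisects to $10^{-6}$ and is
  tested against a $10^{-5}$-step brute-force scan.
* The local-likelihood solver damps Newton steps to ±5 on the logit scale,
  ridges the 2×2 information matrix at $10^{-10}$ of its trace scale, and
  caps local intercepts at logit$(1 - 10^{-6})$.
* Threshold interpolation happens on the $\log_{10}$ grid; `ok`/`floor`/
  `unresolved` flags are propagated alongside numeric values.
* All randomness flows from named seeds: a session seeds one RNG stream;
  cohorts derive one child seed per participant from the cohort seed, so
  any cohort replays bit-identically.

## Validation scale and honest limits

The package's own validation (test suite and acceptance script) runs at
the reference cohort's scale: 37 simulated CVD observers and 117 simulated
normals, each a complete two-set session (≈125–250 trials), fitted at
bandwidth 0.70 and thresholded at level 0.21, classified at criterion
0.59. Threshold-recovery checks use 99 seeded sessions against closed-form
true thresholds of 0.05, 0.1 and 0.2.

Sensitivity is robustly 1.00: every simulated CVD type's true ratio is at
most ~0.26, several noise standard deviations below criterion. Specificity
is the honest weak point: with only 70 observations per axis the
threshold-ratio estimate carries a standard deviation of ≈0.18 log10 units
across a heterogeneous cohort, which places roughly 7–15% of simulated
normals below 0.59 — the measured specificity ranges over about 0.83–0.94
by seed, short of the 0.97 reported for real children. The model-free
estimator is not the culprit (a global parametric logistic fit on the same
sessions does no better than ≈0.13 log10 per axis); the gap traces to the
β = 2 observer slope, which is shallower than real children's psychometric
functions appear to be. We left β at its stated default rather than tune
it to the outcome; the discrepancy is documented rather than hidden.
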