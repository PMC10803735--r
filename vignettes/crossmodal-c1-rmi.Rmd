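---
title: "Methods: the C1 difference wave, Bayesian decisions, and the race model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the C1 difference wave, Bayesian decisions, and the race model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltaC1)
```

This vignette is the package's own account of its science: the model behind
each stage, the tunable parameters and why their defaults are what they are,
the numerical conventions, and the limits of what the synthetic-data tests
establish.

## 1. Why a difference wave

Stimuli in the upper and lower visual field drive opposite banks of the
calcarine sulcus, so the earliest cortical response (the C1 wave, roughly
50–100 ms after onset) projects to the scalp with opposite polarity for the
two fields.  Subtracting the upper-field ERP from the lower-field ERP,

$$\Delta C1(e) \;=\; \overline{v_{LVF}(e,t) - v_{UVF}(e,t)}\Big|_{t \in [50,100]\,\mathrm{ms}},$$

doubles the retinotopic component while cancelling *every* source that is
common to the two fields — in particular the auditory evoked potential of a
concurrent sound, which is identical whether the grating appeared above or
below fixation.  A difference between conditions (visual alone vs.
audiovisual) in this quantity therefore isolates a genuinely retinotopic,
stimulus-driven modulation of the earliest visual cortical response.  The
package computes it at the five posterior electrodes where the component is
largest (O1, O2, P3, P4, Pz).

## 2. The ERP pipeline and its conventions

Stage order (recorded in every output's provenance): common-average
re-reference → zero-phase band-pass → ocular rejection → motor rejection →
nasion–inion mirroring → baseline correction → standards-only averaging →
window mean.

* **Windows are endpoint-inclusive at sample resolution.**  "50–100 ms"
  means every sample with $50 \le t \le 100$; the same convention applies to
  the baseline (−100..0 ms) and artifact (−25..175 ms) windows.  This is
  stated once here to avoid off-by-one drift.
* **Filtering** (0.1–40 Hz default) is a zero-phase frequency-domain filter
  with raised-cosine transition bands (rising over [low/2, low], falling
  over [high, 1.25·high]).  No filter-design library is assumed; the
  transfer function is real, so zero phase holds by construction, and the
  DC bin is always zeroed.  Filtering is circular per epoch after
  demeaning; on 400 ms epochs the practical effect of the 0.1 Hz edge is DC
  removal, which the subsequent baseline step makes exact for the analysis
  window.
* **Ocular rejection** mimics a threshold rule of "k standard deviations of
  the maximal activities" of the frontopolar (blinks, k = 5) and periocular
  (saccades, k = 3) channels within −25..175 ms.  Because the rule is
  applied here to raw channels rather than to isolated ocular component
  traces, a pure k·SD cutoff would sit *below* the typical clean-trial
  maximum; the rule is therefore implemented as a centred robust outlier
  test on the per-trial maxima: reject when the maximum exceeds
  median + k · (1.4826·MAD), computed per participant.  With the shipped
  artifact amplitudes this removes injected blinks/saccades with
  sensitivity ≥ 0.95 while leaving clean trials essentially untouched.
* **Mirroring** swaps the fourteen left/right channel pairs of the
  32-channel montage (midline Fz, FCz, Cz, Pz untouched) for trials with
  left-side visual stimulation (left sound side for auditory-only trials),
  and flips the side labels, which preserves spatial congruence.  The map
  is an involution; collapsing the mirrored cells doubles the trial count
  per condition × field.
* **Averaging uses standards only.**  Target trials carry responses and
  oddball components; they are excluded from ERPs, as is any trial with a
  response within 500 ms.

## 3. The hierarchical model and the decision rule

All inference runs on the participant × condition × electrode table of
window means.  The model is the Gaussian linear mixed model

$$y_i = x_i^\top\beta + u_{p(i)} + \varepsilon_i,\qquad
u_p \sim \mathcal N(0,\tau^2),\quad \varepsilon_i \sim \mathcal N(0,\sigma^2),$$

with one random intercept per participant shared across the five electrodes
(the grouping structure is an interpretation — the source analyses report
"hierarchical models" without printing a formula — and is configurable in
the sense that the table can be subset per electrode).  Priors follow the
auto-scaling rule: $\beta_j \sim \mathcal N(0, (2.5\,\mathrm{SD}(y))^2)$
for non-intercept coefficients and $10\,\mathrm{SD}(y)$ for a global
intercept; $\sigma^2$ and $\tau^2$ carry weakly informative scaled
inverse-gamma priors (shape 1.5, scale 0.5·var(y)).  Because every full
conditional is conjugate, the package uses a blocked **Gibbs sampler**
(no Stan/HMC dependency): coefficients jointly, then random effects, then
variances.  The default budget is 40,000 retained draws with 20% warmup;
the test suite runs at 4,000 draws with correspondingly widened
tolerances.  Divergence counts do not exist for a Gibbs chain; effective
sample sizes and split-chain $\widehat R$ are reported instead, and
$\widehat R > 1.1$ triggers a warning rather than silent output.

**Savage–Dickey Bayes factors.**  For a coefficient with a zero-mean normal
prior, $BF_{10} = p_\text{prior}(0)/p_\text{posterior}(0)$.  The posterior
density at zero is not estimated from a histogram of draws but
**Rao–Blackwellized**: the sampler averages the full-conditional normal
density at zero over iterations, which is unbiased and far more stable in
the tails.  The directional factor reweights by the posterior mass above
zero (the prior is symmetric): $BF_{+0} = BF_{10}\cdot P(\theta>0\mid
y)/\tfrac12$.  The one-sided direction is "positive ΔC1" throughout,
reflecting the strong background expectation that the difference wave as
defined here is nonnegative at posterior electrodes.

**Decisions.**  A cell or contrast is *present*/*substantial* when its
Bayes factor exceeds 3 **and** the 95% highest-density interval (shortest
interval, not equal-tailed) falls **entirely outside** the region of
practical equivalence ±0.1·SD(y); *absent-evidence* when BF < 1/3 or the
HDI lies entirely inside the ROPE; *inconclusive* otherwise.  The ROPE
scale uses the SD of the model's whole response vector (pooled over
electrodes), a choice the sources leave open.  No multiplicity correction
is applied across the planned contrasts: the proper, non-flat hierarchical
priors shrink estimates toward zero, which is the stated rationale for
reporting uncorrected Bayes factors.

**Contrasts.**  The shipped set tests, per electrode: V − AV_i and
V − AV_c within the deprived group, and control − deprived per condition.
The model is reparameterized so that each contrast *is* a coefficient
(design = cell indicators × inverse of the completed contrast matrix),
giving each contrast exactly the 2.5·SD prior; the completion adds the
grand-mean row and an orthonormal basis of the remainder.  Cohen's *d* for
a contrast is its posterior mean divided by the posterior mean residual SD
— the sources report *d* without defining the denominator, so this
mixed-model convention is declared here once.

**Ordered-factor trend.**  Spatial specificity of the suppression is
tested by orthogonal-polynomial coding of the ordered conditions
(V, AV_i, AV_c) shared across electrodes; the linear component is reported
with its sign flipped into a "decline" coefficient (positive = decreasing
amplitude), so the expected effect is positive.

## 4. The behavioral arm

* **Redundancy gain**: min of the four single-target class mean RTs
  (unimodal auditory, unimodal visual, bimodal with only an auditory
  target, bimodal with only a visual target) minus the double-target mean
  RT; negative values are allowed and meaningful.
* **CDF estimation** uses linear interpolation between order statistics
  (quantile type 7 — the dominant convention in race-model tooling; the
  sources do not state one).  At each percentile of the 5th–30th grid
  (step 5) the three class quantiles are pooled into a common time point
  (their mean) and all three empirical CDFs are evaluated there, so the
  race bound is compared at identical times.  Ties average order-statistic
  ranks.  Unimodal targets carry no congruence label and enter both
  congruence-specific analyses.
* **Violation area** integrates $\max[F_{AV}-F_A-F_V,0]$ by composite
  trapezoid over the pooled RT support.  The grid step is 0.25 ms: the
  trapezoid error scales with $h^2$, and 0.25 ms keeps it below 10⁻³ ms
  even for smooth analytic CDFs spanning a second, which a 1 ms grid does
  not guarantee.  For the step-like empirical CDFs the step size is
  immaterial.  The area is computed over the full support, while the
  permutation test restricts itself to the explicit percentile grid — the
  two measures answer different questions (magnitude vs. localization).
* **Cluster permutation test**: one-sided one-sample t statistics across
  participants per grid point; clusters are runs of adjacent points with
  $t$ above the one-sided critical value at α = 0.05 with n−1 df (the
  sources fix only the cluster-level α; the forming threshold is
  configurable); cluster mass is the within-run sum of t.  The null
  distribution is the maximal cluster mass under sign flips of whole
  participant profiles — the group-level analogue of trial relabeling for
  one-sample designs — with the identity flip always included, so
  $p = (1+\#\{\text{perm} \ge \text{obs}\})/(n_\text{perm}+1)$ and the
  smallest attainable p is $2/(n_\text{perm}+1)$ (≈ 2.0·10⁻⁴ at the
  default 10,001 draws).  Under an independent race the expected profile
  is $-F_AF_V < 0$, so the test is conservative under the composite null;
  the calibration test verifies rejection ≤ nominal + Monte-Carlo error.
* **Benjamini–Hochberg** correction at q = 0.05 across the group ×
  congruence cluster p-values (step-up; `stats::p.adjust`).
* **Exponential-null test.**  Violation areas are nonnegative by
  construction, so "different from zero" is the wrong question.  Instead
  the intercept of a hierarchical model of the areas carries an
  **exponential prior** whose rate λ makes the prior variance 1/λ² equal
  to the sample variance of the areas, and the evidence is the density
  ratio at intercept = 0 (prior density at 0 is exactly λ; the posterior
  density is Rao–Blackwellized from the truncated-normal full
  conditional).  How the original analysis operationalized "further from
  zero than an exponential with the data's variance" inside a linear mixed
  model is ambiguous; this prior-plus-density-ratio reading is the
  package's documented interpretation.  A floor on the prior scale
  (`min_prior_sd`, default 1 ms) keeps the degenerate all-zero case
  well-defined — it then yields BF₁₀ ≪ 1, i.e. the null is favored rather
  than an error thrown.  When group and congruence vary, a second,
  factorial model (sum-coded Group × Congruence, normal prior rule)
  reports per-factor Bayes factors.
* **Misses** delete the response; reaction times are never imputed or
  censored (the task is unspeeded), and participants lacking
  `min_trials = 10` correct target RTs in any class are excluded with a
  logged reason — the exclusion rule the sources imply but do not state.

## 5. What the synthetic data emulate — and what they do not

`simulate_eeg_dataset()` states a world with these defaults:

| parameter | default | meaning |
|---|---|---|
| `c1_amplitude` | 2 µV | window-mean source strength; matches the ~1.5–2.4 µV amplitudes typical of this component |
| `suppression` | per-condition factor in [0,1] | `c(V=1, AV_i=0.5, AV_c=0)` emulates a congenitally deprived group; all 1 a control group |
| `noise_sd` | 5 µV | background amplitude, `pink_exponent = 1` (1/f), 25% of variance shared across channels |
| `trials_per_cell` | 200 | per collapsed condition × field cell (split over sides) |
| `participant_sd` | 0.5 µV | between-participant SD of the source amplitude |
| `auditory_amplitude` | 3 µV | fronto-central sound-evoked wave, identical for UVF/LVF (cancels in the difference) |
| `blink_rate`, `saccade_rate` | 0.05 | per-trial artifact probabilities; blink = 400 ms half-cosine, largest frontopolar (~150 µV); saccade = step edge of opposite sign at F9/F10 (~60 µV) |
| `srate` | 250 Hz | desk-scale reduction of 1 kHz acquisition; acceptance replicates run at 125 Hz |

The retinotopic component projects through a fixed weight vector (maximum
at the occipital electrode contralateral to the stimulated side, decaying
toward parietal sites), with the upper/lower field sign flip carried
externally; the temporal template is a raised cosine on 50–100 ms whose
continuous-time window mean is 1, so the injected amplitude is recovered
directly (times the average-reference projection factor ≈ 0.89 at O1).
Per-condition trial counts after rejection are free parameters — the
sources do not report them — and the defaults above were chosen once as
realistic and are not tuned to test outcomes.

What the generator does **not** contain: volume conduction through a head
model (the projection is a stylized topography with the polarity-flip
property, which is all the difference wave needs), oddball-evoked
components beyond the target flag, eye-movement-correlated signal at
posterior channels, and non-stationary noise.  A green test therefore
establishes that the *pipeline and inference machinery* recover a known
ground truth under realistic noise — not that any particular empirical
effect size in recorded data is correct.

`simulate_rt_dataset()` draws two latent ex-Gaussian channel finishing
times per trial (defaults A: μ=350, σ=40, τ=90 ms; V: μ=380, σ=40, τ=90 —
typical simple-RT values with the auditory channel slightly faster).
`race_independent` takes the minimum for double targets and satisfies the
race bound in expectation; `race_correlated` correlates the Gaussian
components; `coactivation` subtracts a shift (floored at 100 ms) from the
minimum, producing genuine violations.  Targets occur with probability
0.2; standards are generated at the complementary rate with a 1%
false-alarm probability; misses (2%) delete the response.

## 6. Numerical and degenerate-case choices

* Seeds: every generator and sampler takes an explicit integer seed;
  identical configuration + seed is bit-identical output, including the
  full pipeline's CSV artifacts.
* The posterior-density fallback in `bayes_factor_directional()` is a
  moment-matched normal (exact for conjugate Gaussian posteriors); the
  kernel option falls back to it, with a warning, when fewer than 1% of
  draws lie near zero.
* A contrast of a cell with itself is identically zero; it is reported
  with estimate 0 and BF₁₀ = 0 rather than entering the (then singular)
  reparameterization.
* All-zero responses: the prior-SD rule would give an improper scale, so
  the response SD is floored at 10⁻³ µV (1 ms for the area test); the
  posterior then concentrates at zero and the null is favored.
* `blink_k`/`saccade_k` = ∞ disables the corresponding rejection rule
  exactly; `motor_window_ms = 0` is the identity.
* HDIs need ≥ 20 finite draws; fewer is an error, not a silent NA.

## 7. Known limitations

* The ocular rule operates on raw channels; it is a faithful threshold
  rule but not a substitute for component-based ocular correction, and its
  centred form is an interpretation (Section 2).
* The Gibbs sampler assumes the conjugate Gaussian structure; it cannot be
  swapped for arbitrary likelihoods without rewriting the conditionals.
* The exponential-null reading of "distributed away from zero" is one of
  at least two defensible operationalizations (Section 4).
* BrainVision support covers the common binary multiplexed
  float32/int16 layout, read-only.
* Inverse source modeling is out of scope; the package stops at the scalp.
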