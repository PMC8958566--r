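---
title: "Methods: segment kinematics, baseline normalisation, and the statistical models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segment kinematics, baseline normalisation, and the statistical models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facekin)
```

## The measurement model

The package analyses facial expressiveness during spoken performance from
3D motion-capture marker trajectories. The unit of measurement is a
*facial segment*: a pair of labelled markers whose Euclidean distance
indexes the expansion or contraction of a facial region. Seven markers
(mid-brow, left/right inner eyebrow, nose bridge, left/right lip corner,
jaw) define four default segments:

| segment | markers | orientation | region |
|---|---|---|---|
| brow | mid_brow — nose_bridge | vertical | upper |
| eyebrow | eyebrow_l — eyebrow_r | horizontal | upper |
| lips | lip_l — lip_r | horizontal | lower |
| jaw | nose_bridge — jaw | vertical | lower |

The published marker wiring of these segments is graphical rather than
tabulated, so the pairs above are a documented package convention; every
pair is configurable through `segment_spec()`, and four supplementary
vertical segments (nose bridge to each inner eyebrow and lip corner) are
provided for exploratory analyses.

For each trial, the per-frame segment length is
$d = \sqrt{(x_2-x_1)^2 + (y_2-y_1)^2 + (z_2-z_1)^2}$ (mm), and the trial
feature is the mean length $M_d$ over the trial. For a gap-free trial this
equals $\sum d / (sr \cdot t)$ with $sr$ the sample rate and $t$ the trial
duration.

**Gap handling.** Motion-capture reconstruction gaps are never
interpolated; a frame missing any coordinate of a marker's triple is
invalid for that marker, and a segment frame is valid only when *both*
markers are valid. The textbook denominator $sr \cdot t$ counts all
frames; dividing a gap-omitted sum by it would bias every mean downward —
the opposite of the reason for refusing interpolation. `facekin` therefore
divides by the number of *valid* frames; on gap-free trials the two forms
coincide exactly (this identity is tested to 1e-12). A trial feature is
declared undefined when fewer than 50% of frames are valid
(`min_coverage`, configurable): enough to reject degenerate trials while
tolerating realistic dropout.

## Baseline normalisation

Each performance trial is scored as percent change against the same
subject's neutral-speech recitation of the same script:

$$\%\mathrm{change} = 100 \cdot \frac{M_d[\mathrm{performance}] -
M_d[\mathrm{neutral}]}{M_d[\mathrm{neutral}]}$$

Positive values are expansions. Because numerator and denominator come from
the same face producing the same speech, the ratio cancels (a) global face
size — multiplying all of a subject's coordinates by any $c > 0$ leaves
every score unchanged, a property tested to 1e-9 — and (b) articulation
movement common to all conditions. The neutral condition maps to exactly 0
and is excluded from the univariate analyses; the control-self trial (an
unannounced conversational recitation) is normalised like any other
condition and used only in the paired performed-self contrast.

After normalisation, each parameter is screened for extreme outliers with
a robust z-score (median/MAD, flag at |z| > 4). The screen is
*report-only*: it emulates a visual check and never edits data, so a
flagged value remains the analyst's decision.

## The design

Characters occupy a 3×3 crossing of cooperativeness and assertiveness
(low/medium/high each). The name-to-cell placement is a required
configuration input: the shipped default (bully/king/hero at high
assertiveness across increasing cooperativeness, jester/self/lover at
medium, recluse/loner/librarian at low) is a convention, not ground truth,
and any complete bijection can be supplied. Emotions are grouped on the
valence × arousal circumplex: happy, proud, surprised (positive, high);
angry, fearful, disgusted (negative, high); calm (positive, low); sad
(negative, low). The emotion design is therefore unbalanced by
construction (cell counts 3/3/1/1), which is why all factors carry
sum-to-zero contrasts: type III tests are only interpretable under such a
coding.

## Univariate models

Per segment, the model is a linear mixed-effects repeated-measures ANOVA
fitted by **maximum likelihood**:

$$\%\mathrm{change}_{ij} = \mu + A_j + B_j + (AB)_j + u_i +
\varepsilon_{ij}, \qquad u_i \sim N(0, \tau^2)$$

with a random intercept per subject and no random slopes (the design has
one trial per subject × condition cell, which cannot identify richer
structures). Type III F statistics use Satterthwaite denominator degrees
of freedom (via lmerTest). Two numerical consequences of the ML choice are
worth stating:

* On balanced, gap-free data the fixed-effect estimates are the classical
  ones, and the ML-based type III F equals the closed-form
  compound-symmetry RM-ANOVA F computed with error variance
  $SSE/(N - S)$ — i.e., the residual sum of squares of the
  subject-blocked linear model divided by observations minus subjects.
  The test suite verifies this identity to 1e-6 against an independent
  `lm()`/`anova()` decomposition.
* The Satterthwaite denominator df under ML works out to $N - S$ (e.g.
  192 for 24 subjects × 9 characters), not the REML-style
  $N - S - p + 1$; both are reported as fitted, to one decimal.

Effect size is the variance-decomposition R² for mixed models: marginal =
var(fixed predictions)/total, conditional = (fixed + random intercept)/
total. Significance over the four-segment family uses the Bonferroni
threshold α/4 = .0125 at α = .05.

Estimated marginal means per factor level (fixed-effect predictions on the
full factor grid, averaged over the other factor) back the profile plots
(`plot_segment_means()`).

## Face–voice correlations and the self contrast

Pearson product–moment correlations (two-tailed t test, Fisher-z
confidence interval) relate each segment's percent change to each vocal
parameter over trials joined on (subject, condition), Bonferroni-corrected
over the segment family. Which trials enter each correlation set is
explicit configuration: the default character set is all nine characters
and the default emotion set the eight non-neutral emotions, because the
published pair counts imply trial exclusions that are not spelled out —
making the rule explicit keeps the df bookkeeping auditable. Missing vocal
rows (e.g. whispered trials) are dropped from pairs, never imputed here;
imputation is reserved for the multivariate stage. The performed-self vs
control-self contrast is a paired t test per segment with Cohen's
d<sub>z</sub>.

## The rotated PCA

The multivariate stage combines the 4 facial scores with 12 vocal
parameters over 9 characters + 9 emotions (neutral included, with facial
scores exactly 0; control-self excluded), i.e. 18 conditions per subject.
Choices, in pipeline order:

* **Within-subject z-scores.** Every parameter is standardised per subject
  across that subject's conditions, putting percent change, cents and
  decibels on one scale and absorbing subject-level offsets.
* **Similar-case imputation.** A missing (subject, condition, parameter)
  cell — e.g. a whispered trial with no usable vocal measures — is filled
  with the mean of that parameter in the same condition across the other
  subjects, *after* z-scoring so donors share a scale. "Similar case" is
  under-specified in the source literature; the same-condition
  cross-subject mean is the closest defensible reading, and every imputed
  cell is flagged in the output.
* **Decomposition.** Eigendecomposition of the parameter correlation
  matrix; loadings are eigenvectors scaled by the square roots of their
  eigenvalues. Component retention reports the Kaiser count (eigenvalues
  strictly > 1) and scree data; the pipeline's retained k is configuration
  with default 2.
* **Varimax.** The first k loading columns are rotated by the varimax
  criterion **without Kaiser row normalisation**, so the rotation
  maximises the plain variance of squared loadings; for k = 2 this makes
  the result verifiable against a brute-force scan of the single rotation
  angle (the test grid uses 0.001-rad steps and the match is required
  within 0.01 rad). Rotation preserves communalities and the total
  retained variance (checked to 1e-9).
* **Sign convention.** Varimax is sign-indeterminate, so each rotated
  component is flipped to make its largest-magnitude loading positive —
  a fixed tie-break that makes outputs reproducible.
* **Scores.** Standardised component scores are rotated by the same
  orthogonal matrix; condition locations are per-condition means across
  subjects. Loading magnitudes are banded for interpretation (< 0.35
  below threshold, 0.35–0.49 moderately low, 0.50–0.59 moderate,
  0.60–0.79 strong, ≥ 0.80 very strong).

## What the synthetic cohort emulates

The generator produces trajectory files in the package's TSV dialect plus
a tidy vocal table, with all randomness derived from one seed
(bit-reproducible). Its defaults encode the study conditions: 24 subjects,
120 Hz capture, 7 markers, 19 trials per subject (9 characters, 9
emotions, control-self), and 10-s trials — performance-length 120-s trials
are one flag away, but 10 s already gives ~1,200 frames per trial, ample
for stable trial means while keeping full-cohort simulations fast enough
for replicated testing.

Structure emulated:

* per-subject face geometry of varying size (scale SD 0.10 — roughly the
  spread of adult face dimensions);
* a speech-articulation oscillation on the lower face (2 mm at 4 Hz, a
  syllable-rate mouth movement), applied identically in every condition
  including neutral, honouring the assumption that the baseline captures
  articulation. Setting `articulation_in_all = FALSE` confines it to
  neutral/control trials, deliberately violating that assumption for
  robustness studies;
* condition effects as multiplicative rest-length offsets, so designed
  percent changes are analytic ground truth (slopes per factor step:
  brow 3, eyebrow 2, lips 4 for cooperativeness; jaw 3 for assertiveness;
  2.5 on the upper segments for valence; jaw 3 for arousal; a 2-unit
  performed-self boost on eyebrow/lips/jaw) — moderate effects of a few
  percent, the order of magnitude a trained performer's facial range
  plausibly spans;
* behavioural noise: a per-subject expressive-style offset (SD 1.5%)
  shared across that subject's performance trials — it survives
  normalisation and is what the random intercept absorbs — plus per-trial
  noise (SD 2%). The subject's single neutral trial contributes its own
  noise to *every* normalised score of that subject, an often-overlooked
  consequence of self-baselining that the generator reproduces;
* marker jitter (0.3 mm) and dropout gaps (2% per marker-frame);
* vocal parameters coupled to the trial's realised jaw offset (pitch
  +25 cents/%, loudness +0.6 dB/%, with pause duration and shimmer coupled
  negatively) and to the mean upper-face offset (duration and the timbre
  measures, negatively), the remaining parameters pure noise — yielding
  the intensity (jaw/pitch/loudness) and quality (upper face vs
  duration/timbre) blocks the rotated PCA should separate.

`simulate_features()` skips frame synthesis and returns the percent-change
scores the trajectory pipeline would recover, exactly reproducing the
offset and vocal draws of `simulate_cohort()` under the same seed (tested
for identity). Frame-level jitter and dropout perturb trial means only at
the 0.1-percentage-point level and are not emulated on this path.

What passing tests on these cohorts do **not** show about real data: real
articulation is neither sinusoidal nor identical across conditions; real
effects need not be multiplicative, monotone, or additive across factors;
real dropout is burst-structured rather than independent; and the vocal
coupling here is linear by construction. The simulations validate the
*machinery* — estimator correctness, calibration, and recovery of designed
structure — not any empirical claim about actors.

## Simulation sizes used by the test suite

Replicated checks run at the study's subject count with feature-level
simulation: type I calibration uses 500 null replicates at 24 subjects
(per-effect rejection rates required inside the exact binomial 95%
interval around .05); power/recovery uses 200 replicates (corrected
significance required in ≥ 90%, with monotone marginal means); the
jaw-leads-the-correlations check uses 20 replicates with coupling on and
off. Trajectory-level tests use small cohorts (2–6 subjects, 2-s trials)
plus one full-scale run in `scripts/acceptance.R`.

## Known limitations

* One trial per subject × condition: random slopes and trial-level
  reliability are out of reach by design.
* The Satterthwaite/ML df bookkeeping matches one defensible reading of
  mixed-model RM-ANOVA; Kenward–Roger is not offered.
* Head-pose correction, velocity/acceleration features and per-frame
  normalisation are out of scope: all inference is on trial means.
* The character scheme's name-to-cell map and the exact segment wiring
  are conventions; conclusions that depend on them should treat them as
  configuration, not fact.
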