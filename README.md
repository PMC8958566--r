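# facekin

Facial kinematics of character and emotion portrayal from 3D motion capture.

## The problem

When actors portray contrastive characters or emotions while speaking, they
reshape their face — but spoken performance confounds expressive movement
with speech articulation, and faces differ in size across people. `facekin`
implements a segment-based analysis of facial motion-capture recordings that
addresses both problems, for researchers studying expressive movement,
performance, or affective kinematics:

1. **Segments.** Pairs of labelled facial markers (mid-brow–nose bridge,
   left–right inner eyebrow, left–right lip corner, nose bridge–jaw) define
   four facial segments. Each segment's per-frame length is the Euclidean
   distance

   `d = sqrt((x2-x1)^2 + (y2-y1)^2 + (z2-z1)^2)` (mm),

   and a trial's feature is the mean segment length `Md` over the trial.
   Reconstruction gaps are omitted, never interpolated — the mean is taken
   over valid frames only.

2. **Baseline normalisation.** Every performance trial is expressed as
   percent change against the same subject's neutral-speech trial:

   `%change = 100 · (Md[performance] − Md[neutral]) / Md[neutral]`.

   Positive values mean expansion. The ratio removes face size and the
   articulation movement common to all conditions.

3. **Design.** Characters sit on a 3×3 grid of cooperativeness ×
   assertiveness (low/medium/high); eight basic emotions are grouped on the
   2×2 valence × arousal circumplex (happy/proud/surprised = positive+high;
   angry/fearful/disgusted = negative+high; calm = positive+low; sad =
   negative+low), with neutral as the baseline.

4. **Statistics.** Per segment, a linear mixed-effects repeated-measures
   ANOVA (`%change ~ A * B + (1 | subject)`, maximum likelihood,
   sum-to-zero contrasts, type III F with Satterthwaite df, marginal and
   conditional R²), Bonferroni-corrected over the four segments
   (α = .05/4 = .0125). Face–voice Pearson correlations with Fisher-z
   intervals, a paired performed-self vs control-self contrast, and a
   varimax-rotated PCA of the combined 4 facial + 12 vocal parameters
   (z-scored within subject, similar-case imputation of missing trials).

Because no motion-capture recordings ship with the package, a first-class
synthetic cohort generator (`simulate_cohort()`, `simulate_features()`)
produces trajectory files and vocal tables with the full statistical
structure the analysis assumes, so every stage is testable end to end.

## Worked example

```r
library(facekin)

cfg <- sim_config(duration_s = 2, seed = 42)     # 24 synthetic subjects
sf  <- simulate_features(cfg)                    # normalised scores + vocal table

design <- build_design_table(dplyr::distinct(sf$face[c("subject_id", "condition")]))
suite  <- run_univariate_suite(sf$face, design, set = "character")
suite$brow
#> Mixed-effects RM-ANOVA: brow ~ cooperativeness * assertiveness + (1 | subject)
#> # A tibble: 3 × 8
#>   effect              sumsq  meansq num_df den_df statistic  p.value significant
#> 1 cooperativeness    1.10e3 550.         2   192.   132.    9.72e-37 TRUE
#> 2 assertiveness      3.15e0   1.57       2   192.     0.377 6.87e- 1 FALSE
#> 3 cooperativeness:a… 2.09e0   0.521      4   192.     0.125 9.73e- 1 FALSE
#> R2 marginal = 0.453, conditional = 0.632; n = 216; alpha = 0.0125
```

The brow expands with increasing character cooperativeness (F(2, 192) = 132,
significant at the corrected α = .0125) and shows no assertiveness effect —
the generator's designed structure, recovered through the full model. The
jaw–voice coupling appears in the correlations:

```r
corr <- correlate_face_voice(sf$face, sf$vocal, conditions = emotion_names(FALSE))
dplyr::arrange(corr, dplyr::desc(abs(r)))[1:2, c("segment", "parameter", "r", "df", "p.value")]
#>   segment parameter     r    df  p.value
#> 1 jaw     pitch     0.875   190 6.98e-62
#> 2 jaw     loudness  0.768   190 1.21e-38
```

and the multivariate structure in the rotated PCA:

```r
multi <- impute_similar_case(zscore_within_subject(
  build_multivariate_table(sf$face, sf$vocal)))
glance(pca_varimax(multi, k = 2))
#>       n n_parameters     k kaiser_k total_var_explained var_RC1 var_RC2
#> 1   432           16     2        4               0.394   0.215   0.179
```

One rotated component collects jaw + pitch + loudness (an intensity
dimension tracking assertiveness/arousal), the other brow + eyebrow + lips
against duration/timbre (a quality dimension tracking
cooperativeness/valence); `autoplot()` on the PCA object maps the conditions
in that plane.

`run_pipeline(cfg, out_dir)` runs everything above from raw trajectory
files (simulating them first when no manifest is supplied) and writes CSV
outputs plus a JSON run report.

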