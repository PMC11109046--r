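---
title: "Quantitative CVM staging: models, geometry and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CVM staging: models, geometry and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvmstage)
```

# The problem

Cervical vertebral maturation (CVM) staging estimates a growing
patient's skeletal maturity from the shapes of the second to fourth
cervical vertebrae (C2–C4) on a lateral cephalogram, and is used in
orthodontics to time treatment relative to the pubertal growth spurt.
Visual staging is notoriously rater-dependent. `cvmstage` implements a
fully quantitative alternative for female adolescents: 15 landmark
coordinates are reduced to 24 morphometric parameters, and a published
pair of logistic models maps age plus three of those parameters to one
of four condensed maturation stages, iCS1 (prepuberty) through iCS4
(post-puberty).

# Geometry: from landmarks to features

Each vertebral body contributes point-to-line distances rather than raw
coordinate differences, which makes every feature invariant to the
position, orientation and reflection of the film:

* **Concavity depths** `D2`, `D3`, `D4`: distance of `d`, the most
  superior point of the lower border, to the infinite line through the
  border's endpoints. A flat border gives 0; the concavity deepens with
  maturation.
* **Body heights** `AH`, `PH` and **widths** `UW`, `LW`: distances of
  the anterior/posterior upper corners to the lower-border line, and of
  the upper-anterior/lower-anterior corners to the posterior-border
  line.
* **Ratios** `D3:AH3`, `D4:AH4`, `PH:UW`, `PH:LW`: dimensionless shape
  descriptors (the body squares up with maturity).
* **Antero-superior angles** `ang2`–`ang4` at the posterior-inferior
  landmark: the angle subtended by the concavity, ~0° for a flat
  border.
* **Inter-vertebral distances** (`C2a–C3ua` etc.): the gaps between
  adjacent bodies, which close with maturity.

Two numerical choices matter. Distances use the cross-product form
`|cross(b−a, p−a)|/|b−a|`, and angles use `atan2(|cross|, dot)` rather
than the plain arc-cosine of the normalised dot product: the two are
mathematically identical, but arc-cosine loses half the machine
precision near 0°, exactly where flat-border angles live, and would
break rigid-motion invariance at the 1e-9 level the package guarantees.

One definitional point deserves a note. The measurement table in the
source literature describes the C3/C4 concavity depth as the distance
of the *upper-border midpoint* to the lower-border line, which would
make it equal to a body height (~8 mm) rather than a concavity depth;
the same source's descriptive statistics (D3 = 1.07 ± 0.80 mm, with
D3:AH3 = 0.11 ≈ 1.07/8.52) and its definition for C2 (from `d`) make
clear this is a typographical slip. The package computes all three
depths from the `d` landmarks. The upper-border midpoint `um` remains a
required landmark and a signed-depth diagnostic is available
(`extract_features(..., signed_depths = TRUE)`), but no model consumes
it.

# The staging models

The primary model is a proportional-odds (cumulative-logit) model over
the four ordered stages. With linear predictor

\[
\beta x = 3.172\,\mathrm{age} + 28.642\,\mathrm{D3{:}AH3}
        + 0.727\,@4 + 0.453\,\mathrm{C3lp\text{-}C4up},
\]

the cumulative probabilities are \(P(y \le j) = \sigma(\alpha_j - \beta
x)\) with thresholds \(\alpha = (32.921,\ 45.460,\ 62.065)\). Larger
\(\beta x\) means a more mature stage; all four slopes are positive.
The predicted stage is the probability argmax, with ties resolved
toward the more mature stage (the same convention used when in-between
morphology is staged visually).

```{r}
m <- cvm_primary_model()
pooled <- data.frame(age = 11.50, D3_AH3 = 0.11, ang4 = 7.74,
                     C3lp_C4up = 3.62, PH4 = 10.22)
predict(m, pooled)
```

The coefficients are applied to **raw** measurement units (years, mm,
degrees, ratios). This is a deliberate reading: the thresholds
(32.9–62.1) are commensurate with the raw-scale linear predictor at the
pooled means (≈46.9), whereas z-scored inputs would put every subject
far below the first threshold. The z-score normalisation step in the
published development pipeline is therefore interpreted as part of
feature *screening*, not of the final formula; the model object carries
a `scale` field so a standardised variant remains expressible.

Because the third stage is the hardest to separate from the fourth, a
binary logistic **correction model**
(\(\beta x = 2.139\,\mathrm{age} + 0.313\,@4 + 1.444\,\mathrm{PH4}\),
cutpoint 51.828) re-decides the iCS3/iCS4 call whenever the primary
model predicts stage 3 or 4: final stage 3 when
\(P(\mathrm{iCS}=3) = \sigma(51.828-\beta x) \ge 0.5\), else 4. The
trigger set {3, 4} and the 0.5 cut are configurable; a primary
prediction of stage 1 or 2 is never altered. The exact rule by which
the original authors combined the two models is not spelled out in the
source; the {3,4}-trigger is this package's operationalisation and is
stated as such.

# Refitting: the development pipeline

`develop_model()` reproduces the model-development procedure on any
cohort: univariate Spearman screening (p < 0.05, no multiple-testing
correction — matching the original pipeline, and noted in the report),
a multivariable proportional-odds fit on the candidates, backward
elimination of non-significant Wald terms, and diagnostics.

The proportional-odds likelihood is maximised by damped Newton
iteration with the analytic gradient and Hessian. Thresholds are
optimised as \((\alpha_1, \alpha_1+e^{\delta_2},
\alpha_1+e^{\delta_2}+e^{\delta_3})\) so ordering is enforced by
construction; features are standardised internally for conditioning and
estimates mapped back to the raw scale (the delta method transforms the
covariance). A step-halving line search guarantees the log-likelihood
never decreases; if the Hessian is not negative-definite the step is
ridged, with a steepest-ascent fallback. Convergence is declared at
gradient infinity-norm < 1e-6, with a hard cap of 200 iterations
(flagged, never silent). Fits with any standardised slope beyond ±50
raise a complete-separation warning. The binary logistic fit is the
two-class special case of the same engine, in the same
\(\alpha - \beta x\) parameterisation as the correction model. In
testing, the engine is cross-checked against an independent ordinal MLE
implementation and against `glm`; it typically attains a marginally
*better* optimum than the reference's default optimiser settings.

Diagnostics follow the classical recipes: the Brant test fits the J−1
cutpoint logits `I(y > j)` and forms the Wald chi-square for slope
equality across cutpoints using the cross-model covariance built from
the fitted cutpoint probabilities (omnibus df = (J−2)k plus
per-variable statistics); it requires J ≥ 3 and raises an explicit
error otherwise. VIF is `1/(1−R²)` from regressing each feature on the
others, with tolerance `1/VIF` and a flag at VIF ≥ 5 (tolerance < 0.2;
a "tolerance > 2" rule sometimes quoted for this pipeline is
impossible, since tolerance ≤ 1 by definition).

# What the synthetic cohorts emulate — and what they do not

No landmark data are deposited with the source study, so the package
ships a seeded generator whose cohorts reproduce the *statistical
shape* of the study population:

* **Stage structure and ages.** Balanced stages (default 120/stage,
  matching the development cohort; 20/stage for the validation layout)
  with per-stage truncated-normal ages (7.6 ± 0.8 years in iCS1 up to
  15.7 ± 1.3 in iCS4, with the published min/max as truncation bounds).
* **Geometry.** The generator's primitives are the directly measured
  lengths (depths, heights, widths, gaps, C2 width). Per-stage means
  and within-stage SDs are derived once from the published pooled
  mean/SD and stage correlation of each primitive by a fixed variance
  decomposition: with balanced stages, between-stage offset
  `Δ = ρ·SD/√1.25` per stage step and within-stage SD `SD·√(1−ρ²)`.
  The pooled mean, pooled SD and the stage-correlation *sign and rough
  magnitude* of every feature then emerge correctly, including the
  derived ones (ratios, angles, inter-vertebral distances) that the
  generator never draws directly. The published pooled SDs confound
  between- and within-stage variance; this decomposition is the
  package's documented resolution of that ambiguity, not a published
  fact. The C2 lower-border width (never published) is fixed at
  11.6 mm, the value implied by the pooled C2 depth and angle.
* **Construction.** Landmarks are placed analytically (corners from
  heights/widths, `d` at the displaced mid-border, `um` at the upper
  mid-border), each vertebra gets a small random inclination, and a
  random small rigid motion is applied. With `noise = 0` every subject
  sits exactly on its stage template — `template_features()` is the
  analytic inverse used in tests. One global seed drives per-subject
  substreams, so a cohort is bitwise reproducible and stable under
  reordering.

What the generator does **not** emulate: within-stage correlation
between geometric primitives (they are drawn independently given the
stage), measurement/digitisation error structure, secular or ethnic
variation, and male anatomy. Consequently, agreement between the
packaged cascade and the generator's stage labels (~85–90% on the
default cohort) is a sanity check of internal consistency — it neither
reproduces nor validates the accuracy reported on the real films, which
is an arithmetic property of the published confusion tables and is
checked as such.

For parameter-recovery and selection-consistency experiments,
`simulate_features_from_model()` works at the feature level: draw
features, compute \(\beta x\), sample the stage from the model's
categorical distribution. By default features are drawn independently
at the published pooled means/SDs. For screening experiments this is
too hostile a world: the C3lp-C4up slope is small enough that its
*marginal* association with stage is mathematically below the
univariate p < 0.05 detection limit even at n = 2000 when features are
independent — whereas in the real cohort all features are mutually
correlated through maturation and passed the screen. The
`latent_loadings = "published"` option therefore draws the model's
features with a shared latent maturation factor, each loading equal to
the magnitude of that feature's published stage correlation; noise
features stay independent. One limitation is documented here openly:
the published *negative* marginal correlation of the inter-vertebral
gap cannot coexist with its positive model slope in a one-factor
design, so the loading uses the magnitude only.

# Evaluation conventions

`evaluate()` reports the 4×4 confusion matrix, one-vs-rest per-stage
precision/recall/F1, macro averages, and overall accuracy as
`trace/N` — the multiclass reading of the textbook
`(TP+TN)/(TP+TN+FP+FN)` formula, whose per-class TN contributions
cancel in the sum (the published 93.96% equals trace/480, not a
TN-inflated binary accuracy). Undefined 0/0 precision or recall is
reported as missing, never coerced to 0 or 1; F1 at precision = recall
= 0 is 0 by continuous extension. Printed metrics use 4 decimals and
percentages 2 decimals, matching the conventions of the source tables.
One published cell (corrected model, validation cohort, stage 3,
F1 = 0.9456) is not the harmonic mean of its own printed
precision/recall pair (0.9474, 0.9000 → 0.9231); the package computes
0.9231 and treats the printed value as a transcription slip.

# Problem sizes and defaults

The stochastic suites use sizes chosen to make their Monte-Carlo error
small relative to the bands they check: 100 replicates of n = 5000 for
slope recovery (each slope within 3 SE), 500 replicates of n = 400 for
Brant type-I error (nominal 0.05, accepted band 0.03–0.07), 100
replicates of n = 2000 for selection consistency, 1000 random triples
for the geometry oracle, and the full 480-subject default cohort for
calibration checks. All tunable defaults — screening and retention
alpha 0.05, correction trigger {3, 4}, decision cut 0.5, age
plausibility window 4–25 years, VIF flag at 5 — mirror either the
published pipeline or the field's standard practice, and every
stochastic routine takes an explicit seed.

# Worked example

```{r}
cohort <- simulate_landmarks(n_per_stage = 30, seed = 7)
features <- extract_features(cohort)
pred <- predict_cascade(features)
evaluate(features$true_stage, pred$stage_final)
```

Refitting on the same cohort:

```{r}
dev <- develop_model(features)
dev$retained
summary(dev$fit)
```

# Known limitations

* The packaged coefficients are for Chinese female adolescents; no male
  or other-population models are provided.
* Whether the published coefficients are on the raw or standardised
  scale is an interpretation (argued above), recorded in the model
  object's `scale` field.
* The landmark generator's independence of primitives within stage
  understates the real data's feature correlations; refits on synthetic
  landmark cohorts therefore retain more features than the published
  four, which is expected behaviour, not a defect.
* Radiograph processing (calibration to true millimetres, landmark
  digitisation) is upstream of this package: inputs are assumed already
  in millimetres.
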