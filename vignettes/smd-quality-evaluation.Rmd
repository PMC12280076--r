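---
title: "Evaluating synthetic medical data with the seven quality criteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating synthetic medical data with the seven quality criteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smdscorecard)
```

## Why seven criteria

Synthetic medical data is usually judged by statistical fidelity alone, and
fidelity alone is not enough: a generated image can match the reference
distribution in every moment a Fréchet distance sees and still contain an
anatomically impossible structure, and a generated clinical note can score
well on overlap metrics while hallucinating a symptom. `smdscorecard`
therefore evaluates a synthetic dataset along seven complementary axes:

* **Congruence** — distributional and perceptual alignment with the
  reference (patient) data;
* **Coverage** — whether the synthetic data spans the variability and modes
  of the reference;
* **Constraint** — adherence to declared clinical/technical validity rules;
* **Completeness** — presence of required fields and records;
* **Compliance** — privacy posture: anonymity structure, declared
  differential-privacy budget, memorization risk;
* **Comprehension** — how clearly the generation process is documented;
* **Consistency** — stability of any of the above across subgroups or time
  slices.

Every metric is computed raw, normalized onto $[0,1]$ against an explicit
calibration, aggregated per criterion, and reported **together with** its
raw value, parameters, and provenance — an aggregated score is never
published without the members that produced it.

## The embedding space

Most binary metrics operate on an $n \times d$ feature embedding. The
pipeline (standardization, optionally a top-$k$ PCA projection) is **fitted
on the reference only** and then applied identically to both datasets, so
the synthetic data cannot influence the space in which it is judged.
Zero-variance features are given scale one (their standardized values are
exactly zero), and each principal direction's sign is fixed by making its
largest-magnitude loading positive, so repeated runs are bit-identical.

The built-in extractors are deterministic and training-free: an 8-feature
image descriptor (mean, spread, tail percentiles, histogram entropy,
gradient magnitudes, Otsu foreground fraction) and a bag-of-token text
vectorizer. Learned embeddings (radiomics, deep features) are supported by
supplying a pre-computed CSV; results always carry the extractor identity
in `params`, because no feature family is canonical for a given modality.

## Metric constructions and numerical choices

Where the metric literature leaves an estimator open, the package fixes one
and records it:

* **Fréchet distance** uses sample moments (denominator $n-1$); the trace
  of the covariance-product square root is the sum of square roots of the
  eigenvalues of $\Sigma_r \Sigma_s$, with eigenvalues above $-10^{-8}$
  (relative) clamped to zero. The computation is embedding-generic — no
  pretrained network is involved.
* **Jensen–Shannon divergence** bins both marginals on shared edges over
  the pooled min–max (32 bins, base-2 logs) so the 0 and 1 endpoints are
  exact; a zero-width feature contributes 0 and is flagged.
* **Earth mover's distance** is the exact 1-D Wasserstein-1 per marginal
  (ECDF-difference integral, no binning), averaged over features.
* **PSNR/SSIM** follow the standard parameterization (Gaussian window 11,
  $\sigma = 1.5$, $C_1 = (0.01L)^2$, $C_2 = (0.03L)^2$; PSNR capped at
  100 dB when MSE is 0). The SSIM implementation is verified against
  scikit-image to $10^{-5}$ in the test suite.
* **Precision / recall / coverage** use the k-nearest-neighbour-radius
  manifold construction ($k = 3$ default); the suite checks exact
  agreement with an $O(n^2)$ membership oracle.
* **Vendi and DPP scores** share a cosine kernel on L2-normalized rows;
  the unit diagonal guarantees the eigenvalues of $K/n$ sum to one.
* **Convex hull volume** is compared in a 2-D PCA plane fitted on the
  reference: high-dimensional hulls are degenerate and exponentially
  costly, and the spread comparison the ratio makes is already visible in
  the plane. Collinear point sets are rejected with an area tolerance of
  $10^{-10}$ of the bounding box.
* **Cluster occupancy** calls a cluster occupied when its synthetic share
  reaches half the uniform share ($0.5/n_{\text{clusters}}$), a scale-free
  threshold recorded in `params`; k-means is seeded with 10 restarts.
* **t-closeness** uses total variation for categorical sensitive
  attributes and rank-normalized 1-D Wasserstein for numeric ones, both
  bounded in $[0,1]$ so direction-aware normalization is well defined.
* **Re-identification risk** is a memorization proxy: the fraction of
  synthetic records closer to a reference record than $\theta$ (default
  0.1) times the reference's own median nearest-neighbour distance.

### Two deliberate direction choices

The metric registry reproduces the printed direction of every metric
family, including *minimize* for "nearest invalid datapoint" and *maximize*
for "t-closeness level". The default **calibrations** deviate in exactly
two places, both safety-motivated and config-overridable: a larger
distance to known-invalid exemplars is treated as better (a literal
minimize reading would reward synthetic data for crowding invalid
regions), and a smaller $t$ is treated as safer (the standard t-closeness
semantics). Both divergences are recorded in the metric `params` so a
scorecard reader sees them.

### The bootstrap ANOVA correction

A quality metric yields one number per subgroup, so testing whether
subgroups differ significantly needs replicates; the package generates
them by seeded within-subgroup bootstrap ($B = 100$ default). A textbook
one-way ANOVA applied directly to those replicates is badly miscalibrated:
all $B$ replicates of a subgroup re-draw the same sample, so the
between-group mean square is inflated by a factor of $B$ and the null
rejection rate approaches one. The reported F statistic therefore divides
the between-group mean square by $B$, which restores a calibrated test
(simulated null type-I error ≈ 5–6% at the nominal 5% level, with full
power against a one-standard-deviation planted shift); the uncorrected
replicate F is kept in `params`. Groups with zero within- and
between-group variance are reported *not assessable* rather than as a
number.

## Calibration, aggregation, thresholds

Normalization is direction-aware: `maximize` maps linearly from `worst` to
`best` and clips to $[0,1]$; `minimize` is the mirror image; `band` scores
1 inside a target range and decays linearly to 0 over `decay_width`
outside it (the band form exists because a coverage-style metric can be
*too* high — broader than the patient population — and a config can switch
any maximize metric to band). Statistical-significance metrics are
reported but never normalized or aggregated.

Calibration anchors come from configuration (clinical knowledge) or from
the reference itself: dataset-dependent anchors (reference diversity,
dispersion, centroid spread) are derived from the reference at run time
and marked `reference-derived`, and `calibrate_from_reference()`
additionally offers a seeded split-half self-congruence baseline — a
synthetic dataset cannot be expected to align with the reference better
than the reference aligns with itself.

Criterion scores are weighted arithmetic or geometric means (geometric
makes any zero member annihilate the criterion — appropriate when a single
hard failure should not be averaged away). Labels use the worked
thresholds *good* ≥ 0.80 > *moderate* ≥ 0.70 > *low*, applied uniformly to
all seven criteria; that uniformity is a generalization of a
coverage-specific example and is flagged in the scorecard footer, since
thresholds are properties of the clinical task, not of the package.

## The scorecard document

`run_evaluation()` assembles an eight-section document: general
information, the seven criterion entries, task-based results, human reader
study results, ethics/limitations, usage, generation process, and
reference-dataset provenance. Sections 3–5 are recorded verbatim from user
input — the package computes nothing for them by design; reader studies
and task benchmarks are evidence the tool transports, not produces. A
criterion without inputs appears as *not applicable* with an explicit
reason, never as a blank. A failed metric becomes a failure note and never
blocks the rest of the evaluation.

JSON output is canonical — recursively sorted keys, floats at six
significant digits — so two runs with the same configuration and seeds are
byte-identical, and re-rendering a parsed scorecard reproduces the exact
bytes. The structural contract is published as a JSON-schema document
(`inst/schema/`), and `validate_scorecard()` enforces the same invariants
natively.

## What the fixture generators emulate — and what they do not

The generators are metrological phantoms with planted, exactly recoverable
ground truth:

* `gen_embedding_pair()` — Gaussian-mixture embeddings where the synthetic
  set differs by a mean shift $\delta$, a spread factor, and dropped
  components. The same seed at different shifts produces *common random
  draws* offset deterministically, so the congruence metrics' monotone
  response to $\delta$ is a designed property, not a statistical accident
  (the k-NN precision term retains $1/n$ granularity).
* `gen_toy_images()` — noisy backgrounds with elliptical "lesions" and a
  planted fraction of diameter/count violations, recovered exactly by the
  constraint engine.
* `gen_anonymity_table()` — quasi-identifier classes constructed so the
  minimum class size is exactly the planted $k^\*$, with missing cells
  planted at exact floor counts outside the quasi-identifiers.

Each generator draws from its own pseudo-random stream derived from
`(seed, generator name)`, so adding a generator never perturbs existing
fixtures, and the caller's RNG state is left untouched.

These fixtures deliberately do **not** emulate real medical data: there is
no anatomy, no acquisition physics, no realistic missingness mechanism
(cells go missing completely at random), and no correlation between
quasi-identifiers and the sensitive attribute. Passing tests therefore
demonstrate that the metrics measure what they claim on data with known
structure — not that any particular synthetic dataset is clinically
adequate.

## Problem sizes and runtime

The shipped tests and the reproduction script use embedding fixtures of
500 samples for monotonicity properties, 60–120 samples per subgroup for
the end-to-end evaluations, $B = 20$–100 bootstrap replicates, and
brute-force oracle sweeps of 100 trials at $n \le 30$ (k-NN) and 100
tables at $n \le 50$ (anonymity) — sizes at which the exhaustive oracles
are exact and the whole suite runs in well under a minute on one core.
All distance computations are dense $O(n^2)$; for datasets beyond a few
tens of thousands of samples, subsample before evaluation (the metrics are
estimators, and their `params` record `n`).

## Known limitations

* Precision/recall manifolds and FID inherit the weaknesses of their
  embedding; a poor feature space hides real defects.
* The differential-privacy entry is a declared, validated attribute of the
  generation pipeline — the package does not estimate $\varepsilon$ from
  data, and the scorecard marks it as declared.
* The comprehension score quantifies a human-scored rubric; it does not
  read documentation.
* Novelty (valid-but-new combinations) has no dedicated statistic; it is
  only indirectly visible through the coverage family.
* Anatomical-plausibility models (segmentation- or registration-based
  structural checks) are out of scope; the constraint engine instead
  accepts any user-derived feature, including outputs of such models.
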