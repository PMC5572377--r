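---
title: "Pattern similarity and learning outcomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern similarity and learning outcomes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsalearn)
```

`rsalearn` relates the reproducibility of regional multivoxel activation
patterns — representational similarity across two stimulus repetitions — to
how quickly people subsequently learn to name novel written words. This
vignette documents the statistical models, the synthetic-data generator that
stands in for subject data, and the choices made where the design was
genuinely open.

## The measurement model

For a subject $s$, ROI $g$ and condition $c$ (trained novel words or a
familiar control language), the input is a pair of condition-mean voxel
activation patterns $\mathbf{v}^{(1)}, \mathbf{v}^{(2)}$ (e.g. GLM contrast
estimates for repetitions 1 and 2). Pattern similarity is their Pearson
correlation, Fisher transformed:

$$ r_{sgc} = \mathrm{cor}(\mathbf{v}^{(1)}, \mathbf{v}^{(2)}), \qquad
   z_{sgc} = \operatorname{atanh}(r_{sgc}). $$

Voxel values are used as-is: no within-pattern standardization is applied,
since Pearson correlation is already invariant to positive affine transforms
of either pattern (a property the test suite asserts). Cells at exactly
$|r| = 1$ — which occur only in degenerate or noiseless synthetic data — are
clamped to $1 - 10^{-7}$ before the transform, with a warning, so that
downstream correlations stay finite rather than propagating infinities.
Zero-variance patterns are an error, never a silent 0 or `NaN`.

## Behavioral model

Training RTs follow the classical power law of practice,

$$ \mathrm{RT}(d) = a\, d^{-b}, $$

with $a$ initial performance (ms) and $b$ the learning rate. Daily naming
speed is the unweighted mean of the word- and picture-naming RTs. Two
summaries feed the brain–behavior analyses:

* **Outcome RT** — the mean over Days 5–12, where the learning curve has
  flattened; it is invariant by construction to anything that happens on
  Days 1–4.
* **Learning rate** — $\hat b$ from a nonlinear least-squares fit.
  Initialization comes from OLS on $\log \mathrm{RT} \sim \log d$ (which is
  exact for noiseless power-law data), refined by Levenberg–Marquardt on the
  original scale. $R^2 = 1 - SS_{res}/SS_{tot}$ is computed on the original
  scale, not the log scale: a single goodness-of-fit number per subject is
  wanted and the original scale weights all days in ms units. Constant
  trajectories make $SS_{tot} = 0$; the fit returns $b = 0$ with $R^2$
  reported as `NaN`, and such fits are excluded (together with any
  $R^2 < 0.7$) before the learning-rate correlation.

## Inference

**Correlation.** Pearson $r$ between $z_{sg,\mathrm{trained}}$ and the
outcome RT, with the usual $t$-distribution p-value on $n - 2$ df.

**Permutation tests.** Two complementary exchangeability arguments:

* *between-subject*: similarity values shuffled across the $n$ subjects
  ($n!$ arrangements);
* *within-subject*: trained and control values swapped independently per
  subject with a fair coin ($2^n$ assignments; for $n = 24$, $2^{24} =$
  16,777,216).

Monte-Carlo p-values use the add-one rule
$p = (1 + \#\{\text{null as or more extreme}\})/(n_{perm} + 1)$, so $p = 0$
is impossible. The one-tailed p is directed by the sign of the observed
correlation, matching how a directional hypothesis (faster naming with
higher similarity) is usually displayed; because that direction is chosen
after seeing the data, it is *not* a fixed-level test, and all calibration
checks and report flags therefore use the two-tailed p. Exhaustive modes
(all $n!$ permutations for $n \le 9$; all $2^n$ swap assignments for
$n \le 20$) report the plain proportion over the full enumeration, which
includes the identity and is likewise never zero.

**Dependent correlations.** Whether the trained condition predicts behavior
better than the control condition is a comparison of two correlations that
share the behavioral variable. The package implements Steiger's (1980)
pooled-estimate $z$ (the variant popularized by Lee & Preacher's utility):
with $\bar r = (r_{jk} + r_{jh})/2$,

$$ \bar\psi = r_{kh}(1 - 2\bar r^2) - \tfrac12 \bar r^2 (1 - 2\bar r^2 - r_{kh}^2),
   \qquad
   Z = \frac{(z_{jk} - z_{jh})\sqrt{n - 3}}{\sqrt{2 - 2\bar\psi/(1-\bar r^2)^2}}. $$

The cross-correlation $r_{kh}$ between the two conditions' similarity
vectors is required; inside `run_full_analysis()` it is estimated from the
data. Correlation triples that are not positive semidefinite are rejected
with an error (such triples cannot arise from any dataset). A
trivariate-normal simulation in the test suite confirms nominal type-I error
at $\alpha = 0.05$.

**Prediction.** Leave-one-out cross-validation fits
`outcome ~ similarity` by OLS on $n - 1$ subjects (one predictor plus an
intercept — the simplest defensible "brain-behavior regression model") and
reports the relative error $(\hat y_i - y_i)/y_i$ per held-out subject, with
its max and min absolute values as summaries.

**Item median split.** Items are split into fast and slow groups at the
median of their Day 5–12 RT, separately per task. Ordering is stable by
(RT, original item position); the lower `ceiling(n/2)` items form the fast
group, so groups differ by at most one and the rule is deterministic under
ties (boundary ties trigger a warning). Group-mean patterns are re-correlated
across repetitions per subject and contrasted with a paired $t$ test.

No multiplicity adjustment is applied across ROI × task cells — the report
states the number of tests and carries an optional Bonferroni column, leaving
the correction decision to the analyst.

## The event-schedule generator

The rapid event-related design has 3 conditions × 30 items × 2 repetitions
plus 9 filler trials (189 total), with 4–8 trials intervening between the two
presentations of an item and ISIs jittered between 1 and 5 s with a 2 s mean.
Two pieces were left open by that description:

* **ISI distribution.** Only the range and mean are stated. The generator
  uses a truncated-geometric profile on a 0.5 s grid over $[1, 5]$,
  $p_k \propto q^k$, with $q$ solved numerically so the expected ISI equals
  2.0 s — many short and few long intervals, the standard shape of optimized
  rapid designs. (A symmetric target mean would make the profile uniform.)
* **Placement.** Scheduling is randomized-greedy with rejection: slots are
  filled in order; a pending second presentation whose spacing window closes
  is placed immediately; otherwise a uniformly random choice among eligible
  seconds, unused firsts, and fillers. Wedged sequences restart, up to 1000
  attempts, after which an explicit "infeasible design" error is raised.
  Everything is deterministic given the seed.

The generated `total_duration` covers onsets plus stimulus extent
(≈ 490 s in expectation at the standard parameters); a scanner run also
includes lead-in/lead-out and null time, which the generator does not model —
volume arithmetic (`ceiling(duration / TR)`) is exposed separately via
`schedule_summary()`.

## What the synthetic data emulate — and what they do not

`simulate_patterns()` plants a per-subject cross-repetition correlation
$\rho$ by constructing repetition 2 as
$\rho\,\tilde{\mathbf{v}}^{(1)} + \sqrt{1-\rho^2}\,\tilde{\boldsymbol\varepsilon}$
(standardized pattern plus independent standardized noise), so the population
correlation equals $\rho$ exactly and the construction is exact at
$\rho = \pm 1$. `simulate_behavior()` couples behavior to the brain through

$$ \mathrm{RT}_{sdt} = a_s d^{-b_s} + \delta_t +
   \beta\, z_s \,[d \ge 5] + \varepsilon_{sdt}, $$

where $z_s = \operatorname{atanh}(\rho_s)$ is the subject's latent
trained-condition similarity and $\beta < 0$ shifts only the post-learning
plateau (Days ≥ 5), because the outcome is defined on that range. Defaults,
chosen once as a realistic study-scale configuration: 24 subjects, 4 ROIs,
100 voxels; $\rho \sim U(0.05, 0.7)$ for both conditions (the control
condition is decoupled from behavior); $a \sim U(1900, 2100)$ ms,
$b \sim U(0.25, 0.35)$; $\beta = -150$ ms per Fisher-z unit; day-level noise
50 ms; picture naming 100 ms slower than word naming. Under these defaults
the population brain-behavior correlation is about $-0.4$ — the order of
magnitude reported in ROI-level individual-difference studies. Item-level
patterns and RTs (for the median split) use the same construction with a
per-item planted $\rho_i$ shared across subjects.

Deliberate simplifications, which bound what passing tests show about real
data: voxel activations are iid Gaussian with no spatial autocorrelation, no
scanner drift or motion structure, and no between-ROI dependence; all coupled
ROIs share one latent similarity rather than partially overlapping signals;
accuracy trajectories are generated (saturating curve) but never analyzed,
mirroring the ceiling effect that excludes accuracy in practice; and the
learning rate $b$ is drawn independently of $z_s$, so the learning-rate
correlation path is exercised mechanically but has no planted effect to
recover. RNG uses one root seed with fixed per-component sub-streams
(schedule / patterns / behavior), so regenerating one component never
perturbs another.

## Numerical and testing choices

* Problem sizes in the test suite are chosen for desk-scale runs: null
  calibration uses 1000 datasets × 1000 permutations at $n = 24$; exhaustive
  agreement uses $n = 8$ (40,320 permutations, 256 swap assignments);
  planted-sign recovery uses 500 replicates at the default effect size; the
  end-to-end recovery study uses 100 replicates with a strong coupling
  ($\beta = -400$ ms/z, 30 ms noise) planted in ROIs 1–2 of 4, checking that
  coupled ROI × task cells are flagged in ≥ 90% of replicates and uncoupled
  cells in ≤ 10% (an uncoupled cell sits at the nominal 5% false-positive
  rate, so demanding *zero* false positives across four cells would
  contradict the calibration the same suite enforces).
* Monte-Carlo permutation null distributions are computed by correlating the
  outcome against a matrix of permuted/swapped similarity columns in one
  `cor()` call — bit-reproducible given `(seed, n_perm)`.
* `fisher_z` clamping threshold: $1 - 10^{-7}$, large enough that real-data
  correlations are unaffected and small enough that clamped values remain
  clearly separated from ordinary ones.
* Degenerate inputs (constant vectors, zero-variance differences, zero
  observed outcomes, non-PSD correlation triples) raise errors naming the
  offending cell rather than returning sentinel values.

## Known limitations

The package deliberately starts from extracted ROI patterns: GLM estimation,
preprocessing, registration and whole-brain inference are out of scope, and
NIfTI support (`extract_patterns_from_nifti()`) is a thin convenience over
user-supplied binary masks, not an atlas pipeline. The dependent-correlation
comparison needs $r_{kh}$, which published tables typically omit — comparing
against printed $z$ values from the literature therefore generally requires
the original similarity vectors. Permutation p-values are Monte-Carlo
estimates; at 5000 iterations their standard error near $p = 0.05$ is about
0.003, which matters only at the significance boundary.
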