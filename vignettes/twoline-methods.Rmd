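---
title: "Two-line nonaccidental-property search: stimuli, model audit and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-line nonaccidental-property search: stimuli, model audit and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(naplines)
```

## The scientific problem

Nonaccidental properties (NAPs) — collinearity, parallelism,
cotermination, the sign of curvature, the type of junction two edges
form — are image relations that survive changes of viewpoint, which is
why Recognition-By-Components theory makes them the defining features of
its volumetric primitives (geons).  Metric properties (MPs), such as the
exact magnitude of an angle or of a curvature, vary continuously with
viewpoint and are correspondingly less diagnostic of 3D structure.

This package implements a complete desk-scale pipeline for studying
sensitivity to NAPs in the most reduced display possible: configurations
of just **two line segments** (one segment for the curvature control).
It covers stimulus construction, low-level image auditing with a
V1-like Gabor-jet model, factorial odd-one-out trial design, a synthetic
observer that stands in for human participants, and the reaction-time
statistics used to quantify a nonaccidental detection advantage.

## The parameter-axis design

Every condition is reduced to **one scalar parameter** whose boundary
value is the nonaccidental configuration.  A triplet is built as

* nonaccidental variant at the boundary `b`,
* base at `b + delta`,
* metric variant at `b + 2 * delta`,

so the two variants are *exactly* equidistant from the base on the
parameter axis, but only the nonaccidental variant crosses the
categorical boundary.  This is the only construction under which
"equally different, opposite directions" is exact rather than
approximate, and it is asserted as an invariant for all 78 triplets.

The 13 conditions and their parameters (`condition_specs()`):

| condition | category | parameter (deg) | boundary |
|---|---|---|---|
| alignment | between objects | lateral offset of parallel lines | 0 (flush) |
| collinearity_between | between objects | angular deviation | 0 (collinear) |
| generic_to_L | between objects | apex separation along the arm | 0 (L junction) |
| generic_to_T | between objects | endpoint height above the bar | 0 (T junction) |
| generic_to_X | between objects | endpoint height above the bar | −0.35 (crossing) |
| T_to_L | between objects | contact distance from the bar end | 0 (L junction) |
| X_to_T | between objects | overhang beyond the crossing | 0 (T junction) |
| cotermination | within object | vertex gap along the arm | 0 (vertex) |
| expansion_constant | within object | divergence angle | 0 (parallel) |
| collinearity_within | within object | bend angle at the joint | 0 (straight) |
| curvature_edges | within object | common edge sagitta (opposed signs) | 0 (straight) |
| curvature_axis | within object | shared sagitta (same sign) | 0 (straight) |
| curvature_control | control | sagitta of a single line | 0 (straight) |

Two decisions here were genuinely open:

* **The crossing boundary.**  When one segment slides along its own
  axis toward another, first contact always happens at the sliding
  segment's leading *endpoint* — which is a T junction, not an X.  An
  interior–interior contact cannot be produced by this motion, so the
  crossing condition places its boundary at an endpoint overhang of
  0.35 deg beyond the bar: a genuine, visible crossing.  With a step of
  0.5 deg the base (0.15 deg short of the bar) is a near-miss and the
  metric variant (0.65 deg short) is a clear miss.
* **Curvature is parametrized by the sagitta** (arc height over the
  chord) rather than by 1/radius, so that the straight line is an
  interior point of the parameter axis and the metric variant
  (sagitta `2 * delta`) is well defined on the same axis.

Default parameter steps are 10 deg for angular parameters, 0.35 deg for
offsets and slides (0.5 deg for the crossing condition) and 0.3 deg of
sagitta for curvature.  These magnitudes keep every metric variant
inside the stimulus extent and, for the expansion condition at the
default 1.5 deg gap, bring the metric variant's edges close together
without letting them touch — which is exactly why the replication
configuration (`replication_config()`) widens the center gap to
2.25 deg.

### Extent and gap: what is exact and what is approximate

Stimuli subtend 3 deg of visual angle and the two segment centers sit
1.5 deg apart.  Both constraints are satisfied *exactly* for the
stacked-parallel and bar-plus-stem layouts (alignment, expansion,
curvature conditions, collinearity within, and the T/X junction family
at their base parameters).  For apex (chevron) layouts the two
constraints are mutually inconsistent: pinning the far endpoints at
±1.5 deg while opening a gap `p` at the apex necessarily pushes the
centers slightly further apart, so `generic_to_L` and `cotermination`
bases have center gaps near 1.65 deg — "approximately 1.5" is the
honest statement for them.  Variant geometry drifts from the 3 deg
extent by at most `2 * delta` for sliding parameters, and rotated
exemplar poses change the axis-aligned bounding box by up to ~20%;
the test suite therefore asserts extent to within 0.1 deg for
canonical-pose bases and a wider band across the full set.

### Exemplars and mirroring

Each condition contributes 6 exemplars: two canonical poses (identity
and a 90 deg rotation), each in unmirrored, left–right-mirrored and
up–down-mirrored form.  Mirroring is implemented as reflection about
the bounding-box midline and is an involution on geometry.  Where a
stimulus is mirror-symmetric (the curvature family, alignment's
centro-symmetric layout, the symmetric bend), the degenerate
combination is replaced deterministically by a rotated pose (30, 60,
120, ... deg); geometric uniqueness of all six exemplars is verified by
comparing dense point clouds.  With substitution disabled, degenerate
combinations raise an error naming the slot.

## Rasterization

Images reproduce the display convention: white strokes (level 1.0) on
mid-gray (0.5).  Defaults are 32 px/deg on a 4 deg canvas (128 × 128)
with 2 px anti-aliased strokes, which keeps the smallest geometric
manipulation (0.3 deg ≈ 10 px) comfortably above the pixel scale.
Arcs are drawn as dense polylines sampled from the exact circle defined
by chord and sagitta (sampling error below a quarter pixel).  Strokes
have round caps, so junction contacts merge cleanly; the stroke-area
oracle in the tests accounts for the cap area.  Pixel centers are
placed symmetrically about the canvas center, making rasterization
commute exactly with stimulus mirroring — a property the test suite
checks to numerical precision.

## The Gabor-jet audit

The low-level similarity model samples the magnitudes of complex Gabor
filter responses ("jets") on a 12 × 12 grid, at 5 log-spaced spatial
frequencies (2–16 cycles/image) × 8 orientations: 2,880 nonnegative
magnitudes per image.  Phase is discarded.  Two images are compared by
the cosine of the angle between their magnitude vectors, which is
bounded in [0, 1] for nonnegative features; dissimilarity is one minus
this value.

Numerical choices:

* Kernels are quadrature pairs under a Gaussian envelope with
  `sigma = 0.35 * wavelength`; the residual DC response is removed
  exactly by subtracting a scaled envelope, so uniform images produce
  zero magnitudes.  An envelope too broad for the image raises an
  error rather than silently truncating.
* Responses are computed by FFT convolution of the median-subtracted
  image (the median is the background level for these sparse stimuli)
  with circular boundaries, then sampled at the grid points — identical
  to direct per-point convolution up to boundary handling and far
  cheaper.
* The sampling grid is forced to be exactly mirror-symmetric about the
  image center, so mirroring an image permutes grid columns and maps
  orientation `theta` to `180 - theta`; feature extraction commutes
  with mirroring under that documented permutation.

`audit_triplets()` renders each triplet in canonical pose (no jitter)
and reports `sim_nap_base`, `sim_mp_base` and a `matched` flag
(`sim_nap_base >= sim_mp_base`): a matched triplet is one whose
residual low-level difference cannot mimic a nonaccidental detection
advantage.

A caution on interpreting the matched fraction: with the default
(deliberately small) parameter steps, the two variants are nearly
symmetric image perturbations of the base, so the two similarities
often differ only in the third or fourth decimal and the strict flag
is decided by higher-order terms whose sign varies by condition — the
crossing condition in particular adds genuinely new image structure on
the nonaccidental side and is reliably unmatched.  The audit is
therefore most informative at the level of per-condition similarity
means (with standard errors across triplets, `audit_summary()`) rather
than the binary flag, and becomes more decisive as the parameter steps
grow.

## Trial design

`build_trial_table()` fully crosses 78 triplets × changed variant
(metric / nonaccidental) × role (variant is the odd target among three
bases, or the base is the odd target among three variant copies) ×
4 target quadrants: 1,248 trials, each combination once, 312 targets
per quadrant.  Interleaved mode shuffles everything; blocked mode (the
replication's design) randomizes condition order and order within
condition.  Both modes contain the same trials as multisets.
`layout_trial()` places the four stimuli at 5 deg eccentricity on the
diagonals (polar angles 45/135/225/315 deg) and jitters each placement
independently: ±0.25 deg per position coordinate, ±5 deg rotation.

## The synthetic observer

Human data for this task are emulated, not reproduced.  The generative
model is a **shifted lognormal** with an additive participant effect on
the log scale:

    RT = shift + exp( N( log(mu_c − a_c · 1[nonaccidental]) + u_p, sigma_t ) ),
    u_p ~ N(0, sigma_p)

This is the minimal standard form that (i) produces the right-skewed
marginals real RT distributions show, and (ii) makes the
per-participant **median** the natural summary: the within-cell median
is `shift + (mu_c − a_c·1[·]) exp(u_p)`, so median differences recover
the generating advantage `a_c` up to the participant's multiplicative
factor.  Defaults: 10 participants, shift 200 ms, `sigma_t = 0.25`,
`sigma_p = 0.1`, condition baselines spread over 820–980 ms (plausible
magnitudes for a peripheral odd-one-out search), a 60 ms nonaccidental
advantage everywhere except the expansion condition, which gets 15 ms —
echoing the empirical pattern that expansion is the weakest, without
claiming any measured value.  Accuracy is Bernoulli at 0.90 (metric)
and 0.97 (nonaccidental); error trials choose a wrong quadrant
uniformly.

What the generator does **not** emulate: sequential effects, learning
and fatigue over the hour-long session, eye movements, any mechanistic
decision process, and condition-specific accuracy structure beyond the
two ceiling levels.  Passing tests therefore certify the statistical
machinery and its calibration under this generative family, not the
behaviour of human observers.

## Analysis

* `compute_medians()` — per participant × condition × changed-variant
  medians (midpoint convention), over correct trials only by default.
  Error exclusion is a flag because practice varies and accuracy is at
  ceiling, making the choice low-impact.
* `paired_t_one_tailed()` — for each condition, t on the
  per-participant differences `median_MP − median_NAP` with the
  one-tailed alternative `mean > 0` (the direction fixed a priori:
  nonaccidental changes are detected faster).  Degenerate inputs are
  defined explicitly: all-zero differences give `t = 0, p = 0.5`; zero
  variance with nonzero mean gives the limiting `p` of 0 or 1.
* `bonferroni_flags()` — strict threshold `p < alpha / 13`; with
  `alpha = 0.05` the threshold is 0.003846, so `p = 0.005` does *not*
  survive.
* `rm_interaction_2x2()` — the condition × distance-type interaction of
  a fully within-subject 2 × 2 design, `F(1, n−1)`, used to compare
  each curvature condition against the single-line control.  With one
  observation per cell this F provably equals the squared paired t on
  difference-of-differences; the tests verify the identity to 1e-9
  against an independent hand computation.
* `model_behavior_correlation()` — Pearson r across the 78 triplets
  between the behavioural RT difference (nonaccidental − metric) and
  the jet similarity difference (`sim_nap_base − sim_mp_base`).
  Whether one correlates against similarity or dissimilarity
  differences only flips the sign of r; the convention is an explicit
  argument.

## Calibration and problem sizes

The test suite checks, under the null observer (`nap_advantage = 0`),
that the uncorrected one-tailed test rejects at the nominal 5% rate
within three Monte-Carlo standard errors over 2,000 simulated
datasets, and that power at a 60 ms advantage with 10 participants
exceeds 0.8.  These simulations use a reduced single-condition design
(6 triplets, 96 trials per participant — the same per-cell trial count
as the full experiment) so that thousands of replicates stay cheap;
the full 1,248-trial pipeline is exercised end-to-end separately and
is deterministic for a fixed seed.

## Known limitations

* Parameter magnitudes (deltas, baselines, advantages) are package
  defaults chosen for realism, not measured quantities.
* The chevron-layout gap compromise described above.
* Under the replication configuration, conditions whose stem length is
  derived from the gap cap that length at the 3 deg extent, so their
  center gaps do not reach 2.25 deg.
* The jet model uses a fixed grid without the elastic displacement
  search of the original jet-matching systems, and magnitudes only.
* The binary matched flag is fragile near symmetric perturbations, as
  discussed; condition-level similarity means are the robust readout.

```{r example, eval = FALSE}
# a reduced end-to-end run
res <- run_twoline_pipeline(seed = 1)
res$t_tests
res$audit_summary$by_condition
```
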