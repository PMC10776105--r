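---
title: "Measuring body-representation distortions in human figure drawings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring body-representation distortions in human figure drawings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drawmetry)
library(dplyr)
```

## The measurement problem

Asking a person to draw a human figure on an A4 sheet is a common clinical
probe of body representation. Stroke patients with a unilateral upper-limb
sensorimotor deficit tend to under-draw the affected arm, so the *relative
length of the two drawn arms* carries signal, while legs — typically spared
or much less affected — serve as a within-subject control body part.
`drawmetry` operationalises this: landmark coordinates clicked on a scanned
drawing become nine metric parameters in centimetres, limb pairs become an
Index of Asymmetry, and cohorts become the group statistics of a validation
study.

Two conventions matter and are fixed throughout:

* **Coordinates** are raster coordinates: origin at the page's top-left
  corner, x rightward, y downward, units pixels. A scan at `dpi` dots per
  inch converts as `cm = px / dpi × 2.54`; the default density is 150 dpi,
  so an A4 page is 1240 × 1754 px.
* **Left/right is the viewer's side** of the image. Whether the figure
  mirrors the drawer or faces them is recorded in the session's free-text
  notes only: the asymmetry index takes an absolute value, so the labelling
  choice cannot change any downstream result.

## The nine parameters

Arm length is the straight shoulder→wrist distance and leg length the
hip→ankle distance — inter-joint segments, not path lengths along drawn
strokes, which keeps the measure well-defined for sketchy or broken
contours. Shoulders and hips widths are the left-right landmark distances,
head size is the crown-to-chin (head_top→head_bottom) distance, and torso
length runs from the shoulder midpoint to the hip midpoint, which makes it
robust to an asymmetrically placed shoulder. Total height is deliberately
*not* a Euclidean distance: it is the vertical extent
`|y(figure_bottommost) − y(figure_topmost)|`, because that is what a ruler
(or graph paper) held against the sheet reads for a tilted figure. The test
suite checks the complementary invariances: the eight Euclidean parameters
are rigid-motion invariant, total height only under horizontal translation.

Missingness is data, never failure: if a limb's feature is marked absent,
or a required landmark was not placed, the parameter is `NA`. Nothing is
ever imputed as zero. A limb drawn detached from the body still contributes
its length — connectedness is a recorded characteristic, not an exclusion.
When a hand is drawn without a discernible wrist, the wrist landmark is
placed at the arm–hand junction, preserving the shoulder-to-wrist
semantics.

## The Index of Asymmetry

For a limb pair with lengths $L$ and $R$,

$$\mathrm{IoA} = \left|\frac{L - R}{L + R}\right| \times 2 \times 100,$$

algebraically identical to the absolute difference expressed as a
percentage of the pair's mean. It lives in $[0, 200]$, is symmetric in its
arguments, scale-invariant (identical in px or cm), and monotone in
$|L - R|$ at fixed $L + R$; the suite verifies all four properties over
randomized pairs. A pair with both lengths zero yields `NA` rather than 0:
a drawing with two zero-length arms carries no asymmetry information, and
reporting perfect symmetry would fabricate data.

## The statistical pipeline

**Prevalence.** Each body feature's presence counts form a 2×2 table
(group × present/absent) tested with a one-tailed Fisher exact test — the
exact hypergeometric tail, checked against full enumeration in the tests.
The default tail direction is *higher prevalence in controls*, the
direction of interest when asking whether patients' drawings are less
elaborated; it is a parameter, not a hard-coded assumption. The family of
all features is adjusted jointly with the Benjamini–Hochberg step-up
procedure (the standard reading of "FDR correction"), and significance
flags use the adjusted values at 0.05.

**Arm vs leg.** Within each group, (arm IoA, leg IoA) pairs go into a
Wilcoxon signed-rank test. Zero differences are discarded before ranking
(Wilcoxon's original policy) and ties among absolute differences get
midranks; both choices are stated because different software disagrees
here. For $n \le 25$ effective pairs the two-sided p-value is exact — the
null distribution of the positive-rank sum is built by convolution, which
equals the $2^n$ sign enumeration the tests compare against — and beyond
that a normal approximation with continuity correction and tie-corrected
variance is used, with the reported $z$ taken from that approximation. The
crossover at 25 keeps exact computation at desk scale (the convolution
support grows as $n(n+1)$, so this is conservative but cheap). Testing two
groups is two comparisons, so the per-group threshold is Bonferroni's
$0.05 / 2 = 0.025$.

**Reliability.** Agreement between two raters (or a rater and a manual
scorer) is summarised per parameter by Spearman's rho over
pairwise-complete drawings, permutation-exact for $n \le 8$ (all $n!$
permutations; at $n = 8$ that is 40&nbsp;320, well within budget) and by
the $t$ approximation beyond. Parameters with fewer than 3 complete pairs
are skipped with a logged reason rather than producing a meaningless
coefficient.

**Normality gate.** A Shapiro–Wilk helper flags
`use_nonparametric = (p < 0.05)`: evidence *against* normality routes to
rank-based tests. (Descriptions of this workflow sometimes state the gate
with the inequality inverted; that reading would route skewed data to
parametric tests, so it is treated as a typo and the conventional direction
is implemented.) The pipeline's own analyses are nonparametric throughout,
matching the skewed, bounded nature of IoA data.

## What the synthetic generator emulates

No public corpus of annotated clinical drawings exists, so the package
ships a generator whose *defaults are the study conditions*: 56 patients
and 46 controls on A4 at 150 dpi, two simulated raters with 2 px landmark
noise per coordinate.

Each subject's skeleton is built from population draws of the six
part-size parameters (head 3.0 ± 0.5 cm, torso 6.5 ± 1.0, shoulders
6.0 ± 1.0, hips 4.5 ± 0.8, arm 7.0 ± 1.0, leg 8.0 ± 1.2 — plausible
figure-drawing dimensions for an A4 sheet, roughly a 17–18 cm figure).
Draws are truncated at mean ± 2.5 SD (floored at 20% of the mean): people
scale their figure to the sheet, so the untruncated Gaussian tail is not
part of the population being modelled, and the truncation guarantees
default-parameter figures always fit the page. Arms leave the shoulders at
35° from vertical and legs at 12°, with wrists and ankles placed so the
intended length *is* the landmark distance — which is what makes the
zero-noise end-to-end recovery test exact to floating-point.

Asymmetry is modelled multiplicatively: each patient's affected side
(chosen at random) has its arm scaled by $1-\delta$ with
$\delta \sim N(0.15, 0.05)$ truncated to $[0, 0.9]$; controls have
$\delta = 0$ and legs default to no shortening, reflecting deficits that
are absent or milder at the lower limb. Independently, all four limbs in
both groups get a multiplicative per-side jitter (SD 3%): real drawings
are never perfectly symmetric, and because the jitter model is identical
for arms and legs, a no-shortening cohort has *exchangeable* arm and leg
IoA — exactly the null the level test needs. The effect-size defaults are
configuration, not clinical claims: the true distribution of patients' arm
shortening is not publicly tabulated, and a mean of 15% simply produces
the qualitative patients-significant / controls-not contrast at realistic
sample sizes.

Feature omissions are Bernoulli per feature and group, with patient
probabilities set higher for face and appearance features (ears 0.60,
clothes 0.35, nose 0.35, hair 0.30, …) than for controls — the direction
reported for real cohorts — again as configuration, not as claims about
rates. Dependent parts are kept consistent (a hand cannot outlive its
arm). Rater noise is i.i.d. Gaussian per coordinate, clipped to the page;
feature *detection* errors by raters are out of scope.

All randomness flows from one seed through named substreams — population
first, then one stream per rater — so the same seed always reproduces the
same cohort and adding a third rater leaves the skeletons and the first
two raters untouched.

What the generator does **not** emulate: stylistic variability (stick vs
contour figures, clothing occluding joints), curved or broken limb
strokes, spatial biases such as hemineglect-driven unilateral omissions,
rater disagreement about *which* point is the landmark (only where it is
clicked), and any correlation between omissions and asymmetry. Passing
tests therefore demonstrate that the measurement and inference machinery
is correct and well-calibrated under a clean generative model — not that
the pipeline is robust to every property of real clinical drawings.

## Numerical and design choices

* Session files are YAML with a required format/version header; floats are
  written with 17 significant digits so read∘write is the identity. The
  flat key-value `.txt` export is one-way (plus a reader returning the raw
  key-value pairs) and byte-deterministic.
* Exact-test crossovers: Wilcoxon exact for $n \le 25$, Spearman exact for
  $n \le 8$; both bounded by enumeration cost, both checked against
  independent brute-force oracles in the tests.
* Degenerate inputs are classed conditions, not silent values: all-zero
  differences, constant sequences, and too-short samples raise a
  `drawmetry_not_testable` condition that the batch pipeline catches and
  logs; invalid arguments (negative lengths, `dpi <= 0`, non-integer
  tables) are errors.
* Human-readable reports round to 2 decimals; CSVs keep full precision so
  reruns are byte-comparable.
* Problem sizes in the test suite were chosen for desk-scale runtimes: the
  power/level check uses 100 replicate cohorts of 52 subjects per
  condition, the IoA algebra check 10 000 random pairs, the Fisher oracle
  1000 random tables with $N \le 40$.

## Known limitations

Straight-line inter-joint distances understate the length of markedly bent
limbs; the landmark vocabulary is a fixed reconstruction and cannot encode
extra points of reference; the renderer exists for sanity checks and I/O
exercise, not perceptual realism; and the generator's effect sizes are
placeholders to be replaced by empirical estimates when real annotated
cohorts are available.
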