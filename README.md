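# drawmetry

Quantitative morphometry of human figure drawings.

Human figure drawings are a long-standing clinical probe of body
representations: after a stroke, patients' drawings can reveal distortions
in how the body's dimensions are perceived — most strikingly an asymmetry
between the drawn lengths of the two arms in patients with a unilateral
upper-limb sensorimotor deficit. `drawmetry` turns landmark annotations of
scanned drawings into reproducible numbers and group statistics for exactly
this kind of study. It is aimed at clinical researchers and methodologists
who have (or simulate) per-drawing landmark coordinates and feature-presence
records, and want the full analysis to be scriptable and seeded.

The package provides:

* **Annotation model** — a structured, human-diffable session file format
  (landmarks in pixels, one presence record per body feature), validation,
  and a flat key-value legacy text export.
* **Morphometry** — the nine metric parameters in cm: total figure height,
  head size, shoulders width, hips width, torso length, left/right arm
  length (shoulder→wrist) and left/right leg length (hip→ankle), converted
  from pixels with `length_px / dpi × 2.54` (default scan density 150 dpi).
* **Index of Asymmetry** — for a limb pair with lengths L and R,

  ```
  IoA = |(L − R) / (L + R)| × 2 × 100
  ```

  the absolute left-right difference as a percentage of the pair's average,
  in [0, 200] and invariant to units.
* **Statistics** — one-tailed Fisher exact prevalence comparisons with
  joint Benjamini–Hochberg FDR correction; Wilcoxon signed-rank arm-vs-leg
  IoA tests (enumeration-exact up to n = 25, continuity-corrected normal
  approximation beyond) at a Bonferroni-corrected 0.025 threshold; Spearman
  inter-rater reliability (permutation-exact up to n = 8); a Shapiro–Wilk
  normality gate.
* **Synthetic cohorts** — a seeded generator of figure skeletons with known
  ground truth (configurable limb-length distributions, unilateral arm
  shortening in patients, feature-omission probabilities, landmark noise
  per simulated rater), a deterministic stick-figure renderer, and a batch
  pipeline (`run_full_analysis()`) writing CSVs plus a run manifest.

## Worked example

Simulate the default study design — 56 patients with a mean 15% unilateral
arm shortening and 46 controls, annotated by two raters with 2 px landmark
noise — then test whether arm asymmetry exceeds leg asymmetry per group:

```r
library(drawmetry)

cohort <- generate_cohort(synth_config(seed = 42))
asym   <- cohort_asymmetry(cohort_measurements(cohort))
head(asym, 3)
#> # A tibble: 3 × 6
#>   subject_id drawing_id group   rater_id    arm_ioa_pct leg_ioa_pct
#> 1 P001       P001       patient sim_rater_1        7.65        7.90
#> 2 P002       P002       patient sim_rater_1       NA          10.0
#> 3 P003       P003       patient sim_rater_1       26.5         1.32

compare_limb_asymmetry(asym, group = "patient")
#> <arm_vs_leg_asymmetry>
#>   group: patient
#>   n_effective: 42
#>   n_dropped: 14
#>   statistic: 896
#>   z: 5.55163
#>   p_value: 2.83023e-08
#>   alpha_threshold: 0.025
#>   significant: TRUE
#>   method: normal approximation with continuity correction

compare_limb_asymmetry(asym, group = "control")$p_value
#> [1] 0.650845
```

Subjects whose drawings omit an arm or a leg have an undefined IoA (`NA`,
shown for `P002` above) and are dropped pairwise — `n_effective` counts the
remaining complete pairs. Here the patient group's arm IoA significantly
exceeds its leg IoA at the Bonferroni-corrected 0.025 threshold while the
control group shows no difference, the pattern the asymmetry index is
designed to detect. `tidy()` and `glance()` return the same report as a
one-row tibble; `autoplot(cohort)` draws the arm-vs-leg distributions.

A command-line front-end with `measure`, `analyze`, `simulate` and
`reliability` subcommands is installed under `inst/cli/drawmetry.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/drawmetry.R", package = "drawmetry"))')" \
  analyze --simulate --seed 7 --out out/
```

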