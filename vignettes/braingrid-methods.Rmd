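---
title: "Sub-lobar Brain-Grid topography and phenotyping of diffuse low-grade glioma: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sub-lobar Brain-Grid topography and phenotyping of diffuse low-grade glioma: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braingrid)
```

## The problem

Diffuse low-grade gliomas (DLGG) are WHO grade 2 infiltrative brain tumours
whose molecular subgroup — IDH-mutated astrocytoma, IDH-wildtype astrocytoma,
or oligodendroglioma (IDH-mutated with 1p/19q codeletion) — strongly shapes
prognosis and management, but is only known after surgery. `braingrid`
implements a clinico-radiological phenotyping pipeline that asks what can be
read off *before* surgery from lesion topography in template (MNI) space plus
routine clinical covariates: where each subgroup preferentially infiltrates,
how extensive ("invasive") each lesion is at the sub-lobar scale, which
clinical presentations separate the subgroups, and how well the subgroup can
be predicted from those variables.

The pipeline has five stages, each an exported module of the package:

1. **Grid system** — partition template space into the 48-cell sub-lobar
   Brain-Grid.
2. **Topography** — per-tumour grid occupancy, group occurrence-weighted
   frequency maps, bundle infiltration, laterality and volume.
3. **Cohort statistics** — the between-group battery with FDR control.
4. **Prediction** — symptom and diagnosis regression models with ROC/AUC and
   PPV/NPV.
5. **Synthetic cohort** — a seeded generator that emulates the cohort
   structure the analysis assumes, so every stage is testable without
   patient data (none are deposited with the source study).

## The Brain-Grid

Three axial (z), two coronal (y) and three sagittal (x) planes partition the
template bounding box into 4 × 3 × 4 = 48 axis-aligned cells ("grid
voxels"), a deliberately coarse sub-lobar reference system that is robust to
registration error and easy to reason about clinically. Cells are labelled
`A{a}C{c}S{s}` with slab indices increasing inferior→superior (A1–A4),
anterior→posterior (C1–C3) and left→right (S1–S4). The per-patient count of
infiltrated cells (`bg_voxel_count`, 1–48) is the invasiveness measure used
throughout.

Numerical conventions, chosen once and applied everywhere:

* The partition lives in **world millimetres**, through each volume's
  voxel-to-world affine; masks on other geometries are resampled to the
  template with nearest-neighbour interpolation (binary data), with a
  warning.
* Slabs are **half-open towards the higher index**: a point exactly on a
  plane belongs to the higher-index slab, so ties are impossible. In
  particular the midline x = 0 belongs to S3, and "left hemisphere" is
  exactly x < 0.
* The middle sagittal plane is required to be the midline (x = 0).

The plane coordinates themselves are anatomical landmarks that the source
literature defines on the MNI template but does not restate numerically.
`default_grid_planes()` therefore ships documented package defaults — axial
z = (−24, 8, 40), coronal y = (−40, 10), sagittal x = (−26, 0, 26) mm —
which produce anatomically plausible slabs (e.g. the insular region falls in
A3C2S2/A2C2S2). They are defaults of this implementation, not published
landmark values; studies with specific landmarks should pass their own
`grid_planes()`.

**S-numbering ambiguity.** Published usage of Brain-Grid labels is
internally ambiguous about whether sagittal indices run left→right across
the whole head or mirror within each hemisphere (the same label is used for
left- and right-sided findings in different places). We default to a fixed,
invertible left→right numbering — a deterministic convention beats guessing
the original — and provide `build_grid(..., s_numbering = "mirrored")`,
which renumbers S lateral→medial within each hemisphere and disambiguates
labels with an `.L`/`.R` suffix.

```{r grid-demo}
grid <- build_grid(default_grid_planes(), mni_geometry(6))
grid
head(grid$cells, 4)
```

## Topography

`occupancy_profile()` tallies a tumour's overlap volume with every cell. A
cell counts as infiltrated when its overlap reaches `min_overlap_mm3`,
default 0 (any presence) — the least-surprise choice, since no minimal
overlap rule is published; the threshold is exposed for sensitivity
analysis, and the infiltrated-cell set is monotone in it. At threshold 0 the
per-cell overlap volumes sum exactly to the tumour volume (a conservation
property the tests assert).

`occurrence_map()` overlays a group's masks and normalises by group size n:
each template voxel carries the percentage of the group's tumours present
there, so every value is a multiple of 100/n and the minimum nonzero
frequency is exactly 100/n (1.5% for n = 65). Per-cell group frequencies use
the any-presence rule. Report CSVs round percentages to one decimal, half
away from zero (`fmt_percent1()`), mirroring clinical table formatting.

`bundle_infiltration()` intersects a group map with a binary tract mask and
reports three scalars — coverage fraction, mean and maximum group frequency
over the bundle — because published tract analyses of this kind are
qualitative ("hot spots") and committing to a single summary would
overstate precision. Real tract masks (e.g. HCP-1065 reconstructions of AF,
SLF2-3, IFOF, CST, FAT, Ci) are consumed as NIfTI inputs;
`synthetic_bundle_masks()` provides geometric tube stand-ins for testing and
demonstration only, with no anatomical authority.

`laterality()` splits tumour volume at x = 0 and calls a lesion bilateral
when the minority-hemisphere fraction reaches 5% (default): a small-but-real
contralateral extension should count as bilateral, but the published
laterality distribution comes without its decision rule, so the threshold is
configurable. Voxels exactly on the midline count as right, consistent with
the half-open grid convention.

## Between-group statistics

`group_comparison_table()` reproduces the between-group battery:

* **Normality gate** — Kolmogorov–Smirnov with Lilliefors correction
  (`ks_normality()`, backed by `nortest::lillie.test`), reported per
  continuous variable. The correction matters because the normal's
  parameters are estimated from the same sample; the naive KS p would be
  anti-conservative.
* **Kruskal–Wallis** (`kruskal_wallis()`) for continuous variables, with tie
  correction; p-values from the χ²(k−1) approximation by default. For very
  small samples (n ≲ 12) that approximation can be off by several
  hundredths, so `p_method = "permutation"` computes a seeded Monte-Carlo
  permutation p instead; the test suite validates that route against an
  independent rank-formula oracle.
* **Pearson chi-square / Fisher exact** (`contingency_test()`) for
  categorical variables. Chi-square is computed without continuity
  correction (this reproduces the published seizure-table p-value of 0.016
  exactly); `method = "auto"` switches to Fisher whenever any expected
  count falls below 5, the standard small-sample rule — the original
  analysis does not state its switching rule. Zero-margin rows/columns are
  dropped with a warning.
* **Mood's median test** (`mood_median_test()`) for tumour volume and the
  invasiveness count: dichotomise at the pooled median with ties counted on
  the "≤ median" side (deterministic, matching common implementations),
  then Pearson chi-square on the k × 2 table.
* **Benjamini–Hochberg FDR** (`bh_fdr()`) applied once across the whole
  battery (m = number of tests in the run, recorded on the result). The
  module always adjusts raw p-values; published FDR columns computed over
  partially censored ("<0.001") entries cannot be exactly re-derived, so no
  attempt is made to parse censored strings.

All p-values are two-sided. Under null simulations (three groups of 20,
2000 replicates) the empirical size of each battery test at α = 0.05 falls
in [0.03, 0.07] (asserted in the test suite).

## Prediction models

**Symptom models.** `fit_binary_logistic()` fits maximum-likelihood
logistic models with Wald 95% intervals (exp(β ± 1.96 SE)) and Wald
p-values for reporting; `forward_conditional_select()` implements
forward-conditional stepwise building with score-test entry and
likelihood-ratio removal (the mixed conventions of standard clinical
statistics packages), thresholds p_enter = 0.05 and p_remove = 0.10 —
common defaults, since none are published — with deterministic tie-breaks
by candidate order. Quasi-separated fits (non-convergence, or |β| > 15 on
the standardised scale) are flagged `non_estimable` instead of being
reported as huge odds ratios: clinical tables of this kind contain fragile
estimates with intervals spanning three orders of magnitude, and a tool
must not reproduce such values silently.

**Diagnosis model.** `fit_multinomial()` fits a baseline-category logit
(via `nnet::multinom`) with the IDH-mutated astrocytoma group as default
reference, after a VIF collinearity check (`check_collinearity()`, flag at
VIF > 10). `classification_metrics()` derives per-class one-vs-rest
sensitivity and specificity from the **argmax** class assignment — the
published sensitivity/specificity pairs are not stated to come from
ROC-optimal thresholds — with `assignment = "youden"` available as the
alternative. AUC comes from the class's predicted probability via
`roc_auc()`, an empirical trapezoidal ROC that equals the tie-corrected
rank (Mann–Whitney) statistic and is invariant under monotone score
transformations (both asserted against an independent implementation).

**Predictive values.** `ppv_npv()` implements the closed forms

$$\mathrm{PPV} = \frac{\mathrm{Se}\,\pi}{\mathrm{Se}\,\pi + (1-\mathrm{Sp})(1-\pi)},
\qquad
\mathrm{NPV} = \frac{\mathrm{Sp}\,(1-\pi)}{\mathrm{Sp}\,(1-\pi) + (1-\mathrm{Se})\,\pi}$$

at class prevalence π. With sensitivity 0.43, specificity 0.82 and
prevalence 0.277 (the published IDH-m astrocytoma values) the NPV formula
returns 0.79, matching the published 79%. The corresponding published
IDH-wt and oligodendroglioma PPV/NPV pairs do *not* back-compute from their
printed sensitivity/specificity/prevalence through these formulas; the
inputs used for those numbers are unknown, so the package documents the
discrepancy here rather than asserting those pairs.

```{r ppv-demo}
ppv_npv(sensitivity = 0.43, specificity = 0.82, prevalence = 0.277)
```

## The synthetic cohort generator

No patient-level data are deposited with the source study, so the generator
is a first-class module that encodes the *published cohort structure* as its
defaults (`default_group_specs()`), fixed once:

* group sizes 65 / 54 / 116 (IDH-m astrocytoma / IDH-wt astrocytoma /
  oligodendroglioma);
* ages 38 ± 13, 48 ± 18, 42 ± 14 years, truncated-normal at ≥ 18 (the adult
  inclusion criterion);
* tumour volumes 60 ± 64, 53 ± 61, 47 ± 43 ml as moment-matched
  **lognormals** — SDs of the same size as the means rule out a normal
  under positivity;
* symptom prevalences, sex ratios, border/contrast rates, laterality and
  location distributions from the published per-group tables;
* invasiveness counts matched to the published per-group median/IQR
  (rounded lognormal, clamped to 1–48) when simulating covariates alone;
* per-group infiltration hotspots: (A3C2S2, A2C2S2) anterior-insular for
  IDH-m astrocytomas, (A3C2S2, A3C2S3) posterior temporo-insular for IDH-wt,
  (A3C2S2, A2C2S2) for oligodendrogliomas.

**Seizure mechanism.** The seizure indicator is generated from a logistic
model on the invasiveness count with slope ln(1.06) per grid voxel —
invasiveness, not volume, is the generative driver, mirroring the finding
that the grid-voxel count predicted seizures in every subgroup — and the
per-group intercept is calibrated by root-finding so the *marginal* seizure
prevalence matches the published one. Other symptoms are independent
Bernoulli draws: the true covariance structure among symptoms, age and
volume is unknown, and inventing one would only manufacture spurious
structure. This independence is a documented limitation.

**Masks.** Each patient gets an ellipsoidal blob centred at one of the
group's hotspot cell centroids (alternating deterministically through the
hotspot list) plus Gaussian spatial jitter (SD 8–10 mm), with mild random
anisotropy, scaled by construction to match the drawn volume to within one
voxel (the target number of voxels with smallest ellipsoidal distance is
taken, clipped to the template). `simulate_cohort()` composes the two
generators so the recorded invasiveness is the one *measured* on the
simulated masks, and the seizure indicator is then re-drawn against those
measured counts.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: infiltrative, tract-following tumour shapes
(blobs are convex ellipsoids); registration error; correlated symptom
profiles; any association between subgroup and radiological border or
contrast beyond the marginal rates; multifocality. Consequences visible in
the worked example: mask-derived invasiveness medians (≈ 6 at 4 mm
resolution) sit below the published clinical medians (7–8.5), and
mask-derived laterality is more often bilateral than the published 5.1%
because single ellipsoids near insular cells cross the midline more than
real lesions do. The cohort table therefore keeps the *drawn* (table-based)
laterality as the clinical covariate, and the mask-derived call is reported
separately.

## Problem sizes and determinism

Everything is deterministic given a seed: the generator consumes one seed
(masks and the seizure re-draw use fixed offsets of it), and rerunning any
pipeline stage with the same configuration reproduces byte-identical CSVs
(asserted in the test suite). The analysis scripts run at 4 mm template
resolution and the simulation-heavy tests at 6 mm; the grid and topography
code is resolution-generic, and these sizes were chosen as the package's
standard desk-scale configuration — coarse enough to iterate comfortably,
fine enough that every grid cell contains many voxels. Monte-Carlo checks
use 500 replicate cohorts of n = 235 for parameter recovery (the seizure
odds ratio per grid voxel is recovered with mean in [1.04, 1.08] under the
generating ln(1.06) slope, and the null-slope test keeps its 5% size) and
10 seeds for hotspot recovery.

## Known limitations

* The default grid planes are plausible, not published, landmarks; absolute
  per-cell frequencies depend on them.
* The generator's spatial model is deliberately simple (see above); it
  validates the *pipeline*, not biological claims about real DLGG.
* Fisher's exact test on tables larger than 2 × 2 uses the exact network
  algorithm where feasible and falls back to seeded Monte-Carlo; published
  analyses may have used different conventions for multi-level tables.
* Published odds ratios and AUCs from the patient-level models are not
  reproducible without the undeposited cohort; the package instead proves
  parameter recovery on its own generator.
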