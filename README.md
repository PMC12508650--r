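# braingrid

Clinico-radiological phenotyping of suspected diffuse low-grade glioma
(DLGG) cohorts in template (MNI) space, for neuro-oncology researchers who
have per-patient binary tumour segmentations registered to a common
template plus a clinical covariate table, and want to know how the three
molecular subgroups — IDH-mutated astrocytoma, IDH-wildtype astrocytoma and
oligodendroglioma — differ in topography, presentation and predictability.

The package implements, as tested and reusable R functions:

* **Brain-Grid system** — an orthogonal partition of template space by 3
  axial, 2 coronal and 3 sagittal planes into 4 × 3 × 4 = 48 labelled
  sub-lobar grid voxels (`A{a}C{c}S{s}`, half-open slabs in world mm). The
  per-patient number of infiltrated cells is the sub-lobar *invasiveness*
  measure.
* **Topography** — per-tumour grid occupancy, group occurrence-weighted
  infiltration maps (voxel value = % of the group's tumours present, so the
  minimum nonzero frequency of a group of n is exactly 100/n), white-matter
  bundle infiltration profiles (AF, SLF2-3, IFOF, CST, FAT, Ci; left/right),
  laterality calls and volumes.
* **Between-group battery** — Kolmogorov–Smirnov (Lilliefors) normality
  gate, Kruskal–Wallis, Pearson chi-square / Fisher exact (auto switch at
  expected count < 5), Mood's median test, one Benjamini–Hochberg FDR family
  per run.
* **Prediction** — univariable and forward-conditional multivariable binary
  logistic regression (score-test entry, likelihood-ratio removal,
  separation flagging), VIF collinearity check, baseline-category
  multinomial diagnosis model, empirical ROC/AUC, and the predictive-value
  closed forms

  PPV = Se·π / (Se·π + (1−Sp)(1−π)),  NPV = Sp(1−π) / (Sp(1−π) + (1−Se)π).

* **Synthetic cohort generator** — a seeded generator whose defaults encode
  the published cohort structure (group sizes 65/54/116, ages 38±13 / 48±18
  / 42±14, published symptom prevalences, lognormal volumes 60±64 / 53±61 /
  47±43 ml, group-specific hotspot cells, seizure risk linked to
  invasiveness with slope ln(1.06) per grid voxel), so the whole pipeline
  runs and is tested without patient data.

## Worked example

The `analysis/` directory is a numbered workflow over the package
(simulate → topography → group statistics → symptom models → diagnosis
model), writing its tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_topography.R
Rscript analysis/03_group_stats.R
Rscript analysis/04_symptom_models.R
Rscript analysis/05_diagnosis_model.R
```

Step 1 simulates the 235-patient cohort (65/54/116) with tumour masks at
4 mm template resolution, seed 42. Step 2 then prints, for this cohort:

```
invasiveness: median 6 BG voxels (IQR 4-8)
astro_IDHm (n=65): min/max voxel infiltration 1.5%/60.0%; top cells A2C2S2 (89.2%), A3C2S2 (78.5%)
astro_IDHwt (n=54): min/max voxel infiltration 1.9%/59.3%; top cells A3C2S3 (88.9%), A3C2S2 (75.9%)
oligo (n=116): min/max voxel infiltration 0.9%/44.8%; top cells A2C2S2 (76.7%), A3C2S2 (75.9%)
```

The minimum infiltration of the 65-patient group is 100/65 = 1.5% — a voxel
covered by exactly one tumour — and each group's hottest cells are its
generating hotspot cells, i.e. the frequency maps recover the spatial
structure put into the simulation. Step 3 runs the battery (15 tests, one
FDR family):

```
variables significant after FDR (q < 0.05):
          variable               test        p      fdr
               age     Kruskal-Wallis 5.19e-05 0.000311
          location       Fisher exact 1.00e-05 0.000150
           seizure Pearson chi-square 9.72e-04 0.003650
 cognitive_deficit Pearson chi-square 6.23e-05 0.000311
```

— age, location, seizure and cognitive deficit separate the subgroups, as
they should given the generator's group-specific settings, while volume,
sex, border and contrast (generated with identical or near-identical
distributions) stay null. Step 4 reports univariable seizure odds ratios
per Brain-Grid voxel of 1.09–1.10 per group (generating value 1.06, n per
group 54–116, hence the spread), and step 5 fits the diagnosis model:

```
per-class prediction metrics (argmax assignment):
       class   n prevalence sensitivity specificity   auc   ppv   npv flag
  astro_IDHm  65      0.277       0.077       0.976 0.653 0.556 0.735
 astro_IDHwt  54      0.230       0.611       0.912 0.858 0.673 0.887
       oligo 116      0.494       0.905       0.395 0.730 0.593 0.810
```

Sensitivity/specificity come from the argmax class assignment, AUC from
each class's predicted probability, and PPV/NPV from the closed forms at
the observed prevalences. The IDH-wt class — given distinctive cognitive
deficits, a posterior hotspot cell and central/bilateral location in the
generator — is the most predictable, echoing the clinical pattern.

A single call runs the whole pipeline programmatically:

```r
library(braingrid)
res <- run_full_pipeline(run_config(voxel_mm = 6, seed = 1), "results/full")
```

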