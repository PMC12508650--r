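Package: braingrid
Title: Sub-Lobar Brain-Grid Topography and Phenotyping of Diffuse Low-Grade Glioma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for clinico-radiological phenotyping of diffuse low-grade
    glioma (DLGG) cohorts in template (MNI) space. Partitions template space
    into the 48-cell sub-lobar Brain-Grid, computes per-tumour grid-voxel
    occupancy ("invasiveness"), group occurrence-weighted infiltration maps
    and white-matter bundle infiltration profiles, runs the between-group
    statistical battery (Kolmogorov-Smirnov normality gate, Kruskal-Wallis,
    Pearson chi-square / Fisher exact, Mood's median test) with
    Benjamini-Hochberg false-discovery-rate control, and fits symptom and
    diagnosis prediction models (binary and multinomial logistic regression
    with forward-conditional selection, ROC/AUC, PPV/NPV). A seeded synthetic
    cohort generator emulates the clinical and spatial structure the analysis
    assumes, so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    nnet,
    nortest,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
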