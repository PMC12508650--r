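#!/usr/bin/env Rscript
# Step 5 - diagnosis prediction.
#
# Multinomial (baseline-category) logistic model of the molecular diagnosis
# on the discriminating clinical/topographical variables, with the IDH-m
# astrocytoma group as reference: collinearity check (VIF), per-class
# one-vs-rest sensitivity/specificity from the argmax assignment, AUC from
# the class probability, and PPV/NPV from the closed forms at the observed
# class prevalences.

suppressMessages(library(braingrid))

cohort <- read_cohort("results/sim/cohort.csv")
occ <- read.csv("results/topography/occupancy.csv")
out <- "results/models"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cohort$age_over_40 <- as.integer(cohort$age > 40)
for (cell in c("A3C2S2", "A3C2S3")) {
  hit <- unique(occ$patient_id[occ$label == cell])
  cohort[[paste0("in_", cell)]] <- as.integer(cohort$patient_id %in% hit)
}
cohort$central_or_bilateral <- as.integer(
  cohort$laterality == "B" | cohort$location == "central")

predictors <- c("age_over_40", "seizure", "cognitive_deficit",
                "central_or_bilateral", "bg_voxel_count",
                "in_A3C2S2", "in_A3C2S3")
dm <- diagnosis_model(cohort, predictors)

cat("collinearity check (VIF):\n")
print(transform(dm$collinearity, vif = round(vif, 2)), row.names = FALSE)

metrics <- dm$metrics
num <- c("prevalence", "sensitivity", "specificity", "auc", "ppv", "npv")
metrics[num] <- lapply(metrics[num], round, 3)
write.csv(metrics, file.path(out, "diagnosis_metrics.csv"),
          row.names = FALSE)
cat("\nper-class prediction metrics (argmax assignment):\n")
print(metrics, row.names = FALSE)
cat("\nwritten to", file.path(out, "diagnosis_metrics.csv"), "\n")
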