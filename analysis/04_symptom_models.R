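#!/usr/bin/env Rscript
# Step 4 - symptom prediction models.
#
# Per molecular subgroup: univariable binary logistic regressions for
# seizure at onset over demographic, radiological and topographical
# predictors, then a forward-conditional multivariable model (score-test
# entry p < 0.05, likelihood-ratio removal p > 0.10). Fits with signs of
# separation are flagged non-estimable rather than reported as huge odds
# ratios.

suppressMessages(library(braingrid))

cohort <- read_cohort("results/sim/cohort.csv")
occ <- read.csv("results/topography/occupancy.csv")
out <- "results/models"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# hotspot-cell infiltration indicators from the occupancy table
for (cell in c("A2C2S2", "A2C2S3", "A3C2S2", "A3C2S3")) {
  hit <- unique(occ$patient_id[occ$label == cell])
  cohort[[paste0("in_", cell)]] <- as.integer(cohort$patient_id %in% hit)
}
cohort$border_diffuse <- as.integer(cohort$border == "diffuse")
predictors <- c("sex", "age", "border_diffuse", "volume_ml",
                "bg_voxel_count", "in_A2C2S2", "in_A2C2S3",
                "in_A3C2S2", "in_A3C2S3")

uni_all <- list(); multi_all <- list()
for (g in unique(cohort$group)) {
  d <- cohort[cohort$group == g, ]
  uni <- suppressWarnings(
    fit_binary_logistic(d, "seizure", predictors, univariable = TRUE))
  uni <- cbind(group = g, uni)
  uni_all[[g]] <- uni
  fwd <- suppressWarnings(
    forward_conditional_select(d, "seizure", predictors))
  cat(sprintf("%s: forward-conditional seizure model selects [%s]\n",
              g, paste(fwd$selected, collapse = ", ")))
  if (!fwd$intercept_only)
    multi_all[[g]] <- cbind(group = g, fwd$summary)
}
uni_tab <- do.call(rbind, uni_all)
num <- c("coef", "or", "ci_low", "ci_high", "p")
uni_tab[num] <- lapply(uni_tab[num], signif, 3)
write.csv(uni_tab, file.path(out, "seizure_univariable.csv"),
          row.names = FALSE)
if (length(multi_all)) {
  multi_tab <- do.call(rbind, multi_all)
  multi_tab[num] <- lapply(multi_tab[num], signif, 3)
  write.csv(multi_tab, file.path(out, "seizure_multivariable.csv"),
            row.names = FALSE)
}

cat("\nunivariable seizure odds ratios per Brain-Grid voxel (invasiveness):\n")
inv <- uni_tab[uni_tab$term == "bg_voxel_count",
               c("group", "or", "ci_low", "ci_high", "p")]
print(inv, row.names = FALSE)
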