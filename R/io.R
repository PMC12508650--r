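cohort_required_cols <- c(
  "patient_id", "group", "age", "sex", "seizure", "cognitive_deficit",
  "motor_deficit", "language_deficit", "visual_deficit", "headache",
  "asymptomatic", "border", "contrast", "volume_ml", "bg_voxel_count",
  "laterality", "location"
)

cohort_vocab <- list(
  group = c("astro_IDHm", "astro_IDHwt", "oligo"),
  sex = c("M", "F"),
  border = c("sharp", "diffuse"),
  laterality = c("L", "R", "B")
)

normalise_binary <- function(x, col) {
  if (is.logical(x)) return(as.integer(x))
  if (is.character(x)) {
    up <- toupper(trimws(x))
    if (all(up %in% c("Y", "N", "YES", "NO", "0", "1")))
      return(as.integer(up %in% c("Y", "YES", "1")))
    stop("column ", col, ": cannot interpret values as Y/N or 0/1")
  }
  if (!all(x %in% c(0, 1))) stop("column ", col, " must be 0/1 or Y/N")
  as.integer(x)
}

#' Validate a cohort table
#'
#' Schema validation for the per-patient cohort table: required columns
#' present, patient ids unique, categorical values from the controlled
#' vocabularies, ages >= 18 (adult inclusion criterion), binary indicators
#' normalised to 0/1 (Y/N accepted on read). Unknown columns are preserved
#' untouched. All offending values are reported together.
#'
#' @param cohort data frame.
#' @return the validated (normalised) data frame.
#' @export
validate_cohort <- function(cohort) {
  problems <- character(0)
  missing <- setdiff(cohort_required_cols, names(cohort))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(cohort$patient_id))
    problems <- c(problems, paste("duplicated patient_id:",
      paste(unique(cohort$patient_id[duplicated(cohort$patient_id)]),
            collapse = ", ")))
  for (col in names(cohort_vocab)) {
    bad <- setdiff(unique(as.character(cohort[[col]])), cohort_vocab[[col]])
    if (length(bad))
      problems <- c(problems,
                    paste0("column ", col, ": unknown value(s) ",
                           paste(bad, collapse = ", ")))
  }
  if (any(!is.finite(cohort$age)) || any(cohort$age < 18))
    problems <- c(problems, "column age: all ages must be finite and >= 18")
  if (length(problems))
    stop("cohort validation failed:\n  ", paste(problems, collapse = "\n  "))
  for (col in c("seizure", "cognitive_deficit", "motor_deficit",
                "language_deficit", "visual_deficit", "headache",
                "asymptomatic", "contrast"))
    cohort[[col]] <- normalise_binary(cohort[[col]], col)
  cohort$bg_voxel_count <- as.integer(cohort$bg_voxel_count)
  cohort
}

#' Read and validate a cohort CSV
#'
#' @param path CSV file with a header row.
#' @return validated cohort data frame; per-group counts are reported via
#'   a message.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort <- validate_cohort(cohort)
  tab <- table(cohort$group)
  message(sprintf("cohort: %d patients (%s)", nrow(cohort),
                  paste(names(tab), tab, sep = "=", collapse = ", ")))
  cohort
}

#' Write a cohort table to CSV
#' @param cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Bundle of the pipeline's tunable settings with their defaults: the grid
#' plane set, presence/bilaterality thresholds, stepwise-selection
#' thresholds, the template resolution used for simulation, and the RNG
#' seed. Round-trips through YAML unchanged.
#'
#' @param planes a [grid_planes()] (default [default_grid_planes()]).
#' @param min_overlap_mm3 grid-cell presence threshold (default 0).
#' @param bilateral_threshold minority-hemisphere fraction for a bilateral
#'   call (default 0.05).
#' @param p_enter,p_remove stepwise thresholds (defaults 0.05 / 0.10).
#' @param voxel_mm simulation template resolution (default 4 mm).
#' @param seed RNG seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(planes = default_grid_planes(),
                       min_overlap_mm3 = 0, bilateral_threshold = 0.05,
                       p_enter = 0.05, p_remove = 0.10,
                       voxel_mm = 4, seed = 1) {
  stopifnot(min_overlap_mm3 >= 0,
            bilateral_threshold >= 0, bilateral_threshold <= 0.5,
            p_enter > 0, p_remove > p_enter, p_remove < 1, voxel_mm > 0)
  structure(list(planes = planes, min_overlap_mm3 = min_overlap_mm3,
                 bilateral_threshold = bilateral_threshold,
                 p_enter = p_enter, p_remove = p_remove,
                 voxel_mm = voxel_mm, seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config a [run_config()].
#' @param path YAML path.
#' @return `path` invisibly; `read_run_config` returns the config.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(list(
    grid = list(axial_mm = config$planes$axial_mm,
                coronal_mm = config$planes$coronal_mm,
                sagittal_mm = config$planes$sagittal_mm),
    thresholds = list(min_overlap_mm3 = config$min_overlap_mm3,
                      bilateral_threshold = config$bilateral_threshold,
                      p_enter = config$p_enter, p_remove = config$p_remove),
    voxel_mm = config$voxel_mm,
    seed = config$seed
  ), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    planes = grid_planes(y$grid$axial_mm, y$grid$coronal_mm,
                         y$grid$sagittal_mm),
    min_overlap_mm3 = y$thresholds$min_overlap_mm3,
    bilateral_threshold = y$thresholds$bilateral_threshold,
    p_enter = y$thresholds$p_enter, p_remove = y$thresholds$p_remove,
    voxel_mm = y$voxel_mm, seed = y$seed
  )
}

#' Run the full phenotyping pipeline
#'
#' End-to-end driver: simulates (or accepts) a cohort with masks, builds
#' the Brain-Grid, computes per-patient occupancy and laterality, the three
#' group occurrence-weighted maps with their per-cell tables, the
#' between-group statistical battery with FDR, the seizure symptom models
#' (univariable and forward-conditional multivariable, per group), and the
#' multinomial diagnosis model with per-class metrics. All tabular outputs
#' are written as CSV under `out_dir`, frequency maps and the grid label
#' volume as NIfTI, plus a YAML run log (seed, config, package version).
#' Deterministic given the config seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param simulation optional pre-built [simulate_cohort()] result; by
#'   default one is simulated from [default_group_specs()] at the config's
#'   seed and resolution.
#' @return (invisibly) list with the grid, simulation, occupancy table,
#'   frequency maps, stats table, symptom models and diagnosis metrics.
#' @export
run_full_pipeline <- function(config = run_config(), out_dir,
                              simulation = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- mni_geometry(config$voxel_mm)
  grid <- build_grid(config$planes, geom)
  if (is.null(simulation))
    simulation <- simulate_cohort(default_group_specs(), grid,
                                  seed = config$seed)
  cohort <- simulation$cohort
  masks <- simulation$masks
  if (is.null(masks) || length(masks) == 0L) stop("no masks to analyse")

  # per-patient occupancy + laterality
  occ_rows <- list(); summ_rows <- list()
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    prof <- occupancy_profile(m, grid, config$min_overlap_mm3)
    lat <- laterality(m, config$bilateral_threshold)
    occ_rows[[i]] <- data.frame(patient_id = prof$patient_id,
                                label = prof$cells$label,
                                overlap_mm3 = prof$cells$overlap_mm3,
                                stringsAsFactors = FALSE)
    summ_rows[[i]] <- data.frame(patient_id = prof$patient_id,
                                 bg_voxel_count = prof$bg_voxel_count,
                                 volume_ml = prof$volume_ml,
                                 laterality = lat$call,
                                 stringsAsFactors = FALSE)
  }
  # the cohort's laterality stays the clinical (report-derived) covariate;
  # the mask-derived call is reported separately in the patient summary
  occupancy <- do.call(rbind, occ_rows)
  summary_tab <- do.call(rbind, summ_rows)
  utils::write.csv(occupancy, file.path(out_dir, "occupancy.csv"),
                   row.names = FALSE)
  utils::write.csv(summary_tab, file.path(out_dir, "patient_summary.csv"),
                   row.names = FALSE)
  write_volume(rasterize_grid(grid), file.path(out_dir, "grid_labels.nii.gz"))
  write_grid_table(grid, file.path(out_dir, "grid_cells.csv"))

  # group occurrence-weighted maps
  maps <- list()
  for (g in unique(cohort$group)) {
    gm <- occurrence_map(masks[cohort$patient_id[cohort$group == g]],
                         grid, group = g)
    maps[[g]] <- gm
    write_volume(gm$frequency,
                 file.path(out_dir, paste0("freqmap_", g, ".nii.gz")))
    tab <- gm$cell_table
    tab$percent <- fmt_percent1(tab$percent)
    utils::write.csv(tab, file.path(out_dir, paste0("cells_", g, ".csv")),
                     row.names = FALSE)
  }

  # between-group battery
  stats_tab <- group_comparison_table(cohort)
  utils::write.csv(stats_tab, file.path(out_dir, "group_comparisons.csv"),
                   row.names = FALSE)

  # seizure symptom models per group (univariable + forward conditional)
  predictors <- c("sex", "age", "border", "volume_ml", "bg_voxel_count")
  symptom <- list()
  for (g in unique(cohort$group)) {
    d <- cohort[cohort$group == g, ]
    uni <- fit_binary_logistic(d, "seizure", predictors, univariable = TRUE)
    fwd <- forward_conditional_select(d, "seizure", predictors,
                                      config$p_enter, config$p_remove)
    uni$group <- g
    symptom[[g]] <- list(univariable = uni, multivariable = fwd)
  }
  uni_all <- do.call(rbind, lapply(symptom, `[[`, "univariable"))
  utils::write.csv(uni_all, file.path(out_dir, "seizure_univariable.csv"),
                   row.names = FALSE)
  multi_rows <- do.call(rbind, lapply(names(symptom), function(g) {
    s <- symptom[[g]]$multivariable$summary
    if (is.null(s)) return(NULL)
    s$group <- g
    s
  }))
  if (!is.null(multi_rows))
    utils::write.csv(multi_rows,
                     file.path(out_dir, "seizure_multivariable.csv"),
                     row.names = FALSE)

  # diagnosis model + metrics
  diag <- diagnosis_model(cohort)
  utils::write.csv(diag$metrics, file.path(out_dir, "diagnosis_metrics.csv"),
                   row.names = FALSE)
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  yaml::write_yaml(list(
    seed = config$seed,
    voxel_mm = config$voxel_mm,
    package_version = as.character(utils::packageVersion("braingrid")),
    n_patients = nrow(cohort),
    groups = as.list(table(cohort$group))
  ), file.path(out_dir, "run_log.yaml"))

  invisible(list(grid = grid, simulation = simulation,
                 occupancy = occupancy, patient_summary = summary_tab,
                 maps = maps, stats = stats_tab, symptom = symptom,
                 diagnosis = diag))
}
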