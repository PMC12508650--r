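#' Default molecular-subgroup specifications
#'
#' Generator settings for the three suspected-DLGG molecular subgroups,
#' taken from the published cohort summaries: group sizes 65/54/116; ages
#' 38+/-13, 48+/-18, 42+/-14 years (truncated at 18, the adult inclusion
#' criterion); symptom prevalences and laterality distributions from the
#' clinical tables; volumes 60+/-64, 53+/-61, 47+/-43 ml (lognormal,
#' moment-matched, since SDs of this size rule out a normal under
#' positivity); invasiveness (Brain-Grid voxel count) matched to the printed
#' per-group median/IQR; and per-group infiltration hotspots - anterior
#' insular (IDH-m astrocytoma), left posterior temporo-insular (IDH-wt) and
#' bifrontal right-leaning (oligodendroglioma). Seizure risk is linked to
#' invasiveness through a logistic model with slope ln(1.06) per Brain-Grid
#' voxel; the intercept is calibrated per group so the marginal seizure
#' prevalence matches the specification.
#'
#' @return named list of three `group_spec` lists
#'   (`astro_IDHm`, `astro_IDHwt`, `oligo`).
#' @export
default_group_specs <- function() {
  spec <- function(name, n, age_mean, age_sd, male, prev, vol_mean, vol_sd,
                   bg_median, bg_q1, bg_q3, hotspots, jitter_sd_mm, lat, loc) {
    list(name = name, n = n, age_mean = age_mean, age_sd = age_sd,
         male_fraction = male, prevalence = prev,
         volume_mean_ml = vol_mean, volume_sd_ml = vol_sd,
         bg_median = bg_median, bg_q1 = bg_q1, bg_q3 = bg_q3,
         hotspots = hotspots, jitter_sd_mm = jitter_sd_mm,
         seizure_slope = log(1.06),
         laterality_probs = lat, location_probs = loc,
         border_diffuse = NA, contrast = NA)
  }
  prev_names <- c("seizure", "cognitive_deficit", "motor_deficit",
                  "language_deficit", "visual_deficit", "headache",
                  "asymptomatic")
  s1 <- spec("astro_IDHm", 65, 38, 13, 0.554,
             setNames(c(0.523, 0.092, 0.108, 0.077, 0.062, 0.262, 0.138),
                      prev_names),
             60, 64, 7, 3, 13,
             hotspots = c("A3C2S2", "A2C2S2"), jitter_sd_mm = 8,
             lat = c(L = 35, R = 28, B = 2) / 65,
             loc = c(frontal = 35, temporal = 16, parietal = 9, occipital = 0,
                     insula = 5, central = 0) / 65)
  s1$border_diffuse <- 0.600; s1$contrast <- 0.138
  s2 <- spec("astro_IDHwt", 54, 48, 18, 0.519,
             setNames(c(0.444, 0.259, 0.185, 0.148, 0.130, 0.185, 0.167),
                      prev_names),
             53, 61, 8.5, 4, 12,
             hotspots = c("A3C2S2", "A3C2S3"), jitter_sd_mm = 8,
             lat = c(L = 24, R = 23, B = 7) / 54,
             loc = c(frontal = 20, temporal = 16, parietal = 3, occipital = 1,
                     insula = 4, central = 10) / 54)
  s2$border_diffuse <- 0.741; s2$contrast <- 0.298
  s3 <- spec("oligo", 116, 42, 14, 0.526,
             setNames(c(0.664, 0.026, 0.095, 0.043, 0.043, 0.155, 0.164),
                      prev_names),
             47, 43, 8, 4, 10,
             hotspots = c("A3C2S2", "A2C2S2"), jitter_sd_mm = 10,
             lat = c(L = 56, R = 57, B = 3) / 116,
             loc = c(frontal = 81, temporal = 13, parietal = 8, occipital = 5,
                     insula = 8, central = 1) / 116)
  s3$border_diffuse <- 0.586; s3$contrast <- 0.250
  list(astro_IDHm = s1, astro_IDHwt = s2, oligo = s3)
}

# moment-matched lognormal parameters for a positive variable with given
# mean and sd
lognormal_params <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# lognormal matched to a median and IQR (meanlog = log median, sdlog from
# the quartile spread)
lognormal_from_quartiles <- function(med, q1, q3) {
  c(meanlog = log(med), sdlog = (log(q3) - log(q1)) / (2 * stats::qnorm(0.75)))
}

# truncated-normal draw by rejection (cheap at these truncation levels)
rtruncnorm_min <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- out < lower
  while (any(bad)) {
    out[bad] <- rnorm(sum(bad), mean, sd)
    bad <- out < lower
  }
  out
}

# intercept alpha such that mean(plogis(alpha + slope * x)) == target
calibrate_intercept <- function(target, slope, x) {
  f <- function(a) mean(plogis(a + slope * x)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0)
    stop("unsatisfiable seizure-prevalence calibration")
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Simulate per-patient clinical covariates
#'
#' Draws a cohort table from group specifications: truncated-normal ages
#' (>= 18), moment-matched lognormal tumour volumes, an invasiveness count
#' (Brain-Grid voxels, rounded lognormal matched to the per-group
#' median/IQR, clamped to 1..48), a seizure indicator from the logistic
#' invasiveness link with the group intercept calibrated to the marginal
#' prevalence, and remaining symptoms/categoricals as independent draws.
#' Fully deterministic given `seed`.
#'
#' @param specs list of group specs ([default_group_specs()] by default).
#' @param seed integer RNG seed.
#' @param bg_counts optional named-by-nothing integer vector (length = total
#'   n, in group order) of invasiveness counts to use instead of drawing
#'   them - used when counts come from simulated masks.
#' @return cohort data frame (one row per patient) with the standard schema
#'   columns.
#' @export
simulate_covariates <- function(specs = default_group_specs(), seed = 1,
                                bg_counts = NULL) {
  set.seed(seed)
  offset <- 0L
  tabs <- lapply(specs, function(sp) {
    n <- sp$n
    age <- rtruncnorm_min(n, sp$age_mean, sp$age_sd, 18)
    vp <- lognormal_params(sp$volume_mean_ml, sp$volume_sd_ml)
    vol <- rlnorm(n, vp["meanlog"], vp["sdlog"])
    if (is.null(bg_counts)) {
      bp <- lognormal_from_quartiles(sp$bg_median, sp$bg_q1, sp$bg_q3)
      bg <- pmin(pmax(round(rlnorm(n, bp["meanlog"], bp["sdlog"])), 1L), 48L)
    } else {
      bg <- bg_counts[offset + seq_len(n)]
    }
    offset <<- offset + n
    alpha <- calibrate_intercept(sp$prevalence[["seizure"]],
                                 sp$seizure_slope, bg)
    seizure <- rbinom(n, 1, plogis(alpha + sp$seizure_slope * bg))
    sym <- function(nm) rbinom(n, 1, sp$prevalence[[nm]])
    data.frame(
      patient_id = sprintf("%s_%03d", sp$name, seq_len(n)),
      group = sp$name,
      age = age,
      sex = ifelse(runif(n) < sp$male_fraction, "M", "F"),
      seizure = seizure,
      cognitive_deficit = sym("cognitive_deficit"),
      motor_deficit = sym("motor_deficit"),
      language_deficit = sym("language_deficit"),
      visual_deficit = sym("visual_deficit"),
      headache = sym("headache"),
      asymptomatic = sym("asymptomatic"),
      border = ifelse(runif(n) < sp$border_diffuse, "diffuse", "sharp"),
      contrast = rbinom(n, 1, sp$contrast),
      volume_ml = vol,
      bg_voxel_count = as.integer(bg),
      laterality = sample(names(sp$laterality_probs), n, replace = TRUE,
                          prob = sp$laterality_probs),
      location = sample(names(sp$location_probs), n, replace = TRUE,
                        prob = sp$location_probs),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

# Ellipsoidal blob of exactly `target_n` voxels (when the template allows)
# centred at `centre` (mm) with mild random anisotropy: the target_n voxels
# with the smallest ellipsoidal distance are taken, restricted to a local
# bounding box for speed.
ellipsoid_mask <- function(geometry, centre, target_n, axis_ratios) {
  vox <- geometry$voxel_mm3
  r0 <- (3 * target_n * vox / (4 * pi * prod(axis_ratios)))^(1 / 3)
  half <- 2.0 * r0 * axis_ratios + 2 * vox^(1 / 3)
  inv <- solve(geometry$affine)
  corners <- as.matrix(expand.grid(x = centre[1] + c(-1, 1) * half[1],
                                   y = centre[2] + c(-1, 1) * half[2],
                                   z = centre[3] + c(-1, 1) * half[3]))
  ijk <- t(inv %*% rbind(t(corners), 1))[, 1:3, drop = FALSE]
  lo <- pmax(floor(apply(ijk, 2, min)), 0)
  hi <- pmin(ceiling(apply(ijk, 2, max)), geometry$dim - 1)
  if (any(lo > hi)) stop("blob centre outside the template")
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  A <- geometry$affine
  sub <- c(length(ii), length(jj), length(kk))
  comp <- function(r) {
    array(rep(A[r, 1] * ii, times = sub[2] * sub[3]), dim = sub) +
      array(rep(rep(A[r, 2] * jj, each = sub[1]), times = sub[3]), dim = sub) +
      array(rep(A[r, 3] * kk, each = sub[1] * sub[2]), dim = sub) + A[r, 4]
  }
  d2 <- ((comp(1) - centre[1]) / axis_ratios[1])^2 +
        ((comp(2) - centre[2]) / axis_ratios[2])^2 +
        ((comp(3) - centre[3]) / axis_ratios[3])^2
  n_take <- min(target_n, length(d2))
  sel <- order(as.vector(d2))[seq_len(n_take)]
  out <- array(0L, dim = geometry$dim)
  sub_idx <- arrayInd(sel, sub)
  lin <- 1 + (lo[1] + sub_idx[, 1] - 1) +
    geometry$dim[1] * ((lo[2] + sub_idx[, 2] - 1) +
                       geometry$dim[2] * (lo[3] + sub_idx[, 3] - 1))
  out[lin] <- 1L
  out
}

#' Simulate tumour masks with group-specific hotspots
#'
#' For each patient an ellipsoidal blob is placed at one of the group's
#' hotspot grid-cell centroids (alternating deterministically through the
#' list), displaced by the group's fixed hotspot shift plus Gaussian
#' spatial jitter, and scaled so the mask volume matches the drawn tumour
#' volume to within one voxel (clipped to the template). Deterministic
#' given `seed`.
#'
#' @param cohort cohort table from [simulate_covariates()] (uses `group`
#'   and `volume_ml`).
#' @param specs group specs (must match the cohort's groups).
#' @param grid a [build_grid()] result defining geometry and hotspot cells.
#' @param seed integer RNG seed.
#' @return named list of binary `brain_volume` masks, one per patient.
#' @export
simulate_masks <- function(cohort, specs, grid, seed = 1) {
  stopifnot(inherits(grid, "brain_grid"))
  set.seed(seed + 1L)
  vox <- grid$geometry$voxel_mm3
  total_vox <- prod(grid$geometry$dim)
  cells <- grid$cells
  masks <- vector("list", nrow(cohort))
  names(masks) <- cohort$patient_id
  per_group_counter <- setNames(rep(0L, length(specs)), names(specs))
  for (i in seq_len(nrow(cohort))) {
    sp <- specs[[cohort$group[i]]]
    per_group_counter[sp$name] <- per_group_counter[sp$name] + 1L
    hs <- sp$hotspots[1 + (per_group_counter[sp$name] - 1L) %% length(sp$hotspots)]
    row <- cells[cells$label == hs, ]
    if (nrow(row) != 1L) stop("hotspot label not in grid: ", hs)
    centre <- c(row$centroid_x, row$centroid_y, row$centroid_z) +
      rnorm(3, 0, sp$jitter_sd_mm)
    target_n <- max(1L, round(cohort$volume_ml[i] * 1000 / vox))
    if (target_n > total_vox)
      stop("requested volume exceeds the template volume")
    ratios <- runif(3, 0.75, 1.3)
    ratios <- ratios / prod(ratios)^(1 / 3)
    arr <- ellipsoid_mask(grid$geometry, centre, target_n, ratios)
    masks[[i]] <- brain_volume(arr, grid$geometry, id = cohort$patient_id[i])
  }
  masks
}

#' Simulate a full synthetic cohort (covariates + masks)
#'
#' Composes the covariate and mask generators so the recorded invasiveness
#' is the one actually measured on the simulated masks: covariates are
#' drawn, masks are simulated to match the drawn volumes and group
#' hotspots, the Brain-Grid occupancy of each mask replaces the drawn
#' invasiveness count, and the seizure indicator is re-drawn from the
#' calibrated logistic link on the measured counts. Fully deterministic
#' given `seed`.
#'
#' @param specs group specs.
#' @param grid a [build_grid()] result.
#' @param seed integer RNG seed.
#' @param masks if FALSE, covariates only (fast path).
#' @return list of class `synthetic_cohort`: `cohort` (data frame),
#'   `masks` (list or NULL), `seed`, `specs`.
#' @export
simulate_cohort <- function(specs = default_group_specs(), grid = NULL,
                            seed = 1, masks = TRUE) {
  cohort <- simulate_covariates(specs, seed)
  mask_list <- NULL
  if (masks) {
    stopifnot(inherits(grid, "brain_grid"))
    mask_list <- simulate_masks(cohort, specs, grid, seed)
    bg <- vapply(mask_list,
                 function(m) occupancy_profile(m, grid)$bg_voxel_count, 0L)
    cohort$bg_voxel_count <- as.integer(bg)
    cohort$volume_ml <- vapply(mask_list, volume_ml, 0)
    # re-draw seizures against the measured invasiveness, per group
    set.seed(seed + 2L)
    for (g in names(specs)) {
      sel <- cohort$group == g
      sp <- specs[[g]]
      alpha <- calibrate_intercept(sp$prevalence[["seizure"]],
                                   sp$seizure_slope,
                                   cohort$bg_voxel_count[sel])
      cohort$seizure[sel] <- rbinom(sum(sel), 1,
        plogis(alpha + sp$seizure_slope * cohort$bg_voxel_count[sel]))
    }
  }
  structure(list(cohort = cohort, masks = mask_list, seed = seed,
                 specs = specs),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d patients (%s), %s, seed %d\n",
              nrow(x$cohort),
              paste(table(x$cohort$group)[unique(x$cohort$group)],
                    collapse = "/"),
              if (is.null(x$masks)) "no masks" else "with masks", x$seed))
  invisible(x)
}

#' End-to-end parameter-recovery report
#'
#' Simulates `reps` covariate cohorts under a chosen seizure-invasiveness
#' slope, refits the logistic model (seizure ~ group + invasiveness) on
#' each, and reports the mean estimated odds ratio per Brain-Grid voxel,
#' the Monte-Carlo standard error, and the rejection rate of the Wald test
#' at alpha = 0.05 (power under the alternative; type-I error when
#' `slope = 0`).
#'
#' @param seed integer RNG seed.
#' @param reps number of simulated cohorts (default 500).
#' @param slope generating log-odds slope per Brain-Grid voxel (default
#'   ln(1.06)).
#' @param specs group specs; `slope` overrides each group's
#'   `seizure_slope`.
#' @return list: `mean_or`, `se_or`, `or_estimates`, `rejection_rate`,
#'   `slope`, `reps`.
#' @export
end_to_end_recovery <- function(seed = 1, reps = 500, slope = log(1.06),
                                specs = default_group_specs()) {
  for (g in names(specs)) specs[[g]]$seizure_slope <- slope
  ors <- numeric(reps)
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    cohort <- simulate_covariates(specs, seed = seed + r)
    fit <- suppressWarnings(glm(seizure ~ group + bg_voxel_count,
                                data = cohort, family = binomial()))
    est <- coef(summary(fit))["bg_voxel_count", ]
    ors[r] <- exp(est["Estimate"])
    rej[r] <- est["Pr(>|z|)"] < 0.05
  }
  list(mean_or = mean(ors), se_or = sd(ors) / sqrt(reps),
       or_estimates = ors, rejection_rate = mean(rej),
       slope = slope, reps = reps)
}

# Voxels within `radius_mm` of a polyline sampled at `pts` (n x 3, mm).
tube_mask <- function(geometry, pts, radius_mm) {
  X <- voxel_world_coords(geometry, 1)
  Y <- voxel_world_coords(geometry, 2)
  Z <- voxel_world_coords(geometry, 3)
  d2min <- array(Inf, geometry$dim)
  for (i in seq_len(nrow(pts))) {
    d2 <- (X - pts[i, 1])^2 + (Y - pts[i, 2])^2 + (Z - pts[i, 3])^2
    d2min <- pmin(d2min, d2)
  }
  array(1L * (d2min <= radius_mm^2), geometry$dim)
}

# quadratic Bezier sampled at m points
bezier3 <- function(p0, p1, p2, m = 40) {
  t <- seq(0, 1, length.out = m)
  (1 - t)^2 %o% p0 + 2 * t * (1 - t) %o% p1 + t^2 %o% p2
}

#' Synthetic white-matter bundle masks
#'
#' Geometric stand-ins for the six bundle masks the tract-infiltration
#' profiling consumes (arcuate fasciculus AF, superior longitudinal
#' fasciculus SLF2-3, inferior fronto-occipital fasciculus IFOF,
#' cortico-spinal tract CST, frontal aslant tract FAT, cingulum Ci; left
#' and right). Each is a tube of the given radius around a smooth curve
#' placed at roughly anatomical coordinates in template space. These are
#' synthetic shapes for pipeline testing and demonstration - they are not
#' tractography reconstructions and carry no anatomical authority.
#'
#' @param geometry a [template_geometry()].
#' @param radius_mm tube radius (default 7 mm).
#' @return named list of 12 binary `brain_volume`s
#'   (`AF_L`, `AF_R`, ..., `Ci_R`).
#' @export
synthetic_bundle_masks <- function(geometry, radius_mm = 7) {
  paths <- list(
    AF   = bezier3(c(-45, -42, -8), c(-42, -25, 32), c(-44, 12, 14)),
    SLF2.3 = bezier3(c(-34, 28, 22), c(-36, -8, 34), c(-34, -44, 24)),
    IFOF = bezier3(c(-27, 32, -4), c(-30, -20, 4), c(-27, -72, 0)),
    CST  = bezier3(c(-20, -30, -52), c(-24, -22, 5), c(-22, -18, 58)),
    FAT  = bezier3(c(-24, 14, 54), c(-34, 18, 30), c(-44, 16, 6)),
    Ci   = bezier3(c(-8, 28, 8), c(-8, -8, 36), c(-8, -44, 14))
  )
  out <- list()
  for (nm in names(paths)) {
    p <- paths[[nm]]
    out[[paste0(nm, "_L")]] <- brain_volume(
      tube_mask(geometry, p, radius_mm), geometry, id = paste0(nm, "_L"))
    pr <- p; pr[, 1] <- -pr[, 1]
    out[[paste0(nm, "_R")]] <- brain_volume(
      tube_mask(geometry, pr, radius_mm), geometry, id = paste0(nm, "_R"))
  }
  out
}
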