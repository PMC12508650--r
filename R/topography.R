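#' Per-tumour grid-voxel occupancy ("invasiveness")
#'
#' Tallies the tumour's overlap volume with every Brain-Grid cell and reports
#' the cells whose overlap reaches `min_overlap_mm3`. The number of occupied
#' grid voxels (`bg_voxel_count`) is the sub-lobar invasiveness measure used
#' throughout the pipeline. At the default threshold of 0 mm^3 (any nonzero
#' overlap counts as presence), per-cell overlap volumes sum exactly to the
#' tumour volume.
#'
#' @param mask binary `brain_volume` (nonempty); resampled to the grid's
#'   geometry (nearest neighbour) if needed.
#' @param grid a [build_grid()] result.
#' @param min_overlap_mm3 minimal overlap volume (mm^3) for a cell to count
#'   as infiltrated; default 0 (any presence).
#' @return object of class `occupancy_profile`: data frame `cells`
#'   (label, code, n_voxels, overlap_mm3), `bg_voxel_count`, `volume_ml`,
#'   `patient_id`.
#' @export
occupancy_profile <- function(mask, grid, min_overlap_mm3 = 0) {
  stopifnot(inherits(mask, "brain_volume"), inherits(grid, "brain_grid"))
  mask <- conform_to(mask, grid$geometry)
  if (sum(mask$data != 0) == 0L) stop("empty mask: nothing to profile")
  vox <- grid$geometry$voxel_mm3
  counts <- tabulate(grid$label_volume[mask$data != 0], nbins = 48L)
  overlap <- counts * vox
  keep <- counts > 0L & overlap >= min_overlap_mm3
  cells <- data.frame(
    label = grid$cells$label[keep],
    code = grid$cells$code[keep],
    n_voxels = counts[keep],
    overlap_mm3 = overlap[keep],
    stringsAsFactors = FALSE
  )
  structure(
    list(cells = cells,
         bg_voxel_count = nrow(cells),
         volume_ml = sum(counts) * vox / 1000,
         patient_id = mask$id,
         min_overlap_mm3 = min_overlap_mm3),
    class = "occupancy_profile"
  )
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat(sprintf("occupancy profile%s: %d BG voxels, %.1f ml\n",
              if (is.null(x$patient_id)) "" else paste0(" [", x$patient_id, "]"),
              x$bg_voxel_count, x$volume_ml))
  invisible(x)
}

#' Group occurrence-weighted infiltration map
#'
#' Overlays a group's tumour masks and normalises to the group size: each
#' template voxel carries the percentage of the group's tumours present
#' there (so every value is a multiple of 100/n and the minimum nonzero
#' frequency is exactly 100/n). A per-grid-cell table gives the percentage
#' of patients with any presence in each Brain-Grid cell.
#'
#' @param masks nonempty list of binary `brain_volume`s on (or resampled to)
#'   the grid geometry.
#' @param grid a [build_grid()] result.
#' @param group group name carried on the result.
#' @return object of class `frequency_map`: `frequency` (a `brain_volume`,
#'   percent 0-100), `cell_table` (label, n_infiltrated, percent), `n`,
#'   `group`.
#' @export
occurrence_map <- function(masks, grid, group = "group") {
  stopifnot(inherits(grid, "brain_grid"))
  if (length(masks) == 0L) stop("empty mask list")
  n <- length(masks)
  acc <- array(0L, dim = grid$geometry$dim)
  cell_hits <- integer(48)
  for (m in masks) {
    m <- conform_to(m, grid$geometry)
    nz <- m$data != 0
    acc <- acc + nz
    cell_hits <- cell_hits +
      (tabulate(grid$label_volume[nz], nbins = 48L) > 0L)
  }
  freq <- brain_volume(100 * acc / n, grid$geometry,
                       id = paste0(group, "_frequency"))
  cell_table <- data.frame(
    label = grid$cells$label,
    code = grid$cells$code,
    n_infiltrated = cell_hits,
    percent = 100 * cell_hits / n,
    stringsAsFactors = FALSE
  )
  structure(list(frequency = freq, cell_table = cell_table,
                 n = n, group = group),
            class = "frequency_map")
}

#' @export
print.frequency_map <- function(x, ...) {
  top <- x$cell_table[which.max(x$cell_table$percent), ]
  cat(sprintf("occurrence map [%s], n = %d; hottest cell %s (%.1f%%)\n",
              x$group, x$n, top$label, top$percent))
  invisible(x)
}

#' Minimum (nonzero) and maximum infiltration frequency of a map
#'
#' The minimum is over strictly positive voxels (for a group of n tumours it
#' is 100/n whenever any voxel is covered by exactly one tumour); the
#' maximum is over all voxels.
#'
#' @param map a [occurrence_map()] result.
#' @return named numeric vector `c(min = , max = )`, in percent.
#' @export
minmax_frequency <- function(map) {
  stopifnot(inherits(map, "frequency_map"))
  v <- map$frequency$data
  pos <- v[v > 0]
  if (length(pos) == 0L) stop("all-zero frequency map: minimum undefined")
  c(min = min(pos), max = max(v))
}

#' White-matter bundle infiltration profile
#'
#' Intersects a group frequency map with a binary bundle (tract) mask and
#' summarises infiltration with three scalars: the fraction of bundle voxels
#' with nonzero group frequency (coverage), and the mean and maximum group
#' frequency over the bundle. If the per-patient masks are supplied, a
#' per-patient any-overlap indicator is returned as well.
#'
#' @param map a [occurrence_map()] result.
#' @param bundle_mask nonempty binary `brain_volume` for the tract, on (or
#'   resampled to) the map geometry.
#' @param name bundle name, e.g. `"IFOF_L"`.
#' @param masks optional list of the group's tumour masks for the
#'   per-patient indicators.
#' @return object of class `bundle_profile`: `name`, `coverage_fraction`,
#'   `mean_frequency`, `max_frequency`, and `patient_overlap` (logical
#'   vector or NULL).
#' @export
bundle_infiltration <- function(map, bundle_mask, name, masks = NULL) {
  stopifnot(inherits(map, "frequency_map"),
            inherits(bundle_mask, "brain_volume"))
  bundle_mask <- conform_to(bundle_mask, map$frequency$geometry)
  inb <- bundle_mask$data != 0
  if (!any(inb)) stop("empty bundle mask")
  f <- map$frequency$data[inb]
  overlap <- NULL
  if (!is.null(masks)) {
    overlap <- vapply(masks, function(m) {
      m <- conform_to(m, map$frequency$geometry)
      any(m$data[inb] != 0)
    }, logical(1))
  }
  structure(list(name = name,
                 coverage_fraction = mean(f > 0),
                 mean_frequency = mean(f),
                 max_frequency = max(f),
                 n_bundle_voxels = sum(inb),
                 patient_overlap = overlap),
            class = "bundle_profile")
}

#' @export
print.bundle_profile <- function(x, ...) {
  cat(sprintf("bundle %s: coverage %.2f, mean %.1f%%, max %.1f%%\n",
              x$name, x$coverage_fraction, x$mean_frequency,
              x$max_frequency))
  invisible(x)
}

#' Tumour laterality call
#'
#' Splits the tumour volume at the interhemispheric midline (world x = 0;
#' voxels exactly at x = 0 count as right, matching the grid's half-open
#' convention) and calls the lesion bilateral when the minority-hemisphere
#' fraction reaches `bilateral_threshold`, otherwise the majority side.
#'
#' @param mask nonempty binary `brain_volume`.
#' @param bilateral_threshold minority-hemisphere volume fraction at or
#'   above which the call is `"B"`; default 0.05.
#' @return object of class `laterality_call`: `call` (`"L"`, `"R"` or
#'   `"B"`), `left_fraction`, `right_fraction`.
#' @export
laterality <- function(mask, bilateral_threshold = 0.05) {
  stopifnot(inherits(mask, "brain_volume"))
  nz <- mask$data != 0
  if (!any(nz)) stop("empty mask: laterality undefined")
  x <- voxel_world_coords(mask$geometry, 1)
  left <- sum(x[nz] < 0)
  total <- sum(nz)
  lf <- left / total
  minority <- min(lf, 1 - lf)
  call <- if (minority >= bilateral_threshold) "B" else if (lf > 0.5) "L" else "R"
  structure(list(call = call, left_fraction = lf, right_fraction = 1 - lf,
                 bilateral_threshold = bilateral_threshold),
            class = "laterality_call")
}

#' @export
print.laterality_call <- function(x, ...) {
  cat(sprintf("laterality %s (left fraction %.3f)\n", x$call, x$left_fraction))
  invisible(x)
}

#' Tumour volume in millilitres
#'
#' @param mask a binary `brain_volume`.
#' @return volume in ml (nonzero voxel count x voxel volume / 1000).
#' @export
volume_ml <- function(mask) {
  stopifnot(inherits(mask, "brain_volume"))
  sum(mask$data != 0) * mask$geometry$voxel_mm3 / 1000
}

#' Round a percentage to one decimal, half away from zero
#'
#' Report formatting used in the pipeline's CSV outputs, mirroring clinical
#' table conventions (100 * 1/65 prints as 1.5).
#' @param x numeric vector of percentages.
#' @return numeric vector rounded to 1 decimal, half-up.
#' @export
fmt_percent1 <- function(x) floor(x * 10 + 0.5) / 10
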