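#' Brain-Grid plane set
#'
#' The Brain-Grid partitions template space with three axial (z), two coronal
#' (y) and three sagittal (x) planes; their intersections define 48 sub-lobar
#' grid voxels. Planes are given as world-space millimetre coordinates on the
#' template; the middle sagittal plane must sit on the interhemispheric
#' midline (x = 0).
#'
#' @param axial_mm three strictly increasing z coordinates (mm).
#' @param coronal_mm two strictly increasing y coordinates (mm).
#' @param sagittal_mm three strictly increasing x coordinates (mm); the
#'   middle one must be 0.
#' @return object of class `plane_set`.
#' @export
grid_planes <- function(axial_mm, coronal_mm, sagittal_mm) {
  axial_mm <- as.numeric(axial_mm)
  coronal_mm <- as.numeric(coronal_mm)
  sagittal_mm <- as.numeric(sagittal_mm)
  if (length(axial_mm) != 3L || length(coronal_mm) != 2L ||
      length(sagittal_mm) != 3L)
    stop("need exactly 3 axial, 2 coronal and 3 sagittal plane coordinates")
  if (!all(is.finite(c(axial_mm, coronal_mm, sagittal_mm))))
    stop("plane coordinates must be finite")
  if (any(diff(axial_mm) <= 0) || any(diff(coronal_mm) <= 0) ||
      any(diff(sagittal_mm) <= 0))
    stop("plane coordinates must be strictly increasing within each axis")
  if (sagittal_mm[2] != 0)
    stop("the middle sagittal plane must be the midline (x = 0)")
  structure(list(axial_mm = axial_mm, coronal_mm = coronal_mm,
                 sagittal_mm = sagittal_mm),
            class = "plane_set")
}

#' Default Brain-Grid planes
#'
#' Package defaults producing anatomically plausible sub-lobar slabs on the
#' MNI 2 mm template. These are documented defaults of this implementation,
#' not published anatomical landmark coordinates; studies with specific
#' landmarks should pass their own [grid_planes()].
#'
#' @return a [grid_planes()] object.
#' @export
default_grid_planes <- function() {
  grid_planes(axial_mm = c(-24, 8, 40),
              coronal_mm = c(-40, 10),
              sagittal_mm = c(-26, 0, 26))
}

#' @export
print.plane_set <- function(x, ...) {
  cat("Brain-Grid planes (mm):\n",
      " axial z:    ", paste(x$axial_mm, collapse = ", "), "\n",
      " coronal y:  ", paste(x$coronal_mm, collapse = ", "), "\n",
      " sagittal x: ", paste(x$sagittal_mm, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Slab indices for world coordinates (vectorised). Conventions:
#   A (axial)    1..4, inferior -> superior (increasing z)
#   C (coronal)  1..3, anterior -> posterior (DECREASING y)
#   S (sagittal) 1..4, left -> right (increasing x)
# Slabs are half-open towards the higher index: a point exactly on a plane
# belongs to the higher-index slab (so x = 0 is S3, the left hemisphere is
# exactly x < 0).
slab_indices <- function(planes, x, y, z) {
  list(
    a = findInterval(z, planes$axial_mm) + 1L,
    c = findInterval(-y, rev(-planes$coronal_mm)) + 1L,
    s = findInterval(x, planes$sagittal_mm) + 1L
  )
}

grid_label_string <- function(a, c_, s, s_numbering) {
  if (s_numbering == "left_to_right") {
    sprintf("A%dC%dS%d", a, c_, s)
  } else {
    # mirrored: S counts lateral -> medial within each hemisphere, so the
    # homotopic left/right cells share an S index and the hemisphere suffix
    # keeps the 48 labels distinct
    hemi <- ifelse(s <= 2L, "L", "R")
    sm <- ifelse(s <= 2L, s, 5L - s)
    sprintf("A%dC%dS%d.%s", a, c_, sm, hemi)
  }
}

#' Build a Brain-Grid
#'
#' Constructs the 48-cell sub-lobar partition from a plane set on a template
#' geometry and rasterizes it: every voxel centre of the template is assigned
#' to exactly one grid voxel (cell). Slab indices increase inferior to
#' superior (A1-A4), anterior to posterior (C1-C3) and left to right (S1-S4);
#' the canonical label is `"A{a}C{c}S{s}"`. With
#' `s_numbering = "mirrored"` the sagittal index instead counts lateral to
#' medial within each hemisphere (S1-S2) and labels carry an `.L`/`.R`
#' suffix.
#'
#' @param planes a [grid_planes()] object.
#' @param geometry a [template_geometry()] whose world bounding box strictly
#'   contains all planes.
#' @param s_numbering `"left_to_right"` (default) or `"mirrored"`.
#' @return object of class `brain_grid` with the plane set, geometry, a
#'   48-row `cells` data frame (code, label, a, c, s indices, hemisphere,
#'   voxel count, centroid in mm) and the rasterized integer label volume.
#' @export
build_grid <- function(planes, geometry,
                       s_numbering = c("left_to_right", "mirrored")) {
  stopifnot(inherits(planes, "plane_set"),
            inherits(geometry, "template_geometry"))
  s_numbering <- match.arg(s_numbering)
  bb <- world_bbox(geometry)
  if (any(planes$sagittal_mm <= bb[1, 1]) || any(planes$sagittal_mm >= bb[2, 1]) ||
      any(planes$coronal_mm <= bb[1, 2]) || any(planes$coronal_mm >= bb[2, 2]) ||
      any(planes$axial_mm <= bb[1, 3]) || any(planes$axial_mm >= bb[2, 3]))
    stop("all planes must lie strictly inside the template bounding box")

  X <- voxel_world_coords(geometry, 1)
  Y <- voxel_world_coords(geometry, 2)
  Z <- voxel_world_coords(geometry, 3)
  idx <- slab_indices(planes, X, Y, Z)
  # findInterval drops array dims; restore the template shape
  code <- array((idx$a - 1L) * 12L + (idx$c - 1L) * 4L + idx$s,
                dim = geometry$dim)
  storage.mode(code) <- "integer"

  cells <- expand.grid(s = 1:4, c = 1:3, a = 1:4,
                       KEEP.OUT.ATTRS = FALSE)[, c("a", "c", "s")]
  cells$code <- (cells$a - 1L) * 12L + (cells$c - 1L) * 4L + cells$s
  cells <- cells[order(cells$code), ]
  cells$label <- grid_label_string(cells$a, cells$c, cells$s, s_numbering)
  cells$hemisphere <- ifelse(cells$s <= 2L, "L", "R")
  counts <- tabulate(code, nbins = 48L)
  cells$n_voxels <- counts
  cells$centroid_x <- as.vector(tapply(X, factor(code, levels = 1:48), mean))
  cells$centroid_y <- as.vector(tapply(Y, factor(code, levels = 1:48), mean))
  cells$centroid_z <- as.vector(tapply(Z, factor(code, levels = 1:48), mean))
  rownames(cells) <- NULL

  structure(
    list(planes = planes, geometry = geometry, s_numbering = s_numbering,
         cells = cells[, c("code", "label", "a", "c", "s", "hemisphere",
                           "n_voxels", "centroid_x", "centroid_y",
                           "centroid_z")],
         label_volume = code),
    class = "brain_grid"
  )
}

#' @export
print.brain_grid <- function(x, ...) {
  cat(sprintf("Brain-Grid: %d cells (%s S numbering) on a %d x %d x %d template\n",
              nrow(x$cells), x$s_numbering,
              x$geometry$dim[1], x$geometry$dim[2], x$geometry$dim[3]))
  invisible(x)
}

#' Grid-voxel label of world-space points
#'
#' @param points numeric vector of length 3 or an n x 3 matrix of world
#'   coordinates (mm). Points must lie inside the template bounding box.
#' @param grid a [build_grid()] result.
#' @return data frame with one row per point: label, a, c, s, hemisphere.
#' @export
label_of <- function(points, grid) {
  stopifnot(inherits(grid, "brain_grid"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  stopifnot(ncol(points) == 3)
  bb <- world_bbox(grid$geometry)
  inside <- points[, 1] >= bb[1, 1] & points[, 1] <= bb[2, 1] &
            points[, 2] >= bb[1, 2] & points[, 2] <= bb[2, 2] &
            points[, 3] >= bb[1, 3] & points[, 3] <= bb[2, 3]
  if (!all(inside))
    stop(sum(!inside), " point(s) outside the template bounding box")
  idx <- slab_indices(grid$planes, points[, 1], points[, 2], points[, 3])
  code <- (idx$a - 1L) * 12L + (idx$c - 1L) * 4L + idx$s
  cells <- grid$cells
  out <- cells[match(code, cells$code),
               c("code", "label", "a", "c", "s", "hemisphere")]
  rownames(out) <- NULL
  out
}

#' Rasterized label volume of a grid
#'
#' Returns the integer-coded label volume (codes 1-48) as a `brain_volume`,
#' together with the code-to-label table via the grid's `cells` element.
#' The histogram of codes sums to the template voxel count by construction.
#'
#' @param grid a [build_grid()] result.
#' @return a `brain_volume` of integer codes.
#' @export
rasterize_grid <- function(grid) {
  stopifnot(inherits(grid, "brain_grid"))
  brain_volume(grid$label_volume, grid$geometry, id = "brain_grid_labels")
}

#' Write the code/label lookup table of a grid as CSV
#'
#' @param grid a [build_grid()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_table <- function(grid, path) {
  utils::write.csv(grid$cells, path, row.names = FALSE)
  invisible(path)
}
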