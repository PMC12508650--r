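#' Template geometry
#'
#' A template geometry couples a 3D array shape with a voxel-to-world affine
#' (NIfTI convention: world mm = affine %*% c(i, j, k, 1) with 0-based voxel
#' indices). All Brain-Grid operations are defined in world millimetres, so
#' any mask entering the pipeline is interpreted (or resampled) through a
#' geometry like this one.
#'
#' @param dim integer length-3 array dimensions.
#' @param affine 4x4 voxel-to-world affine matrix (mm), last row (0,0,0,1).
#' @return an object of class `template_geometry` with elements `dim`,
#'   `affine` and `voxel_mm3` (volume of one voxel in mm^3).
#' @export
template_geometry <- function(dim, affine) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L))
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (!all(is.finite(affine))) stop("affine must be finite")
  if (abs(det(affine[1:3, 1:3])) < 1e-12) stop("affine is not invertible")
  structure(
    list(dim = dim, affine = affine,
         voxel_mm3 = abs(det(affine[1:3, 1:3]))),
    class = "template_geometry"
  )
}

#' MNI-like template geometry at a chosen resolution
#'
#' Returns an axis-aligned geometry covering the MNI152 bounding box
#' (x in \[-90, 90\], y in \[-126, 90\], z in \[-72, 108\] mm) at `voxel_mm`
#' isotropic resolution, with the conventional negative x step (the first
#' index runs right-to-left). At `voxel_mm = 2` this reproduces the familiar
#' 91 x 109 x 91 grid; coarser settings give smaller, geometry-compatible
#' volumes that are convenient for simulation.
#'
#' @param voxel_mm isotropic voxel size in mm (default 2).
#' @return a [template_geometry()].
#' @export
mni_geometry <- function(voxel_mm = 2) {
  stopifnot(voxel_mm > 0)
  extent <- c(180, 216, 180)
  d <- as.integer(floor(extent / voxel_mm)) + 1L
  affine <- rbind(
    c(-voxel_mm, 0, 0, 90),
    c(0, voxel_mm, 0, -126),
    c(0, 0, voxel_mm, -72),
    c(0, 0, 0, 1)
  )
  template_geometry(d, affine)
}

#' @export
print.template_geometry <- function(x, ...) {
  cat(sprintf("template geometry: %d x %d x %d voxels, %.1f mm^3/voxel\n",
              x$dim[1], x$dim[2], x$dim[3], x$voxel_mm3))
  invisible(x)
}

#' World-space bounding box of a geometry
#'
#' Box spanned by the outer voxel edges (voxel centres +/- half a voxel),
#' returned as a 2x3 matrix (rows min/max, columns x/y/z in mm).
#' @param geometry a [template_geometry()].
#' @return 2x3 numeric matrix.
#' @export
world_bbox <- function(geometry) {
  corners <- as.matrix(expand.grid(
    i = c(-0.5, geometry$dim[1] - 0.5),
    j = c(-0.5, geometry$dim[2] - 0.5),
    k = c(-0.5, geometry$dim[3] - 0.5)
  ))
  w <- t(geometry$affine %*% rbind(t(corners), 1))[, 1:3, drop = FALSE]
  rbind(apply(w, 2, min), apply(w, 2, max))
}

# World coordinates of every voxel centre, one component at a time.
# Returns arrays the same shape as the volume; exploits linearity of the
# affine so no n x 4 matrix is ever materialised.
voxel_world_coords <- function(geometry, component) {
  A <- geometry$affine
  d <- geometry$dim
  i <- seq_len(d[1]) - 1
  j <- seq_len(d[2]) - 1
  k <- seq_len(d[3]) - 1
  r <- component
  xi <- A[r, 1] * i
  xj <- A[r, 2] * j
  xk <- A[r, 3] * k
  array(rep(xi, times = d[2] * d[3]), dim = d) +
    array(rep(rep(xj, each = d[1]), times = d[3]), dim = d) +
    array(rep(xk, each = d[1] * d[2]), dim = d) + A[r, 4]
}

#' Construct a brain volume
#'
#' Minimal container for a 3D volume plus its voxel-to-world affine. Binary
#' tumour masks are brain volumes with values in \{0, 1\}.
#'
#' @param data 3D numeric/integer array.
#' @param geometry a [template_geometry()] matching `dim(data)`.
#' @param id optional identifier (e.g. patient id).
#' @return object of class `brain_volume`.
#' @export
brain_volume <- function(data, geometry, id = NULL) {
  stopifnot(inherits(geometry, "template_geometry"))
  data <- as.array(data)
  if (!identical(as.integer(dim(data)), geometry$dim))
    stop("data dimensions do not match geometry")
  structure(list(data = data, geometry = geometry, id = id),
            class = "brain_volume")
}

#' @export
print.brain_volume <- function(x, ...) {
  cat(sprintf("brain volume%s: %d x %d x %d, %d nonzero voxels\n",
              if (is.null(x$id)) "" else paste0(" [", x$id, "]"),
              x$geometry$dim[1], x$geometry$dim[2], x$geometry$dim[3],
              sum(x$data != 0)))
  invisible(x)
}

#' Read a binary mask from a NIfTI file
#'
#' Values are binarised at > 0.5; a warning is emitted if the input was not
#' already binary (e.g. a probabilistic map). 4D inputs and non-invertible
#' affines are rejected.
#'
#' @param path NIfTI-1 file path.
#' @param id optional identifier stored on the returned mask (defaults to the
#'   file name without extension).
#' @return a binary `brain_volume`.
#' @export
read_mask <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L) stop("expected a 3D volume: ", path)
  affine <- unclass(RNifti::xform(img))
  geom <- template_geometry(dim(arr), affine)
  vals <- unique(as.vector(arr))
  if (!all(vals %in% c(0, 1))) {
    warning("non-binary input binarised at > 0.5: ", path)
    arr <- (arr > 0.5) * 1
  }
  if (is.null(id)) id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  brain_volume(arr, geom, id = id)
}

#' Write a volume to a NIfTI file
#'
#' @param volume a `brain_volume` (or plain array with `geometry` supplied).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param geometry required if `volume` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, geometry = NULL) {
  if (inherits(volume, "brain_volume")) {
    arr <- volume$data
    geometry <- volume$geometry
  } else {
    stopifnot(inherits(geometry, "template_geometry"))
    arr <- as.array(volume)
  }
  img <- RNifti::asNifti(arr)
  # pixdim must match the affine's column norms or the writer rescales the
  # stored xform back to unit voxels
  RNifti::pixdim(img) <- sqrt(colSums(geometry$affine[1:3, 1:3]^2))
  img <- RNifti::`sform<-`(img, structure(geometry$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(geometry$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

geometry_equal <- function(a, b, tol = 1e-6) {
  identical(a$dim, b$dim) && max(abs(a$affine - b$affine)) < tol
}

#' Nearest-neighbour resampling onto a target geometry
#'
#' Each target voxel centre is mapped through the source affine inverse and
#' the nearest source voxel value is taken; targets falling outside the
#' source volume become 0. Intended for binary masks, hence nearest
#' neighbour only.
#'
#' @param volume a `brain_volume`.
#' @param geometry target [template_geometry()].
#' @return a `brain_volume` on `geometry`.
#' @export
resample_nn <- function(volume, geometry) {
  stopifnot(inherits(volume, "brain_volume"),
            inherits(geometry, "template_geometry"))
  if (geometry_equal(volume$geometry, geometry)) return(volume)
  M <- solve(volume$geometry$affine) %*% geometry$affine
  d <- geometry$dim
  sd <- volume$geometry$dim
  # source index components as linear functions of target indices
  src <- vector("list", 3)
  for (r in 1:3) {
    xi <- M[r, 1] * (seq_len(d[1]) - 1)
    xj <- M[r, 2] * (seq_len(d[2]) - 1)
    xk <- M[r, 3] * (seq_len(d[3]) - 1)
    src[[r]] <- round(
      array(rep(xi, times = d[2] * d[3]), dim = d) +
      array(rep(rep(xj, each = d[1]), times = d[3]), dim = d) +
      array(rep(xk, each = d[1] * d[2]), dim = d) + M[r, 4])
  }
  ok <- src[[1]] >= 0 & src[[1]] < sd[1] &
        src[[2]] >= 0 & src[[2]] < sd[2] &
        src[[3]] >= 0 & src[[3]] < sd[3]
  out <- array(0, dim = d)
  lin <- 1 + src[[1]][ok] + sd[1] * (src[[2]][ok] + sd[2] * src[[3]][ok])
  out[ok] <- volume$data[lin]
  brain_volume(out, geometry, id = volume$id)
}

# Resample-or-pass with a logged warning, shared by the analysis operations.
conform_to <- function(volume, geometry) {
  if (geometry_equal(volume$geometry, geometry)) return(volume)
  warning("mask ", if (is.null(volume$id)) "" else volume$id,
          " resampled (nearest neighbour) to the template geometry")
  resample_nn(volume, geometry)
}
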