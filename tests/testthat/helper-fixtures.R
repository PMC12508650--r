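# Shared fixtures: small geometries, grids and masks built in code.

# Axis-aligned positive-step geometry, world origin at the volume centre.
toy_geometry <- function(dim = c(20, 24, 20), voxel = 4) {
  half <- (dim - 1) / 2 * voxel
  affine <- rbind(c(voxel, 0, 0, -half[1]),
                  c(0, voxel, 0, -half[2]),
                  c(0, 0, voxel, -half[3]),
                  c(0, 0, 0, 1))
  template_geometry(dim, affine)
}

toy_planes <- function() {
  grid_planes(axial_mm = c(-18, 0, 18), coronal_mm = c(-15, 15),
              sagittal_mm = c(-18, 0, 18))
}

toy_grid <- function(geom = toy_geometry(), planes = toy_planes(), ...) {
  build_grid(planes, geom, ...)
}

# Binary mask from a voxel-index predicate on world coordinates.
mask_where <- function(geom, predicate, id = "toy") {
  X <- braingrid:::voxel_world_coords(geom, 1)
  Y <- braingrid:::voxel_world_coords(geom, 2)
  Z <- braingrid:::voxel_world_coords(geom, 3)
  brain_volume(1L * predicate(X, Y, Z), geom, id = id)
}

ball_mask <- function(geom, centre, radius_mm, id = "ball") {
  mask_where(geom, function(x, y, z)
    (x - centre[1])^2 + (y - centre[2])^2 + (z - centre[3])^2 <= radius_mm^2,
    id = id)
}

# Independent per-voxel Brain-Grid classifier: explicit comparisons, no
# shared code with slab_indices().
oracle_classify <- function(planes, x, y, z) {
  a <- ifelse(z < planes$axial_mm[1], 1L,
       ifelse(z < planes$axial_mm[2], 2L,
       ifelse(z < planes$axial_mm[3], 3L, 4L)))
  cc <- ifelse(y > planes$coronal_mm[2], 1L,
        ifelse(y > planes$coronal_mm[1], 2L, 3L))
  s <- ifelse(x < planes$sagittal_mm[1], 1L,
       ifelse(x < 0, 2L,
       ifelse(x < planes$sagittal_mm[3], 3L, 4L)))
  (a - 1L) * 12L + (cc - 1L) * 4L + s
}

# Rank-formula Kruskal-Wallis H with tie correction, independent of
# kruskal.test.
oracle_kw_H <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  Rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(n * (Rbar - (N + 1) / 2)^2)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}
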