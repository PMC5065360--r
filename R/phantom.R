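#' Tensor models for phantom regions
#'
#' `tensor_iso()` describes isotropic diffusion with a single diffusivity;
#' `tensor_aniso()` an axially symmetric-or-not anisotropic tensor given by
#' its sorted eigenvalues and the principal eigenvector direction.
#' Diffusivities are in mm^2/s (brain tissue is of order 1e-3).
#'
#' @param d isotropic diffusivity in mm^2/s.
#' @return A `tensor_model` list.
#' @export
tensor_iso <- function(d) {
  stopifnot(is.finite(d), d >= 0)
  structure(list(kind = "isotropic", lambda = c(d, d, d),
                 direction = c(1, 0, 0)), class = "tensor_model")
}

#' @param l1,l2,l3 eigenvalues in mm^2/s, required sorted `l1 >= l2 >= l3 >= 0`.
#' @param direction principal eigenvector (unit 3-vector).
#' @rdname tensor_iso
#' @export
tensor_aniso <- function(l1, l2, l3, direction) {
  lam <- c(l1, l2, l3)
  if (any(!is.finite(lam)) || any(lam < 0) || is.unsorted(rev(lam)))
    stop("eigenvalues must be non-negative and sorted l1 >= l2 >= l3")
  direction <- as.numeric(direction)
  if (length(direction) != 3L || abs(sqrt(sum(direction^2)) - 1) > 1e-9)
    stop("principal direction must be a unit 3-vector")
  structure(list(kind = "anisotropic", lambda = lam, direction = direction),
            class = "tensor_model")
}

#' Region geometries in voxel coordinates
#'
#' Axis-aligned boxes and spheres, in 1-based voxel indices. A voxel belongs
#' to a box when its index lies in `[min, max]` per axis, and to a sphere
#' when its index is within `radius` of `center` (Euclidean, in voxels).
#'
#' @param min,max integer 3-vectors of inclusive voxel bounds.
#' @return A `phantom_geometry` list.
#' @export
geom_box <- function(min, max) {
  stopifnot(length(min) == 3L, length(max) == 3L, all(max >= min))
  structure(list(kind = "box", min = min, max = max),
            class = "phantom_geometry")
}

#' @param center numeric 3-vector, voxel coordinates of the sphere center.
#' @param radius radius in voxels.
#' @rdname geom_box
#' @export
geom_sphere <- function(center, radius) {
  stopifnot(length(center) == 3L, radius > 0)
  structure(list(kind = "sphere", center = center, radius = radius),
            class = "phantom_geometry")
}

#' Phantom region
#'
#' @param label one of `"background_wm"`, `"cavity_csf"`,
#'   `"t2_hyperintense"`, `"lesion"`.
#' @param geometry a [geom_box()] or [geom_sphere()]; `NULL` fills the whole
#'   grid (only sensible for the background region).
#' @param tensor a [tensor_iso()] or [tensor_aniso()].
#' @param s0 non-diffusion-weighted signal level for the region (arbitrary
#'   units, must be positive).
#' @export
phantom_region <- function(label, geometry, tensor, s0) {
  label <- match.arg(label,
                     c("background_wm", "cavity_csf", "t2_hyperintense", "lesion"))
  if (!is.null(geometry) && !inherits(geometry, "phantom_geometry"))
    stop("geometry must be geom_box()/geom_sphere() or NULL")
  stopifnot(inherits(tensor, "tensor_model"), is.finite(s0), s0 > 0)
  structure(list(label = label, geometry = geometry, tensor = tensor, s0 = s0),
            class = "phantom_region")
}

#' Phantom specification
#'
#' Describes a digital tensor phantom: grid, voxel size, and an ordered list
#' of regions. Later regions overwrite earlier ones, so a typical phantom is
#' background white matter, then the resection cavity, then the adjacent
#' T2w-hyperintense zone, then a focal lesion inside that zone. When both a
#' `lesion` and a `t2_hyperintense` region are present, the lesion must lie
#' entirely inside the hyperintense zone.
#'
#' @param grid_shape integer 3-vector of voxel counts.
#' @param voxel_size numeric 3-vector of voxel edge lengths in mm.
#' @param regions list of [phantom_region()] in paint order.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape, voxel_size, regions) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(voxel_size) == 3L, all(voxel_size > 0),
            length(regions) >= 1L)
  if (!all(vapply(regions, inherits, logical(1), "phantom_region")))
    stop("regions must be a list of phantom_region()")
  structure(list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 regions = regions), class = "phantom_spec")
}

#' Default post-resection phantom
#'
#' A 48 x 48 x 24 grid at the DTI acquisition resolution of 1.8 x 1.8 x 4 mm:
#' anisotropic background white matter (eigenvalues 1.7/0.4/0.3 e-3 mm^2/s,
#' a literature-typical default), a CSF-filled resection cavity (isotropic
#' 3.0e-3), a surrounding T2w-hyperintense zone at the stable-cohort axial
#' diffusivity level (isotropic 1.28e-3), and a focal lesion inside it at the
#' transformed-cohort level (isotropic 0.72e-3). S0 levels are arbitrary
#' units in the range of magnitude MRI.
#'
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function() {
  phantom_spec(
    grid_shape = c(48L, 48L, 24L),
    voxel_size = c(1.8, 1.8, 4),
    regions = list(
      phantom_region("background_wm", NULL,
                     tensor_aniso(1.7e-3, 0.4e-3, 0.3e-3, c(1, 0, 0)), s0 = 800),
      phantom_region("cavity_csf", geom_sphere(c(24, 24, 12), 6),
                     tensor_iso(3.0e-3), s0 = 1000),
      phantom_region("t2_hyperintense", geom_sphere(c(32, 24, 12), 7),
                     tensor_iso(1.28e-3), s0 = 900),
      phantom_region("lesion", geom_sphere(c(34, 24, 12), 3),
                     tensor_iso(0.72e-3), s0 = 850)
    )
  )
}

# rotation taking e1 to `dir` (columns: dir and any orthonormal completion)
principal_rotation <- function(dir) {
  a <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u2 <- a - sum(a * dir) * dir
  u2 <- u2 / sqrt(sum(u2^2))
  u3 <- c(dir[2] * u2[3] - dir[3] * u2[2],
          dir[3] * u2[1] - dir[1] * u2[3],
          dir[1] * u2[2] - dir[2] * u2[1])
  cbind(dir, u2, u3, deparse.level = 0)
}

# 6 unique components of R diag(lambda) R^T, order Dxx Dyy Dzz Dxy Dxz Dyz
tensor_components <- function(model) {
  R <- if (model$kind == "isotropic") diag(3) else principal_rotation(model$direction)
  D <- R %*% diag(model$lambda) %*% t(R)
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

geometry_mask <- function(geom, grid_shape) {
  if (is.null(geom)) return(array(TRUE, grid_shape))
  ix <- slice.index(array(0L, grid_shape), 1L)
  iy <- slice.index(array(0L, grid_shape), 2L)
  iz <- slice.index(array(0L, grid_shape), 3L)
  if (geom$kind == "box") {
    ix >= geom$min[1] & ix <= geom$max[1] &
      iy >= geom$min[2] & iy <= geom$max[2] &
      iz >= geom$min[3] & iz <= geom$max[3]
  } else {
    (ix - geom$center[1])^2 + (iy - geom$center[2])^2 +
      (iz - geom$center[3])^2 <= geom$radius^2
  }
}

#' Rasterise a phantom specification into a ground-truth tensor field
#'
#' Paints regions in order onto the grid (later regions overwrite earlier
#' voxels), assigning each voxel the region's tensor, S0 level and label.
#' Every voxel must be covered by some region, and a `lesion` region must be
#' contained in the `t2_hyperintense` region when both are present.
#'
#' @param spec a [phantom_spec()].
#' @return A `tensor_field` (see [tensor_field()]) with additional elements
#'   `labels` (region label per voxel), `masks` (named list of logical
#'   arrays per region label; `masks$tumor` aliases the lesion and
#'   `masks$t2w` the T2w-hyperintense zone) and `s0` (S0 array).
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  nvox <- prod(gs)
  labels <- array(NA_character_, gs)
  s0 <- array(NA_real_, gs)
  tensors <- array(NA_real_, c(gs, 6L))
  eig <- array(NA_real_, c(gs, 3L))
  masks <- list()
  tmat <- matrix(tensors, nvox, 6L)
  emat <- matrix(eig, nvox, 3L)
  for (rg in spec$regions) {
    m <- geometry_mask(rg$geometry, gs)
    if (rg$label == "lesion" && !is.null(masks$t2_hyperintense) &&
        any(m & !masks$t2_hyperintense))
      stop("geometry error: lesion region extends outside the t2_hyperintense region")
    idx <- which(m)
    labels[idx] <- rg$label
    s0[idx] <- rg$s0
    tmat[idx, ] <- rep(tensor_components(rg$tensor), each = length(idx))
    emat[idx, ] <- rep(rg$tensor$lambda, each = length(idx))
    masks[[rg$label]] <- if (is.null(masks[[rg$label]])) m else masks[[rg$label]] | m
  }
  # painting order: a voxel's final mask is where its label survived
  for (lb in names(masks)) masks[[lb]] <- array(labels == lb, gs)
  if (anyNA(labels))
    stop("phantom regions do not cover the grid: ", sum(is.na(labels)),
         " unassigned voxels")
  if (!is.null(masks$lesion)) masks$tumor <- masks$lesion
  if (!is.null(masks$t2_hyperintense)) masks$t2w <- masks$t2_hyperintense
  field <- tensor_field(array(tmat, c(gs, 6L)), voxel_size = spec$voxel_size)
  field$eigenvalues <- array(emat, c(gs, 3L))
  field$labels <- labels
  field$masks <- masks
  field$s0 <- s0
  field
}
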