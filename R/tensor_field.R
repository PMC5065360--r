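#' Voxel grid of symmetric diffusion tensors
#'
#' Container shared by ground-truth phantoms and fitted results. Tensors are
#' stored as their 6 unique components in the order
#' `Dxx, Dyy, Dzz, Dxy, Dxz, Dyz` (mm^2/s) in a 4D array whose first three
#' dimensions are the voxel grid.
#'
#' @param tensors 4D array, `c(grid_shape, 6)`.
#' @param voxel_size numeric 3-vector, mm.
#' @param s0_est optional per-voxel estimated S0 (3D array).
#' @param valid_mask optional logical 3D array of voxels with a usable
#'   tensor; defaults to voxels whose components are all finite.
#' @return An object of class `tensor_field`.
#' @export
tensor_field <- function(tensors, voxel_size, s0_est = NULL, valid_mask = NULL) {
  stopifnot(length(dim(tensors)) == 4L, dim(tensors)[4L] == 6L,
            length(voxel_size) == 3L, all(voxel_size > 0))
  gs <- dim(tensors)[1:3]
  if (is.null(valid_mask)) {
    tm <- matrix(tensors, prod(gs), 6L)
    valid_mask <- array(rowSums(!is.finite(tm)) == 0L, gs)
  }
  structure(list(tensors = tensors, voxel_size = as.numeric(voxel_size),
                 s0_est = s0_est, eigenvalues = NULL,
                 valid_mask = valid_mask, n_clamped = 0L),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  gs <- dim(x$tensors)[1:3]
  cat(sprintf("Tensor field %d x %d x %d (voxel %s mm); %d/%d valid voxels",
              gs[1], gs[2], gs[3], paste(x$voxel_size, collapse = " x "),
              sum(x$valid_mask), prod(gs)))
  if (!is.null(x$eigenvalues))
    cat(sprintf("; eigenvalues computed (%d clamped)", x$n_clamped))
  cat("\n")
  invisible(x)
}

# full 3x3 tensor at one voxel (linear index i)
tensor_at <- function(field, i) {
  tm <- matrix(field$tensors, prod(dim(field$tensors)[1:3]), 6L)
  d <- tm[i, ]
  matrix(c(d[1], d[4], d[5],
           d[4], d[2], d[6],
           d[5], d[6], d[3]), 3L, 3L)
}

#' Sorted eigenvalues of every tensor in a field
#'
#' Populates `field$eigenvalues` with the per-voxel eigenvalues sorted
#' descending (the axial/mean/radial diffusivity formulas assume
#' `lambda1 >= lambda2 >= lambda3`). Eigenvalues below `clamp_floor` are
#' raised to it so the maps stay physical; clamped voxels are counted in
#' `n_clamped`. Voxels with non-finite tensor components are flagged invalid.
#'
#' @param field a [tensor_field()].
#' @param clamp_floor smallest admissible eigenvalue in mm^2/s.
#' @return The field with `eigenvalues` (4D array, last dim 3), updated
#'   `valid_mask` and `n_clamped`.
#' @export
eigendecompose <- function(field, clamp_floor = 1e-12) {
  stopifnot(inherits(field, "tensor_field"))
  gs <- dim(field$tensors)[1:3]
  nvox <- prod(gs)
  tm <- matrix(field$tensors, nvox, 6L)
  valid <- as.vector(field$valid_mask) & rowSums(!is.finite(tm)) == 0L
  ev <- matrix(NA_real_, nvox, 3L)
  D <- matrix(0, 3L, 3L)
  for (i in which(valid)) {
    d <- tm[i, ]
    D[1, 1] <- d[1]; D[2, 2] <- d[2]; D[3, 3] <- d[3]
    D[1, 2] <- D[2, 1] <- d[4]
    D[1, 3] <- D[3, 1] <- d[5]
    D[2, 3] <- D[3, 2] <- d[6]
    ev[i, ] <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  }
  clamped <- valid & !is.na(ev[, 3L]) & ev[, 3L] < clamp_floor
  ev[ev < clamp_floor & !is.na(ev)] <- clamp_floor
  field$eigenvalues <- array(ev, c(gs, 3L))
  field$valid_mask <- array(valid, gs)
  field$n_clamped <- sum(clamped)
  field
}

#' Diffusivity maps from sorted eigenvalues
#'
#' Axial diffusivity is the largest eigenvalue, radial diffusivity the mean
#' of the two smaller ones, and mean diffusivity the mean of all three:
#' `AD = lambda1`, `RD = (lambda2 + lambda3)/2`,
#' `MD = (lambda1 + lambda2 + lambda3)/3`. The ordering
#' `lambda1 >= lambda2 >= lambda3` forces `AD >= MD >= RD` voxel-wise, and
#' `MD = (AD + 2 RD)/3` holds as an algebraic identity. Invalid voxels carry
#' `NaN`.
#'
#' @param field a [tensor_field()] with eigenvalues populated (run
#'   [eigendecompose()] first; called automatically if missing).
#' @return An object of class `diffusivity_maps`: list with 3D arrays `ad`,
#'   `md`, `rd` (mm^2/s), `valid_mask`, `voxel_size` and `n_clamped`.
#' @export
compute_maps <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  if (is.null(field$eigenvalues)) field <- eigendecompose(field)
  gs <- dim(field$tensors)[1:3]
  ev <- matrix(field$eigenvalues, prod(gs), 3L)
  ev[!as.vector(field$valid_mask), ] <- NaN
  structure(list(ad = array(ev[, 1L], gs),
                 md = array(rowMeans(ev), gs),
                 rd = array((ev[, 2L] + ev[, 3L]) / 2, gs),
                 valid_mask = field$valid_mask,
                 voxel_size = field$voxel_size,
                 n_clamped = field$n_clamped),
            class = "diffusivity_maps")
}

#' @export
print.diffusivity_maps <- function(x, ...) {
  gs <- dim(x$ad)
  rng <- range(x$md[x$valid_mask])
  cat(sprintf(paste0("Diffusivity maps %d x %d x %d; MD range ",
                     "%.3g - %.3g mm^2/s; %d invalid voxels\n"),
              gs[1], gs[2], gs[3], rng[1], rng[2], sum(!x$valid_mask)))
  invisible(x)
}
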