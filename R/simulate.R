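#' Simulate a diffusion-weighted acquisition from a tensor field
#'
#' Forward-models the single-tensor signal decay
#' `S = S0 * exp(-b * g' D g)` per voxel and measurement, then (optionally)
#' corrupts it with Rician magnitude noise: each measurement is replaced by
#' `sqrt((S + e1)^2 + e2^2)` with independent zero-mean Gaussian `e1, e2` of
#' standard deviation `sigma = max(s0_map) / snr`. With `snr = NULL` the
#' noiseless signal is returned. Identical inputs and seed reproduce the
#' volume bit-identically.
#'
#' @param truth a [tensor_field()] (e.g. from [build_phantom()]).
#' @param scheme a [gradient_scheme()].
#' @param s0_map 3D array of S0 levels; defaults to `truth$s0` when the
#'   field carries one.
#' @param snr signal-to-noise ratio referenced to the maximum S0, or `NULL`
#'   for a noiseless acquisition.
#' @param seed integer seed for the noise draw (ignored when noiseless).
#' @return An object of class `dwi_volume`: list with `data` (4D array,
#'   measurements along dim 4), `scheme` and `voxel_size`.
#' @export
simulate_dwi <- function(truth, scheme, s0_map = truth$s0, snr = NULL,
                         seed = 1L) {
  stopifnot(inherits(truth, "tensor_field"),
            inherits(scheme, "gradient_scheme"))
  if (is.null(s0_map)) stop("s0_map is required when the field carries no s0")
  gs <- dim(truth$tensors)[1:3]
  if (!identical(dim(s0_map), as.integer(gs)) &&
      !identical(dim(s0_map), gs))
    stop("s0_map and tensor field must share the grid shape")
  if (!is.null(snr) && snr <= 0) stop("snr must be positive")
  m <- length(scheme$bvals)
  nvox <- prod(gs)
  tm <- matrix(truth$tensors, nvox, 6L)
  # per-measurement quadratic form coefficients: b * (gx^2, gy^2, gz^2,
  # 2 gx gy, 2 gx gz, 2 gy gz) so that exponent = -coef . tensor components
  g <- scheme$bvecs
  coef <- rbind(g[1, ]^2, g[2, ]^2, g[3, ]^2,
                2 * g[1, ] * g[2, ], 2 * g[1, ] * g[3, ],
                2 * g[2, ] * g[3, ]) * rep(scheme$bvals, each = 6L)
  bgDg <- tm %*% coef                       # nvox x m
  if (any(bgDg < -1e-12, na.rm = TRUE))
    stop("non-positive-semidefinite tensor: b * g' D g < 0 encountered")
  signal <- as.vector(s0_map) * exp(-bgDg)
  if (!is.null(snr)) {
    sigma <- max(s0_map) / snr
    set.seed(as.integer(seed))
    e1 <- matrix(stats::rnorm(nvox * m, sd = sigma), nvox, m)
    e2 <- matrix(stats::rnorm(nvox * m, sd = sigma), nvox, m)
    signal <- sqrt((signal + e1)^2 + e2^2)
  }
  structure(list(data = array(signal, c(gs, m)), scheme = scheme,
                 voxel_size = truth$voxel_size),
            class = "dwi_volume")
}

#' Assemble or read a DWI volume
#'
#' `dwi_volume()` wraps an existing 4D signal array and scheme;
#' `read_dwi_nifti()` loads a volume written as NIfTI plus FSL-style
#' bval/bvec files (e.g. by [run_imaging_pipeline()]).
#'
#' @param data 4D array of non-negative signal intensities, measurements
#'   along the 4th dimension.
#' @param scheme a [gradient_scheme()] with one entry per measurement.
#' @param voxel_size numeric 3-vector, mm.
#' @return A `dwi_volume`.
#' @export
dwi_volume <- function(data, scheme, voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(scheme, "gradient_scheme"), length(dim(data)) == 4L)
  if (dim(data)[4L] != length(scheme$bvals))
    stop("4th dimension must match the number of scheme entries")
  if (any(!is.finite(data)) || any(data < 0))
    stop("signal intensities must be finite and non-negative")
  structure(list(data = data, scheme = scheme,
                 voxel_size = as.numeric(voxel_size)),
            class = "dwi_volume")
}

#' @param nifti_path,bval_path,bvec_path paths to the 4D NIfTI and its
#'   gradient table.
#' @rdname dwi_volume
#' @export
read_dwi_nifti <- function(nifti_path, bval_path, bvec_path) {
  arr <- read_volume_nifti(nifti_path)
  vs <- attr(arr, "voxel_size")[1:3]
  attr(arr, "voxel_size") <- NULL
  dwi_volume(arr, read_bvalbvec(bval_path, bvec_path), voxel_size = vs)
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("DWI volume %d x %d x %d, %d measurements\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Cohort specification for the biomarker generator
#'
#' Group-wise normal models for the per-subject ROI-minimum diffusivities.
#' Defaults reproduce the study cohort structure: 29 stable patients versus
#' 18 with malignant transformation, with group means and standard
#' deviations (in 1e-3 mm^2/s) of axial 1.28 +/- 0.31 vs 0.72 +/- 0.23,
#' mean 1.00 +/- 0.26 vs 0.64 +/- 0.21, and radial 0.97 +/- 0.26 vs
#' 0.56 +/- 0.20.
#'
#' @param n_stable,n_transformed subject counts per group (>= 2).
#' @param means,sds 2 x 3 numeric matrices (rows `stable`, `transformed`;
#'   columns `ad_min`, `md_min`, `rd_min`), units 1e-3 mm^2/s.
#' @param seed integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_stable = 29L, n_transformed = 18L,
                        means = default_cohort_means(),
                        sds = default_cohort_sds(),
                        seed = 1L) {
  means <- as.matrix(means); sds <- as.matrix(sds)
  stopifnot(n_stable >= 2L, n_transformed >= 2L,
            identical(dim(means), c(2L, 3L)), identical(dim(sds), c(2L, 3L)),
            all(means > 0), all(sds > 0))
  structure(list(n_stable = as.integer(n_stable),
                 n_transformed = as.integer(n_transformed),
                 means = means, sds = sds, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_cohort_means <- function() {
  matrix(c(1.28, 0.72, 1.00, 0.64, 0.97, 0.56), 2L, 3L,
         dimnames = list(c("stable", "transformed"),
                         c("ad_min", "md_min", "rd_min")))
}

#' @rdname cohort_spec
#' @export
default_cohort_sds <- function() {
  matrix(c(0.31, 0.23, 0.26, 0.21, 0.26, 0.20), 2L, 3L,
         dimnames = list(c("stable", "transformed"),
                         c("ad_min", "md_min", "rd_min")))
}

# normal draw truncated at zero by redrawing (diffusivities are physical)
rnorm_positive <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Simulate a biomarker cohort table
#'
#' Draws per-subject `ad_min`/`md_min`/`rd_min` values independently from
#' the group-wise normal distributions in `spec`, redrawing non-positive
#' values (diffusivities are non-negative). The three parameters are drawn
#' independently per subject; real diffusivities are correlated, so this is
#' a deliberate simplification of the generator.
#'
#' @param spec a [cohort_spec()].
#' @return A data frame with columns `subject_id`, `label`
#'   (0 = stable, 1 = transformed), `ad_min`, `md_min`, `rd_min`
#'   (1e-3 mm^2/s).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- c(spec$n_stable, spec$n_transformed)
  out <- data.frame(
    subject_id = sprintf("S%03d", seq_len(sum(n))),
    label = rep(c(0L, 1L), n)
  )
  for (j in colnames(spec$means)) {
    out[[j]] <- c(rnorm_positive(n[1], spec$means["stable", j],
                                 spec$sds["stable", j]),
                  rnorm_positive(n[2], spec$means["transformed", j],
                                 spec$sds["transformed", j]))
  }
  out
}

#' Read and write cohort tables
#'
#' CSV with header `subject_id,label,ad_min,md_min,rd_min`, diffusivities in
#' 1e-3 mm^2/s.
#'
#' @param cohort a cohort data frame (see [simulate_cohort()]).
#' @param path file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(all(c("subject_id", "label", "ad_min", "md_min", "rd_min")
                %in% names(cohort)))
  utils::write.csv(cohort[, c("subject_id", "label", "ad_min", "md_min",
                              "rd_min")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "ad_min", "md_min", "rd_min")
  if (!all(need %in% names(x)))
    stop("cohort CSV must have columns ", paste(need, collapse = ", "))
  x
}
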