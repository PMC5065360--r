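#' Diffusion gradient scheme
#'
#' A gradient scheme pairs each diffusion-weighted measurement with a b-value
#' (s/mm^2) and a unit gradient direction. Tensor estimation needs at least
#' one b = 0 measurement and six diffusion-sensitising directions that span
#' the space of symmetric tensors.
#'
#' @param bvals numeric vector of b-values in s/mm^2 (one per measurement).
#' @param bvecs 3 x m matrix of gradient directions (columns are unit
#'   vectors; the direction of b = 0 entries is ignored and stored as zero).
#' @return An object of class `gradient_scheme`: a list with elements
#'   `bvals` and `bvecs`.
#' @examples
#' sch <- default_gradient_scheme()
#' sch$bvals
#' @export
gradient_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L || ncol(bvecs) != length(bvals))
    stop("bvecs must be a 3 x length(bvals) matrix")
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop("b-values must be finite and non-negative")
  dw <- bvals > 0
  if (sum(!dw) < 1L)
    stop("scheme needs at least one b = 0 measurement")
  if (any(dw)) {
    nrm <- sqrt(colSums(bvecs[, dw, drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-9))
      stop("diffusion-weighted directions must have unit norm (within 1e-9)")
  }
  if (n_distinct_axes(bvecs[, dw, drop = FALSE]) < 6L)
    stop("scheme needs at least 6 non-collinear diffusion directions")
  bvecs[, !dw] <- 0
  dimnames(bvecs) <- NULL
  structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_scheme")
}

# count gradient axes that are pairwise non-collinear (antipodal = collinear)
n_distinct_axes <- function(v, tol = 1e-6) {
  if (ncol(v) == 0L) return(0L)
  keep <- rep(TRUE, ncol(v))
  for (i in seq_len(ncol(v))) {
    if (!keep[i]) next
    if (i < ncol(v)) for (j in (i + 1L):ncol(v)) {
      if (keep[j] && abs(abs(sum(v[, i] * v[, j])) - 1) < tol) keep[j] <- FALSE
    }
  }
  sum(keep)
}

#' Default 12-direction acquisition scheme
#'
#' One b = 0 measurement plus 12 directions at b = 1000 s/mm^2, matching a
#' routine clinical DTI protocol. The 12 directions are a fixed
#' electrostatic-repulsion set shipped with the package as a text fixture
#' (minimum inter-axis angle about 39 degrees), chosen for reproducibility.
#'
#' @param b diffusion weighting in s/mm^2 for the sensitised measurements.
#' @param n_b0 number of b = 0 measurements to prepend.
#' @return A [gradient_scheme()].
#' @export
default_gradient_scheme <- function(b = 1000, n_b0 = 1L) {
  stopifnot(b > 0, n_b0 >= 1L)
  path <- system.file("extdata", "directions12.txt", package = "dtimt",
                      mustWork = TRUE)
  dirs <- t(as.matrix(utils::read.table(path)))
  dirs <- sweep(dirs, 2L, sqrt(colSums(dirs^2)), "/")
  gradient_scheme(c(rep(0, n_b0), rep(b, ncol(dirs))),
                  cbind(matrix(0, 3L, n_b0), dirs))
}

#' Read and write FSL-style bval/bvec files
#'
#' The FSL dialect stores b-values as a single whitespace-separated row and
#' directions as three rows (x, y, z components).
#'
#' @param bval_path,bvec_path paths to the two text files.
#' @return `read_bvalbvec()` returns a [gradient_scheme()].
#' @export
read_bvalbvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  bvec <- as.matrix(utils::read.table(bvec_path))
  dimnames(bvec) <- NULL
  if (nrow(bvec) != 3L)
    stop("bvec file must have exactly 3 rows")
  # tolerate text round-off: renormalise diffusion-weighted columns
  dw <- bvals > 0
  nrm <- sqrt(colSums(bvec[, dw, drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-3))
    stop("bvec directions are not close to unit norm")
  bvec[, dw] <- sweep(bvec[, dw, drop = FALSE], 2L, nrm, "/")
  gradient_scheme(bvals, bvec)
}

#' @param scheme a [gradient_scheme()].
#' @param prefix output path prefix; writes `<prefix>.bval` and
#'   `<prefix>.bvec`.
#' @rdname read_bvalbvec
#' @export
write_bvalbvec <- function(scheme, prefix) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  cat(paste(format(scheme$bvals, trim = TRUE), collapse = " "), "\n",
      sep = "", file = paste0(prefix, ".bval"))
  con <- file(paste0(prefix, ".bvec"), "w")
  on.exit(close(con))
  for (i in 1:3)
    cat(paste(format(scheme$bvecs[i, ], digits = 15, trim = TRUE),
              collapse = " "), "\n", sep = "", file = con)
  invisible(c(paste0(prefix, ".bval"), paste0(prefix, ".bvec")))
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat("Gradient scheme:", length(x$bvals), "measurements;",
      sum(x$bvals == 0), "b=0,", sum(x$bvals > 0), "diffusion-weighted",
      sprintf("(b = %s s/mm^2)\n",
              paste(unique(x$bvals[x$bvals > 0]), collapse = ", ")))
  invisible(x)
}
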