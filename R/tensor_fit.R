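#' Voxel-wise diffusion tensor fit by log-linear least squares
#'
#' Linearises the single-tensor signal model
#' `S_i = S0 * exp(-b_i g_i' D g_i)` by taking logs and solves, per voxel,
#' the 7-unknown least-squares problem (6 tensor components plus `ln S0`)
#' `ln S_i = ln S0 - b_i g_i' D g_i`. The fit is ordinary (unweighted) least
#' squares by default: deterministic, and exact in the noiseless limit.
#' `weighted = TRUE` switches to signal-weighted least squares (weights
#' proportional to the squared observed signal, the usual variance
#' stabilisation for log-transformed magnitude data). Multiple b = 0
#' measurements enter the regression as separate rows. Voxels with any
#' non-positive or non-finite signal are flagged invalid and left unfitted.
#'
#' @param dwi a `dwi_volume` (see [simulate_dwi()]).
#' @param weighted use signal-weighted instead of ordinary least squares.
#' @return A [tensor_field()] with `tensors`, `s0_est` and `valid_mask`
#'   populated (eigenvalues via [eigendecompose()]).
#' @export
fit_tensor <- function(dwi, weighted = FALSE) {
  stopifnot(inherits(dwi, "dwi_volume"))
  scheme <- dwi$scheme
  X <- dti_design_matrix(scheme)
  qrX <- qr(X)
  if (qrX$rank < 7L)
    stop("degenerate gradient design: rank ", qrX$rank,
         " < 7 (collinear diffusion directions)")
  gs <- dim(dwi$data)[1:3]
  m <- dim(dwi$data)[4L]
  nvox <- prod(gs)
  sig <- matrix(dwi$data, nvox, m)
  valid <- rowSums(!is.finite(sig) | sig <= 0) == 0L
  beta <- matrix(NA_real_, 7L, nvox)
  if (!weighted) {
    if (any(valid))
      beta[, valid] <- qr.coef(qrX, log(t(sig[valid, , drop = FALSE])))
  } else {
    for (i in which(valid)) {
      s <- sig[i, ]
      w <- s^2
      beta[, i] <- solve(crossprod(X, w * X), crossprod(X, w * log(s)))
    }
  }
  tensors <- array(t(beta[2:7, , drop = FALSE]), c(gs, 6L))
  tensor_field(tensors, voxel_size = dwi$voxel_size,
               s0_est = array(exp(beta[1L, ]), gs),
               valid_mask = array(valid, gs))
}

# design matrix of the log-linearised model; columns:
# ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz
dti_design_matrix <- function(scheme) {
  g <- scheme$bvecs
  b <- scheme$bvals
  cbind(1,
        -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
        -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
        -2 * b * g[2, ] * g[3, ])
}
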