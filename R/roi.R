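#' ROI statistics on a diffusivity map
#'
#' Mean, sample standard deviation, minimum and minimum-voxel location of a
#' scalar map inside a binary mask, after excluding invalid voxels (`NaN`
#' sentinel) and any voxels in an optional exclusion mask (e.g. known
#' susceptibility/bleed artifacts, which must not contribute the minimum).
#' Ties for the minimum are broken toward the smallest linear voxel index
#' (x-fastest order), so the readout is deterministic.
#'
#' @param map 3D numeric array (invalid voxels `NaN`/`NA`).
#' @param mask logical/0-1 array of the same shape.
#' @param reader_id identifier of the reader who drew the mask.
#' @param roi_name one of `"tumor"`, `"t2w"`.
#' @param map_name one of `"AD"`, `"MD"`, `"RD"` (free-form allowed).
#' @param exclude optional logical array of voxels to drop before readout.
#' @return An object of class `roi_stats`: list with `map_name`, `roi_name`,
#'   `reader_id`, `mean`, `sd`, `minimum`, `argmin` (1-based voxel index
#'   triple), `n_voxels` (used), `n_excluded`.
#' @export
extract_roi_stats <- function(map, mask, reader_id = "reader1",
                              roi_name = "tumor", map_name = "MD",
                              exclude = NULL) {
  stopifnot(identical(dim(map), dim(mask)))
  mask <- array(as.logical(mask), dim(mask))
  keep <- mask & is.finite(map)
  if (!is.null(exclude)) {
    stopifnot(identical(dim(exclude), dim(map)))
    keep <- keep & !as.logical(exclude)
  }
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("ROI '", roi_name, "' is empty after excluding invalid voxels")
  vals <- map[idx]
  imin <- idx[which.min(vals)]        # which.min: first minimum wins
  structure(list(map_name = map_name, roi_name = roi_name,
                 reader_id = reader_id,
                 mean = mean(vals),
                 sd = if (length(vals) > 1L) stats::sd(vals) else 0,
                 minimum = min(vals),
                 argmin = as.integer(arrayInd(imin, dim(map))),
                 n_voxels = length(idx),
                 n_excluded = sum(mask) - length(idx)),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf(
    "%s in %s ROI (%s): mean %.4g, sd %.3g, min %.4g at (%d,%d,%d); n=%d (%d excluded)\n",
    x$map_name, x$roi_name, x$reader_id, x$mean, x$sd, x$minimum,
    x$argmin[1], x$argmin[2], x$argmin[3], x$n_voxels, x$n_excluded))
  invisible(x)
}

#' Two-reader contrast-to-noise ratio between tumor and T2w-hyperintense ROIs
#'
#' The CNR contrasts the reader-averaged mean map value of the surrounding
#' T2w-hyperintense tissue against the reader-averaged mean of the tumor
#' ROI, normalised by a pooled spread term:
#'
#' \deqn{CNR = \frac{(D_{T2w,r1} + D_{T2w,r2})/2 - (D_{tum,r1} + D_{tum,r2})/2}{STD}}
#'
#' with `STD = (SD_t2w,r1 + SD_t2w,r2)/2 + (SD_tum,r1 + SD_tum,r2)/2` (the
#' plain sum of the two reader-averaged standard deviations). The statistic
#' is symmetric under swapping the reader labels, zero when the
#' reader-averaged means coincide, and positive when the tumor is darker
#' than the surrounding hyperintense tissue.
#'
#' @param t2w_r1,t2w_r2 [extract_roi_stats()] results for the
#'   T2w-hyperintense ROI of readers 1 and 2.
#' @param tumor_r1,tumor_r2 the same for the tumor ROI.
#' @return An object of class `cnr_result`: list with `map_name`, `cnr`,
#'   `pooled_sd` and `inputs`.
#' @export
compute_cnr <- function(t2w_r1, t2w_r2, tumor_r1, tumor_r2) {
  inputs <- list(t2w_r1 = t2w_r1, t2w_r2 = t2w_r2,
                 tumor_r1 = tumor_r1, tumor_r2 = tumor_r2)
  stopifnot(all(vapply(inputs, inherits, logical(1), "roi_stats")))
  maps <- vapply(inputs, `[[`, character(1), "map_name")
  if (length(unique(maps)) != 1L)
    stop("all four ROI statistics must come from the same map")
  pooled_sd <- (t2w_r1$sd + t2w_r2$sd) / 2 + (tumor_r1$sd + tumor_r2$sd) / 2
  num <- (t2w_r1$mean + t2w_r2$mean) / 2 - (tumor_r1$mean + tumor_r2$mean) / 2
  if (pooled_sd == 0) {
    if (num == 0)
      return(structure(list(map_name = maps[[1]], cnr = 0,
                            pooled_sd = 0, inputs = inputs),
                       class = "cnr_result"))
    stop("pooled standard deviation is zero (constant ROIs): CNR undefined")
  }
  structure(list(map_name = maps[[1]], cnr = num / pooled_sd,
                 pooled_sd = pooled_sd, inputs = inputs),
            class = "cnr_result")
}

#' @export
print.cnr_result <- function(x, ...) {
  cat(sprintf("CNR(%s) = %.3f (pooled SD %.4g)\n",
              x$map_name, x$cnr, x$pooled_sd))
  invisible(x)
}

#' Signal drop of a biomarker relative to a reference level
#'
#' Expresses a group-mean biomarker (typically the early-transformation
#' subgroup mean) as a percentage of a reference group mean (the stable
#' cohort): `100 * event / reference`. Both the full-precision value and the
#' one-decimal value used for reporting are returned.
#'
#' @param group_mean_event event-group mean diffusivity.
#' @param group_mean_reference reference-group mean diffusivity (> 0), same
#'   units.
#' @return List with `percent` (unrounded) and `percent_reported`
#'   (one decimal).
#' @examples
#' signal_drop_percent(0.82, 1.28)$percent_reported  # 64.1
#' @export
signal_drop_percent <- function(group_mean_event, group_mean_reference) {
  if (!is.finite(group_mean_reference) || group_mean_reference <= 0)
    stop("reference group mean must be positive")
  p <- 100 * group_mean_event / group_mean_reference
  list(percent = p, percent_reported = round(p, 1))
}

#' Emulate a second reader's ROI by boundary perturbation
#'
#' Real readers segment the same structure with small boundary differences.
#' This helper perturbs a mask by toggling each boundary voxel (an in-mask
#' voxel with an out-of-mask 6-neighbour, or vice versa) independently with
#' probability `p`, under a fixed seed, while guaranteeing a non-empty
#' result. It supplies non-identical masks for two-reader CNR and agreement
#' statistics in synthetic runs.
#'
#' @param mask logical 3D array.
#' @param p per-boundary-voxel toggle probability.
#' @param seed integer seed.
#' @return A perturbed logical array of the same shape.
#' @export
perturb_mask <- function(mask, p = 0.3, seed = 1L) {
  stopifnot(length(dim(mask)) == 3L, p >= 0, p <= 1)
  mask <- array(as.logical(mask), dim(mask))
  nb <- neighbour_count(mask)
  boundary <- which((mask & nb < 6L) | (!mask & nb > 0L))
  set.seed(as.integer(seed))
  flip <- boundary[stats::runif(length(boundary)) < p]
  out <- mask
  out[flip] <- !out[flip]
  if (!any(out)) out[which(mask)[1L]] <- TRUE
  out
}

# number of TRUE 6-neighbours per voxel (zero padding at the faces)
neighbour_count <- function(mask) {
  d <- dim(mask)
  m <- array(as.integer(mask), d)
  out <- array(0L, d)
  shift <- function(a, axis, by) {
    idx <- lapply(d, seq_len)
    src <- seq_len(d[axis]) - by
    ok <- src >= 1L & src <= d[axis]
    res <- array(0L, d)
    idx_to <- idx; idx_to[[axis]] <- which(ok)
    idx_from <- idx; idx_from[[axis]] <- src[ok]
    res[idx_to[[1]], idx_to[[2]], idx_to[[3]]] <-
      a[idx_from[[1]], idx_from[[2]], idx_from[[3]]]
    res
  }
  for (axis in 1:3) for (by in c(-1L, 1L)) out <- out + shift(m, axis, by)
  out
}
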