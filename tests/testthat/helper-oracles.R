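# Independent oracles and small fixtures shared across test files.

# Brute-force AUC for the low-is-positive marker: pairwise concordance of
# (transformed below stable), with half credit for ties.
auc_concordance <- function(values, labels) {
  pos <- values[labels == 1]
  neg <- values[labels == 0]
  mean(outer(pos, neg, function(a, b) (a < b) + 0.5 * (a == b)))
}

# Compact three-tissue phantom for fast tests: cavity + hyperintense zone +
# lesion over anisotropic white matter, same structure as the default.
small_phantom_spec <- function() {
  phantom_spec(
    grid_shape = c(16L, 16L, 8L),
    voxel_size = c(1.8, 1.8, 4),
    regions = list(
      phantom_region("background_wm", NULL,
                     tensor_aniso(1.7e-3, 0.4e-3, 0.3e-3, c(1, 0, 0)), 800),
      phantom_region("cavity_csf", geom_sphere(c(8, 8, 4), 2),
                     tensor_iso(3.0e-3), 1000),
      phantom_region("t2_hyperintense", geom_sphere(c(11, 8, 4), 3),
                     tensor_iso(1.28e-3), 900),
      phantom_region("lesion", geom_sphere(c(12, 8, 4), 1.4),
                     tensor_iso(0.72e-3), 850)
    )
  )
}

# Single-region isotropic phantom on a tiny grid.
iso_phantom_spec <- function(d = 1.0e-3, grid = c(4L, 4L, 2L), s0 = 500) {
  phantom_spec(grid, c(2, 2, 2),
               list(phantom_region("background_wm", NULL, tensor_iso(d), s0)))
}

# Build roi_stats objects directly (for CNR identity tests).
make_roi_stats <- function(mean, sd, map_name = "AD", roi_name = "tumor",
                           reader_id = "reader1") {
  structure(list(map_name = map_name, roi_name = roi_name,
                 reader_id = reader_id, mean = mean, sd = sd,
                 minimum = mean, argmin = c(1L, 1L, 1L),
                 n_voxels = 10L, n_excluded = 0L),
            class = "roi_stats")
}
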