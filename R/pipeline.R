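#' Write and read volumes as NIfTI
#'
#' Thin wrappers over RNifti that stamp the voxel size into the header.
#' Masks are written as uint8.
#'
#' @param vol 3D/4D numeric array or logical mask.
#' @param path output path (`.nii.gz`).
#' @param voxel_size numeric 3-vector, mm.
#' @export
write_volume_nifti <- function(vol, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(vol * 1)
  pd <- c(voxel_size, rep(1, max(0L, length(dim(vol)) - 3L)))
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
write_mask_nifti <- function(vol, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.integer(vol), dim(vol)))
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  attr(arr, "voxel_size") <- RNifti::pixdim(img)[seq_len(min(3L, length(dim(img))))]
  arr
}

#' Imaging pipeline configuration
#'
#' Collects every knob of the phantom-to-CNR pipeline so a run is fully
#' reproducible from its config and seed.
#'
#' @param phantom a [phantom_spec()]; default [default_phantom_spec()].
#' @param scheme a [gradient_scheme()]; default [default_gradient_scheme()].
#' @param snr signal-to-noise ratio for the simulated acquisition, or `NULL`
#'   for noiseless data.
#' @param seed integer master seed; the noise and reader-perturbation seeds
#'   are derived from it.
#' @param reader_perturb_p boundary-toggle probability used to emulate the
#'   second reader's masks.
#' @param out_dir optional directory: when given, maps, masks, bval/bvec and
#'   result tables are written there.
#' @return A list of class `run_config`.
#' @export
imaging_config <- function(phantom = default_phantom_spec(),
                           scheme = default_gradient_scheme(),
                           snr = 20, seed = 1L, reader_perturb_p = 0.3,
                           out_dir = NULL) {
  structure(list(phantom = phantom, scheme = scheme, snr = snr,
                 seed = as.integer(seed),
                 reader_perturb_p = reader_perturb_p, out_dir = out_dir),
            class = "run_config")
}

#' Run the imaging pipeline: phantom to two-reader CNR
#'
#' Builds the phantom, simulates the DWI acquisition, fits tensors, derives
#' the AD/MD/RD maps, extracts tumor and T2w-hyperintense ROI statistics
#' for two emulated readers (reader 2 uses boundary-perturbed masks) and
#' computes the per-map CNR. With `out_dir` set, writes the maps, masks and
#' gradient table to disk alongside CSV summaries.
#'
#' @param config an [imaging_config()].
#' @return A list of class `run_report` with elements `maps`
#'   ([compute_maps()] output), `roi_stats` (data frame, diffusivities in
#'   1e-3 mm^2/s), `cnr` (data frame per map), `n_clamped`, `config` and
#'   `seed`.
#' @export
run_imaging_pipeline <- function(config = imaging_config()) {
  stopifnot(inherits(config, "run_config"))
  truth <- build_phantom(config$phantom)
  dwi <- simulate_dwi(truth, config$scheme, snr = config$snr,
                      seed = config$seed)
  field <- eigendecompose(fit_tensor(dwi))
  maps <- compute_maps(field)

  masks_r1 <- list(tumor = truth$masks$tumor, t2w = truth$masks$t2w)
  if (is.null(masks_r1$tumor) || is.null(masks_r1$t2w))
    stop("imaging pipeline needs lesion and t2_hyperintense regions")
  masks_r2 <- list(
    tumor = perturb_mask(masks_r1$tumor, config$reader_perturb_p,
                         seed = config$seed + 1000L),
    t2w = perturb_mask(masks_r1$t2w, config$reader_perturb_p,
                       seed = config$seed + 2000L))

  map_list <- list(AD = maps$ad, MD = maps$md, RD = maps$rd)
  roi_rows <- list()
  cnr_rows <- list()
  for (mn in names(map_list)) {
    st <- list()
    for (rd in c("reader1", "reader2")) {
      mk <- if (rd == "reader1") masks_r1 else masks_r2
      for (roi in c("tumor", "t2w")) {
        s <- extract_roi_stats(map_list[[mn]], mk[[roi]], reader_id = rd,
                               roi_name = roi, map_name = mn)
        st[[paste(roi, rd, sep = "_")]] <- s
        roi_rows[[length(roi_rows) + 1L]] <- data.frame(
          map = mn, roi = roi, reader = rd,
          mean = s$mean * 1e3, sd = s$sd * 1e3, minimum = s$minimum * 1e3,
          argmin_x = s$argmin[1], argmin_y = s$argmin[2],
          argmin_z = s$argmin[3],
          n_voxels = s$n_voxels, n_excluded = s$n_excluded)
      }
    }
    cnr <- compute_cnr(st$t2w_reader1, st$t2w_reader2,
                       st$tumor_reader1, st$tumor_reader2)
    cnr_rows[[mn]] <- data.frame(map = mn, cnr = cnr$cnr,
                                 pooled_sd = cnr$pooled_sd * 1e3)
  }
  report <- structure(list(maps = maps,
                           roi_stats = do.call(rbind, roi_rows),
                           cnr = do.call(rbind, cnr_rows),
                           n_clamped = maps$n_clamped,
                           config = config, seed = config$seed),
                      class = "run_report")
  rownames(report$cnr) <- NULL
  if (!is.null(config$out_dir)) write_imaging_outputs(report, truth, dwi)
  report
}

write_imaging_outputs <- function(report, truth, dwi) {
  dir.create(report$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(report$config$out_dir, f)
  vs <- dwi$voxel_size
  write_volume_nifti(dwi$data, out("dwi.nii.gz"), vs)
  write_bvalbvec(dwi$scheme, out("dwi"))
  maps <- report$maps
  for (mn in c("ad", "md", "rd"))
    write_volume_nifti(maps[[mn]], out(paste0(mn, ".nii.gz")), vs)
  write_mask_nifti(truth$masks$tumor, out("mask_tumor.nii.gz"), vs)
  write_mask_nifti(truth$masks$t2w, out("mask_t2w.nii.gz"), vs)
  utils::write.csv(report$roi_stats, out("roi_stats.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(report$cnr, out("cnr.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(report$config$out_dir)
}

#' Run the cohort statistics pipeline
#'
#' Simulates (or loads) a biomarker cohort, runs the ROC analysis per
#' parameter with the less-than-or-equal positivity rule, the group
#' comparison (ANOVA with Bonferroni correction), a two-reader agreement
#' analysis on binary "diffusion restriction present" ratings, and the
#' signal-drop percentages of an early-transformation subgroup relative to
#' the stable group.
#'
#' Reader ratings are emulated by adding independent per-reader Gaussian
#' measurement noise (`reader_noise_sd`, 1e-3 mm^2/s) to each subject's
#' biomarker and rating positive when the noisy value falls at or below the
#' parameter's Youden cutoff.
#'
#' @param cohort a cohort data frame (see [simulate_cohort()]); simulated
#'   from `spec` when `NULL`.
#' @param spec a [cohort_spec()] used when `cohort` is `NULL`.
#' @param early_mt_means named vector of early-transformation subgroup mean
#'   biomarkers (1e-3 mm^2/s) for the signal-drop computation.
#' @param reader_noise_sd per-reader measurement noise for the agreement
#'   emulation (1e-3 mm^2/s).
#' @param kappa_weighting `"linear"` or `"quadratic"`.
#' @param seed integer seed for the reader-noise draws.
#' @param out_dir optional output directory for CSV reports.
#' @return A list of class `run_report` with `roc` (data frame styled after
#'   a cutoff/sensitivity/specificity/AUC table), `roc_full` (the
#'   `roc_summary` objects), `groups` (the [group_compare()] table),
#'   `kappa` (per-parameter `kappa_result`s), `signal_drop` (data frame)
#'   and `cohort`.
#' @export
run_cohort_pipeline <- function(cohort = NULL, spec = cohort_spec(),
                                early_mt_means = c(ad_min = 0.82,
                                                   md_min = 0.73,
                                                   rd_min = 0.62),
                                reader_noise_sd = 0.05,
                                kappa_weighting = "linear",
                                seed = 1L, out_dir = NULL) {
  if (is.null(cohort)) cohort <- simulate_cohort(spec)
  params <- c("ad_min", "md_min", "rd_min")
  stopifnot(all(params %in% names(cohort)))

  roc_full <- lapply(params, function(p)
    roc_analysis(cohort[[p]], cohort$label, parameter_name = p))
  names(roc_full) <- params
  roc_tab <- do.call(rbind, lapply(roc_full, function(r) data.frame(
    parameter = r$parameter_name, cutoff = r$cutoff,
    sensitivity = r$sensitivity, specificity = r$specificity,
    auc = r$auc, auc_se = r$auc_se, ppv = r$ppv)))
  rownames(roc_tab) <- NULL

  groups <- group_compare(cohort, params)

  set.seed(as.integer(seed))
  kappa <- lapply(params, function(p) {
    r1 <- cohort[[p]] + stats::rnorm(nrow(cohort), 0, reader_noise_sd)
    r2 <- cohort[[p]] + stats::rnorm(nrow(cohort), 0, reader_noise_sd)
    cut <- roc_full[[p]]$cutoff
    weighted_kappa(as.integer(r1 <= cut), as.integer(r2 <= cut),
                   weighting = kappa_weighting)
  })
  names(kappa) <- params

  stable_means <- vapply(params, function(p)
    mean(cohort[[p]][cohort$label == 0L]), numeric(1))
  drops <- do.call(rbind, lapply(params, function(p) {
    sd_ <- signal_drop_percent(early_mt_means[[p]], stable_means[[p]])
    data.frame(parameter = p, early_mt_mean = early_mt_means[[p]],
               stable_mean = stable_means[[p]],
               drop_percent = sd_$percent,
               drop_percent_reported = sd_$percent_reported)
  }))

  report <- structure(list(roc = roc_tab, roc_full = roc_full,
                           groups = groups, kappa = kappa,
                           signal_drop = drops, cohort = cohort,
                           seed = as.integer(seed)),
                      class = "run_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(roc_tab, file.path(out_dir, "roc_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(groups, file.path(out_dir, "group_comparison.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(drops, file.path(out_dir, "signal_drop.csv"),
                     row.names = FALSE, quote = FALSE)
    for (p in params)
      utils::write.csv(roc_full[[p]]$curve,
                       file.path(out_dir, paste0("roc_curve_", p, ".csv")),
                       row.names = FALSE, quote = FALSE)
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  if (!is.null(x$cnr)) {
    cat("Imaging run report\n")
    print(x$cnr)
    cat(sprintf("clamped voxels: %d\n", x$n_clamped))
  }
  if (!is.null(x$roc)) {
    cat("Cohort run report\n")
    print(x$roc)
  }
  invisible(x)
}
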