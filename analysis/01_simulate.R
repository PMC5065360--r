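#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Builds the default post-resection phantom (CSF-filled cavity, adjacent
# T2w-hyperintense zone at the stable-group axial diffusivity, focal lesion
# at the transformed-group level), simulates a 13-measurement DWI
# acquisition (1 x b=0 + 12 directions at b = 1000 s/mm^2) with Rician
# noise at SNR 20, and simulates the 29-stable / 18-transformed biomarker
# cohort. Everything downstream reads only these files.

suppressPackageStartupMessages(library(dtimt))

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

truth <- build_phantom(default_phantom_spec())
scheme <- default_gradient_scheme()
cat("Phantom: "); print(truth)

dwi <- simulate_dwi(truth, scheme, snr = 20, seed = seed)
write_volume_nifti(dwi$data, file.path(out, "dwi.nii.gz"), dwi$voxel_size)
write_bvalbvec(scheme, file.path(out, "dwi"))
write_mask_nifti(truth$masks$tumor, file.path(out, "mask_tumor.nii.gz"),
                 dwi$voxel_size)
write_mask_nifti(truth$masks$t2w, file.path(out, "mask_t2w.nii.gz"),
                 dwi$voxel_size)
# ground-truth maps, for the fit-accuracy check in stage 2
ref <- compute_maps(truth)
for (mp in c("ad", "md", "rd"))
  write_volume_nifti(ref[[mp]], file.path(out, paste0("truth_", mp, ".nii.gz")),
                     dwi$voxel_size)

cohort <- simulate_cohort(cohort_spec(seed = seed))
write_cohort_csv(cohort, file.path(out, "cohort.csv"))

cat(sprintf("Wrote DWI (%s measurements), masks and a %d-subject cohort (%d transformed) to %s\n",
            length(scheme$bvals), nrow(cohort), sum(cohort$label), out))
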