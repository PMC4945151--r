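# Calibration-recovery targets: for each experiment preset, calibrate the
# generator so expected per-line crossings equal the published group means,
# re-measure through the full synthetic -> place -> count chain on fresh
# scenes, and report the measured grand means. Used both by the acceptance
# test suite and by scripts/acceptance.R.

#' Recompute the calibration-recovery target values
#'
#' Runs the four calibrated experiment geometries (layer-IV barrels with
#' astrocytes and capillaries, the A1/A2 disc, the IIIa/IIIb laminar strip,
#' and the blob mosaic) and returns the measured grand mean crossings per
#' line for each published group mean, with the number of lines behind each
#' value.
#'
#' @param seed integer root seed.
#' @param scale scene-count multiplier (1 = the designed measurement scale;
#'   smaller values give fast, noisier sanity runs).
#' @return named list: each element `list(value =, n =, target =)`.
#' @export
acceptance_targets <- function(seed = 1L, scale = 1) {
  cal <- calibration_constants()
  sc <- function(n) max(2L, as.integer(ceiling(n * scale)))
  out <- list()
  grab <- function(rc, tgt_id, group) {
    v <- rc$table$count[rc$table$group == group]
    out[[tgt_id]] <<- list(value = mean(v), n = length(v))
  }

  # t1-t4: layer-IV barrel field, astrocytes (pilot-calibrated) and
  # capillaries (analytic Buffon calibration), same measurement scenes
  ps <- build_preset("barrel_layer4", cal,
                     list(n_pilot = sc(180), n_scenes = sc(180)))
  rc <- run_calibrated(ps, derive_seed(seed, "acc_barrel"))
  grab(rc, "t1", "septal")
  grab(rc, "t2", "core")
  grab(rc, "t3", "cap_septal")
  grab(rc, "t4", "cap_core")

  # t5-t6: A1/A2 50 um offset lines
  ps <- build_preset("auditory_A1A2", cal,
                     list(n_pilot = sc(40), n_scenes = sc(40)))
  rc <- run_calibrated(ps, derive_seed(seed, "acc_auditory"),
                       with_capillary = FALSE)
  grab(rc, "t5", "A1_50")
  grab(rc, "t6", "A2_50")

  # t7-t8: IIIa/IIIb 50 um offset lines (375 um long)
  ps <- build_preset("human_IIIaIIIb", cal,
                     list(n_pilot = sc(90), n_scenes = sc(90)))
  rc <- run_calibrated(ps, derive_seed(seed, "acc_laminar"),
                       with_capillary = FALSE)
  grab(rc, "t7", "IIIa_50")
  grab(rc, "t8", "IIIb_50")

  # t9-t10: blob mosaic vertical lines
  ps <- build_preset("human_blobs", cal,
                     list(n_pilot = sc(380), n_scenes = sc(380)))
  rc <- run_calibrated(ps, derive_seed(seed, "acc_blobs"),
                       with_capillary = FALSE)
  grab(rc, "t9", "interblob_center")
  grab(rc, "t10", "blob_center")

  targets <- c(t1 = cal$barrel_layer4$astro$septal,
               t2 = cal$barrel_layer4$astro$core,
               t3 = cal$barrel_layer4$capillary$septal,
               t4 = cal$barrel_layer4$capillary$core,
               t5 = cal$auditory_A1A2$astro$A1_50,
               t6 = cal$auditory_A1A2$astro$A2_50,
               t7 = cal$human_IIIaIIIb$astro$IIIa_50,
               t8 = cal$human_IIIaIIIb$astro$IIIb_50,
               t9 = cal$human_blobs$astro$interblob_center,
               t10 = cal$human_blobs$astro$blob_center)
  for (id in names(out)) out[[id]]$target <- unname(targets[id])
  out
}
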