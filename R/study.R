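#' Desk-scale deformation-recovery study settings
#'
#' The fixed conditions of the displacement-model recovery study used by the
#' package's validation suite and the acceptance script: phantom geometry on
#' a 16^3 grid at 6 mm (same ~90 mm field of view as the clinical-scale
#' grid), a 3-level base-4 displacement U-Net, 50 training pairs built from
#' smooth random ground-truth fields (4 control points, 10 mm amplitude) and
#' supervised field-regression training. Held-out evaluation uses new fields
#' never seen in training.
#'
#' @return List of settings (prior, network spec, pair counts, field and
#'   optimizer parameters).
#' @export
ddfm_study_settings <- function() {
  base <- anatomy_params(grid_shape = c(16, 16, 16), spacing_mm = c(6, 6, 6),
                         rectum_z_extent = c(20, 70),
                         texture_amplitude = 15, noise_sd = 2)
  list(prior = list(base = base, axis_jitter = 0.12, center_jitter_mm = 3),
       spec = network_spec(3, 4, "displacement"),
       n_patients = 5, n_fields = 10, n_pairs = 50,
       field_ctrl = 4, field_amp = 10,
       epochs = 60, lr = 5e-3, lr_decay = 1)
}

#' Desk-scale method-comparison study configuration
#'
#' The shipped analogue of the clinical comparison: a training cohort with
#' moderate inter-fraction variation, and a test cohort whose fractions have
#' large bladder filling changes (volume factor 1.75-2.0) with a near-rigid
#' CTV — the regime in which segmentation models keep working, displacement
#' models cannot express the volume change, and rigid CTV copying is
#' near-optimal.
#'
#' @param seed master seed.
#' @param out_dir optional artifact directory.
#' @return An [experiment_config()].
#' @export
comparison_study_config <- function(seed = 1, out_dir = NULL) {
  experiment_config(
    n_train = 5, n_test = 3, n_fractions = 2,
    grid_shape = c(24, 24, 24), spacing_mm = c(4, 4, 4),
    anatomy = anatomy_params(texture_amplitude = 10),
    train_variation = variation_params(c(0.9, 1.3), c(0.9, 1.2), 1.5, 1.5),
    test_variation = variation_params(c(1.75, 2.0), c(0.9, 1.2), 0, 0),
    seg_levels = 3, ddf_levels = 3, base_channels = 4,
    bm_epochs = 45, psm_epochs = 25, ddfm_epochs = 15,
    seed = seed, out_dir = out_dir)
}
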