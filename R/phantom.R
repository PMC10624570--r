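#' Anatomy parameters for the pelvic phantom
#'
#' Describes one patient's planning-day anatomy as geometric primitives in
#' physical millimetres: the bladder and clinical target volume (CTV,
#' prostate) as ellipsoids and the rectum as a curved, capped tube posterior
#' to the CTV. Intensities follow a piecewise-constant tissue model (bright
#' fluid-filled bladder, darker rectum, intermediate prostate against a
#' muscle/fat background, qualitatively like low-field bSSFP contrast) with
#' additive Gaussian noise and an optional smooth multiplicative bias field.
#'
#' Defaults assume a field of view of roughly 96 mm per axis (64^3 voxels at
#' 1.5 mm); coarser desk-scale grids with the same physical extent (e.g. 24^3
#' at 4 mm) reuse the same geometry.
#'
#' @param grid_shape integer length-3 voxel counts.
#' @param spacing_mm voxel size per axis (mm).
#' @param bladder_center,bladder_axes ellipsoid centre and semi-axes (mm).
#' @param rectum_center (x, y) centreline position, curvature along z (mm).
#' @param rectum_radius tube radius (mm).
#' @param rectum_z_extent (zmin, zmax) of the capped tube (mm).
#' @param rectum_curve_mm amplitude of the sinusoidal centreline curve (mm).
#' @param ctv_center,ctv_axes CTV ellipsoid centre and semi-axes (mm).
#' @param intensity_means named per-tissue mean intensity (arbitrary units).
#' @param noise_sd additive Gaussian noise sd.
#' @param bias_amplitude amplitude of the smooth multiplicative bias field
#'   (0 disables it; then noiseless renders take the configured tissue means
#'   exactly inside the organs).
#' @param texture_amplitude amplitude of the smooth additive background
#'   texture emulating soft-tissue heterogeneity outside the organs (organ
#'   interiors keep their configured means). The texture is anchored to the
#'   patient (`texture_seed`), not to the acquisition day.
#' @param texture_seed patient-level seed for the background texture
#'   (defaults to `seed`); kept fixed across fractions of one patient.
#' @param seed RNG seed for noise/bias.
#' @return An object of class `anatomy_params`.
#' @export
anatomy_params <- function(grid_shape = c(64, 64, 64),
                           spacing_mm = c(1.5, 1.5, 1.5),
                           bladder_center = c(48, 30, 62),
                           bladder_axes = c(15, 13, 13),
                           rectum_center = c(48, 68),
                           rectum_radius = 7,
                           rectum_z_extent = c(10, 86),
                           rectum_curve_mm = 3,
                           ctv_center = c(48, 50, 40),
                           ctv_axes = c(11, 9, 9),
                           intensity_means = c(background = 60, bladder = 100,
                                               rectum = 40, ctv = 75),
                           noise_sd = 3,
                           bias_amplitude = 0,
                           texture_amplitude = 8,
                           texture_seed = NULL,
                           seed = 1) {
  p <- list(grid_shape = as.integer(rep(grid_shape, length.out = 3)),
            spacing_mm = rep(as.numeric(spacing_mm), length.out = 3),
            bladder_center = bladder_center, bladder_axes = bladder_axes,
            rectum_center = rectum_center, rectum_radius = rectum_radius,
            rectum_z_extent = rectum_z_extent, rectum_curve_mm = rectum_curve_mm,
            ctv_center = ctv_center, ctv_axes = ctv_axes,
            intensity_means = intensity_means, noise_sd = noise_sd,
            bias_amplitude = bias_amplitude,
            texture_amplitude = texture_amplitude,
            texture_seed = texture_seed, seed = seed)
  if (any(c(p$bladder_axes, p$ctv_axes, p$rectum_radius) <= 0)) {
    stop("all axes and radii must be positive")
  }
  if (p$noise_sd < 0 || p$bias_amplitude < 0) stop("noise/bias must be >= 0")
  structure(p, class = "anatomy_params")
}

#' Inter-fraction variation parameters
#'
#' Governs how each fraction's anatomy differs from the planning day: bladder
#' and rectum volumes are rescaled by factors drawn from the stated ranges
#' (emulating filling differences between treatment days), the CTV receives a
#' small random rigid displacement, and a smooth background deformation
#' shifts all structures coherently. Defaults are plausible clinical
#' magnitudes for pelvic anatomy, not measured values.
#'
#' @param bladder_volume_factor_range,rectum_volume_factor_range positive
#'   multiplicative volume ranges.
#' @param ctv_shift_sd_mm SD of the random rigid CTV displacement (mm).
#' @param elastic_amplitude_mm amplitude of the smooth background deformation.
#' @param seed RNG seed.
#' @return An object of class `variation_params`.
#' @export
variation_params <- function(bladder_volume_factor_range = c(0.6, 1.8),
                             rectum_volume_factor_range = c(0.7, 1.5),
                             ctv_shift_sd_mm = 1.5,
                             elastic_amplitude_mm = 2,
                             seed = 1) {
  if (any(c(bladder_volume_factor_range, rectum_volume_factor_range) <= 0)) {
    stop("volume factor ranges must be positive")
  }
  if (ctv_shift_sd_mm < 0 || elastic_amplitude_mm < 0) stop("amplitudes must be >= 0")
  structure(list(bladder_volume_factor_range = bladder_volume_factor_range,
                 rectum_volume_factor_range = rectum_volume_factor_range,
                 ctv_shift_sd_mm = ctv_shift_sd_mm,
                 elastic_amplitude_mm = elastic_amplitude_mm, seed = seed),
            class = "variation_params")
}

# Physical voxel-centre coordinate arrays (mm), origin at the first voxel.
phys_coords <- function(d, sp) {
  list(x = array(rep((0:(d[1] - 1)) * sp[1], times = d[2] * d[3]), d),
       y = array(rep(rep((0:(d[2] - 1)) * sp[2], each = d[1]), times = d[3]), d),
       z = array(rep((0:(d[3] - 1)) * sp[3], each = d[1] * d[2]), d))
}

render_ellipsoid <- function(co, center, axes) {
  (((co$x - center[1]) / axes[1])^2 + ((co$y - center[2]) / axes[2])^2 +
     ((co$z - center[3]) / axes[3])^2 <= 1) * 1
}

render_rectum <- function(co, p) {
  zlen <- diff(p$rectum_z_extent)
  cy <- p$rectum_center[2] +
    p$rectum_curve_mm * sin(2 * pi * (co$z - p$rectum_z_extent[1]) / max(zlen, 1))
  tube <- ((co$x - p$rectum_center[1])^2 + (co$y - cy)^2 <= p$rectum_radius^2)
  (tube & co$z >= p$rectum_z_extent[1] & co$z <= p$rectum_z_extent[2]) * 1
}

check_in_bounds <- function(mask, name, d) {
  if (sum(mask) == 0) stop(sprintf("structure '%s' renders empty", name))
  idx <- which(mask == 1, arr.ind = TRUE)
  # >= 2-voxel margin to every face
  if (any(idx < 3) || any(t(t(idx) > d - 2))) {
    stop(sprintf("structure '%s' extends outside the grid margin", name))
  }
}

render_anatomy <- function(p, noise_seed = p$seed) {
  d <- p$grid_shape; sp <- p$spacing_mm
  co <- phys_coords(d, sp)
  ctv <- render_ellipsoid(co, p$ctv_center, p$ctv_axes)
  bladder <- render_ellipsoid(co, p$bladder_center, p$bladder_axes)
  rectum <- render_rectum(co, p)
  check_in_bounds(ctv, "ctv", d)
  check_in_bounds(bladder, "bladder", d)
  check_in_bounds(rectum, "rectum", d)
  # enforce pairwise disjointness (CTV has priority, then bladder)
  bladder <- bladder * (1 - ctv)
  rectum <- rectum * (1 - ctv) * (1 - bladder)
  im <- p$intensity_means
  img <- array(im[["background"]], d)
  if ((p$texture_amplitude %||% 0) > 0) {
    tex <- smooth_noise3(d, pmax(4L, d %/% 3L), p$texture_amplitude,
                         p$texture_seed %||% p$seed)
    bg <- (bladder == 0) & (rectum == 0) & (ctv == 0)
    img[bg] <- img[bg] + tex[bg]
  }
  img[bladder == 1] <- im[["bladder"]]
  img[rectum == 1] <- im[["rectum"]]
  img[ctv == 1] <- im[["ctv"]]
  with_seed(noise_seed, {
    if (p$bias_amplitude > 0) {
      phase <- runif(3, 0, 2 * pi)
      fov <- (d - 1) * sp
      bias <- 1 + p$bias_amplitude *
        sin(2 * pi * co$x / fov[1] + phase[1]) *
        sin(2 * pi * co$y / fov[2] + phase[2]) *
        sin(2 * pi * co$z / fov[3] + phase[3])
      img <- img * bias
    }
    if (p$noise_sd > 0) img <- img + array(rnorm(prod(d), 0, p$noise_sd), d)
  })
  list(image = volume_image(img, sp),
       structures = structure_set(list(bladder = bladder, rectum = rectum,
                                       ctv = ctv), sp))
}

#' Generate a planning case
#'
#' Renders one patient's planning-day image and ground-truth structure masks
#' from the geometric anatomy description. Identical parameters and seed give
#' identical output.
#'
#' @param params an [anatomy_params()] object.
#' @return An object of class `patient_case` with the planning part filled.
#' @export
make_planning_case <- function(params) {
  rend <- render_anatomy(params)
  structure(list(id = "P01", planning = c(rend, list(params = params)),
                 fractions = list()),
            class = "patient_case")
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("<patient_case> %s: planning %s voxels, %d fraction(s)\n", x$id,
              paste(dim(x$planning$image$data), collapse = "x"),
              length(x$fractions)))
  invisible(x)
}

# Derive the fraction-day anatomy parameters from the planning parameters and
# one draw of the variation model. Volume factors act on the linear scale as
# factor^(1/3); structures are re-rendered (not warped), so genuine volume
# change exists in the ground truth.
vary_anatomy <- function(p, variation, fraction_seed) {
  with_seed(fraction_seed, {
    bf <- runif(1, variation$bladder_volume_factor_range[1],
                variation$bladder_volume_factor_range[2])
    rf <- runif(1, variation$rectum_volume_factor_range[1],
                variation$rectum_volume_factor_range[2])
    shift <- rnorm(3, 0, variation$ctv_shift_sd_mm)
    el <- if (variation$elastic_amplitude_mm > 0) {
      # smooth coherent background displacement, one offset per structure
      matrix(runif(9, -variation$elastic_amplitude_mm,
                   variation$elastic_amplitude_mm), nrow = 3)
    } else matrix(0, 3, 3)
    q <- p
    q$bladder_axes <- p$bladder_axes * bf^(1 / 3)
    q$bladder_center <- p$bladder_center + el[, 1]
    q$rectum_radius <- p$rectum_radius * sqrt(rf)   # tube: area scales volume
    q$rectum_center <- p$rectum_center + el[1:2, 2]
    q$ctv_center <- p$ctv_center + shift + el[, 3]
    q$texture_seed <- p$texture_seed %||% p$seed   # texture belongs to the patient
    q$seed <- fraction_seed
    list(params = q,
         truth = list(bladder_volume_factor = bf, rectum_volume_factor = rf,
                      ctv_shift_mm = shift))
  })
}

#' Sample fraction cases for a patient
#'
#' Each fraction gets its own anatomy: organ volumes rescaled by factors drawn
#' from the variation ranges, the CTV shifted by a small random rigid offset,
#' and a smooth background deformation. Ground-truth fraction masks are
#' re-rendered from the deformed geometry rather than produced by warping the
#' planning masks, so organ volume change (which no smooth displacement field
#' can express) genuinely exists in the ground truth. The generating draw is
#' recorded per fraction for later recovery checks.
#'
#' @param planning a [patient_case()] from [make_planning_case()].
#' @param variation a [variation_params()] object.
#' @param n_fractions number of fractions (>= 1).
#' @return The case with `fractions` populated.
#' @export
sample_fraction_case <- function(planning, variation, n_fractions = 1) {
  if (n_fractions < 1) stop("n_fractions must be >= 1")
  p <- planning$planning$params
  planning$fractions <- lapply(seq_len(n_fractions), function(f) {
    fs <- derive_seed(variation$seed, f)
    va <- vary_anatomy(p, variation, fs)
    rend <- render_anatomy(va$params, noise_seed = derive_seed(fs, 1))
    c(rend, list(params = va$params, truth = va$truth))
  })
  planning
}

#' Generate a synthetic cohort
#'
#' Per-patient anatomy is jittered around a base description (simulating
#' inter-patient variability), then fractions are sampled per patient. All
#' randomness flows through a seed hierarchy (cohort seed, then patient seed,
#' then fraction seed), so the cohort is reproducible.
#'
#' @param n_patients number of patients (>= 1).
#' @param anatomy_prior list with `base` (an [anatomy_params()]),
#'   `axis_jitter` (fractional semi-axis jitter) and `center_jitter_mm`.
#' @param variation a [variation_params()].
#' @param n_fractions fractions per patient (0 for planning-only cohorts).
#' @param seed cohort seed.
#' @return List of `patient_case` objects.
#' @export
make_cohort <- function(n_patients, anatomy_prior = list(base = anatomy_params(),
                                                         axis_jitter = 0.12,
                                                         center_jitter_mm = 3),
                        variation = variation_params(), n_fractions = 3, seed = 1) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  base <- anatomy_prior$base
  aj <- anatomy_prior$axis_jitter %||% 0.12
  cj <- anatomy_prior$center_jitter_mm %||% 3
  lapply(seq_len(n_patients), function(i) {
    ps <- derive_seed(seed, i)
    p <- with_seed(ps, {
      q <- base
      q$bladder_axes <- base$bladder_axes * runif(3, 1 - aj, 1 + aj)
      q$ctv_axes <- base$ctv_axes * runif(3, 1 - aj, 1 + aj)
      q$rectum_radius <- base$rectum_radius * runif(1, 1 - aj, 1 + aj)
      q$bladder_center <- base$bladder_center + runif(3, -cj, cj)
      q$ctv_center <- base$ctv_center + runif(3, -cj, cj)
      q$seed <- ps
      q
    })
    case <- make_planning_case(p)
    case$id <- sprintf("P%02d", i)
    if (n_fractions >= 1) {
      v <- variation
      v$seed <- derive_seed(ps, 7)
      case <- sample_fraction_case(case, v, n_fractions)
    }
    case
  })
}

#' Derive a planning target volume (PTV) by isotropic dilation
#'
#' Spacing-aware morphological dilation of the CTV by `margin_mm`, computed
#' with an exact Euclidean distance transform; the PTV always contains the
#' CTV.
#'
#' @param ctv binary CTV mask.
#' @param margin_mm dilation margin in mm (>= 0); default 5 mm.
#' @param spacing_mm voxel spacing.
#' @return Binary PTV mask.
#' @export
derive_ptv <- function(ctv, margin_mm = 5, spacing_mm = c(1.5, 1.5, 1.5)) {
  if (margin_mm < 0) stop("margin must be >= 0")
  if (margin_mm == 0) return(ctv * 1)
  d2 <- cp_edt_sq(as.numeric(ctv), dim(ctv), rep(as.numeric(spacing_mm), length.out = 3))
  (array(d2, dim(ctv)) <= margin_mm^2 + 1e-9) * 1
}
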