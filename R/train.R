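#' Augmentation parameters
#'
#' On-the-fly augmentation used for patient-specific fine-tuning: random
#' affine (rotation, translation, isotropic scale), random smooth elastic
#' deformation, additive Gaussian noise and multiplicative intensity scaling,
#' applied consistently to image (linear interpolation) and masks
#' (linear-then-threshold). All amplitudes zero gives the identity.
#'
#' @param rot_deg max rotation per axis (degrees).
#' @param trans_mm max translation per axis (mm).
#' @param scale max fractional isotropic scale change.
#' @param elastic_mm elastic deformation amplitude (mm).
#' @param noise_sd additive noise sd (intensity units).
#' @param intensity max fractional intensity scaling.
#' @return An object of class `augment_params`.
#' @export
augment_params <- function(rot_deg = 5, trans_mm = 3, scale = 0.05,
                           elastic_mm = 2, noise_sd = 2, intensity = 0.1) {
  structure(list(rot_deg = rot_deg, trans_mm = trans_mm, scale = scale,
                 elastic_mm = elastic_mm, noise_sd = noise_sd,
                 intensity = intensity), class = "augment_params")
}

#' Training configuration
#'
#' One object covering the three regimes: generic baseline segmentation
#' models (BM), patient-specific fine-tuned models (PSM) and displacement
#' models (DDFM) with their data variants (synthetic ground-truth fields,
#' registration-derived "realistic" fields, or true planning/fraction pairs
#' without ground truth) and schedules (at-once or progressive
#' coarse-to-fine).
#'
#' @param regime "BM", "PSM" or "DDFM".
#' @param spec a [network_spec()] (head must match the regime).
#' @param epochs training epochs (>= 1).
#' @param batch_size minibatch size (>= 1).
#' @param learning_rate Adam step size; defaults to 1e-3 (BM/DDFM) or 1e-4
#'   (PSM fine-tuning).
#' @param lr_decay per-epoch multiplicative learning-rate decay (1 = none).
#' @param ddfm_data_variant "gt_synthetic_ddf", "gt_realistic_ddf" or
#'   "true_pairs" (read only when regime is DDFM).
#' @param schedule "at_once" or "progressive".
#' @param weights a [loss_weights()] object.
#' @param scales multi-scale Dice smoothing extents (voxels).
#' @param img_kind image-similarity kind, "l2" or "ncc".
#' @param structures structure names entering the contour loss (default: all
#'   present in the data).
#' @param augment an [augment_params()] (PSM only).
#' @param ddf_control_points,ddf_max_mm sampling parameters of the synthetic
#'   training fields (gt_synthetic_ddf variant).
#' @param seed RNG seed controlling shuffling, augmentation and field draws.
#' @return An object of class `training_config`.
#' @export
training_config <- function(regime = c("BM", "PSM", "DDFM"),
                            spec = NULL,
                            epochs = 50, batch_size = 2,
                            learning_rate = NULL, lr_decay = 1,
                            ddfm_data_variant = c("true_pairs", "gt_synthetic_ddf",
                                                  "gt_realistic_ddf"),
                            schedule = c("at_once", "progressive"),
                            weights = loss_weights(),
                            scales = c(0, 2, 4),
                            img_kind = c("l2", "ncc"),
                            structures = NULL,
                            augment = augment_params(),
                            ddf_control_points = 6, ddf_max_mm = 6,
                            seed = 1) {
  regime <- match.arg(regime)
  if (epochs < 1 || batch_size < 1) stop("epochs and batch_size must be >= 1")
  structure(list(regime = regime, spec = spec, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate %||%
                   if (regime == "PSM") 1e-4 else 1e-3,
                 lr_decay = lr_decay,
                 ddfm_data_variant = match.arg(ddfm_data_variant),
                 schedule = match.arg(schedule), weights = weights,
                 scales = scales, img_kind = match.arg(img_kind),
                 structures = structures, augment = augment,
                 ddf_control_points = ddf_control_points,
                 ddf_max_mm = ddf_max_mm, seed = seed),
            class = "training_config")
}

# ---- parameter-tree utilities and Adam -------------------------------------

tree_flatten <- function(p) unlist(p, use.names = FALSE)

tree_unflatten <- function(vec, skel) {
  i <- 0L
  fill <- function(s) {
    if (is.null(s)) return(NULL)
    if (is.list(s)) return(lapply(s, fill))
    n <- length(s)
    out <- vec[(i + 1L):(i + n)]
    i <<- i + n
    dim(out) <- dim(s)
    out
  }
  fill(skel)
}

adam_new <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- b1 * st$m + (1 - b1) * grad
  st$v <- b2 * st$v + (1 - b2) * grad^2
  mh <- st$m / (1 - b1^st$t)
  vh <- st$v / (1 - b2^st$t)
  list(theta = theta - lr * mh / (sqrt(vh) + eps), state = st)
}

# One segmentation gradient step contribution for a single (image, mask) pair.
seg_sample_grad <- function(model, x, target) {
  fw <- unet_forward(model, x, want_cache = TRUE)
  p <- sigmoid(fw$out[, , , 1])
  loss <- soft_dice_loss(p, target)
  gp <- soft_dice_grad(p, target)
  gout <- array(gp * p * (1 - p), dim(fw$out))
  g <- unet_backward(model, fw$cache, gout)
  list(loss = loss, grad = tree_flatten(g))
}

run_seg_training <- function(model, data, config) {
  theta <- tree_flatten(model$params)
  st <- adam_new(length(theta))
  hist <- data.frame(epoch = integer(), total = numeric())
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      lr_ep <- config$learning_rate * (config$lr_decay %||% 1)^(ep - 1)
      ord <- sample(length(data))
      losses <- numeric(0)
      bi <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (batch in bi) {
        gacc <- numeric(length(theta)); lacc <- 0
        for (s in batch) {
          r <- seg_sample_grad(model, data[[s]]$x, data[[s]]$t)
          gacc <- gacc + r$grad / length(batch)
          lacc <- lacc + r$loss / length(batch)
        }
        up <- adam_step(theta, gacc, st, lr_ep)
        theta <- up$theta; st <- up$state
        model$params <- tree_unflatten(theta, model$params)
        losses <- c(losses, lacc)
      }
      hist <- rbind(hist, data.frame(epoch = ep, total = mean(losses)))
    }
  })
  model$history <- hist
  model
}

#' Train a baseline segmentation model (BM)
#'
#' Trains one single-structure 3D U-Net on the planning images and planning
#' contours of a cohort, minimizing the soft Dice loss with Adam. The
#' per-epoch training loss is recorded in the returned model's `history`.
#'
#' @param planning_cases list of `patient_case` objects (>= 2).
#' @param structure structure name to segment (must exist in every case).
#' @param config a [training_config()] with regime "BM" and a segmentation
#'   [network_spec()].
#' @return A trained `unet3d`.
#' @export
train_baseline <- function(planning_cases, structure, config) {
  if (length(planning_cases) < 2) stop("need at least 2 planning cases")
  data <- lapply(planning_cases, function(cs) {
    m <- cs$planning$structures$masks[[structure]]
    if (is.null(m)) stop(sprintf("case %s lacks structure '%s'", cs$id, structure))
    list(x = array(normalize_volume(cs$planning$image$data),
                   c(dim(cs$planning$image$data), 1)),
         t = m)
  })
  model <- build_network(config$spec, seed = config$seed)
  model <- run_seg_training(model, data, config)
  model$structure <- structure
  model
}

#' Fine-tune a baseline model on one patient (PSM)
#'
#' All parameters are updated from the baseline initialization using only
#' augmented copies of the patient's single planning image and contour;
#' the augmentation is re-sampled at every step.
#'
#' @param base_model trained baseline `unet3d`.
#' @param planning_case the patient's `patient_case` (planning part used).
#' @param config a [training_config()] with regime "PSM".
#' @return The fine-tuned `unet3d` (same architecture and parameter count).
#' @export
finetune_patient <- function(base_model, planning_case, config) {
  structure_name <- config$structures %||% base_model$structure
  m <- planning_case$planning$structures$masks[[structure_name[1]]]
  if (is.null(m)) stop(sprintf("planning case lacks structure '%s'", structure_name[1]))
  model <- base_model
  theta <- tree_flatten(model$params)
  st <- adam_new(length(theta))
  hist <- data.frame(epoch = integer(), total = numeric())
  part <- list(image = planning_case$planning$image,
               structures = planning_case$planning$structures)
  for (ep in seq_len(config$epochs)) {
    aug <- augment_case(part, config$augment, seed = derive_seed(config$seed, ep))
    x <- array(normalize_volume(aug$image$data), c(dim(aug$image$data), 1))
    r <- seg_sample_grad(model, x, aug$structures$masks[[structure_name[1]]])
    up <- adam_step(theta, r$grad, st, config$learning_rate)
    theta <- up$theta; st <- up$state
    model$params <- tree_unflatten(theta, model$params)
    hist <- rbind(hist, data.frame(epoch = ep, total = r$loss))
  }
  model$history <- hist
  model$structure <- structure_name[1]
  model
}

#' Randomly augment a case (image plus structures)
#'
#' Applies a random affine (rotation, translation, scale) composed with a
#' random smooth elastic deformation, then additive noise and intensity
#' scaling. Image and masks receive the identical geometric transform;
#' deterministic under the seed.
#'
#' @param case list with `image` ([volume_image()]) and `structures`
#'   ([structure_set()]).
#' @param params an [augment_params()].
#' @param seed RNG seed.
#' @return The augmented case (same list shape).
#' @export
augment_case <- function(case, params, seed = 1) {
  img <- case$image
  d <- dim(img$data); sp <- img$spacing
  with_seed(seed, {
    ang <- runif(3, -params$rot_deg, params$rot_deg) * pi / 180
    tr <- runif(3, -params$trans_mm, params$trans_mm)
    sc <- runif(1, 1 - params$scale, 1 + params$scale)
    ifac <- runif(1, 1 - params$intensity, 1 + params$intensity)
    eseed <- derive_seed(seed, 99)
    noise <- if (params$noise_sd > 0) array(rnorm(prod(d), 0, params$noise_sd), d) else 0
    Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])), c(0, sin(ang[1]), cos(ang[1])))
    Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0), c(-sin(ang[2]), 0, cos(ang[2])))
    Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0), c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
    A <- sc * Rz %*% Ry %*% Rx
    co <- phys_coords(d, sp)
    cen <- (d - 1) * sp / 2
    xc <- co$x - cen[1]; yc <- co$y - cen[2]; zc <- co$z - cen[3]
    u <- array(0, c(d, 3))
    u[, , , 1] <- A[1, 1] * xc + A[1, 2] * yc + A[1, 3] * zc + cen[1] + tr[1] - co$x
    u[, , , 2] <- A[2, 1] * xc + A[2, 2] * yc + A[2, 3] * zc + cen[2] + tr[2] - co$y
    u[, , , 3] <- A[3, 1] * xc + A[3, 2] * yc + A[3, 3] * zc + cen[3] + tr[3] - co$z
    ddf <- displacement_field(u, sp, img$origin)
    if (params$elastic_mm > 0) {
      el <- random_bspline_ddf(img, 5, params$elastic_mm, seed = eseed)
      ddf$vectors <- ddf$vectors + el$vectors
    }
    wimg <- warp_image(img, ddf, "linear")
    wimg$data <- wimg$data * ifac + noise
    wmasks <- lapply(case$structures$masks, warp_mask, ddf = ddf)
    list(image = wimg,
         structures = structure_set(wmasks, sp, img$origin))
  })
}

#' Progressive coarse-to-fine schedule
#'
#' Splits training into `n_levels` stages: stage `s` trains on data
#' sub-sampled by `2^(n_levels - s)` (the first stage therefore sees the
#' coarsest alignment, the last full resolution), with epochs divided evenly
#' and the remainder assigned to the final stage. Stage parameters warm-start
#' from the previous stage.
#'
#' @param n_levels number of U-Net levels (>= 2).
#' @param total_epochs total epochs (>= n_levels).
#' @return data.frame with columns `stage`, `factor`, `epochs`, `start`, `end`.
#' @export
progressive_schedule <- function(n_levels, total_epochs) {
  if (n_levels < 2) stop("n_levels must be >= 2")
  if (total_epochs < n_levels) stop("total_epochs must be >= n_levels")
  fac <- 2^((n_levels - 1):0)
  per <- total_epochs %/% n_levels
  ep <- rep(per, n_levels)
  ep[n_levels] <- ep[n_levels] + total_epochs %% n_levels
  end <- cumsum(ep)
  data.frame(stage = seq_len(n_levels), factor = fac, epochs = ep,
             start = c(1, head(end, -1) + 1), end = end)
}

# Sub-sample by `factor` and interpolate back to the full grid: a smoothed
# (frequency-limited) copy at unchanged shape, so the network's divisibility
# contract holds at every progressive stage.
blur_by_factor <- function(vol, factor) {
  if (factor <= 1) return(vol)
  d <- dim(vol)
  small <- pmax(2L, as.integer(round(d / factor)))
  dn <- cp_resize3d(as.numeric(vol), d, small, 0L)
  array(cp_resize3d(as.numeric(dn), small, d, 0L), d)
}

# Gradient of the DDFM composite loss with respect to the mm-unit field.
ddfm_loss_and_grad <- function(v_mm, spacing, planning_norm, fraction_norm,
                               pl_masks, fr_masks, gt_ddf, config) {
  w <- config$weights
  has_gt <- !is.null(gt_ddf)
  ddf <- displacement_field(v_mm, spacing)
  comp <- list()
  g <- array(0, dim(v_mm))
  eff_reg <- w$lambda_ddf * w$lambda_ddf_reg
  eff_l2 <- if (has_gt) w$lambda_ddf * w$lambda_ddf_l2 else 0
  comp$reg <- bending_energy(ddf)
  if (eff_reg > 0) g <- g + eff_reg * bending_energy_grad(ddf)
  if (has_gt) {
    comp$l2 <- ddf_l2_loss(ddf, gt_ddf)
    if (eff_l2 > 0) g <- g + eff_l2 * 2 * (v_mm - gt_ddf$vectors) / length(v_mm)
  }
  if (w$lambda_seg > 0) {
    segs <- 0
    for (nm in names(pl_masks)) {
      wm <- spatial_transform(pl_masks[[nm]], ddf)
      segs <- segs + multiscale_dice_loss(wm, fr_masks[[nm]], config$scales)
      gw <- multiscale_dice_grad(wm, fr_masks[[nm]], config$scales) / length(pl_masks)
      g <- g + w$lambda_seg * spatial_transform_grad_ddf(pl_masks[[nm]], ddf, gw)
    }
    comp$seg <- segs / length(pl_masks)
  }
  if (w$lambda_img > 0) {
    wi <- spatial_transform(planning_norm, ddf)
    comp$img <- image_similarity_loss(wi, fraction_norm, config$img_kind)
    gi <- image_similarity_grad(wi, fraction_norm, config$img_kind)
    g <- g + w$lambda_img * spatial_transform_grad_ddf(planning_norm, ddf, gi)
  }
  list(components = comp,
       total = total_loss(comp, w, has_gt_ddf = has_gt),
       grad_mm = g)
}

#' Train a displacement model (DDFM)
#'
#' Trains the 3-channel displacement U-Net through the spatial transformer by
#' minimizing the weighted sum of bending-energy regularization, multi-scale
#' soft Dice on the warped planning contours, image similarity of the warped
#' planning image, and (when ground-truth fields exist) supervised field
#' regression. Three data variants are supported: `gt_synthetic_ddf` draws a
#' fresh random smooth field per sample and step and warps the planning data
#' with it (on-the-fly pair synthesis), `gt_realistic_ddf` does the same with
#' fields drawn from a supplied registration-derived pool (`config$ddf_pool`
#' or per-pair `gt_ddf`), and `true_pairs` uses real planning/fraction pairs
#' without any ground-truth field (no L2 term).
#'
#' @param pairs list; each element has `planning` ([volume_image()]),
#'   `planning_masks` (named list of binary arrays), and for `true_pairs`
#'   also `fraction` and `fraction_masks`; for `gt_realistic_ddf` optionally
#'   `gt_ddf`.
#' @param config a [training_config()] with regime "DDFM" and a displacement
#'   [network_spec()]; `config$ddf_pool` may hold a list of
#'   [displacement_field()]s for the realistic variant.
#' @return A trained `unet3d` with per-epoch loss components in `history`.
#' @export
train_ddfm <- function(pairs, config) {
  variant <- config$ddfm_data_variant
  if (variant == "true_pairs") {
    ok <- vapply(pairs, function(p) !is.null(p$fraction) && !is.null(p$fraction_masks), TRUE)
    if (!all(ok)) stop("true_pairs variant requires fraction images and contours")
  }
  if (variant == "gt_realistic_ddf") {
    pool <- config$ddf_pool
    has_own <- vapply(pairs, function(p) !is.null(p$gt_ddf), TRUE)
    if (is.null(pool) && !all(has_own)) {
      stop("gt_realistic_ddf variant requires gt_ddf per pair or config$ddf_pool")
    }
  }
  model <- build_network(config$spec, seed = config$seed)
  theta <- tree_flatten(model$params)
  st <- adam_new(length(theta))
  stages <- if (config$schedule == "progressive") {
    progressive_schedule(config$spec$n_levels, config$epochs)
  } else {
    data.frame(stage = 1, factor = 1, epochs = config$epochs,
               start = 1, end = config$epochs)
  }
  sp <- pairs[[1]]$planning$spacing
  hist <- NULL
  with_seed(config$seed, {
    step <- 0L
    for (si in seq_len(nrow(stages))) {
      fac <- stages$factor[si]
      for (ep in seq_len(stages$epochs[si])) {
        ep_global <- nrow(hist %||% data.frame()) + 1
        lr_ep <- config$learning_rate * (config$lr_decay %||% 1)^(ep_global - 1)
        ord <- sample(length(pairs))
        comp_sums <- c(reg = 0, l2 = 0, seg = 0, img = 0, total = 0)
        nb <- 0
        for (batch in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
          gacc <- numeric(length(theta))
          for (s in batch) {
            step <- step + 1L
            pr <- pairs[[s]]
            pl_img <- pr$planning$data
            pl_masks <- pr$planning_masks
            if (variant == "true_pairs") {
              fr_img <- pr$fraction$data
              fr_masks <- pr$fraction_masks
              gt <- NULL
            } else {
              gt <- if (variant == "gt_synthetic_ddf") {
                random_bspline_ddf(pr$planning, config$ddf_control_points,
                                   config$ddf_max_mm,
                                   seed = derive_seed(config$seed, step))
              } else if (!is.null(pr$gt_ddf)) pr$gt_ddf else {
                config$ddf_pool[[sample(length(config$ddf_pool), 1)]]
              }
              fr_img <- spatial_transform(pl_img, gt)
              fr_masks <- if (config$weights$lambda_seg > 0) {
                lapply(pl_masks, function(m) (spatial_transform(m * 1, gt) >= 0.5) * 1)
              } else {
                lapply(pl_masks, function(m) m)
              }
            }
            if (!is.null(config$structures)) {
              pl_masks <- pl_masks[config$structures]
              fr_masks <- fr_masks[config$structures]
            }
            pn <- normalize_volume(pl_img); fn <- normalize_volume(fr_img)
            if (fac > 1) {
              pn <- blur_by_factor(pn, fac); fn <- blur_by_factor(fn, fac)
              pl_masks <- lapply(pl_masks, blur_by_factor, factor = fac)
              fr_masks <- lapply(fr_masks, blur_by_factor, factor = fac)
            }
            x <- array(c(pn, fn), c(dim(pn), 2))
            fw <- unet_forward(model, x, want_cache = TRUE)
            v_mm <- fw$out
            for (k in 1:3) v_mm[, , , k] <- v_mm[, , , k] * sp[k]
            lg <- ddfm_loss_and_grad(v_mm, sp, pn, fn, pl_masks, fr_masks, gt, config)
            gout <- lg$grad_mm
            for (k in 1:3) gout[, , , k] <- gout[, , , k] * sp[k]
            g <- unet_backward(model, fw$cache, gout)
            gacc <- gacc + tree_flatten(g) / length(batch)
            for (nm in names(lg$components)) {
              comp_sums[nm] <- comp_sums[nm] + lg$components[[nm]]
            }
            comp_sums["total"] <- comp_sums["total"] + lg$total
          }
          up <- adam_step(theta, gacc, st, lr_ep)
          theta <- up$theta; st <- up$state
          model$params <- tree_unflatten(theta, model$params)
          nb <- nb + length(batch)
        }
        hist <- rbind(hist, data.frame(
          stage = si, factor = fac, epoch = nrow(hist %||% data.frame()) + 1,
          reg = comp_sums[["reg"]] / nb, l2 = comp_sums[["l2"]] / nb,
          seg = comp_sums[["seg"]] / nb, img = comp_sums[["img"]] / nb,
          total = comp_sums[["total"]] / nb))
      }
    }
  })
  model$history <- hist
  model
}
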