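#' Training-loss weights
#'
#' Weights of the total objective
#' `L_tot = lambda_ddf * (lambda_ddf_l2 * L2 + lambda_ddf_reg * L_reg) +
#'  lambda_seg * L_seg + lambda_img * L_img`.
#' Defaults are the configuration found optimal for displacement-model
#' training in this workflow.
#'
#' @param lambda_ddf,lambda_ddf_l2,lambda_ddf_reg,lambda_seg,lambda_img
#'   nonnegative scalars.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_ddf = 1, lambda_ddf_l2 = 0, lambda_ddf_reg = 10,
                         lambda_seg = 100, lambda_img = 1) {
  w <- list(lambda_ddf = lambda_ddf, lambda_ddf_l2 = lambda_ddf_l2,
            lambda_ddf_reg = lambda_ddf_reg, lambda_seg = lambda_seg,
            lambda_img = lambda_img)
  if (any(unlist(w) < 0)) stop("loss weights must be nonnegative")
  structure(w, class = "loss_weights")
}

# Second-derivative terms of one scalar component on the interior box
# (central finite differences, spacing-aware).
be_component_terms <- function(u, sp) {
  d <- dim(u)
  I1 <- 2:(d[1] - 1); I2 <- 2:(d[2] - 1); I3 <- 2:(d[3] - 1)
  h <- sp
  list(
    xx = (u[I1 + 1, I2, I3] - 2 * u[I1, I2, I3] + u[I1 - 1, I2, I3]) / h[1]^2,
    yy = (u[I1, I2 + 1, I3] - 2 * u[I1, I2, I3] + u[I1, I2 - 1, I3]) / h[2]^2,
    zz = (u[I1, I2, I3 + 1] - 2 * u[I1, I2, I3] + u[I1, I2, I3 - 1]) / h[3]^2,
    xy = (u[I1 + 1, I2 + 1, I3] - u[I1 + 1, I2 - 1, I3] -
          u[I1 - 1, I2 + 1, I3] + u[I1 - 1, I2 - 1, I3]) / (4 * h[1] * h[2]),
    xz = (u[I1 + 1, I2, I3 + 1] - u[I1 + 1, I2, I3 - 1] -
          u[I1 - 1, I2, I3 + 1] + u[I1 - 1, I2, I3 - 1]) / (4 * h[1] * h[3]),
    yz = (u[I1, I2 + 1, I3 + 1] - u[I1, I2 - 1, I3 + 1] -
          u[I1, I2 + 1, I3 - 1] + u[I1, I2 - 1, I3 - 1]) / (4 * h[2] * h[3])
  )
}

#' Bending energy of a displacement field
#'
#' Mean over interior voxels of the summed squared second-order spatial
#' derivatives of all three components (mixed terms doubled), computed with
#' spacing-aware central finite differences. Zero for any affine field.
#'
#' @param ddf a [displacement_field()] on a grid with >= 3 voxels per axis.
#' @return Nonnegative scalar (mm^2 / mm^4 units at mm spacing).
#' @export
bending_energy <- function(ddf) {
  d <- dim(ddf$vectors)[1:3]
  if (any(d < 3)) stop("bending energy needs >= 3 voxels per axis")
  tot <- 0
  for (k in 1:3) {
    tm <- be_component_terms(ddf$vectors[, , , k], ddf$spacing)
    tot <- tot + sum(tm$xx^2 + tm$yy^2 + tm$zz^2 +
                     2 * (tm$xy^2 + tm$xz^2 + tm$yz^2))
  }
  tot / prod(d - 2)
}

# Gradient of bending_energy with respect to the mm-unit vectors
# (same shape as ddf$vectors). Used by registration and network training.
bending_energy_grad <- function(ddf) {
  d <- dim(ddf$vectors)[1:3]
  if (any(d < 3)) stop("bending energy needs >= 3 voxels per axis")
  sp <- ddf$spacing
  N <- prod(d - 2)
  I1 <- 2:(d[1] - 1); I2 <- 2:(d[2] - 1); I3 <- 2:(d[3] - 1)
  g <- array(0, dim(ddf$vectors))
  for (k in 1:3) {
    u <- ddf$vectors[, , , k]
    tm <- be_component_terms(u, sp)
    gk <- array(0, d)
    add <- function(gk, s1, s2, s3, v) {
      gk[s1, s2, s3] <- gk[s1, s2, s3] + v
      gk
    }
    v <- 2 * tm$xx / sp[1]^2
    gk <- add(gk, I1 + 1, I2, I3, v); gk <- add(gk, I1 - 1, I2, I3, v)
    gk <- add(gk, I1, I2, I3, -2 * v)
    v <- 2 * tm$yy / sp[2]^2
    gk <- add(gk, I1, I2 + 1, I3, v); gk <- add(gk, I1, I2 - 1, I3, v)
    gk <- add(gk, I1, I2, I3, -2 * v)
    v <- 2 * tm$zz / sp[3]^2
    gk <- add(gk, I1, I2, I3 + 1, v); gk <- add(gk, I1, I2, I3 - 1, v)
    gk <- add(gk, I1, I2, I3, -2 * v)
    v <- 4 * tm$xy / (4 * sp[1] * sp[2])     # doubled mixed term
    gk <- add(gk, I1 + 1, I2 + 1, I3, v); gk <- add(gk, I1 - 1, I2 - 1, I3, v)
    gk <- add(gk, I1 + 1, I2 - 1, I3, -v); gk <- add(gk, I1 - 1, I2 + 1, I3, -v)
    v <- 4 * tm$xz / (4 * sp[1] * sp[3])
    gk <- add(gk, I1 + 1, I2, I3 + 1, v); gk <- add(gk, I1 - 1, I2, I3 - 1, v)
    gk <- add(gk, I1 + 1, I2, I3 - 1, -v); gk <- add(gk, I1 - 1, I2, I3 + 1, -v)
    v <- 4 * tm$yz / (4 * sp[2] * sp[3])
    gk <- add(gk, I1, I2 + 1, I3 + 1, v); gk <- add(gk, I1, I2 - 1, I3 - 1, v)
    gk <- add(gk, I1, I2 + 1, I3 - 1, -v); gk <- add(gk, I1, I2 - 1, I3 + 1, -v)
    g[, , , k] <- gk / N
  }
  g
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)` with `eps = 1e-5`,
#' chosen over cross-entropy because foreground voxels are a small minority.
#'
#' @param prediction probability volume in [0, 1].
#' @param target binary volume of the same shape.
#' @return Scalar in [0, 1].
#' @export
soft_dice_loss <- function(prediction, target) {
  if (!identical(dim(prediction), dim(target))) stop("shape mismatch")
  eps <- 1e-5
  1 - (2 * sum(prediction * target) + eps) / (sum(prediction) + sum(target) + eps)
}

soft_dice_grad <- function(prediction, target) {
  eps <- 1e-5
  num <- 2 * sum(prediction * target) + eps
  den <- sum(prediction) + sum(target) + eps
  -(2 * target * den - num) / den^2
}

#' Multi-scale soft Dice loss
#'
#' Mean of a soft Dice loss over copies of prediction and target smoothed
#' with Gaussian kernels of the listed extents (sigma in voxels; scale 0 is
#' the unsmoothed pair). Smoothing creates overlap between nearby but
#' disjoint contours, giving the loss a useful gradient at coarse alignment.
#' The smoothed comparisons use the squared-denominator soft Dice
#' `1 - (2 sum(pt) + eps) / (sum(p^2) + sum(t^2) + eps)`, which coincides
#' with [soft_dice_loss()] on binary inputs and is exactly zero whenever the
#' smoothed copies agree.
#'
#' @param prediction probability volume.
#' @param target binary volume.
#' @param scales nonnegative smoothing extents in voxels.
#' @return Scalar in [0, 1].
#' @export
multiscale_dice_loss <- function(prediction, target, scales = c(0, 2, 4)) {
  if (!length(scales)) stop("scales must be non-empty")
  if (any(scales < 0)) stop("scales must be nonnegative")
  mean(vapply(scales, function(s) {
    soft_dice_sq(gauss_smooth3(prediction, s), gauss_smooth3(target, s))
  }, 0))
}

# Squared-denominator soft Dice: ideal (0) exactly when p == t, binary or not.
soft_dice_sq <- function(p, t) {
  eps <- 1e-5
  1 - (2 * sum(p * t) + eps) / (sum(p^2) + sum(t^2) + eps)
}

soft_dice_sq_grad <- function(p, t) {
  eps <- 1e-5
  num <- 2 * sum(p * t) + eps
  den <- sum(p^2) + sum(t^2) + eps
  -(2 * t * den - num * 2 * p) / den^2
}

# Gradient wrt prediction (adjoint smoothing with the transposed kernels).
multiscale_dice_grad <- function(prediction, target, scales = c(0, 2, 4)) {
  d <- dim(prediction)
  g <- array(0, d)
  for (s in scales) {
    if (s <= 0) {
      g <- g + soft_dice_sq_grad(prediction, target)
    } else {
      Bs <- lapply(1:3, function(a) gauss_matrix(d[a], s))
      ps <- tensor3_contract(prediction, Bs[[1]], Bs[[2]], Bs[[3]])
      ts <- tensor3_contract(target, Bs[[1]], Bs[[2]], Bs[[3]])
      gs <- soft_dice_sq_grad(ps, ts)
      g <- g + tensor3_contract(gs, t(Bs[[1]]), t(Bs[[2]]), t(Bs[[3]]))
    }
  }
  g / length(scales)
}

#' Image similarity loss
#'
#' `l2` is the mean squared intensity difference; `ncc` is one minus the
#' global normalized cross-correlation (affine-invariant in intensity). Both
#' are 0 at perfect match and nonnegative.
#'
#' @param a,b numeric volumes of the same shape.
#' @param kind "l2" or "ncc".
#' @return Scalar >= 0.
#' @export
image_similarity_loss <- function(a, b, kind = c("l2", "ncc")) {
  kind <- match.arg(kind)
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  if (kind == "l2") return(mean((a - b)^2))
  sa <- sqrt(mean((a - mean(a))^2)); sb <- sqrt(mean((b - mean(b))^2))
  if (sa == 0 || sb == 0) {
    warning("constant image under ncc; correlation undefined, loss set to 1")
    return(1)
  }
  1 - mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

# Gradient of image_similarity_loss with respect to `a`.
image_similarity_grad <- function(a, b, kind = c("l2", "ncc")) {
  kind <- match.arg(kind)
  n <- length(a)
  if (kind == "l2") return(2 * (a - b) / n)
  am <- a - mean(a); bm <- b - mean(b)
  sa <- sqrt(mean(am^2)); sb <- sqrt(mean(bm^2))
  if (sa == 0 || sb == 0) return(array(0, dim(a)))
  r <- mean(am * bm) / (sa * sb)
  -(bm / (n * sa * sb) - r * am / (n * sa^2))
}

#' Supervised displacement-field regression loss
#'
#' Mean squared component difference between predicted and ground-truth
#' fields, in mm^2.
#'
#' @param predicted,truth [displacement_field()] objects on one grid.
#' @return Scalar >= 0 (mm^2).
#' @export
ddf_l2_loss <- function(predicted, truth) {
  stopifnot_same_grid(dim(predicted$vectors), dim(truth$vectors),
                      "predicted and truth fields")
  mean((predicted$vectors - truth$vectors)^2)
}

#' Total training objective
#'
#' Weighted sum of the field term (supervised L2 plus bending-energy
#' regularization), the contour term and the image term:
#' `lambda_ddf * (lambda_ddf_l2 * l2 + lambda_ddf_reg * reg) +
#'  lambda_seg * seg + lambda_img * img`.
#' When no ground-truth field exists (`has_gt_ddf = FALSE`) the L2-to-truth
#' term is omitted regardless of its weight.
#'
#' @param components named list with any of `l2`, `reg`, `seg`, `img`
#'   (unweighted scalar loss values).
#' @param weights a [loss_weights()] object.
#' @param has_gt_ddf is a ground-truth field available?
#' @return Scalar total loss.
#' @export
total_loss <- function(components, weights = loss_weights(), has_gt_ddf = TRUE) {
  eff <- c(
    l2 = if (has_gt_ddf) weights$lambda_ddf * weights$lambda_ddf_l2 else 0,
    reg = weights$lambda_ddf * weights$lambda_ddf_reg,
    seg = weights$lambda_seg,
    img = weights$lambda_img
  )
  tot <- 0
  for (nm in names(eff)) {
    if (eff[[nm]] == 0) next
    if (is.null(components[[nm]])) {
      stop(sprintf("loss component '%s' required by a nonzero weight is missing", nm))
    }
    tot <- tot + eff[[nm]] * components[[nm]]
  }
  tot
}
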