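#' One stage of the multi-resolution B-spline registration
#'
#' @param control_spacing_vox control-grid spacing in voxels (coarse stages
#'   use wide spacing).
#' @param iterations optimizer iteration cap (>= 1).
#' @param similarity "mse" or "ncc".
#' @param reg_weight bending-energy regularization weight.
#' @return An object of class `bspline_stage`.
#' @export
bspline_stage <- function(control_spacing_vox, iterations = 30,
                          similarity = c("mse", "ncc"), reg_weight = 1e-4) {
  similarity <- match.arg(similarity)
  if (control_spacing_vox <= 0) stop("control spacing must be positive")
  if (iterations < 1) stop("iterations must be >= 1")
  structure(list(control_spacing_vox = control_spacing_vox,
                 iterations = as.integer(iterations), similarity = similarity,
                 reg_weight = reg_weight), class = "bspline_stage")
}

#' Default coarse-to-fine stage list
#'
#' Three stages with control-grid spacings 32/16/8 voxels, mean-squared-error
#' similarity and light bending-energy regularization: a standard
#' multi-resolution free-form-deformation recipe.
#'
#' @param iterations per-stage iteration caps (recycled).
#' @return List of [bspline_stage()] objects.
#' @export
default_bspline_stages <- function(iterations = c(30, 30, 40)) {
  sp <- c(32, 16, 8)
  iterations <- rep(iterations, length.out = 3)
  lapply(1:3, function(i) bspline_stage(sp[i], iterations[i]))
}

#' Rigid contour copying
#'
#' Transfers the planning contours unchanged onto the fraction grid. The
#' crop around the CTV centroid plays the role of the clinical manual rigid
#' alignment, so planning and fraction cases must share the post-crop grid.
#'
#' @param planning_structures a [structure_set()].
#' @param fraction_grid a [volume_image()] defining the fraction grid.
#' @return A [structure_set()] on the fraction grid.
#' @export
rigid_copy <- function(planning_structures, fraction_grid) {
  stopifnot_same_grid(dim(planning_structures$masks[[1]]), dim(fraction_grid$data),
                      "planning structures and fraction grid")
  if (!isTRUE(all.equal(planning_structures$spacing, fraction_grid$spacing))) {
    stop("planning and fraction grids have different spacing")
  }
  structure_set(planning_structures$masks, fraction_grid$spacing,
                fraction_grid$origin)
}

ncc_value_grad <- function(a, b) {
  # returns list(loss, grad wrt a) for 1 - ncc
  list(loss = image_similarity_loss(a, b, "ncc"),
       grad = image_similarity_grad(a, b, "ncc"))
}

#' Multi-resolution B-spline deformable registration
#'
#' Coarse-to-fine optimization of cubic B-spline control-point offsets
#' minimizing image similarity plus bending-energy regularization; each stage
#' warm-starts from the previous stage's dense field. The control points are
#' optimized with L-BFGS-B using the analytic gradient (chain rule through
#' the trilinear warp and the B-spline basis). Deterministic given inputs
#' and stages.
#'
#' @param fixed,moving [volume_image()] objects on one grid.
#' @param stages list of [bspline_stage()], coarse to fine.
#' @return A [displacement_field()] (mm, backward convention) with a
#'   `diagnostics` attribute holding per-stage objective traces.
#' @export
bspline_register <- function(fixed, moving, stages = default_bspline_stages()) {
  stopifnot_same_grid(dim(fixed$data), dim(moving$data), "fixed and moving images")
  if (!length(stages)) stop("need at least one stage")
  spv <- vapply(stages, function(s) s$control_spacing_vox, 0)
  if (any(diff(spv) > 0)) {
    warning("stage control spacings are not coarse-to-fine (non-increasing)")
  }
  d <- dim(fixed$data)
  sp <- fixed$spacing
  fnorm <- normalize_volume(fixed$data)
  mnorm <- normalize_volume(moving$data)
  mvol <- volume_image(mnorm, sp, fixed$origin)
  u_base <- array(0, c(d, 3))
  diagnostics <- list()
  for (si in seq_along(stages)) {
    stg <- stages[[si]]
    nc <- pmax(4L, as.integer(round(d / stg$control_spacing_vox)) + 3L)
    B <- lapply(1:3, function(a) bspline_basis_matrix(d[a], nc[a]))
    Bt <- lapply(B, t)
    npar <- prod(nc)
    trace_env <- new.env(); trace_env$vals <- numeric(0)
    dense_from_par <- function(par) {
      coefs <- array(par, c(nc, 3))
      u <- u_base
      for (k in 1:3) {
        u[, , , k] <- u[, , , k] +
          tensor3_contract(coefs[, , , k], B[[1]], B[[2]], B[[3]])
      }
      u
    }
    fn <- function(par) {
      u <- dense_from_par(par)
      ddf <- displacement_field(u, sp, fixed$origin)
      w <- spatial_transform(mnorm, ddf)
      simv <- if (stg$similarity == "mse") mean((w - fnorm)^2) else {
        image_similarity_loss(w, fnorm, "ncc")
      }
      val <- simv + stg$reg_weight * bending_energy(ddf)
      trace_env$vals <- c(trace_env$vals, val)
      val
    }
    gr <- function(par) {
      u <- dense_from_par(par)
      ddf <- displacement_field(u, sp, fixed$origin)
      w <- spatial_transform(mnorm, ddf)
      gsim <- if (stg$similarity == "mse") 2 * (w - fnorm) / length(w) else {
        image_similarity_grad(w, fnorm, "ncc")
      }
      gu <- spatial_transform_grad_ddf(mnorm, ddf, gsim) +
        stg$reg_weight * bending_energy_grad(ddf)
      gc_ <- numeric(npar * 3)
      for (k in 1:3) {
        gc_[(k - 1) * npar + seq_len(npar)] <-
          tensor3_contract(gu[, , , k], Bt[[1]], Bt[[2]], Bt[[3]])
      }
      gc_
    }
    f0 <- fn(numeric(npar * 3))
    opt <- tryCatch(
      optim(numeric(npar * 3), fn, gr, method = "L-BFGS-B",
            control = list(maxit = stg$iterations)),
      error = function(e) list(par = numeric(npar * 3), value = f0,
                               convergence = 52L, message = conditionMessage(e)))
    if (!opt$convergence %in% c(0, 1)) {
      # line-search stalls at flat optima (e.g. identical images) are benign;
      # anything that increased the objective is a genuine failure
      if (!is.finite(opt$value) || opt$value > f0 + 1e-12) {
        stop(sprintf("stage %d optimization diverged: %s", si,
                     opt$message %||% "non-finite objective"))
      }
    }
    u_base <- dense_from_par(opt$par)
    diagnostics[[si]] <- list(objective = trace_env$vals, final = opt$value,
                              convergence = opt$convergence)
  }
  out <- displacement_field(u_base, sp, fixed$origin)
  attr(out, "diagnostics") <- diagnostics
  out
}

#' Propagate planning contours with a displacement field
#'
#' Warps each planning mask by the field ([warp_mask()] semantics). Following
#' the clinical convention for prostate, the CTV can instead be rigidly
#' copied while the organs at risk are deformed (`ctv_rigid = TRUE`).
#'
#' @param structures planning [structure_set()].
#' @param ddf a [displacement_field()] on the fraction grid.
#' @param ctv_rigid copy the CTV rigidly instead of warping it?
#' @return A [structure_set()] on the fraction grid.
#' @export
propagate_contours <- function(structures, ddf, ctv_rigid = FALSE) {
  stopifnot_same_grid(dim(structures$masks[[1]]), dim(ddf$vectors)[1:3],
                      "structures and ddf")
  out <- lapply(structures$masks, warp_mask, ddf = ddf)
  if (ctv_rigid && "ctv" %in% names(out)) out$ctv <- structures$masks$ctv
  structure_set(out, ddf$spacing, ddf$origin)
}
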