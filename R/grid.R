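#' Create a 3D scalar volume with physical geometry
#'
#' The basic unit all pipeline stages operate on: a 3D intensity array with
#' per-axis voxel spacing (mm) and the physical position of voxel (1,1,1).
#' Axis convention is (x, y, z) index order with axial slices along z.
#'
#' @param data 3D numeric array of finite values.
#' @param spacing_mm numeric length-3, voxel size per axis in mm (all > 0).
#' @param origin_mm numeric length-3, physical position of the first voxel.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, spacing_mm = c(1.5, 1.5, 1.5), origin_mm = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) stop("spacing must be 3 positive values")
  if (!all(is.finite(data))) stop("data must be finite")
  structure(list(data = data, spacing = as.numeric(spacing_mm),
                 origin = as.numeric(origin_mm)),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s voxels @ %s mm, intensity [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Create a named set of binary structure masks on a shared grid
#'
#' @param masks named list of binary 3D arrays (values 0/1) on one grid.
#' @param spacing_mm,origin_mm grid geometry, as in [volume_image()].
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks, spacing_mm = c(1.5, 1.5, 1.5), origin_mm = c(0, 0, 0)) {
  if (!length(masks) || is.null(names(masks))) stop("masks must be a named list")
  d <- dim(masks[[1]])
  for (nm in names(masks)) {
    stopifnot_same_grid(d, dim(masks[[nm]]), sprintf("mask '%s'", nm))
    v <- masks[[nm]]
    if (!all(v %in% c(0, 1))) stop(sprintf("mask '%s' is not binary", nm))
  }
  structure(list(masks = masks, spacing = as.numeric(spacing_mm),
                 origin = as.numeric(origin_mm)),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  v <- vapply(x$masks, sum, 0)
  cat("<structure_set>", paste(sprintf("%s (%d vox)", names(v), as.integer(v)),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Create a dense displacement field (DDF)
#'
#' Vectors are stored in millimetres on the fixed (fraction) grid with the
#' backward-warping convention: the warped value at fixed-grid physical point
#' `x` is sampled from the moving (planning) volume at `x + u(x)`.
#'
#' @param vectors 4D array (nx, ny, nz, 3) of mm displacements.
#' @param spacing_mm,origin_mm grid geometry.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, spacing_mm = c(1.5, 1.5, 1.5), origin_mm = c(0, 0, 0)) {
  d <- dim(vectors)
  if (length(d) != 4L || d[4] != 3L) stop("vectors must be (nx, ny, nz, 3)")
  if (!all(is.finite(vectors))) stop("vectors must be finite")
  structure(list(vectors = vectors, spacing = as.numeric(spacing_mm),
                 origin = as.numeric(origin_mm)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field> %s, |u| mean %.2f mm, max %.2f mm\n",
              paste(dim(x$vectors)[1:3], collapse = "x"),
              mean(abs(x$vectors)), max(abs(x$vectors))))
  invisible(x)
}

ddf_to_voxel_units <- function(ddf) {
  v <- ddf$vectors
  for (k in 1:3) v[, , , k] <- v[, , , k] / ddf$spacing[k]
  v
}

#' Warp a volume by a displacement field
#'
#' Backward warping: `out(x) = moving(x + u(x))` with the chosen interpolation;
#' out-of-bounds samples take the border (clamped) value. This is the
#' reference R implementation; [spatial_transform()] is the independent
#' differentiable implementation with the same numerical contract.
#'
#' @param moving a [volume_image()] sharing the ddf's physical space.
#' @param ddf a [displacement_field()] on the output grid.
#' @param mode "linear" or "nearest".
#' @return A warped [volume_image()] on the ddf grid.
#' @export
warp_image <- function(moving, ddf, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  d <- dim(moving$data)
  stopifnot_same_grid(d, dim(ddf$vectors)[1:3], "moving image and ddf")
  n1 <- d[1]; n2 <- d[2]; n3 <- d[3]
  u <- ddf_to_voxel_units(ddf)
  px <- array(rep(0:(n1 - 1), times = n2 * n3), d) + u[, , , 1]
  py <- array(rep(rep(0:(n2 - 1), each = n1), times = n3), d) + u[, , , 2]
  pz <- array(rep(0:(n3 - 1), each = n1 * n2), d) + u[, , , 3]
  px <- pmin(pmax(px, 0), n1 - 1)
  py <- pmin(pmax(py, 0), n2 - 1)
  pz <- pmin(pmax(pz, 0), n3 - 1)
  vals <- as.vector(moving$data)
  gather <- function(ix, iy, iz) vals[1 + ix + n1 * (iy + n2 * iz)]
  if (mode == "nearest") {
    out <- gather(floor(px + 0.5), floor(py + 0.5), floor(pz + 0.5))
  } else {
    x0 <- pmin(floor(px), n1 - 2); y0 <- pmin(floor(py), n2 - 2); z0 <- pmin(floor(pz), n3 - 2)
    tx <- px - x0; ty <- py - y0; tz <- pz - z0
    out <-
      gather(x0, y0, z0) * (1 - tx) * (1 - ty) * (1 - tz) +
      gather(x0 + 1, y0, z0) * tx * (1 - ty) * (1 - tz) +
      gather(x0, y0 + 1, z0) * (1 - tx) * ty * (1 - tz) +
      gather(x0 + 1, y0 + 1, z0) * tx * ty * (1 - tz) +
      gather(x0, y0, z0 + 1) * (1 - tx) * (1 - ty) * tz +
      gather(x0 + 1, y0, z0 + 1) * tx * (1 - ty) * tz +
      gather(x0, y0 + 1, z0 + 1) * (1 - tx) * ty * tz +
      gather(x0 + 1, y0 + 1, z0 + 1) * tx * ty * tz
  }
  volume_image(array(out, d), ddf$spacing, ddf$origin)
}

#' Warp a binary mask by a displacement field
#'
#' Linear interpolation of the 0/1 mask followed by thresholding at 0.5, the
#' common convention for propagating contours with a deformable field.
#'
#' @param mask binary 3D array.
#' @param ddf a [displacement_field()].
#' @return Binary 3D array on the ddf grid.
#' @export
warp_mask <- function(mask, ddf) {
  w <- warp_image(volume_image(mask * 1, ddf$spacing, ddf$origin), ddf, "linear")
  (w$data >= 0.5) * 1
}

#' Resample the axial (z) slice thickness of a volume
#'
#' Regrids the z axis to the target spacing, leaving x/y untouched; linear
#' interpolation for images, nearest neighbour for contour masks (which then
#' stay binary).
#'
#' @param image a [volume_image()].
#' @param target_thickness_mm new z spacing in mm (> 0).
#' @param mode "linear" (images) or "nearest" (masks).
#' @return A resampled [volume_image()].
#' @export
resample_slices <- function(image, target_thickness_mm, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  if (!is.numeric(target_thickness_mm) || target_thickness_mm <= 0) {
    stop("target thickness must be positive")
  }
  d <- dim(image$data)
  dz <- image$spacing[3]
  nz2 <- floor((d[3] - 1) * dz / target_thickness_mm + 1e-9) + 1
  zpos <- (0:(nz2 - 1)) * target_thickness_mm / dz   # in old voxel units
  out <- array(0, c(d[1], d[2], nz2))
  if (mode == "nearest") {
    zi <- pmin(pmax(floor(zpos + 0.5), 0), d[3] - 1)
    for (k in seq_len(nz2)) out[, , k] <- image$data[, , zi[k] + 1]
  } else {
    z0 <- pmin(floor(zpos), d[3] - 2); t <- zpos - z0
    for (k in seq_len(nz2)) {
      out[, , k] <- image$data[, , z0[k] + 1] * (1 - t[k]) + image$data[, , z0[k] + 2] * t[k]
    }
  }
  volume_image(out, c(image$spacing[1:2], target_thickness_mm), image$origin)
}

#' Crop image and structures around a structure centroid
#'
#' Emulates the clinical rigid pre-alignment: a fixed-size window centred on
#' the anchor structure's voxel centroid (rounded half-up per axis), applied
#' identically to the image and every mask. Windows reaching outside the grid
#' are padded with border (replicated) values so the output always has the
#' requested shape.
#'
#' @param image a [volume_image()].
#' @param structures a [structure_set()] on the same grid.
#' @param anchor name of the anchor structure (non-empty mask).
#' @param size_voxels integer length-3 window size.
#' @return list with elements `image` and `structures`.
#' @export
crop_around_centroid <- function(image, structures, anchor, size_voxels) {
  d <- dim(image$data)
  m <- structures$masks[[anchor]]
  if (is.null(m)) stop(sprintf("anchor structure '%s' not found", anchor))
  if (sum(m) == 0) stop(sprintf("anchor structure '%s' is empty", anchor))
  size_voxels <- rep(as.integer(size_voxels), length.out = 3)
  idx <- which(m == 1, arr.ind = TRUE)
  cen <- floor(colMeans(idx) + 0.5)              # round half-up, 1-based
  win <- lapply(1:3, function(a) {
    s <- cen[a] - size_voxels[a] %/% 2
    pmin(pmax(s:(s + size_voxels[a] - 1), 1L), d[a])   # border replication
  })
  start_mm <- vapply(1:3, function(a) (win[[a]][1] - 1) * image$spacing[a], 0)
  new_origin <- image$origin + start_mm
  ci <- volume_image(image$data[win[[1]], win[[2]], win[[3]], drop = FALSE],
                     image$spacing, new_origin)
  cm <- lapply(structures$masks, function(mk) mk[win[[1]], win[[2]], win[[3]], drop = FALSE])
  list(image = ci, structures = structure_set(cm, image$spacing, new_origin))
}

#' Draw a random smooth B-spline displacement field
#'
#' Control-point offsets are drawn uniformly in [-max, +max] per component and
#' interpolated to a dense field with cubic B-splines. Because the basis is a
#' partition of unity, no dense component exceeds `max_displacement_mm`.
#'
#' @param grid a [volume_image()] (or anything with `$data` dims and `$spacing`)
#'   defining the output grid.
#' @param n_control_points control points per axis (>= 4).
#' @param max_displacement_mm amplitude bound in mm (>= 0).
#' @param seed RNG seed; identical seeds give identical fields.
#' @return A [displacement_field()].
#' @export
random_bspline_ddf <- function(grid, n_control_points = 10, max_displacement_mm = 35,
                               seed = 1) {
  if (max_displacement_mm < 0) stop("max displacement must be >= 0")
  d <- dim(grid$data)
  nc <- rep(as.integer(n_control_points), length.out = 3)
  B <- lapply(1:3, function(a) bspline_basis_matrix(d[a], nc[a]))
  vec <- array(0, c(d, 3))
  coefs <- with_seed(seed, {
    array(runif(prod(nc) * 3, -max_displacement_mm, max_displacement_mm), c(nc, 3))
  })
  for (k in 1:3) {
    vec[, , , k] <- tensor3_contract(coefs[, , , k], B[[1]], B[[2]], B[[3]])
  }
  displacement_field(vec, grid$spacing, grid$origin)
}
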