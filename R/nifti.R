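#' Write a volume, mask or displacement field as NIfTI
#'
#' Spacing is carried in the pixdim header; displacement fields are written
#' as 4D volumes with three components in the fourth dimension and NIfTI
#' vector intent.
#'
#' @param x a [volume_image()], [displacement_field()], or binary 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing_mm spacing when `x` is a plain array.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path, spacing_mm = c(1.5, 1.5, 1.5)) {
  if (inherits(x, "volume_image")) {
    arr <- x$data; sp <- x$spacing
  } else if (inherits(x, "displacement_field")) {
    arr <- x$vectors; sp <- x$spacing
  } else {
    arr <- x; sp <- rep(spacing_mm, length.out = 3)
  }
  img <- RNifti::asNifti(arr)
  if (length(dim(arr)) == 4L) {
    RNifti::pixdim(img) <- c(sp, 1)
    img$intent_code <- 1007L               # NIFTI_INTENT_VECTOR
  } else {
    RNifti::pixdim(img) <- sp
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as a volume image or displacement field
#'
#' 3D files become [volume_image()]s; 4D files with 3 components become
#' [displacement_field()]s.
#'
#' @param path NIfTI file path.
#' @return A [volume_image()] or [displacement_field()].
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim(img))   # plain array, header stripped
  if (length(dim(arr)) == 4L && dim(arr)[4] == 3L) {
    displacement_field(arr, sp)
  } else {
    volume_image(arr, sp)
  }
}

#' Write a patient case to a directory
#'
#' One NIfTI per image and structure mask per time point, plus a JSON sidecar
#' recording the generating parameters (for synthetic cases).
#'
#' @param case a `patient_case`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(part, prefix) {
    write_nifti_volume(part$image, file.path(dir, paste0(prefix, "_image.nii.gz")))
    for (nm in names(part$structures$masks)) {
      write_nifti_volume(part$structures$masks[[nm]],
                         file.path(dir, paste0(prefix, "_mask_", nm, ".nii.gz")),
                         spacing_mm = part$image$spacing)
    }
    if (!is.null(part$gt_ddf)) {
      write_nifti_volume(part$gt_ddf, file.path(dir, paste0(prefix, "_ddf.nii.gz")))
    }
  }
  wr(case$planning, "planning")
  for (f in seq_along(case$fractions)) {
    wr(case$fractions[[f]], sprintf("fraction%02d", f))
  }
  side <- list(id = case$id,
               planning_params = case$planning$params[
                 setdiff(names(case$planning$params), "intensity_means")],
               n_fractions = length(case$fractions),
               fraction_truth = lapply(case$fractions, function(f) f$truth))
  jsonlite::write_json(side, file.path(dir, "case.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a patient case from a directory written by [write_case()]
#'
#' @param dir case directory.
#' @return A `patient_case`.
#' @export
read_case <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "case.json"))
  rd <- function(prefix) {
    img <- read_nifti_volume(file.path(dir, paste0(prefix, "_image.nii.gz")))
    mfiles <- list.files(dir, pattern = paste0("^", prefix, "_mask_.*\\.nii\\.gz$"))
    masks <- list()
    for (mf in mfiles) {
      nm <- sub(paste0(prefix, "_mask_"), "", sub("\\.nii\\.gz$", "", mf))
      masks[[nm]] <- round(as.array(read_nifti_volume(file.path(dir, mf))$data))
    }
    list(image = img, structures = structure_set(masks, img$spacing, img$origin))
  }
  planning <- rd("planning")
  nfr <- side$n_fractions %||% 0
  fractions <- lapply(seq_len(nfr), function(f) rd(sprintf("fraction%02d", f)))
  structure(list(id = side$id %||% basename(dir), planning = planning,
                 fractions = fractions),
            class = "patient_case")
}
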