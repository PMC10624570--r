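#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks are defined as perfectly
#' agreeing (DSC 1) and flagged with a `degenerate` attribute.
#'
#' @param a,b binary masks on one grid.
#' @return Scalar in [0, 1].
#' @export
dsc <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  sa <- sum(a); sb <- sum(b)
  if (sa == 0 && sb == 0) return(structure(1.0, degenerate = TRUE))
  2 * sum(a * b) / (sa + sb)
}

# Surface voxels: foreground voxels with at least one face-adjacent
# background neighbour; voxels on the volume border count as surface.
mask_surface <- function(mask) {
  d <- dim(mask)
  pad <- array(0, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] *
        pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] *
        pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] *
        pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] *
        pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] *
        pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  (mask == 1 & nb == 0) * 1
}

#' Directed surface-distance sets between two masks
#'
#' Euclidean millimetre distances from every surface voxel of `a` to the
#' surface of `b`, and vice versa, computed with an exact anisotropic
#' distance transform. The symmetric Hausdorff statistics ([hd95()],
#' [hd_avg()]) are reductions of these two sets.
#'
#' @param a,b non-empty binary masks on one grid.
#' @param spacing voxel spacing in mm.
#' @return List with numeric vectors `a_to_b` and `b_to_a`.
#' @export
surface_distances <- function(a, b, spacing = c(1.5, 1.5, 1.5)) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  if (sum(a) == 0) stop("mask 'a' is empty")
  if (sum(b) == 0) stop("mask 'b' is empty")
  spacing <- rep(as.numeric(spacing), length.out = 3)
  sa <- mask_surface(a); sb <- mask_surface(b)
  da <- sqrt(array(cp_edt_sq(as.numeric(sb), dim(b), spacing), dim(b)))
  db <- sqrt(array(cp_edt_sq(as.numeric(sa), dim(a), spacing), dim(a)))
  list(a_to_b = da[sa == 1], b_to_a = db[sb == 1])
}

#' 95th-percentile Hausdorff distance
#'
#' Maximum of the 95th percentiles (linear interpolation between order
#' statistics) of the two directed surface-distance sets, in mm.
#'
#' @inheritParams surface_distances
#' @return Scalar >= 0 (mm).
#' @export
hd95 <- function(a, b, spacing = c(1.5, 1.5, 1.5)) {
  sd_ <- surface_distances(a, b, spacing)
  max(quantile(sd_$a_to_b, 0.95, names = FALSE, type = 7),
      quantile(sd_$b_to_a, 0.95, names = FALSE, type = 7))
}

#' Average Hausdorff (mean surface) distance
#'
#' Mean of the two directed mean surface distances, in mm.
#'
#' @inheritParams surface_distances
#' @return Scalar >= 0 (mm).
#' @export
hd_avg <- function(a, b, spacing = c(1.5, 1.5, 1.5)) {
  sd_ <- surface_distances(a, b, spacing)
  (mean(sd_$a_to_b) + mean(sd_$b_to_a)) / 2
}

#' Axial slice range for rectum evaluation
#'
#' The rectum is clinically corrected mostly near the high-dose region, so
#' its evaluation considers only slices containing the PTV plus a margin
#' above and below (15 mm, i.e. ten 1.5 mm slices, by default). Returns the
#' inclusive slice range, clamped to the volume.
#'
#' @param ptv non-empty binary PTV mask.
#' @param slice_thickness_mm axial slice thickness.
#' @param margin_mm extra margin beyond each PTV end (mm).
#' @return Integer length-2 (zlo, zhi), 1-based inclusive.
#' @export
rectum_eval_region <- function(ptv, slice_thickness_mm = 1.5, margin_mm = 15) {
  zs <- which(apply(ptv, 3, sum) > 0)
  if (!length(zs)) stop("PTV mask is empty")
  k <- round(margin_mm / slice_thickness_mm)
  c(max(1L, min(zs) - k), min(dim(ptv)[3], max(zs) + k))
}

crop_to_slices <- function(mask, zrange) {
  out <- array(0, dim(mask))
  out[, , zrange[1]:zrange[2]] <- mask[, , zrange[1]:zrange[2]]
  out
}

#' Per-fraction metric record
#'
#' Computes the (DSC, HD95, HDavg) triple for one predicted structure against
#' its ground truth. An empty prediction gets DSC 0 and missing distances
#' (flagged), the convention for failed propagation.
#'
#' @param pred,truth binary masks.
#' @param spacing voxel spacing in mm.
#' @param patient,fraction,structure,method record identifiers.
#' @return One-row data.frame.
#' @export
eval_record <- function(pred, truth, spacing, patient, fraction, structure, method) {
  empty <- sum(pred) == 0 || sum(truth) == 0
  data.frame(patient = patient, fraction = fraction, structure = structure,
             method = method,
             dsc = as.numeric(dsc(pred, truth)),
             hd95_mm = if (empty) NA_real_ else hd95(pred, truth, spacing),
             hdavg_mm = if (empty) NA_real_ else hd_avg(pred, truth, spacing),
             degenerate = empty,
             stringsAsFactors = FALSE)
}

#' Two-stage cohort aggregation
#'
#' To avoid bias towards patients with many fractions, fraction-level metrics
#' are first averaged per patient; the cohort mean and SD are then taken over
#' the per-patient means with equal patient weight. Duplicating fraction
#' records therefore leaves all cohort statistics unchanged.
#'
#' @param records data.frame of [eval_record()] rows.
#' @return An object of class `cohort_stats`: list with `per_patient` and
#'   `cohort` data.frames (the latter with a normality p-value per group).
#' @export
aggregate_metrics <- function(records) {
  if (!nrow(records)) stop("no records")
  metrics <- c("dsc", "hd95_mm", "hdavg_mm")
  per_patient <- do.call(rbind, lapply(
    split(records, list(records$method, records$structure, records$patient),
          drop = TRUE),
    function(g) {
      out <- data.frame(method = g$method[1], structure = g$structure[1],
                        patient = g$patient[1], n_fractions = nrow(g),
                        stringsAsFactors = FALSE)
      for (m in metrics) out[[m]] <- mean(g[[m]], na.rm = TRUE)
      out
    }))
  rownames(per_patient) <- NULL
  cohort <- do.call(rbind, lapply(
    split(per_patient, list(per_patient$method, per_patient$structure), drop = TRUE),
    function(g) {
      out <- data.frame(method = g$method[1], structure = g$structure[1],
                        n_patients = nrow(g), stringsAsFactors = FALSE)
      for (m in metrics) {
        out[[paste0(m, "_mean")]] <- mean(g[[m]])
        out[[paste0(m, "_sd")]] <- if (nrow(g) >= 2) sd(g[[m]]) else NA_real_
        out[[paste0(m, "_normality_p")]] <- if (nrow(g) >= 3) {
          normality_test(g[[m]])$p
        } else NA_real_
      }
      out
    }))
  rownames(cohort) <- NULL
  structure(list(per_patient = per_patient, cohort = cohort),
            class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat("<cohort_stats>", length(unique(x$per_patient$patient)), "patients,",
      length(unique(x$per_patient$method)), "methods\n")
  print(x$cohort[, c("method", "structure", "dsc_mean", "dsc_sd",
                     "hd95_mm_mean", "hdavg_mm_mean")], digits = 3)
  invisible(x)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of the values against a normal distribution with the
#' sample mean and SD (estimated parameters; the resulting p-values carry the
#' usual Lilliefors caveat). A constant vector is degenerate and flagged.
#'
#' @param values numeric vector, length >= 3.
#' @return List with `p`, `statistic`, `degenerate`.
#' @export
normality_test <- function(values) {
  if (length(values) < 3) stop("need at least 3 values")
  if (sd(values) == 0) {
    return(list(p = NA_real_, statistic = NA_real_, degenerate = TRUE))
  }
  kt <- suppressWarnings(ks.test(values, "pnorm", mean(values), sd(values)))
  list(p = unname(kt$p.value), statistic = unname(kt$statistic),
       degenerate = FALSE)
}

#' Paired t-test between two methods' per-patient means
#'
#' Two-sided paired t-test on the patient-aligned differences at significance
#' level `alpha`. Zero-variance differences are degenerate: all-zero
#' differences are not significant; a constant nonzero shift is reported as a
#' (degenerate) significant difference.
#'
#' @param method_a,method_b per-patient means, patient-aligned (same order,
#'   or identically named).
#' @param alpha significance level.
#' @return List with `t`, `p`, `significant`, `degenerate`.
#' @export
paired_test <- function(method_a, method_b, alpha = 0.05) {
  if (length(method_a) != length(method_b) || length(method_a) < 2) {
    stop("need two patient-aligned vectors of equal length >= 2")
  }
  if (!is.null(names(method_a)) && !is.null(names(method_b)) &&
      !identical(names(method_a), names(method_b))) {
    stop("patient sets are misaligned")
  }
  d <- method_a - method_b
  if (sd(d) == 0) {
    return(list(t = NA_real_, p = NA_real_,
                significant = any(d != 0), degenerate = TRUE))
  }
  tt <- t.test(method_a, method_b, paired = TRUE)
  list(t = unname(tt$statistic), p = unname(tt$p.value),
       significant = unname(tt$p.value) < alpha, degenerate = FALSE)
}

#' Pairwise method comparison for one structure and metric
#'
#' Runs [paired_test()] on every method pair of the per-patient means.
#'
#' @param stats a `cohort_stats` object from [aggregate_metrics()].
#' @param structure structure name.
#' @param metric one of "dsc", "hd95_mm", "hdavg_mm".
#' @param alpha significance level.
#' @return data.frame of pairwise results.
#' @export
compare_methods <- function(stats, structure, metric = "dsc", alpha = 0.05) {
  pp <- stats$per_patient[stats$per_patient$structure == structure, ]
  methods <- sort(unique(pp$method))
  res <- list()
  for (i in seq_along(methods)) for (j in seq_along(methods)) {
    if (j <= i) next
    a <- pp[pp$method == methods[i], ]
    b <- pp[pp$method == methods[j], ]
    a <- a[order(a$patient), ]; b <- b[order(b$patient), ]
    if (!identical(a$patient, b$patient)) stop("patient sets are misaligned")
    pt <- paired_test(a[[metric]], b[[metric]], alpha)
    res[[length(res) + 1]] <- data.frame(
      method_a = methods[i], method_b = methods[j], structure = structure,
      metric = metric, t = pt$t, p = pt$p, significant = pt$significant,
      degenerate = pt$degenerate, stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Render a Markdown comparison table
#'
#' "Mean (SD)" per method and structure for the three metrics, with the best
#' value per structure/metric in bold.
#'
#' @param stats a `cohort_stats` object.
#' @return Character vector of Markdown lines.
#' @export
report_table <- function(stats) {
  co <- stats$cohort
  metrics <- c(dsc = "DSC", hd95_mm = "HD95 [mm]", hdavg_mm = "HDavg [mm]")
  better <- c(dsc = max, hd95_mm = min, hdavg_mm = min)
  structures <- unique(co$structure)
  hdr <- c("Method", unlist(lapply(names(metrics), function(m)
    paste(metrics[[m]], structures))))
  lines <- c(paste("|", paste(hdr, collapse = " | "), "|"),
             paste("|", paste(rep("---", length(hdr)), collapse = " | "), "|"))
  for (meth in unique(co$method)) {
    cells <- meth
    for (m in names(metrics)) for (s in structures) {
      row <- co[co$method == meth & co$structure == s, ]
      col <- co[co$structure == s, ]
      val <- row[[paste0(m, "_mean")]]
      cell <- sprintf("%.2f (%.2f)", val, row[[paste0(m, "_sd")]])
      if (isTRUE(all.equal(val, better[[m]](col[[paste0(m, "_mean")]])))) {
        cell <- paste0("**", cell, "**")
      }
      cells <- c(cells, cell)
    }
    lines <- c(lines, paste("|", paste(cells, collapse = " | "), "|"))
  }
  lines
}
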