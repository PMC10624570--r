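#' Full synthetic-replication experiment configuration
#'
#' Describes the two cohorts (a training cohort for the generic models and a
#' held-out test cohort whose planning images drive patient-specific
#' fine-tuning), the network and training settings per regime, the benchmark
#' registration stages, and the evaluation settings. Defaults are desk-scale
#' (24^3 voxels at 4 mm covering the same physical field of view as the
#' clinical-scale grid).
#'
#' @param n_train,n_test patients per cohort.
#' @param n_fractions fractions per test patient (and per training patient,
#'   used by displacement-model training on true pairs).
#' @param grid_shape,spacing_mm phantom grid.
#' @param anatomy base [anatomy_params()] (grid fields are overridden).
#' @param train_variation,test_variation [variation_params()] per cohort.
#' @param structures structures to evaluate.
#' @param methods methods to run (subset of copy, plastimatch_like, BM, PSM,
#'   DDFM).
#' @param seg_levels,ddf_levels,base_channels network size.
#' @param bm_epochs,psm_epochs,ddfm_epochs training lengths.
#' @param bm_lr,psm_lr,ddfm_lr Adam step sizes per regime (desk-scale
#'   defaults; the narrow desk-scale networks tolerate and need larger steps
#'   than clinical-scale training).
#' @param ddfm_variant displacement-model data variant.
#' @param stages B-spline benchmark stages.
#' @param ptv_margin_mm CTV-to-PTV dilation margin.
#' @param rectum_margin_mm rectum evaluation margin beyond the PTV ends.
#' @param ctv_rigid_in_dir rigidly copy the CTV in the registration benchmark?
#' @param seed master seed.
#' @param out_dir optional output directory for artifacts.
#' @param train_ids,test_ids optional explicit patient id lists (checked for
#'   leakage).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_train = 4, n_test = 2, n_fractions = 2,
                              grid_shape = c(24, 24, 24),
                              spacing_mm = c(4, 4, 4),
                              anatomy = anatomy_params(),
                              train_variation = variation_params(),
                              test_variation = variation_params(),
                              structures = c("bladder", "rectum", "ctv"),
                              methods = c("copy", "plastimatch_like", "BM",
                                          "PSM", "DDFM"),
                              seg_levels = 3, ddf_levels = 3, base_channels = 4,
                              bm_epochs = 40, psm_epochs = 25, ddfm_epochs = 12,
                              bm_lr = 5e-3, psm_lr = 1e-3, ddfm_lr = 3e-3,
                              ddfm_variant = "true_pairs",
                              stages = default_bspline_stages(c(15, 15, 20)),
                              ptv_margin_mm = 5, rectum_margin_mm = 15,
                              ctv_rigid_in_dir = FALSE,
                              seed = 1, out_dir = NULL,
                              train_ids = NULL, test_ids = NULL) {
  anatomy$grid_shape <- as.integer(rep(grid_shape, length.out = 3))
  anatomy$spacing_mm <- rep(as.numeric(spacing_mm), length.out = 3)
  structure(list(n_train = n_train, n_test = n_test, n_fractions = n_fractions,
                 anatomy = anatomy, train_variation = train_variation,
                 test_variation = test_variation, structures = structures,
                 methods = methods, seg_levels = seg_levels,
                 ddf_levels = ddf_levels, base_channels = base_channels,
                 bm_epochs = bm_epochs, psm_epochs = psm_epochs,
                 ddfm_epochs = ddfm_epochs, bm_lr = bm_lr, psm_lr = psm_lr,
                 ddfm_lr = ddfm_lr, ddfm_variant = ddfm_variant,
                 stages = stages, ptv_margin_mm = ptv_margin_mm,
                 rectum_margin_mm = rectum_margin_mm,
                 ctv_rigid_in_dir = ctv_rigid_in_dir, seed = seed,
                 out_dir = out_dir, train_ids = train_ids, test_ids = test_ids),
            class = "experiment_config")
}

#' Validate an experiment configuration
#'
#' Checks grid divisibility for the network specs, weight sanity and split
#' integrity without mutating anything. Findings marked `fatal` would make
#' [run_experiment()] refuse to run.
#'
#' @param config an [experiment_config()].
#' @return data.frame with columns `level` ("fatal"/"warning") and `message`;
#'   zero rows for a valid config.
#' @export
validate_config <- function(config) {
  findings <- data.frame(level = character(), message = character(),
                         stringsAsFactors = FALSE)
  add <- function(level, message) {
    findings <<- rbind(findings, data.frame(level = level, message = message,
                                            stringsAsFactors = FALSE))
  }
  d <- config$anatomy$grid_shape
  for (lv in unique(c(config$seg_levels, config$ddf_levels))) {
    f <- 2^(lv - 1)
    if (any(d %% f != 0)) {
      add("fatal", sprintf("grid %s not divisible by 2^(levels-1) = %d",
                           paste(d, collapse = "x"), f))
    }
  }
  if (config$n_train < 2 && any(c("BM", "PSM") %in% config$methods)) {
    add("fatal", "baseline training needs at least 2 training patients")
  }
  leak <- intersect(config$train_ids %||% character(),
                    config$test_ids %||% character())
  if (length(leak)) {
    add("fatal", sprintf("test patient(s) %s appear in the training list",
                         paste(leak, collapse = ", ")))
  }
  w <- tryCatch(loss_weights(), error = function(e) NULL)
  if ("PSM" %in% config$methods && !"BM" %in% config$methods) {
    add("fatal", "patient-specific fine-tuning requires the baseline model")
  }
  if (config$n_fractions < 1) add("fatal", "need at least one fraction")
  findings
}

binarize <- function(prob_volume) (prob_volume$data >= 0.5) * 1

config_hash <- function(config) {
  js <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                         auto_unbox = TRUE, force = TRUE, digits = NA)
  tf <- tempfile()
  writeLines(as.character(js), tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

#' Run the full contour-propagation comparison experiment
#'
#' Generates the synthetic training and test cohorts, trains the requested
#' strategies (baseline models per structure, patient-specific fine-tuning on
#' each test patient's planning case only, and the displacement model), runs
#' the classical benchmarks, predicts contours for every test fraction, and
#' evaluates everything with the per-patient-then-cohort protocol. The
#' returned bundle contains the per-fraction records, the cohort statistics,
#' the rendered comparison table and a manifest (config hash, seed,
#' version). Test patients never enter generic-model training; an explicit
#' split violation in the config is refused by name.
#'
#' @param config an [experiment_config()].
#' @return List with `records`, `stats`, `tests`, `report`, `manifest`, and
#'   `models`.
#' @export
run_experiment <- function(config) {
  findings <- validate_config(config)
  fatal <- findings[findings$level == "fatal", ]
  if (nrow(fatal)) stop(paste(fatal$message, collapse = "; "))
  prior <- list(base = config$anatomy, axis_jitter = 0.12, center_jitter_mm = 3)
  train_cohort <- make_cohort(config$n_train, prior, config$train_variation,
                              n_fractions = config$n_fractions,
                              seed = derive_seed(config$seed, 1))
  test_cohort <- make_cohort(config$n_test, prior, config$test_variation,
                             n_fractions = config$n_fractions,
                             seed = derive_seed(config$seed, 2))
  for (i in seq_along(train_cohort)) train_cohort[[i]]$id <- sprintf("TR%02d", i)
  for (i in seq_along(test_cohort)) test_cohort[[i]]$id <- sprintf("TE%02d", i)
  models <- list()
  sp <- config$anatomy$spacing_mm

  if ("BM" %in% config$methods) {
    seg_spec <- network_spec(config$seg_levels, config$base_channels, "segmentation")
    models$BM <- lapply(config$structures, function(s) {
      cfg <- training_config("BM", spec = seg_spec, epochs = config$bm_epochs,
                             learning_rate = config$bm_lr,
                             seed = derive_seed(config$seed, 3))
      train_baseline(train_cohort, s, cfg)
    })
    names(models$BM) <- config$structures
  }
  if ("PSM" %in% config$methods) {
    models$PSM <- lapply(test_cohort, function(cs) {
      ms <- lapply(config$structures, function(s) {
        cfg <- training_config("PSM", spec = models$BM[[s]]$spec,
                               epochs = config$psm_epochs,
                               learning_rate = config$psm_lr,
                               seed = derive_seed(config$seed, 4))
        finetune_patient(models$BM[[s]], cs, cfg)
      })
      names(ms) <- config$structures
      ms
    })
    names(models$PSM) <- vapply(test_cohort, function(cs) cs$id, "")
  }
  if ("DDFM" %in% config$methods) {
    ddf_spec <- network_spec(config$ddf_levels, config$base_channels, "displacement")
    pairs <- list()
    for (cs in train_cohort) {
      for (fr in cs$fractions) {
        pairs[[length(pairs) + 1]] <- list(
          planning = cs$planning$image,
          planning_masks = cs$planning$structures$masks[config$structures],
          fraction = fr$image, fraction_masks = fr$structures$masks[config$structures])
      }
    }
    cfg <- training_config("DDFM", spec = ddf_spec, epochs = config$ddfm_epochs,
                           learning_rate = config$ddfm_lr,
                           ddfm_data_variant = config$ddfm_variant,
                           structures = config$structures,
                           seed = derive_seed(config$seed, 5))
    models$DDFM <- train_ddfm(pairs, cfg)
  }

  records <- NULL
  for (cs in test_cohort) {
    ptv <- derive_ptv(cs$planning$structures$masks$ctv, config$ptv_margin_mm, sp)
    for (fi in seq_along(cs$fractions)) {
      fr <- cs$fractions[[fi]]
      preds <- list()
      if ("copy" %in% config$methods) {
        preds$copy <- rigid_copy(cs$planning$structures, fr$image)$masks
      }
      if ("plastimatch_like" %in% config$methods) {
        ddf <- bspline_register(fr$image, cs$planning$image, config$stages)
        preds$plastimatch_like <- propagate_contours(
          cs$planning$structures, ddf, ctv_rigid = config$ctv_rigid_in_dir)$masks
      }
      if ("BM" %in% config$methods) {
        preds$BM <- lapply(models$BM[config$structures], function(m) {
          binarize(predict_segmentation(m, fr$image))
        })
      }
      if ("PSM" %in% config$methods) {
        preds$PSM <- lapply(models$PSM[[cs$id]][config$structures], function(m) {
          binarize(predict_segmentation(m, fr$image))
        })
      }
      if ("DDFM" %in% config$methods) {
        ddf <- predict_ddf(models$DDFM, cs$planning$image, fr$image)
        preds$DDFM <- propagate_contours(cs$planning$structures, ddf)$masks
      }
      zr <- rectum_eval_region(ptv, sp[3], config$rectum_margin_mm)
      for (meth in names(preds)) {
        for (s in config$structures) {
          pm <- preds[[meth]][[s]]
          tm <- fr$structures$masks[[s]]
          if (s == "rectum") {
            pm <- crop_to_slices(pm, zr); tm <- crop_to_slices(tm, zr)
          }
          records <- rbind(records, eval_record(pm, tm, sp, cs$id, fi, s, meth))
        }
      }
    }
  }
  stats <- aggregate_metrics(records)
  tests <- if (length(unique(records$method)) >= 2 && config$n_test >= 2) {
    do.call(rbind, lapply(config$structures, function(s) {
      compare_methods(stats, s, "dsc")
    }))
  } else NULL
  report <- report_table(stats)
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   package_version = as.character(utils::packageVersion("contourprop")),
                   n_records = nrow(records))
  if (!is.null(config$out_dir)) {
    dir.create(file.path(config$out_dir, "metrics"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(config$out_dir, "report"), showWarnings = FALSE)
    write.csv(records, file.path(config$out_dir, "metrics", "records.csv"),
              row.names = FALSE)
    write.csv(stats$cohort, file.path(config$out_dir, "metrics", "cohort.csv"),
              row.names = FALSE)
    writeLines(report, file.path(config$out_dir, "report", "report.md"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  list(records = records, stats = stats, tests = tests, report = report,
       manifest = manifest, models = models)
}

#' Read an experiment configuration from YAML
#'
#' Scalar fields of the YAML map onto [experiment_config()] arguments;
#' unknown fields are rejected.
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(experiment_config, y)
}
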