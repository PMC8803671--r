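# End-to-end pipeline: synthesize-or-load, QC screen, fit the three
# statistical models, cross-validate all four classifiers, and write every
# declared output plus a machine-readable run manifest.

#' Validated run configuration
#'
#' @param generator A [generator_config()] (synthetic mode) or `NULL` when
#'   `cohort_dir` points at an existing cohort on disk.
#' @param cohort_dir Optional directory holding a cohort written by
#'   [write_cohort()].
#' @param k Cross-validation folds (default 10); validated against the class
#'   counts before any computation.
#' @param seed Seed for fold assignment and bootstrap.
#' @param n_components Logistic predictors per model (default 2).
#' @param n_boot Bootstrap resamples for AUC CIs.
#' @param varexp_cut SSIM first-level block variance cut (default 0.9).
#' @param qc_threshold Cook's distance threshold; `NULL` for the `4/N`
#'   default.
#' @param qc_components PLS components in the outlier screen (default 2).
#' @param n_export_modes Leading modes exported as +/- sigma mesh files
#'   (default 2).
#' @return A validated `run_config` list.
#' @export
run_config <- function(generator = generator_config(), cohort_dir = NULL,
                       k = 10L, seed = 1L, n_components = 2L,
                       n_boot = 2000L, varexp_cut = 0.9,
                       qc_threshold = NULL, qc_components = 2L,
                       n_export_modes = 2L) {
  if (is.null(generator) && is.null(cohort_dir))
    stop("either a generator config or a cohort_dir is required",
         call. = FALSE)
  if (!is.null(cohort_dir) && !dir.exists(cohort_dir))
    stop("cohort_dir does not exist: ", cohort_dir, call. = FALSE)
  k <- as.integer(k)
  if (!is.null(generator)) {
    stopifnot(inherits(generator, "generator_config"))
    min_class <- min(generator$n_fractured,
                     generator$n_subjects - generator$n_fractured)
    if (k > min_class)
      stop(sprintf("k = %d exceeds the smaller class count (%d)", k,
                   min_class), call. = FALSE)
  }
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (!is.finite(varexp_cut) || varexp_cut <= 0 || varexp_cut >= 1)
    stop("varexp_cut must lie in (0, 1)", call. = FALSE)
  if (n_components < 1L) stop("n_components must be >= 1", call. = FALSE)
  structure(list(generator = generator, cohort_dir = cohort_dir,
                 k = k, seed = as.integer(seed),
                 n_components = as.integer(n_components),
                 n_boot = as.integer(n_boot), varexp_cut = varexp_cut,
                 qc_threshold = qc_threshold,
                 qc_components = as.integer(qc_components),
                 n_export_modes = as.integer(n_export_modes)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' The YAML mirrors [run_config()]; generator settings live under a
#' `generator:` block mirroring [generator_config()].
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  gen <- if (!is.null(raw$generator))
    do.call(generator_config, raw$generator)
  else if (is.null(raw$cohort_dir)) generator_config() else NULL
  args <- raw[setdiff(names(raw), "generator")]
  do.call(run_config, c(list(generator = gen), args))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort synthesis (or load), Cook's-distance outlier
#' screening with exclusions, full-cohort SSM/SIM/SSIM fits, +/- sigma mode
#' exports, and cross-validated classification for SSM, SIM, SSIM and the
#' aBMD baseline.  All declared outputs are written under `out_dir`:
#' cohort matrices, `cooks_shape.csv` / `cooks_intensity.csv`,
#' `varexp_<model>.csv`, `roc_<model>.csv`, mode mesh exports,
#' `report.json` (AUCs, CIs, confusion matrices, logistic coefficients,
#' modes-to-90%-variance counts) and `manifest.json` (configuration, package
#' version and MD5 digests of every output file).  A failing stage aborts
#' with the stage name.
#'
#' @param config A [run_config()] (or a YAML path understood by
#'   [read_run_config()]).
#' @param out_dir Output directory (created).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  cohort <- stage("cohort", {
    if (!is.null(config$cohort_dir)) read_cohort(config$cohort_dir)
    else sample_cohort(config$generator)
  })
  if (!is.null(config$generator) && is.null(config$cohort_dir)) {
    min_class <- min(table(cohort$status))
    if (config$k > min_class)
      stop("k exceeds the smaller class count of the loaded cohort",
           call. = FALSE)
  }
  stage("write-cohort", write_cohort(cohort, file.path(out_dir, "cohort")))

  y <- cohort$status
  qc <- stage("qc", {
    list(shape = cooks_distance_loo(cohort$moments, y,
                                    m = config$qc_components,
                                    threshold = config$qc_threshold),
         intensity = cooks_distance_loo(cohort$element_density, y,
                                        m = config$qc_components,
                                        threshold = config$qc_threshold))
  })
  write.csv(data.frame(subject = seq_along(y),
                       cooks_d_shape = qc$shape$cooks_d,
                       cooks_d_intensity = qc$intensity$cooks_d),
            file.path(out_dir, "cooks_distances.csv"), row.names = FALSE)
  flagged <- sort(unique(c(qc$shape$flagged, qc$intensity$flagged)))
  cohort_used <- stage("exclusions", apply_exclusions(cohort, flagged))
  y <- cohort_used$status

  models <- stage("fit-models", {
    ssm <- fit_pls(cohort_used$moments, y, id = "SSM")
    sim <- fit_pls(cohort_used$element_density, y, id = "SIM")
    ssim <- fit_ssim(ssm, sim, y)
    list(SSM = ssm, SIM = sim, SSIM = ssim)
  })
  for (nm in names(models)) {
    mod <- models[[nm]]
    write.csv(data.frame(mode = seq_len(mod$n_modes),
                         mode_variance = mod$mode_variance,
                         varexp_x = mod$varexp_x,
                         varexp_y = mod$varexp_y),
              file.path(out_dir, sprintf("varexp_%s.csv", tolower(nm))),
              row.names = FALSE)
  }

  stage("mode-export", {
    tpl <- cohort_used$template
    if (!is.null(tpl) && !is.null(tpl$grid)) {
      for (j in seq_len(min(config$n_export_modes,
                            models$SSM$n_modes))) {
        for (s in c(-1, 1)) {
          tag <- sprintf("mode%d_%s", j, if (s < 0) "minus" else "plus")
          export_mode_shapes(models$SSM, tpl, j, scale = s, what = "shape",
                             file = file.path(out_dir,
                                              sprintf("ssm_%s.ply", tag)))
          export_mode_shapes(models$SIM, tpl, j, scale = s,
                             what = "intensity",
                             file = file.path(out_dir,
                                              sprintf("sim_%s.vtk", tag)))
        }
      }
    }
  })

  cv <- stage("cross-validate", {
    kinds <- c("SSM", "SIM", "SSIM", "aBMD")
    out <- lapply(kinds, function(kind)
      cross_validate(cohort_used, kind, k = config$k, seed = config$seed,
                     n_components = config$n_components,
                     n_boot = config$n_boot))
    names(out) <- kinds
    out
  })
  for (nm in names(cv)) {
    write.csv(as.data.frame(cv[[nm]]$roc_points),
              file.path(out_dir, sprintf("roc_%s.csv", tolower(nm))),
              row.names = FALSE)
  }

  report <- list(
    n_subjects = length(y),
    n_fractured = sum(y == 1),
    qc = list(threshold_shape = qc$shape$threshold,
              flagged = flagged),
    modes_to_90pct = list(
      SSM = as.integer(modes_to_explain(models$SSM, 0.9)),
      SIM = as.integer(modes_to_explain(models$SIM, 0.9)),
      SSIM = as.integer(modes_to_explain(models$SSIM, 0.9))),
    classifiers = lapply(cv, function(r) list(
      auc = r$auc, auc_ci = r$auc_ci,
      confusion = as.vector(r$confusion),
      confusion_layout = "TP,FP,FN,TN (column-major; rows = actual)",
      coefficients = lapply(r$per_fold_models, function(m)
        unname(m$coefficients))))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE)

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  digests <- as.vector(tools::md5sum(file.path(out_dir, files)))
  manifest <- list(
    package = "ssimfem",
    version = as.character(utils::packageVersion("ssimfem")),
    config = .config_as_list(config),
    files = as.list(stats::setNames(digests, files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(manifest)
}

.config_as_list <- function(config) {
  out <- unclass(config)
  if (!is.null(out$generator)) out$generator <- unclass(out$generator)
  out
}
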