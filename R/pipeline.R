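#' Experiment configuration
#'
#' Bundles everything needed to reproduce one classification experiment:
#' the input (a cohort directory in the on-disk dialect, an
#' [imu_cohort()], or a [sim_config()] to generate one), the two-group
#' contrast, catalog and segmentation parameters, selection and classifier
#' configuration, the number of CV folds and the master seed. All
#' randomness in the run flows from `seed`.
#'
#' @param input Cohort directory path, `imu_cohort` or `sim_config`.
#' @param contrast A contrast list, see [contrast_groups()]. Default:
#'   patients versus controls.
#' @param classifier A [classifier_spec()].
#' @param selection Selection configuration as in [cross_validate()].
#' @param catalog_params A [catalog_params()] list.
#' @param seg A [seg_params()] list.
#' @param k CV folds.
#' @param seed Integer master seed.
#' @param out_dir Output directory for artifacts (`NULL`: no files).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(input,
                              contrast = list(type = "pd_vs_control"),
                              classifier = classifier_spec("lda"),
                              selection = list(ig_prefilter = 50,
                                               patience = 3, max_k = 25),
                              catalog_params = imugait::catalog_params(),
                              seg = seg_params(), k = 10, seed = 1,
                              out_dir = NULL) {
  structure(list(input = input, contrast = contrast,
                 classifier = classifier, selection = selection,
                 catalog_params = catalog_params, seg = seg,
                 k = k, seed = seed, out_dir = out_dir),
            class = "experiment_config")
}

#' Resolve a contrast into two groups
#'
#' Supported contrast types:
#' * `pd_vs_control` — all patients versus all controls;
#' * `hy_vs_control` — patients at Hoehn & Yahr stage `level` versus all
#'   controls;
#' * `updrs_vs_control` — patients in UPDRS-III bin `level` (`"low"`
#'   0-12, `"mild"` 13-22, `"high"` 23-50) versus all controls;
#' * `hy_pair` — patients at stage `levels[1]` versus stage `levels[2]`;
#' * `updrs_pair` — patients in bin `levels[1]` versus bin `levels[2]`.
#'
#' @param meta Metadata data frame (from [extract_cohort_features()]).
#' @param contrast Contrast list with `type` and `level`/`levels`.
#' @return List with `keep` (row indices), `y` (labels) and `positive`
#'   (the positive-class label); errors, naming the contrast, when a side
#'   is empty.
#' @export
contrast_groups <- function(meta, contrast) {
  type <- contrast$type
  updrs_bin <- function(u) {
    ifelse(is.na(u), NA_character_,
           ifelse(u <= 12, "low", ifelse(u <= 22, "mild", "high")))
  }
  pd <- meta$group == "pd"
  side <- switch(type,
    pd_vs_control = list(a = pd, b = !pd, lab = c("pd", "control")),
    hy_vs_control = list(a = pd & !is.na(meta$hy_stage) &
                             meta$hy_stage == contrast$level,
                         b = !pd,
                         lab = c(paste0("hy", contrast$level), "control")),
    updrs_vs_control = list(a = pd & updrs_bin(meta$updrs_iii) %in% contrast$level,
                            b = !pd,
                            lab = c(paste0("updrs_", contrast$level), "control")),
    hy_pair = list(a = pd & !is.na(meta$hy_stage) &
                       meta$hy_stage == contrast$levels[1],
                   b = pd & !is.na(meta$hy_stage) &
                       meta$hy_stage == contrast$levels[2],
                   lab = paste0("hy", contrast$levels)),
    updrs_pair = list(a = pd & updrs_bin(meta$updrs_iii) %in% contrast$levels[1],
                      b = pd & updrs_bin(meta$updrs_iii) %in% contrast$levels[2],
                      lab = paste0("updrs_", contrast$levels)),
    stop("unknown contrast type: ", type))
  if (!any(side$a) || !any(side$b)) {
    stop(sprintf("contrast '%s' selects an empty subgroup (%d vs %d subjects)",
                 paste(unlist(contrast), collapse = "/"),
                 sum(side$a), sum(side$b)))
  }
  keep <- which(side$a | side$b)
  y <- ifelse(side$a[keep], side$lab[1], side$lab[2])
  list(keep = keep, y = y, positive = side$lab[1])
}

resolve_cohort <- function(input) {
  if (inherits(input, "imu_cohort")) return(input)
  if (inherits(input, "sim_config")) return(simulate_cohort(input))
  if (is.character(input)) return(read_cohort(input))
  stop("input must be a cohort directory, an imu_cohort or a sim_config")
}

#' Run a complete classification experiment
#'
#' Resolves the input cohort (reading or simulating it), extracts the
#' feature bank, applies the contrast, and runs stratified k-fold
#' cross-validation with per-fold feature selection. When `out_dir` is
#' set, writes the feature matrix CSV (+ JSON sidecar), the cross-
#' validation report JSON, a one-row summary CSV (groups, n, classifier,
#' number of features, class rate, sensitivity, specificity, PPV) and a
#' run log recording the seed and package version. Artifacts carry no
#' timestamps, so a rerun with an identical configuration reproduces them
#' byte for byte.
#'
#' @param config An [experiment_config()].
#' @return The `cv_report`, invisibly extended with `contrast` and `n`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- resolve_cohort(config$input)
  catalog <- build_feature_catalog(config$catalog_params)
  feats <- extract_cohort_features(cohort, catalog, config$seg)
  grp <- contrast_groups(feats$meta, config$contrast)
  X <- feats$X[grp$keep, , drop = FALSE]
  report <- cross_validate(X, grp$y, spec = config$classifier,
                           selection = config$selection, k = config$k,
                           seed = config$seed, positive = grp$positive)
  report$contrast <- config$contrast
  report$n <- table(grp$y)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_matrix(feats, file.path(config$out_dir, "features.csv"),
                         catalog)
    write_cv_report(report, file.path(config$out_dir, "cv_report.json"))
    utils::write.csv(summarize_report(report),
                     file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
    writeLines(c(sprintf("seed: %d", config$seed),
                 sprintf("imugait version: %s",
                         as.character(utils::packageVersion("imugait"))),
                 sprintf("classifier: %s", config$classifier$kind),
                 sprintf("subjects: %s",
                         paste(sprintf("%s=%d", names(report$n), report$n),
                               collapse = ", "))),
               file.path(config$out_dir, "run_log.txt"))
  }
  invisible(report)
}

#' Summarize a CV report as a one-row table
#'
#' @param report A `cv_report` (from [cross_validate()] or
#'   [run_experiment()]).
#' @return One-row data frame: groups, n, classifier, features, class
#'   rate, sensitivity, specificity, PPV (integer percentages).
#' @export
summarize_report <- function(report) {
  m <- report$metrics$rounded
  n_feat <- if (!is.null(report$selected)) {
    length(unique(unlist(report$selected)))
  } else NA_integer_
  data.frame(
    groups = if (!is.null(report$n)) paste(names(report$n), collapse = " vs ")
             else NA_character_,
    n = if (!is.null(report$n)) paste(report$n, collapse = ":") else NA,
    classifier = report$classifier,
    features = n_feat,
    class_rate = m$balanced_rate,
    sens = m$sensitivity,
    spec = m$specificity,
    ppv = m$ppv,
    stringsAsFactors = FALSE)
}

#' Write a CV report as JSON
#'
#' @param report A `cv_report`.
#' @param path Output path.
#' @export
write_cv_report <- function(report, path) {
  out <- list(
    k = report$k, seed = report$seed, classifier = report$classifier,
    positive = report$positive,
    fold_counts = report$fold_counts,
    pooled = as.list(report$pooled),
    metrics = report$metrics[c("sensitivity", "specificity", "ppv",
                               "balanced_rate")],
    selected = report$selected)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(NULL)
}

#' Train on one cohort, validate once on an independent cohort
#'
#' Imputation, feature selection and classifier training use the training
#' cohort only; the validation cohort is evaluated exactly once with the
#' frozen pipeline, mirroring a training-population /
#' validation-population design. Overlapping subject ids are an error.
#'
#' @param train_cohort,validation_cohort [imu_cohort()]s (or inputs
#'   resolvable by [run_experiment()]) with disjoint subject ids.
#' @param config An [experiment_config()]; its `input` field is ignored.
#' @return List with `counts`, `metrics`, `selected` (training-selected
#'   column indices) and `train_n`/`validation_n`.
#' @export
run_holdout_validation <- function(train_cohort, validation_cohort, config) {
  stopifnot(inherits(config, "experiment_config"))
  train_cohort <- resolve_cohort(train_cohort)
  validation_cohort <- resolve_cohort(validation_cohort)
  overlap <- intersect(names(train_cohort$sessions),
                       names(validation_cohort$sessions))
  if (length(overlap)) {
    stop("training and validation cohorts share subject ids: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  }
  catalog <- build_feature_catalog(config$catalog_params)
  tr <- extract_cohort_features(train_cohort, catalog, config$seg)
  va <- extract_cohort_features(validation_cohort, catalog, config$seg)
  gtr <- contrast_groups(tr$meta, config$contrast)
  gva <- contrast_groups(va$meta, config$contrast)
  Xtr <- impute_median(tr$X[gtr$keep, , drop = FALSE])
  Xva <- impute_median(tr$X[gtr$keep, , drop = FALSE],
                       va$X[gva$keep, , drop = FALSE])
  cols <- seq_len(ncol(Xtr))
  if (!is.null(config$selection)) {
    if (!is.null(config$selection$fixed_subset)) {
      cols <- config$selection$fixed_subset
    } else {
      args <- c(list(X = Xtr, y = gtr$y, spec = config$classifier,
                     seed = config$seed, positive = gtr$positive),
                config$selection)
      cols <- do.call(sequential_forward_selection, args)$selected
      if (!length(cols)) cols <- seq_len(ncol(Xtr))
    }
  }
  model <- train_classifier(config$classifier, Xtr[, cols, drop = FALSE],
                            gtr$y, seed = config$seed)
  pred <- predict(model, Xva[, cols, drop = FALSE])
  counts <- confusion_counts(gva$y, pred, gtr$positive)
  list(counts = counts, metrics = classification_metrics(counts),
       selected = cols, train_n = table(gtr$y), validation_n = table(gva$y))
}

#' Load a simulation configuration from YAML
#'
#' Reads a flat YAML mapping whose keys are [sim_config()] arguments.
#'
#' @param path YAML file.
#' @return A [sim_config()].
#' @export
load_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown simulation key(s): ", paste(bad, collapse = ", "))
  do.call(sim_config, vals)
}
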