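## The feature bank: a fixed grid of definitions instantiated over
## (definition x channel x task x foot). Counts are structural invariants,
## asserted at construction:
##   step (gyro-z only, walk)    5 defs x 1 ch x 2 feet =  10
##   step (all channels, walk)   6 defs x 6 ch x 2 feet =  72
##   sequence (all tasks)        8 defs x 6 ch x 3 tasks x 2 feet = 288
##   frequency (all tasks)       9 defs x 6 ch x 3 tasks x 2 feet = 324
##   total                                                        = 694
## per task: walk 82 + 96 + 108 = 286; tapping/circling 96 + 108 = 204 each.

step_gyroz_defs <- function() {
  c("step_duration", "step_max", "step_min", "step_minmax_diff",
    "step_energy")
}

step_allchannel_defs <- function() {
  c("step_mean", "step_variance", "step_rms", "step_skewness",
    "step_kurtosis", "step_mean_abs_diff")
}

sequence_defs <- function() {
  c("minmax_diff", "variance", "rms", "entropy", "regression_extrema",
    "mean", "zero_crossing_rate", "mean_abs_diff")
}

frequency_defs <- function() {
  c("dominant_frequency", "dominant_amplitude", "band_energy_low",
    "band_energy_tremor", "windowed_band_energy", "band_psd_low",
    "regression_windowed_energy", "spectral_entropy", "spectral_centroid")
}

## operator registry: sequence/frequency ops are f(x, rate), per-step ops
## are f(step_slice, rate)
op_registry <- function(params) {
  lo <- params$band_low
  tr <- params$band_tremor
  list(
    step_duration = function(x, rate) length(x) / rate,
    step_max = function(x, rate) max(x),
    step_min = function(x, rate) min(x),
    step_minmax_diff = function(x, rate) minmax_difference(x),
    step_energy = function(x, rate) step_energy(x, rate),
    step_mean = function(x, rate) mean(x),
    step_variance = function(x, rate) pop_variance(x),
    step_rms = function(x, rate) root_mean_square(x),
    step_skewness = function(x, rate) pop_skewness(x),
    step_kurtosis = function(x, rate) pop_kurtosis(x),
    step_mean_abs_diff = function(x, rate) mean_abs_diff(x),
    minmax_diff = function(x, rate) minmax_difference(x),
    variance = function(x, rate) pop_variance(x),
    rms = function(x, rate) root_mean_square(x),
    entropy = function(x, rate) signal_entropy(x, params$entropy_bins),
    regression_extrema = function(x, rate) regression_line_of_extrema(x, rate),
    mean = function(x, rate) mean(x),
    zero_crossing_rate = function(x, rate) zero_crossing_rate(x, rate),
    mean_abs_diff = function(x, rate) mean_abs_diff(x),
    dominant_frequency = function(x, rate) dominant_frequency(x, rate),
    dominant_amplitude = function(x, rate) dominant_amplitude(x, rate),
    band_energy_low = function(x, rate) band_energy(x, rate, lo[1], lo[2]),
    band_energy_tremor = function(x, rate) band_energy(x, rate, tr[1], tr[2]),
    windowed_band_energy = function(x, rate)
      windowed_band_energy(x, rate, params$win_s, params$overlap_s,
                           lo[1], lo[2]),
    band_psd_low = function(x, rate) band_psd(x, rate, lo[1], lo[2]),
    regression_windowed_energy = function(x, rate)
      regression_of_windowed_energy(x, rate, params$reg_win_s, lo[1], lo[2]),
    spectral_entropy = function(x, rate) spectral_entropy(x, rate),
    spectral_centroid = function(x, rate) spectral_centroid(x, rate)
  )
}

#' Catalog parameters
#'
#' Tunable constants of the feature bank: the locomotor band (0.5-3 Hz,
#' covering gait and tapping fundamentals), the tremor band (3-8 Hz,
#' containing the 4-6 Hz parkinsonian resting/postural tremor range),
#' spectral windowing (5 s windows with 2.5 s overlap for averaged band
#' energy; 2.5 s windows for the energy-trend regression), amplitude
#' histogram bins for the entropy descriptor, and the lead-in skipped
#' before the 15 s analysis window of the timed tasks.
#'
#' @param band_low Locomotor band, Hz.
#' @param band_tremor Tremor band, Hz.
#' @param win_s,overlap_s Window/overlap for averaged band energy, s.
#' @param reg_win_s Window for the energy-trend regression, s.
#' @param entropy_bins Amplitude histogram bins.
#' @param lead_in_s Lead-in before the 15 s analysis window, s.
#' @return A list of class `catalog_params`.
#' @export
catalog_params <- function(band_low = c(0.5, 3), band_tremor = c(3, 8),
                           win_s = 5, overlap_s = 2.5, reg_win_s = 2.5,
                           entropy_bins = 16, lead_in_s = 2.5) {
  structure(list(band_low = band_low, band_tremor = band_tremor,
                 win_s = win_s, overlap_s = overlap_s,
                 reg_win_s = reg_win_s, entropy_bins = entropy_bins,
                 lead_in_s = lead_in_s),
            class = "catalog_params")
}

#' Build the 694-entry feature catalog
#'
#' Instantiates every feature over (definition x channel x task x foot):
#' per foot, 5 step definitions on the walk gyroscope z-axis, 6 step
#' definitions on all six walk channels, 8 sequence definitions and 9
#' frequency definitions on all six channels of all three tasks. Canonical
#' feature names are `task.foot.channel.definition`. The structural counts
#' (694 total; 286 walk, 204 tapping, 204 circling; 10 + 72 + 288 + 324
#' by category) are asserted at construction.
#'
#' @param params A [catalog_params()] list.
#' @return A `feature_catalog`: data frame with columns `feature`, `task`,
#'   `foot`, `channel`, `category`, `def_name`.
#' @export
build_feature_catalog <- function(params = catalog_params()) {
  rows <- list()
  add <- function(task, foot, channel, category, def_name) {
    rows[[length(rows) + 1]] <<- data.frame(
      feature = paste(task, foot, channel, def_name, sep = "."),
      task = task, foot = foot, channel = channel,
      category = category, def_name = def_name,
      stringsAsFactors = FALSE)
  }
  for (task in imu_tasks()) {
    for (foot in imu_feet()) {
      if (task == "walk_10m") {
        for (d in step_gyroz_defs()) add(task, foot, "gyr_z", "step_gyroz", d)
        for (d in step_allchannel_defs()) {
          for (ch in imu_channels()) add(task, foot, ch, "step_all", d)
        }
      }
      for (d in sequence_defs()) {
        for (ch in imu_channels()) add(task, foot, ch, "sequence", d)
      }
      for (d in frequency_defs()) {
        for (ch in imu_channels()) add(task, foot, ch, "frequency", d)
      }
    }
  }
  cat_df <- do.call(rbind, rows)
  cat_df$def_id <- seq_len(nrow(cat_df))
  counts <- table(cat_df$category)
  stopifnot(
    nrow(cat_df) == 694,
    counts[["step_gyroz"]] == 10,
    counts[["step_all"]] == 72,
    counts[["sequence"]] == 288,
    counts[["frequency"]] == 324,
    sum(cat_df$task == "walk_10m") == 286,
    sum(cat_df$task == "heel_toe_tapping") == 204,
    sum(cat_df$task == "circling") == 204,
    !anyDuplicated(cat_df$feature)
  )
  structure(cat_df, params = params,
            class = c("feature_catalog", "data.frame"))
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat(sprintf("<feature_catalog> %d features\n", nrow(x)))
  print(table(task = x$task, category = x$category))
  invisible(x)
}

#' Extract the full feature vector of one subject
#'
#' Computes every catalog feature from a complete session: walk sequence
#' and frequency features on the pass-concatenated walk signal (turn
#' segments between passes excluded when pass boundaries are present),
#' walk step features on per-step slices from [segment_steps()] applied to
#' the gyroscope z-axis of the same foot, and tapping/circling features on
#' the 15 s analysis window. An operator whose preconditions fail on a
#' given recording yields `NA` at that position, never an error.
#'
#' @param session A complete [subject_session()].
#' @param catalog A [build_feature_catalog()] catalog.
#' @param seg A [seg_params()] list for step segmentation.
#' @return A named numeric vector of length `nrow(catalog)` (class
#'   `feature_vector`) with attributes `subject_id` and `n_missing`.
#' @export
extract_features <- function(session, catalog = build_feature_catalog(),
                             seg = seg_params()) {
  assert_complete_session(session)
  params <- attr(catalog, "params")
  ops <- op_registry(params)
  safely <- function(expr) {
    v <- tryCatch(expr, error = function(e) NA_real_)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) NA_real_ else v
  }

  ## per (task, foot): analysis signal matrix + step list for the walk
  prepared <- list()
  for (foot in imu_feet()) {
    walk <- session$recordings[[recording_key("walk_10m", foot)]]
    if (!is.null(walk$passes)) {
      idx <- unlist(lapply(seq_len(nrow(walk$passes)), function(i) {
        (walk$passes[i, 1] + 1):walk$passes[i, 2]
      }))
      sig <- walk$samples[idx, , drop = FALSE]
    } else {
      sig <- walk$samples
    }
    steps <- tryCatch(
      segment_steps(walk$samples[, "gyr_z"], walk$rate, walk$passes, seg),
      error = function(e) NULL)
    prepared[[recording_key("walk_10m", foot)]] <-
      list(signal = sig, raw = walk$samples, steps = steps, rate = walk$rate)
    for (task in c("heel_toe_tapping", "circling")) {
      rec <- session$recordings[[recording_key(task, foot)]]
      win <- tryCatch(task_analysis_window(rec, params$lead_in_s),
                      error = function(e) NULL)
      sig <- if (is.null(win)) rec$samples
             else slice_interval(rec$samples, win$start, win$end)
      prepared[[recording_key(task, foot)]] <-
        list(signal = sig, raw = rec$samples, steps = NULL, rate = rec$rate)
    }
  }

  values <- numeric(nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    p <- prepared[[recording_key(catalog$task[i], catalog$foot[i])]]
    op <- ops[[catalog$def_name[i]]]
    values[i] <- if (catalog$category[i] %in% c("step_gyroz", "step_all")) {
      safely(step_feature(op, p$raw[, catalog$channel[i]], p$steps, p$rate))
    } else {
      safely(op(p$signal[, catalog$channel[i]], p$rate))
    }
  }
  names(values) <- catalog$feature
  structure(values, subject_id = session$subject_id,
            n_missing = sum(is.na(values)), class = "feature_vector")
}

#' Extract the feature matrix of a cohort
#'
#' @param cohort An [imu_cohort()].
#' @inheritParams extract_features
#' @return List with `X` (subjects x features numeric matrix, `NA` for
#'   missing) and `meta` (data frame of subject_id, group, updrs_iii,
#'   hy_stage, age, sex).
#' @export
extract_cohort_features <- function(cohort, catalog = build_feature_catalog(),
                                    seg = seg_params()) {
  stopifnot(inherits(cohort, "imu_cohort"))
  vecs <- lapply(cohort$sessions, extract_features, catalog = catalog,
                 seg = seg)
  X <- do.call(rbind, lapply(vecs, as.numeric))
  colnames(X) <- catalog$feature
  rownames(X) <- names(cohort$sessions)
  meta <- data.frame(
    subject_id = vapply(cohort$sessions, function(s) s$subject_id, character(1)),
    group = vapply(cohort$sessions, function(s) as.character(s$group), character(1)),
    updrs_iii = vapply(cohort$sessions, function(s) as.integer(s$clinical$updrs_iii), integer(1)),
    hy_stage = vapply(cohort$sessions, function(s) as.integer(s$clinical$hy_stage), integer(1)),
    age = vapply(cohort$sessions, function(s) as.numeric(s$clinical$age), numeric(1)),
    sex = vapply(cohort$sessions, function(s) as.character(s$clinical$sex), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(X = X, meta = meta)
}

#' Write a cohort feature matrix with catalog sidecar
#'
#' Writes the matrix as CSV (canonical feature names in the header, one
#' row per subject, `NA` for missing values) plus a JSON sidecar recording
#' the catalog parameters.
#'
#' @param features Result of [extract_cohort_features()].
#' @param path Output CSV path; the sidecar gets extension `.json`.
#' @param catalog The catalog used for extraction.
#' @export
write_feature_matrix <- function(features, path,
                                 catalog = build_feature_catalog()) {
  df <- data.frame(subject_id = features$meta$subject_id,
                   group = features$meta$group,
                   features$X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- list(catalog_version = "1",
                  n_features = nrow(catalog),
                  params = unclass(attr(catalog, "params")))
  jsonlite::write_json(sidecar, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
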