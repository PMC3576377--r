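#' @keywords internal
"_PACKAGE"

#' Channel, task and foot vocabularies
#'
#' The sensing model is a pair of shoe-mounted inertial measurement units,
#' each providing a 3-axis accelerometer (units: g) and a 3-axis gyroscope
#' (units: deg/s), sampled at a common rate (50 Hz by default). Recordings
#' are taken per foot for three standardized tasks: a 10-meter walk
#' (several passes), 20 s of heel-toe tapping and 20 s of foot circling.
#'
#' @return Character vectors of valid identifiers.
#' @export
imu_channels <- function() {
  c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")
}

#' @rdname imu_channels
#' @export
imu_tasks <- function() {
  c("walk_10m", "heel_toe_tapping", "circling")
}

#' @rdname imu_channels
#' @export
imu_feet <- function() {
  c("left", "right")
}

channel_sensor <- function(channel) {
  ifelse(substr(channel, 1, 3) == "acc", "accelerometer", "gyroscope")
}

## intervals are 0-based half-open [start, end) sample index pairs, stored as
## a 2-column integer matrix; this matches the on-disk `# passes=` header
as_interval_matrix <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.list(x)) x <- do.call(rbind, lapply(x, function(p) as.integer(p[1:2])))
  x <- matrix(as.integer(x), ncol = 2,
              dimnames = list(NULL, c("start", "end")))
  x
}

validate_intervals <- function(iv, n, what = "pass boundaries") {
  if (is.null(iv)) return(invisible(NULL))
  if (any(iv[, 2] <= iv[, 1])) {
    stop(sprintf("%s must be non-empty half-open intervals", what))
  }
  if (any(iv < 0L) || any(iv[, 2] > n)) {
    stop(sprintf("%s must lie within [0, %d)", what, n))
  }
  if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2])) {
    stop(sprintf("%s must be disjoint and ordered", what))
  }
  invisible(NULL)
}

#' Construct a single-foot, single-task inertial recording
#'
#' @param samples Numeric matrix, one row per time point, six columns named
#'   as in [imu_channels()]. Accelerometer columns are in g, gyroscope
#'   columns in deg/s.
#' @param foot `"left"` or `"right"`.
#' @param task One of [imu_tasks()].
#' @param rate Sampling rate in Hz.
#' @param passes Optional pass boundaries for the walk task: a 2-column
#'   matrix (or list of pairs) of 0-based half-open sample intervals,
#'   disjoint and ordered. Samples between passes (turns) are excluded from
#'   sequence and frequency analysis.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(samples, foot, task, rate = 50, passes = NULL) {
  foot <- match.arg(foot, imu_feet())
  task <- match.arg(task, imu_tasks())
  samples <- as.matrix(samples)
  if (is.null(colnames(samples))) colnames(samples) <- imu_channels()
  missing_ch <- setdiff(imu_channels(), colnames(samples))
  if (length(missing_ch)) {
    stop("missing channel column(s): ", paste(missing_ch, collapse = ", "))
  }
  samples <- samples[, imu_channels(), drop = FALSE]
  if (nrow(samples) < 1) stop("recording must contain at least one sample")
  if (!all(is.finite(samples))) stop("recording contains non-finite samples")
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("sampling rate must be a single positive number")
  }
  passes <- as_interval_matrix(passes)
  validate_intervals(passes, nrow(samples))
  structure(list(samples = samples, foot = foot, task = task,
                 rate = rate, passes = passes),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s / %s: %d samples @ %g Hz (%.1f s)%s\n",
              x$task, x$foot, nrow(x$samples), x$rate,
              nrow(x$samples) / x$rate,
              if (!is.null(x$passes)) sprintf(", %d passes", nrow(x$passes))
              else ""))
  invisible(x)
}

recording_key <- function(task, foot) paste(task, foot, sep = "_")

#' Construct a subject session
#'
#' A session bundles the six recordings of one subject (2 feet x 3 tasks)
#' with group and clinical metadata. Sessions may be built incrementally
#' with a subset of recordings; completeness is enforced where it matters
#' (writing to disk, feature extraction) via [assert_complete_session()].
#'
#' @param subject_id Character scalar, unique within a cohort.
#' @param group `"pd"`, `"control"`, or `NA` when unknown.
#' @param recordings Named list of [imu_recording()] objects; names must be
#'   `<task>_<foot>` (e.g. `"walk_10m_left"`).
#' @param clinical Named list; recognised entries: `updrs_iii` (integer
#'   0-108 or `NA`), `hy_stage` (1, 2, 3 or `NA`), `age` (years), `sex`.
#' @return An object of class `subject_session`.
#' @export
subject_session <- function(subject_id, group = NA_character_,
                            recordings = list(), clinical = list()) {
  stopifnot(is.character(subject_id), length(subject_id) == 1,
            nzchar(subject_id))
  if (!is.na(group)) group <- match.arg(group, c("pd", "control"))
  valid_keys <- as.vector(outer(imu_tasks(), imu_feet(), recording_key))
  bad <- setdiff(names(recordings), valid_keys)
  if (length(bad)) stop("unknown recording key(s): ", paste(bad, collapse = ", "))
  for (k in names(recordings)) {
    r <- recordings[[k]]
    if (!inherits(r, "imu_recording")) stop("recordings must be imu_recording objects")
    if (recording_key(r$task, r$foot) != k) {
      stop(sprintf("recording stored under '%s' is labelled %s/%s", k, r$task, r$foot))
    }
  }
  clin <- list(updrs_iii = NA_integer_, hy_stage = NA_integer_,
               age = NA_real_, sex = NA_character_)
  clin[names(clinical)] <- clinical
  if (!is.na(clin$updrs_iii) &&
      (clin$updrs_iii < 0 || clin$updrs_iii > 108)) {
    stop("updrs_iii must lie in [0, 108]")
  }
  if (!is.na(clin$hy_stage) && !(clin$hy_stage %in% 1:3)) {
    stop("hy_stage must be 1, 2 or 3")
  }
  structure(list(subject_id = subject_id, group = group,
                 recordings = recordings, clinical = clin),
            class = "subject_session")
}

#' Assert that a session carries all six recordings
#'
#' @param session A [subject_session()].
#' @return The session, invisibly; otherwise an incomplete-session error
#'   listing every missing `<task>_<foot>` item.
#' @export
assert_complete_session <- function(session) {
  stopifnot(inherits(session, "subject_session"))
  expected <- as.vector(outer(imu_tasks(), imu_feet(), recording_key))
  missing <- setdiff(expected, names(session$recordings))
  if (length(missing)) {
    stop(sprintf("incomplete session '%s': missing %s", session$subject_id,
                 paste(missing, collapse = ", ")))
  }
  invisible(session)
}

#' Construct a cohort of subject sessions
#'
#' @param sessions List of [subject_session()] objects with unique ids.
#' @return An object of class `imu_cohort`.
#' @export
imu_cohort <- function(sessions = list()) {
  stopifnot(all(vapply(sessions, inherits, TRUE, "subject_session")))
  ids <- vapply(sessions, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate subject ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(sessions) <- ids
  structure(list(sessions = sessions), class = "imu_cohort")
}

#' @export
print.imu_cohort <- function(x, ...) {
  grp <- vapply(x$sessions, function(s) as.character(s$group), character(1))
  cat(sprintf("<imu_cohort> %d subjects (%d pd, %d control)\n",
              length(x$sessions), sum(grp == "pd", na.rm = TRUE),
              sum(grp == "control", na.rm = TRUE)))
  invisible(x)
}

#' Convert raw sensor millivolts to physical units
#'
#' Applies the nominal sensitivities of the sensing hardware: 300 mV/g for
#' the accelerometer and 2 mV per deg/s for the gyroscope, then clips to
#' the measurement range (+/- 6 g, +/- 500 deg/s). Input is assumed
#' zero-centered at rest; device bias calibration is an upstream concern.
#' Clipping is silent but counted in the `"n_clipped"` attribute.
#'
#' @param raw_mv Numeric vector of raw values in millivolts.
#' @param channel A channel id (e.g. `"acc_x"`) or sensor name
#'   (`"accelerometer"` / `"gyroscope"`).
#' @return Numeric vector in g (accelerometer) or deg/s (gyroscope), with
#'   attribute `n_clipped`.
#' @examples
#' raw_to_physical(300, "acc_x")   # 1 g
#' raw_to_physical(2000, "gyr_z")  # 500 deg/s after clipping
#' @export
raw_to_physical <- function(raw_mv, channel) {
  sensor <- if (channel %in% c("accelerometer", "gyroscope")) channel
            else channel_sensor(match.arg(channel, imu_channels()))
  if (sensor == "accelerometer") {
    out <- raw_mv / 300
    lim <- 6
  } else {
    out <- raw_mv / 2
    lim <- 500
  }
  n_clip <- sum(abs(out) > lim)
  out <- pmin(pmax(out, -lim), lim)
  attr(out, "n_clipped") <- n_clip
  out
}

#' Analysis window for the timed tasks
#'
#' Heel-toe tapping and circling are analysed over a fixed 15-second
#' period. The window starts after a configurable lead-in (default 2.5 s,
#' skipping movement-initiation transients); for recordings too short to
#' hold lead-in plus 15 s, the longest available 15-s-or-shorter interval
#' is returned and flagged as truncated.
#'
#' @param rec An [imu_recording()] for `heel_toe_tapping` or `circling`.
#' @param lead_in_s Lead-in to skip, in seconds.
#' @param window_s Window length, in seconds.
#' @return List with 0-based half-open sample indices `start`, `end` and a
#'   logical `truncated`.
#' @export
task_analysis_window <- function(rec, lead_in_s = 2.5, window_s = 15) {
  stopifnot(inherits(rec, "imu_recording"))
  if (!rec$task %in% c("heel_toe_tapping", "circling")) {
    stop("analysis window applies to heel_toe_tapping and circling only")
  }
  n <- nrow(rec$samples)
  if (n < 5 * rec$rate) {
    stop(sprintf("insufficient data: %.1f s recorded, at least 5 s required",
                 n / rec$rate))
  }
  win <- round(window_s * rec$rate)
  lead <- round(lead_in_s * rec$rate)
  start <- max(0L, min(lead, n - win))
  end <- min(n, start + win)
  list(start = as.integer(start), end = as.integer(end),
       truncated = (end - start) < win)
}

slice_interval <- function(x, start, end) {
  if (is.matrix(x)) x[(start + 1):end, , drop = FALSE]
  else x[(start + 1):end]
}

## ---- CSV dialect -----------------------------------------------------------
## <subject_id>/<task>_<foot>.csv
##   # rate_hz=50
##   # passes=0:500,600:1100        (walk only, optional, 0-based half-open)
##   t,acc_x,acc_y,acc_z,gyr_x,gyr_y,gyr_z

format_passes <- function(iv) {
  paste(sprintf("%d:%d", iv[, 1], iv[, 2]), collapse = ",")
}

parse_passes <- function(txt) {
  parts <- strsplit(strsplit(txt, ",")[[1]], ":")
  as_interval_matrix(lapply(parts, as.integer))
}

write_recording_csv <- function(rec, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%g", rec$rate), con)
  if (!is.null(rec$passes)) {
    writeLines(sprintf("# passes=%s", format_passes(rec$passes)), con)
  }
  df <- data.frame(t = (seq_len(nrow(rec$samples)) - 1) / rec$rate,
                   rec$samples, check.names = FALSE)
  ## default double formatting round-trips to full precision
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

read_recording_csv <- function(file, task, foot) {
  lines <- readLines(file, n = 5L)
  hdr <- grep("^#", lines, value = TRUE)
  rate_line <- grep("^# *rate_hz=", hdr, value = TRUE)
  if (!length(rate_line)) {
    stop(sprintf("format error in '%s': missing '# rate_hz=' header", file))
  }
  rate <- as.numeric(sub("^# *rate_hz=", "", rate_line[1]))
  passes <- NULL
  pass_line <- grep("^# *passes=", hdr, value = TRUE)
  if (length(pass_line)) passes <- parse_passes(sub("^# *passes=", "", pass_line[1]))
  df <- utils::read.csv(file, comment.char = "#")
  need <- c("t", imu_channels())
  missing_col <- setdiff(need, names(df))
  if (length(missing_col)) {
    stop(sprintf("format error in '%s': missing column(s) %s", file,
                 paste(missing_col, collapse = ", ")))
  }
  if (anyNA(df$t) || any(diff(df$t) <= 0)) {
    stop(sprintf("format error in '%s': timestamps missing or non-monotonic",
                 file))
  }
  imu_recording(as.matrix(df[imu_channels()]), foot = foot, task = task,
                rate = rate, passes = passes)
}

#' Read and write a subject session in the on-disk CSV dialect
#'
#' Each subject is a directory containing one CSV per task and foot,
#' `<task>_<foot>.csv`, with a `# rate_hz=` header line, an optional
#' `# passes=a:b,c:d,...` header for the walk task (0-based half-open
#' sample indices) and columns `t,acc_x,acc_y,acc_z,gyr_x,gyr_y,gyr_z`
#' (t in seconds; accelerometer in g; gyroscope in deg/s).
#'
#' @param path Subject directory.
#' @param subject_id Subject id; defaults to the directory name.
#' @return [read_session()]: a [subject_session()] (group and clinical
#'   fields are carried by the cohort manifest, see [read_cohort()]).
#' @export
read_session <- function(path, subject_id = basename(normalizePath(path))) {
  if (!dir.exists(path)) stop("no such subject directory: ", path)
  recs <- list()
  missing <- character(0)
  for (task in imu_tasks()) {
    for (foot in imu_feet()) {
      key <- recording_key(task, foot)
      f <- file.path(path, paste0(key, ".csv"))
      if (!file.exists(f)) {
        missing <- c(missing, key)
      } else {
        recs[[key]] <- read_recording_csv(f, task, foot)
      }
    }
  }
  if (length(missing)) {
    stop(sprintf("incomplete session '%s': missing %s", subject_id,
                 paste(missing, collapse = ", ")))
  }
  subject_session(subject_id, recordings = recs)
}

#' @rdname read_session
#' @param session A complete [subject_session()].
#' @export
write_session <- function(session, path) {
  assert_complete_session(session)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create subject directory: ", path)
  for (key in names(session$recordings)) {
    write_recording_csv(session$recordings[[key]],
                        file.path(path, paste0(key, ".csv")))
  }
  invisible(NULL)
}

#' Read and write a cohort directory
#'
#' A cohort directory holds one subdirectory per subject plus a manifest
#' `cohort.csv` with columns `subject_id,group,updrs_iii,hy_stage,age,sex`.
#'
#' @param dir Cohort directory.
#' @return [read_cohort()]: an [imu_cohort()].
#' @export
read_cohort <- function(dir) {
  manifest <- file.path(dir, "cohort.csv")
  if (!file.exists(manifest)) stop("missing cohort manifest: ", manifest)
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  sessions <- lapply(seq_len(nrow(man)), function(i) {
    s <- read_session(file.path(dir, man$subject_id[i]), man$subject_id[i])
    s$group <- man$group[i]
    s$clinical$updrs_iii <- suppressWarnings(as.integer(man$updrs_iii[i]))
    s$clinical$hy_stage <- suppressWarnings(as.integer(man$hy_stage[i]))
    s$clinical$age <- suppressWarnings(as.numeric(man$age[i]))
    s$clinical$sex <- as.character(man$sex[i])
    s
  })
  imu_cohort(sessions)
}

#' @rdname read_cohort
#' @param cohort An [imu_cohort()].
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "imu_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- data.frame(
    subject_id = vapply(cohort$sessions, function(s) s$subject_id, character(1)),
    group = vapply(cohort$sessions, function(s) as.character(s$group), character(1)),
    updrs_iii = vapply(cohort$sessions, function(s) as.integer(s$clinical$updrs_iii), integer(1)),
    hy_stage = vapply(cohort$sessions, function(s) as.integer(s$clinical$hy_stage), integer(1)),
    age = vapply(cohort$sessions, function(s) as.numeric(s$clinical$age), numeric(1)),
    sex = vapply(cohort$sessions, function(s) as.character(s$clinical$sex), character(1)),
    stringsAsFactors = FALSE)
  if (nrow(man) == 0) {
    man <- data.frame(subject_id = character(0), group = character(0),
                      updrs_iii = integer(0), hy_stage = integer(0),
                      age = numeric(0), sex = character(0))
  }
  utils::write.csv(man, file.path(dir, "cohort.csv"), row.names = FALSE)
  for (s in cohort$sessions) write_session(s, file.path(dir, s$subject_id))
  invisible(NULL)
}
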