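#' Step segmentation parameters
#'
#' Controls the detection of individual steps in the walk-task gyroscope
#' z-axis signal. The signal is band-pass filtered to the locomotor band,
#' mid-swing angular-velocity extrema are detected as peaks of topographic
#' prominence at least `prominence_degps` separated by at least
#' `min_separation_s`, and step boundaries are placed at midpoints between
#' consecutive peaks (pass edges bound the first and last step).
#'
#' @param prominence_degps Minimum peak prominence, deg/s.
#' @param min_separation_s Minimum distance between detected peaks, s.
#' @param band_hz Two-element pass band for the zero-phase 2nd-order
#'   Butterworth filter, Hz.
#' @param polarity `-1` to detect negative gyroscope-z peaks (the default
#'   mounting convention), `+1` to flip for mirrored sensor mountings.
#' @param min_step_s,max_step_s Admissible step duration range, s; steps
#'   outside it are dropped.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(prominence_degps = 50, min_separation_s = 0.4,
                       band_hz = c(0.5, 8), polarity = -1,
                       min_step_s = 0.3, max_step_s = 3.0) {
  stopifnot(prominence_degps > 0, min_separation_s > 0,
            length(band_hz) == 2, band_hz[1] > 0, band_hz[2] > band_hz[1],
            polarity %in% c(-1, 1), min_step_s > 0, max_step_s > min_step_s)
  structure(list(prominence_degps = prominence_degps,
                 min_separation_s = min_separation_s,
                 band_hz = band_hz, polarity = polarity,
                 min_step_s = min_step_s, max_step_s = max_step_s),
            class = "seg_params")
}

## topographic prominence of a strict local maximum p of v: height above
## the higher of the two key saddles (lowest point between the peak and the
## nearest at-least-as-high terrain per side; signal edge if none exists)
peak_prominence_one <- function(v, p) {
  h <- v[p]
  left <- v[1:(p - 1)]
  higher <- which(left >= h)
  lo_l <- if (length(higher)) min(left[(max(higher) + 1):length(left)])
          else min(left)
  right <- v[(p + 1):length(v)]
  higher <- which(right >= h)
  lo_r <- if (length(higher)) min(right[1:(min(higher) - 1)])
          else min(right)
  h - max(lo_l, lo_r)
}

#' Detect peaks by prominence and minimum separation
#'
#' Peaks are strict local maxima (plateaus contribute their first sample)
#' with topographic prominence at least `min_prominence`; when two peaks
#' are closer than `min_distance` samples, the higher one wins.
#'
#' @param x Numeric signal.
#' @param min_prominence Minimum topographic prominence.
#' @param min_distance Minimum index distance between kept peaks.
#' @return Integer vector of 1-based peak indices, ascending.
#' @export
find_peaks <- function(x, min_prominence = 0, min_distance = 1) {
  r <- rle(x)
  v <- r$values
  k <- length(v)
  if (k < 3) return(integer(0))
  first_idx <- cumsum(c(1L, r$lengths[-k]))
  core <- which(v[2:(k - 1)] > v[1:(k - 2)] & v[2:(k - 1)] > v[3:k]) + 1L
  if (!length(core)) return(integer(0))
  prom <- vapply(core, function(p) peak_prominence_one(v, p), numeric(1))
  core <- core[prom >= min_prominence]
  if (!length(core)) return(integer(0))
  cand <- first_idx[core]
  keep <- logical(length(cand))
  for (i in order(-x[cand], cand)) {
    if (!any(keep & abs(cand - cand[i]) < min_distance)) keep[i] <- TRUE
  }
  sort(cand[keep])
}

bandpass_filter <- function(x, rate, band) {
  ny <- rate / 2
  hi <- min(band[2], 0.99 * ny)
  bf <- signal::butter(2, c(band[1], hi) / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Segment individual steps from the walk gyroscope z-axis
#'
#' Within each pass the signal is band-pass filtered (zero-phase,
#' 2nd-order, 0.5-8 Hz by default), swing-phase angular-velocity extrema
#' are detected as prominent peaks of the configured polarity, and each
#' step is the half-open sample interval between midpoints of consecutive
#' peaks, the first and last step being bounded by the pass edges. Steps
#' whose duration falls outside `[min_step_s, max_step_s]` are dropped;
#' steps never straddle pass boundaries.
#'
#' @param gyro_z Gyroscope z-axis signal, deg/s.
#' @param rate Sampling rate, Hz.
#' @param passes Optional pass intervals (0-based half-open 2-column
#'   matrix); defaults to one pass spanning the whole signal.
#' @param params A [seg_params()] list.
#' @return A `step_list`: data frame with columns `start`, `end` (0-based
#'   half-open sample indices) and `pass_index`, with attribute `rate`.
#'   Zero detected steps yield an empty step list, not an error.
#' @export
segment_steps <- function(gyro_z, rate, passes = NULL, params = seg_params()) {
  if (length(gyro_z) == 0) stop("insufficient data: empty signal")
  stopifnot(rate > 0, all(is.finite(gyro_z)))
  if (is.null(passes)) passes <- matrix(c(0L, length(gyro_z)), ncol = 2)
  passes <- as_interval_matrix(passes)
  validate_intervals(passes, length(gyro_z))
  min_dist <- round(params$min_separation_s * rate)
  out <- list()
  for (p in seq_len(nrow(passes))) {
    a <- passes[p, 1]; b <- passes[p, 2]
    seg <- gyro_z[(a + 1):b]
    if (length(seg) < max(12, 3 * rate / params$band_hz[2])) next
    y <- params$polarity * bandpass_filter(seg, rate, params$band_hz)
    pk <- find_peaks(y, params$prominence_degps, min_dist)
    if (!length(pk)) next
    bounds <- c(0L, if (length(pk) > 1) as.integer(floor((pk[-1] + pk[-length(pk)]) / 2)) else integer(0),
                length(seg))
    st <- data.frame(start = a + bounds[-length(bounds)],
                     end = a + bounds[-1], pass_index = p)
    dur <- (st$end - st$start) / rate
    out[[length(out) + 1]] <- st[dur >= params$min_step_s & dur <= params$max_step_s, ]
  }
  steps <- if (length(out)) do.call(rbind, out)
           else data.frame(start = integer(0), end = integer(0),
                           pass_index = integer(0))
  rownames(steps) <- NULL
  structure(steps, rate = rate, class = c("step_list", "data.frame"))
}

#' @export
print.step_list <- function(x, ...) {
  cat(sprintf("<step_list> %d steps @ %g Hz\n", nrow(x), attr(x, "rate")))
  if (nrow(x)) {
    dur <- (x$end - x$start) / attr(x, "rate")
    cat(sprintf("  duration: %.2f-%.2f s (mean %.2f)\n",
                min(dur), max(dur), mean(dur)))
  }
  invisible(x)
}
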