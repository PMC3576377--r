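## Scalar time- and frequency-domain descriptors. All operators take a
## finite 1-D signal (and the sampling rate where needed) and return a
## single number, or NA_real_ for a flagged missing value. Hard errors are
## reserved for violated preconditions (empty input, invalid band).

check_signal <- function(x, min_len = 1) {
  if (length(x) < min_len) {
    stop(sprintf("insufficient data: need at least %d samples, got %d",
                 min_len, length(x)))
  }
  invisible(x)
}

#' Amplitude range of a signal
#'
#' `max(x) - min(x)`; for step-dependent use this is the global maximum of
#' one step minus the global minimum, averaged over steps via
#' [step_feature()].
#'
#' @param x Numeric signal.
#' @return Range in amplitude units.
#' @export
minmax_difference <- function(x) {
  check_signal(x, 1)
  max(x) - min(x)
}

#' Shannon entropy of the amplitude histogram
#'
#' Uncertainty measure of the signal: amplitudes are binned into `n_bins`
#' equal-width bins spanning `[min(x), max(x)]` and the Shannon entropy of
#' the bin proportions is returned in bits. A constant signal has entropy
#' 0 by definition (its amplitude distribution is degenerate).
#'
#' @param x Numeric signal of length >= 2.
#' @param n_bins Number of histogram bins.
#' @return Entropy in bits.
#' @export
signal_entropy <- function(x, n_bins = 16) {
  check_signal(x, 2)
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  cnt <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), n_bins),
                  nbins = n_bins)
  p <- cnt[cnt > 0] / length(x)
  -sum(p * log2(p))
}

## strict local extrema (minima and maxima); plateaus contribute their
## first sample; returns ascending 1-based indices
local_extrema_idx <- function(x) {
  r <- rle(x)
  v <- r$values
  k <- length(v)
  if (k < 3) return(integer(0))
  first_idx <- cumsum(c(1L, r$lengths[-k]))
  mid <- 2:(k - 1)
  is_ext <- (v[mid] > v[mid - 1] & v[mid] > v[mid + 1]) |
            (v[mid] < v[mid - 1] & v[mid] < v[mid + 1])
  first_idx[mid[is_ext]]
}

#' Least-squares slope through all local extrema
#'
#' Fits a regression line to (time, value) over every strict local minimum
#' and maximum of the sequence; the slope tracks envelope drift (e.g.
#' progressive amplitude decrement over a task).
#'
#' @param x Numeric signal.
#' @param rate Sampling rate, Hz.
#' @return Slope in amplitude units per second, or `NA` when fewer than
#'   two interior extrema exist.
#' @export
regression_line_of_extrema <- function(x, rate) {
  idx <- local_extrema_idx(x)
  if (length(idx) < 2) return(NA_real_)
  tt <- (idx - 1) / rate
  v <- x[idx]
  sum((tt - mean(tt)) * (v - mean(v))) / sum((tt - mean(tt))^2)
}

#' Population variance
#'
#' Square of the (population) standard deviation, i.e. dividing by N.
#'
#' @param x Numeric signal of length >= 2.
#' @return Variance in squared amplitude units.
#' @export
pop_variance <- function(x) {
  check_signal(x, 2)
  mean((x - mean(x))^2)
}

#' Root mean square
#'
#' @param x Numeric signal.
#' @return `sqrt(mean(x^2))` in amplitude units.
#' @export
root_mean_square <- function(x) {
  check_signal(x, 1)
  sqrt(mean(x^2))
}

pop_skewness <- function(x) {
  check_signal(x, 2)
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(NA_real_)
  mean((x - mean(x))^3) / m2^1.5
}

pop_kurtosis <- function(x) {
  check_signal(x, 2)
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(NA_real_)
  mean((x - mean(x))^4) / m2^2
}

mean_abs_diff <- function(x) {
  check_signal(x, 2)
  mean(abs(diff(x)))
}

zero_crossing_rate <- function(x, rate) {
  check_signal(x, 2)
  sum(x[-length(x)] * x[-1] < 0) / (length(x) / rate)
}

## one-sided energy spectrum after mean removal: bin k (0-based, up to
## Nyquist) carries w_k |X_k|^2 / N with w = 2 except DC and (even N)
## Nyquist, so that the bins sum to sum(x^2) (Parseval)
one_sided_spectrum <- function(x, rate) {
  x <- x - mean(x)
  n <- length(x)
  X <- stats::fft(x)
  k <- 0:(n %/% 2)
  w <- rep(2, length(k))
  w[1] <- 1
  if (n %% 2 == 0) w[length(k)] <- 1
  list(f = k * rate / n, energy = w * Mod(X[k + 1])^2 / n,
       mod = Mod(X[k + 1]), n = n)
}

#' Energy in a frequency band
#'
#' The mean is removed, the discrete Fourier transform is taken, and the
#' one-sided energies `|X_k|^2 / N` (doubled off DC/Nyquist) are summed
#' over bins with `f_lo <= f_k <= f_hi`. Summed over a partition of
#' `[0, Nyquist]` the band energies reproduce the time-domain energy
#' `sum((x - mean(x))^2)`.
#'
#' @param x Numeric signal of length >= 8.
#' @param rate Sampling rate, Hz.
#' @param f_lo,f_hi Band edges, Hz, with `f_lo < f_hi <= rate/2`.
#' @return Band energy (squared amplitude units).
#' @export
band_energy <- function(x, rate, f_lo = 0.5, f_hi = 3.0) {
  check_signal(x, 8)
  if (f_lo < 0 || f_hi > rate / 2 || f_lo >= f_hi) {
    stop(sprintf("invalid band [%g, %g] Hz for rate %g Hz", f_lo, f_hi, rate))
  }
  sp <- one_sided_spectrum(x, rate)
  sel <- sp$f >= f_lo & sp$f <= f_hi
  sum(sp$energy[sel])
}

#' Band energy averaged over sliding windows
#'
#' [band_energy()] is computed in windows of `win_s` seconds advanced by
#' `win_s - overlap_s` and averaged over all full windows; a 15 s signal
#' at the defaults yields 5 windows.
#'
#' @inheritParams band_energy
#' @param win_s Window length, s.
#' @param overlap_s Overlap between consecutive windows, s.
#' @return Mean windowed band energy, or `NA` when the signal is shorter
#'   than one window.
#' @export
windowed_band_energy <- function(x, rate, win_s = 5.0, overlap_s = 2.5,
                                 f_lo = 0.5, f_hi = 3.0) {
  win <- round(win_s * rate)
  hop <- round((win_s - overlap_s) * rate)
  stopifnot(hop >= 1)
  if (length(x) < win) return(NA_real_)
  starts <- seq(0, length(x) - win, by = hop)
  mean(vapply(starts, function(s) band_energy(x[(s + 1):(s + win)], rate,
                                              f_lo, f_hi), numeric(1)))
}

#' Power spectral density integral over a band
#'
#' The PSD is estimated by the Wiener-Khinchin route: the biased
#' autocorrelation of the mean-removed signal is computed for all lags and
#' Fourier-transformed, yielding the spectral density on a `2N - 1` point
#' grid; the density is integrated over `[f_lo, f_hi]` (one-sided). For
#' the biased autocorrelation this estimator coincides with the
#' zero-padded periodogram. The full-band integral equals the mean square
#' of the mean-removed signal.
#'
#' @inheritParams band_energy
#' @return Integrated PSD over the band (squared amplitude units).
#' @export
band_psd <- function(x, rate, f_lo = 0.5, f_hi = 3.0) {
  check_signal(x, 8)
  if (f_lo < 0 || f_hi > rate / 2 || f_lo >= f_hi) {
    stop(sprintf("invalid band [%g, %g] Hz for rate %g Hz", f_lo, f_hi, rate))
  }
  x <- x - mean(x)
  n <- length(x)
  m <- 2 * n - 1
  xp <- c(x, rep(0, n - 1))
  ## biased autocorrelation at lags 0..n-1 then wrapped negative lags
  r <- Re(stats::fft(Mod(stats::fft(xp))^2, inverse = TRUE)) / (m * n)
  dens <- Re(stats::fft(r)) / rate            # amplitude^2 per Hz
  k <- 0:((m - 1) / 2)
  f <- k * rate / m
  w <- rep(2, length(k))
  w[1] <- 1                                   # m is odd: no Nyquist bin
  sel <- f >= f_lo & f <= f_hi
  sum(w[sel] * dens[k[sel] + 1]) * rate / m
}

#' Temporal trend of windowed band energy
#'
#' [band_energy()] is computed in windows of `win_s` seconds advanced by
#' half a window (50 % overlap) and the least-squares slope of energy
#' against window-center time is returned, capturing e.g. fatigue-related
#' energy decline over a task.
#'
#' @inheritParams band_energy
#' @param win_s Window length, s.
#' @return Slope in energy units per second, or `NA` with fewer than two
#'   windows.
#' @export
regression_of_windowed_energy <- function(x, rate, win_s = 2.5,
                                          f_lo = 0.5, f_hi = 3.0) {
  win <- round(win_s * rate)
  hop <- round(win_s * rate / 2)
  if (length(x) < win + hop) return(NA_real_)
  starts <- seq(0, length(x) - win, by = hop)
  if (length(starts) < 2) return(NA_real_)
  e <- vapply(starts, function(s) band_energy(x[(s + 1):(s + win)], rate,
                                              f_lo, f_hi), numeric(1))
  tt <- (starts + win / 2) / rate
  sum((tt - mean(tt)) * (e - mean(e))) / sum((tt - mean(tt))^2)
}

#' Dominant frequency of a signal
#'
#' Frequency of the maximum-magnitude bin of the mean-removed DFT
#' (DC excluded), refined by parabolic interpolation over the three bins
#' around the peak. For gait signals this approximates cadence or
#' movement rate.
#'
#' @inheritParams band_energy
#' @return Frequency in Hz; `NA` for an identically constant signal.
#' @export
dominant_frequency <- function(x, rate) {
  check_signal(x, 8)
  sp <- one_sided_spectrum(x, rate)
  mag <- sp$mod
  mag[1] <- 0                                 # exclude DC
  if (max(mag) == 0) return(NA_real_)
  k <- which.max(mag)                         # 1-based bin index
  if (k > 2 && k < length(mag)) {
    a <- mag[k - 1]; b <- mag[k]; cc <- mag[k + 1]
    den <- a - 2 * b + cc
    d <- if (den == 0) 0 else 0.5 * (a - cc) / den
    d <- max(-0.5, min(0.5, d))
  } else {
    d <- 0
  }
  (k - 1 + d) * rate / sp$n
}

#' Amplitude at the dominant frequency
#'
#' Sinusoid-equivalent amplitude `2 |X_k| / N` at the peak bin of the
#' mean-removed spectrum.
#'
#' @inheritParams band_energy
#' @return Amplitude units; `NA` for a constant signal.
#' @export
dominant_amplitude <- function(x, rate) {
  check_signal(x, 8)
  sp <- one_sided_spectrum(x, rate)
  mag <- sp$mod
  mag[1] <- 0
  if (max(mag) == 0) return(NA_real_)
  2 * max(mag) / sp$n
}

#' Spectral entropy
#'
#' Shannon entropy (bits) of the normalized one-sided energy spectrum
#' (DC excluded): low for a pure oscillation, high for broadband signals.
#'
#' @inheritParams band_energy
#' @return Entropy in bits; 0 for a constant (empty-spectrum) signal.
#' @export
spectral_entropy <- function(x, rate) {
  check_signal(x, 8)
  sp <- one_sided_spectrum(x, rate)
  e <- sp$energy[-1]
  tot <- sum(e)
  if (tot == 0) return(0)
  p <- e[e > 0] / tot
  -sum(p * log2(p))
}

#' Spectral centroid
#'
#' Energy-weighted mean frequency of the one-sided spectrum (DC
#' excluded).
#'
#' @inheritParams band_energy
#' @return Hz; `NA` for a constant signal.
#' @export
spectral_centroid <- function(x, rate) {
  check_signal(x, 8)
  sp <- one_sided_spectrum(x, rate)
  e <- sp$energy[-1]
  f <- sp$f[-1]
  tot <- sum(e)
  if (tot == 0) return(NA_real_)
  sum(f * e) / tot
}

## per-step signal energy: integral of squared amplitude over the step
step_energy <- function(x, rate) {
  check_signal(x, 1)
  sum(x^2) / rate
}

#' Apply a per-step operator and average over steps
#'
#' One value is computed per detected step (on that step's sample slice)
#' and the arithmetic mean over all steps of the subject is returned.
#'
#' @param op Function with signature `op(x, rate)` applied to each step's
#'   sample slice.
#' @param x Full task signal for one channel.
#' @param steps A `step_list` from [segment_steps()].
#' @param rate Sampling rate, Hz.
#' @return Mean per-step value, or `NA` when the step list is empty.
#' @export
step_feature <- function(op, x, steps, rate) {
  if (is.null(steps) || nrow(steps) == 0) return(NA_real_)
  vals <- vapply(seq_len(nrow(steps)), function(i) {
    op(slice_interval(x, steps$start[i], steps$end[i]), rate)
  }, numeric(1))
  mean(vals)
}
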