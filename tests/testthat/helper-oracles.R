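## Independent brute-force oracles for the scalar descriptors. These are
## deliberately naive (explicit loops, direct DFT sums) and share no code
## with the package implementations they check.

oracle_minmax <- function(x) {
  mx <- x[1]; mn <- x[1]
  for (v in x) { if (v > mx) mx <- v; if (v < mn) mn <- v }
  mx - mn
}

oracle_variance <- function(x) {
  m <- sum(x) / length(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  s / length(x)
}

oracle_rms <- function(x) {
  s <- 0
  for (v in x) s <- s + v * v
  sqrt(s / length(x))
}

oracle_entropy <- function(x, n_bins = 16) {
  lo <- min(x); hi <- max(x)
  if (lo == hi) return(0)
  counts <- rep(0, n_bins)
  width <- (hi - lo) / n_bins
  for (v in x) {
    b <- floor((v - lo) / width) + 1
    if (b > n_bins) b <- n_bins
    counts[b] <- counts[b] + 1
  }
  h <- 0
  for (c in counts) {
    if (c > 0) { p <- c / length(x); h <- h - p * log2(p) }
  }
  h
}

## exhaustive strict-extrema scan (run-compressed) + closed-form least squares
oracle_extrema_slope <- function(x, rate) {
  keep <- c(TRUE, diff(x) != 0)
  idx0 <- which(keep)
  v <- x[keep]
  ext_t <- c(); ext_v <- c()
  if (length(v) >= 3) {
    for (i in 2:(length(v) - 1)) {
      if ((v[i] > v[i - 1] && v[i] > v[i + 1]) ||
          (v[i] < v[i - 1] && v[i] < v[i + 1])) {
        ext_t <- c(ext_t, (idx0[i] - 1) / rate)
        ext_v <- c(ext_v, v[i])
      }
    }
  }
  if (length(ext_v) < 2) return(NA_real_)
  mt <- mean(ext_t); mv <- mean(ext_v)
  sum((ext_t - mt) * (ext_v - mv)) / sum((ext_t - mt)^2)
}

## direct O(N^2) DFT
oracle_dft <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  vapply(k, function(kk) {
    sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n))
  }, complex(1))
}

oracle_band_energy <- function(x, rate, f_lo, f_hi) {
  x <- x - mean(x)
  n <- length(x)
  X <- oracle_dft(x)
  total <- 0
  for (k in 0:(n %/% 2)) {
    f <- k * rate / n
    if (f >= f_lo && f <= f_hi) {
      w <- if (k == 0 || (n %% 2 == 0 && k == n / 2)) 1 else 2
      total <- total + w * Mod(X[k + 1])^2 / n
    }
  }
  total
}

## zero-padded direct periodogram integral: the Wiener-Khinchin estimator
## with biased autocorrelation must coincide with this
oracle_periodogram_band <- function(x, rate, f_lo, f_hi) {
  x <- x - mean(x)
  n <- length(x)
  m <- 2 * n - 1
  X <- stats::fft(c(x, rep(0, n - 1)))
  total <- 0
  for (k in 0:((m - 1) / 2)) {
    f <- k * rate / m
    if (f >= f_lo && f <= f_hi) {
      w <- if (k == 0) 1 else 2
      total <- total + w * Mod(X[k + 1])^2 / (n * rate) * rate / m
    }
  }
  total
}

oracle_dominant_frequency <- function(x, rate) {
  x <- x - mean(x)
  n <- length(x)
  mag <- Mod(oracle_dft(x))[1:(n %/% 2 + 1)]
  mag[1] <- 0
  k <- which.max(mag)
  d <- 0
  if (k > 2 && k < length(mag)) {
    den <- mag[k - 1] - 2 * mag[k] + mag[k + 1]
    if (den != 0) d <- max(-0.5, min(0.5, 0.5 * (mag[k - 1] - mag[k + 1]) / den))
  }
  (k - 1 + d) * rate / n
}

## hand-summed information gain over an explicit bin x class table
oracle_ig_from_table <- function(tab) {
  n <- sum(tab)
  py <- colSums(tab) / n
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  hcond <- 0
  for (b in seq_len(nrow(tab))) {
    nb <- sum(tab[b, ])
    if (nb == 0) next
    p <- tab[b, ] / nb
    hcond <- hcond + nb / n * (-sum(p[p > 0] * log2(p[p > 0])))
  }
  hy - hcond
}

## minimal independent discrete AdaBoost with exhaustive stump search,
## for cross-checking the package booster on small datasets
oracle_adaboost_predict <- function(X, yy, iterations, Xnew = X) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  score <- rep(0, nrow(Xnew))
  for (t in seq_len(iterations)) {
    ## first candidate in (feature, polarity, threshold) order wins ties;
    ## errors rounded to absorb floating-point noise in the tie comparison
    best <- NULL
    for (j in seq_len(ncol(X))) {
      for (pol in c(1, -1)) {
        for (thr in c(-Inf, sort(unique(X[, j])))) {
          h <- pol * ifelse(X[, j] > thr, 1, -1)
          err <- round(sum(w[h != yy]), 10)
          if (is.null(best) || err < best$err) {
            best <- list(err = err, j = j, thr = thr, pol = pol)
          }
        }
      }
    }
    if (best$err >= 0.5) break
    err <- max(best$err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    h <- best$pol * ifelse(X[, best$j] > best$thr, 1, -1)
    w <- w * exp(-alpha * yy * h)
    w <- w / sum(w)
    score <- score + alpha * best$pol * ifelse(Xnew[, best$j] > best$thr, 1, -1)
    if (err <= 1e-10) break
  }
  ifelse(score >= 0, 1, -1)
}

## random test signal with mixed periodic + noise content
random_signal <- function(n, rate = 50) {
  tt <- (0:(n - 1)) / rate
  stats::runif(1, 0.5, 3) * sin(2 * pi * stats::runif(1, 0.5, 8) * tt +
                                stats::runif(1, 0, 2 * pi)) +
    stats::rnorm(n, sd = stats::runif(1, 0.1, 2)) +
    stats::runif(1, -5, 5)
}

## a small complete session with the given constant fill value
constant_session <- function(value = 0, id = "const", rate = 50) {
  recs <- list()
  for (task in imu_tasks()) {
    for (foot in imu_feet()) {
      n <- if (task == "walk_10m") 2000 else 1000
      m <- matrix(value, nrow = n, ncol = 6,
                  dimnames = list(NULL, imu_channels()))
      passes <- if (task == "walk_10m") {
        matrix(c(0L, 900L, 1000L, 1900L), ncol = 2, byrow = TRUE)
      } else NULL
      recs[[paste(task, foot, sep = "_")]] <-
        imu_recording(m, foot, task, rate, passes = passes)
    }
  }
  subject_session(id, group = "control", recordings = recs)
}

## 50-column noise matrix with one planted feature of disjoint class support
planted_noise_data <- function(seed = 404, n = 100, p_noise = 49) {
  set.seed(seed)
  y <- rep(c("pd", "control"), each = n / 2)
  X <- matrix(stats::rnorm(n * (p_noise + 1)), n, p_noise + 1)
  X[, 17] <- ifelse(y == "pd", stats::runif(n, 2, 3), stats::runif(n, -3, -2))
  colnames(X) <- paste0("f", seq_len(p_noise + 1))
  list(X = X, y = y)
}
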