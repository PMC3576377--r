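rel_diff <- function(a, b) {
  if (is.na(a) && is.na(b)) return(0)
  abs(a - b) / max(1e-12, abs(a), abs(b))
}

test_that("every scalar operator matches its brute-force oracle on 100 random signals", {
  set.seed(2024)
  rate <- 50
  for (i in 1:100) {
    n <- sample(64:400, 1)
    x <- random_signal(n, rate)
    expect_lt(rel_diff(minmax_difference(x), oracle_minmax(x)), 1e-9)
    expect_lt(rel_diff(pop_variance(x), oracle_variance(x)), 1e-9)
    expect_lt(rel_diff(root_mean_square(x), oracle_rms(x)), 1e-9)
    expect_lt(rel_diff(signal_entropy(x), oracle_entropy(x)), 1e-9)
    expect_lt(rel_diff(regression_line_of_extrema(x, rate),
                       oracle_extrema_slope(x, rate)), 1e-9)
    if (i <= 30) {   # O(N^2) oracles on a subset
      expect_lt(rel_diff(band_energy(x, rate, 0.5, 3),
                         oracle_band_energy(x, rate, 0.5, 3)), 1e-9)
      expect_lt(rel_diff(dominant_frequency(x, rate),
                         oracle_dominant_frequency(x, rate)), 1e-9)
    }
    expect_lt(rel_diff(band_psd(x, rate, 0.5, 3),
                       oracle_periodogram_band(x, rate, 0.5, 3)), 1e-9)
  }
})

test_that("closed forms hold for sinusoids and simple vectors", {
  rate <- 200
  tt <- (0:(10 * rate - 1)) / rate   # 10 s, whole periods of 2 Hz
  A <- 3.7
  x <- A * sin(2 * pi * 2 * tt)
  expect_lt(abs(root_mean_square(x) - A / sqrt(2)), 1e-6)
  expect_lt(abs(pop_variance(x) - A^2 / 2), 1e-6)
  expect_lt(abs(minmax_difference(x) - 2 * A), 1e-3)
  expect_lt(abs(dominant_frequency(x, rate) - 2.0), 0.02)
  ## constant-envelope cosine: extrema alternate +/- A symmetrically (odd
  ## count, first and last both minima), so the regression slope vanishes
  expect_lt(abs(regression_line_of_extrema(A * cos(2 * pi * 2 * tt), rate)),
            1e-9)
  ## oscillation on a rising trend: extrema track the drift
  drift <- tt + 0.5 * sin(2 * pi * 2 * tt)
  expect_gt(regression_line_of_extrema(drift, rate), 0.5)
  expect_lt(abs(regression_line_of_extrema(drift, rate) - 1), 0.2)
  ## simple vectors
  expect_equal(minmax_difference(c(1, 5, -2)), 7)
  expect_equal(root_mean_square(c(3, 4)), sqrt(12.5))
  expect_equal(pop_variance(c(-1, 1)), 1)
  expect_equal(root_mean_square(rep(-2.5, 10)), 2.5)
  expect_equal(minmax_difference(rep(4, 5)), 0)
})

test_that("amplitude-histogram entropy behaves as a distributional measure", {
  expect_equal(signal_entropy(rep(3.2, 100)), 0)
  ## 16 equally spaced samples: exactly one per bin -> log2(16) = 4 bits
  x <- (0:15) / 15
  expect_equal(signal_entropy(x), 4, tolerance = 1e-12)
  ## monotone signal has no interior extrema -> missing slope
  expect_true(is.na(regression_line_of_extrema(1:50, 50)))
})

test_that("band energy concentrates on the tone and partitions by Parseval", {
  rate <- 50
  tt <- (0:(15 * rate - 1)) / rate   # exact periods of 2 Hz
  x <- 4 * sin(2 * pi * 2 * tt)
  total <- band_energy(x, rate, 0, rate / 2)
  expect_gte(band_energy(x, rate, 0.5, 3) / total, 0.999)
  expect_lte(band_energy(x, rate, 5, 8) / total, 0.001)
  expect_equal(band_energy(rep(0, 100), rate), 0)
  ## Parseval: band energies over a partition of [0, Nyquist] sum to the
  ## time-domain energy of the mean-removed signal
  set.seed(99)
  for (i in 1:20) {
    y <- random_signal(sample(80:300, 1), rate)
    edges <- c(0, sort(runif(3, 1, 24)), 25)
    parts <- vapply(seq_len(4), function(j) {
      band_energy(y, rate, edges[j], edges[j + 1])
    }, numeric(1))
    ## interior edges could double-count a bin only if they hit f_k exactly;
    ## random edges avoid that almost surely
    expect_lt(rel_diff(sum(parts), sum((y - mean(y))^2)), 1e-9)
  }
})

test_that("windowed band energy averages full windows", {
  rate <- 50
  tt <- (0:(15 * rate - 1)) / rate
  x <- 2 * sin(2 * pi * 2 * tt)
  ## stationary signal: windowed average equals any single full window
  w1 <- band_energy(x[1:(5 * rate)], rate, 0.5, 3)
  expect_lt(rel_diff(windowed_band_energy(x, rate), w1), 1e-6)
  ## window count: 15 s at 5 s windows / 2.5 s hop -> 5 windows
  counter <- local({
    starts <- seq(0, length(x) - 5 * rate, by = 2.5 * rate)
    length(starts)
  })
  expect_equal(counter, 5)
  expect_true(is.na(windowed_band_energy(rnorm(4 * rate), rate)))
})

test_that("Wiener-Khinchin PSD integral matches the padded periodogram and concentrates", {
  rate <- 50
  set.seed(5)
  x <- rnorm(300)
  expect_lt(rel_diff(band_psd(x, rate, 0.5, 3),
                     oracle_periodogram_band(x, rate, 0.5, 3)), 1e-9)
  expect_equal(band_psd(rep(0, 100), rate), 0)
  ## an in-band tone concentrates its PSD integral in the band; on the
  ## 2N-1 padded grid a finite tone is never bin-aligned, so rectangular-
  ## window leakage caps the concentration just below the bin-aligned case
  tt <- (0:(15 * rate - 1)) / rate
  tone <- 3 * sin(2 * pi * 2 * tt)
  ratio <- band_psd(tone, rate, 0.5, 3) / band_psd(tone, rate, 0, rate / 2)
  expect_gte(ratio, 0.99)
})

test_that("windowed-energy regression tracks amplitude trends", {
  rate <- 50
  tt <- (0:(15 * rate - 1)) / rate
  x <- 2 * sin(2 * pi * 2 * tt)
  base <- band_energy(x[1:(2.5 * rate)], rate, 0.5, 3)
  expect_lt(abs(regression_of_windowed_energy(x, rate)), 1e-6 * base)
  grow <- (1 + tt) * sin(2 * pi * 2 * tt)
  expect_gt(regression_of_windowed_energy(grow, rate), 0)
  expect_true(is.na(regression_of_windowed_energy(rnorm(3 * rate), rate)))
})

test_that("dominant frequency resolves competing tones and interpolates off-bin", {
  rate <- 50
  tt <- (0:(15 * rate - 1)) / rate
  two <- sin(2 * pi * 1 * tt) + 2 * sin(2 * pi * 3 * tt)
  expect_lt(abs(dominant_frequency(two, rate) - 3.0), 0.05)
  ## off-bin tone: parabolic interpolation beats the bin width
  off <- sin(2 * pi * 2.03 * tt)
  expect_lt(abs(dominant_frequency(off, rate) - 2.03), 0.02)
})

test_that("operators scale as their units dictate", {
  set.seed(13)
  rate <- 50
  x <- random_signal(256, rate)
  for (a in c(0.5, 2, 7)) {
    expect_equal(minmax_difference(a * x), a * minmax_difference(x))
    expect_equal(root_mean_square(a * x), a * root_mean_square(x),
                 tolerance = 1e-12)
    expect_equal(pop_variance(a * x), a^2 * pop_variance(x),
                 tolerance = 1e-12)
    expect_equal(band_energy(a * x, rate, 0.5, 3),
                 a^2 * band_energy(x, rate, 0.5, 3), tolerance = 1e-9)
    ## range-relative binning and spectral shape are scale-free
    expect_equal(signal_entropy(a * x), signal_entropy(x), tolerance = 1e-12)
    expect_equal(dominant_frequency(a * x, rate), dominant_frequency(x, rate),
                 tolerance = 1e-12)
  }
})

test_that("per-step averaging reduces to the plain operator on trivial step lists", {
  rate <- 50
  x <- random_signal(200, rate)
  one <- structure(data.frame(start = 0L, end = 200L, pass_index = 1L),
                   rate = rate, class = c("step_list", "data.frame"))
  op <- function(s, r) root_mean_square(s)
  expect_equal(step_feature(op, x, one, rate), root_mean_square(x))
  ## two identical steps average to the single-step value
  xx <- c(x[1:100], x[1:100])
  two <- structure(data.frame(start = c(0L, 100L), end = c(100L, 200L),
                              pass_index = c(1L, 1L)),
                   rate = rate, class = c("step_list", "data.frame"))
  expect_equal(step_feature(op, xx, two, rate), root_mean_square(x[1:100]))
  ## known piecewise signal: mean of hand-computed per-step values
  pw <- c(rep(2, 100), rep(-4, 100))
  expect_equal(step_feature(function(s, r) mean(s), pw, two, rate),
               mean(c(2, -4)))
  empty <- structure(data.frame(start = integer(0), end = integer(0),
                                pass_index = integer(0)),
                     rate = rate, class = c("step_list", "data.frame"))
  expect_true(is.na(step_feature(op, x, empty, rate)))
})
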