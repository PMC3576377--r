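test_that("raw millivolt conversion applies sensitivities and clips to range", {
  expect_equal(as.numeric(raw_to_physical(300, "acc_x")), 1.0)
  expect_equal(as.numeric(raw_to_physical(0, "gyr_z")), 0.0)
  expect_equal(as.numeric(raw_to_physical(0, "acc_y")), 0.0)
  ## 2000 mV at 2 mV/(deg/s) would be 1000 deg/s; clipped at 500
  v <- raw_to_physical(2000, "gyr_y")
  expect_equal(as.numeric(v), 500)
  expect_equal(attr(v, "n_clipped"), 1L)
  expect_equal(as.numeric(raw_to_physical(-3000, "acc_z")), -6)
  ## linearity below the clip bound
  set.seed(1)
  x <- runif(50, -500, 500)
  for (a in c(0.25, 0.5, 1)) {
    expect_equal(as.numeric(raw_to_physical(a * x, "gyr_x")),
                 a * as.numeric(raw_to_physical(x, "gyr_x")))
  }
})

test_that("session round-trips through the CSV dialect within 1e-9", {
  set.seed(7)
  s <- simulate_subject(sim_config(delta = 1), "pd", 123, "subj01")
  dir <- withr::local_tempdir()
  write_session(s, file.path(dir, "subj01"))
  s2 <- read_session(file.path(dir, "subj01"))
  expect_equal(s2$subject_id, "subj01")
  for (key in names(s$recordings)) {
    r1 <- s$recordings[[key]]
    r2 <- s2$recordings[[key]]
    expect_equal(r2$rate, r1$rate)
    expect_identical(r2$passes, r1$passes)
    expect_lt(max(abs(r2$samples - r1$samples)), 1e-9)
  }
})

test_that("cohort round-trip preserves manifest metadata and empty cohorts", {
  co <- simulate_cohort(sim_config(n_pd = 1, n_control = 1, delta = 0, seed = 3))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  co2 <- read_cohort(dir)
  expect_setequal(names(co2$sessions), names(co$sessions))
  s1 <- co$sessions[[1]]; s2 <- co2$sessions[[s1$subject_id]]
  expect_equal(s2$group, s1$group)
  expect_equal(s2$clinical$updrs_iii, s1$clinical$updrs_iii)
  expect_equal(s2$clinical$hy_stage, s1$clinical$hy_stage)
  ## empty cohort: manifest only, no error
  dir2 <- withr::local_tempdir()
  expect_silent(write_cohort(imu_cohort(list()), dir2))
  expect_true(file.exists(file.path(dir2, "cohort.csv")))
})

test_that("format errors name the offending part", {
  dir <- withr::local_tempdir()
  s <- constant_session(1)
  write_session(s, file.path(dir, "const"))
  f <- file.path(dir, "const", "circling_left.csv")
  ## drop a channel column
  df <- read.csv(f, comment.char = "#")
  writeLines(c("# rate_hz=50",
               paste(setdiff(names(df), "gyr_y"), collapse = ",")), f)
  write.table(df[setdiff(names(df), "gyr_y")], f, sep = ",", append = TRUE,
              row.names = FALSE, col.names = FALSE)
  expect_error(read_session(file.path(dir, "const")), "gyr_y")
  ## missing task file -> incomplete-session error listing it
  file.remove(f)
  expect_error(read_session(file.path(dir, "const")), "circling_left")
  ## incomplete session refuses to be written
  s$recordings$circling_left <- NULL
  expect_error(write_session(s, file.path(dir, "x")),
               "incomplete session.*circling_left")
})

test_that("timed-task analysis window is 15 s after the lead-in", {
  mk <- function(sec) {
    imu_recording(matrix(rnorm(sec * 50 * 6), ncol = 6,
                         dimnames = list(NULL, imu_channels())),
                  "left", "heel_toe_tapping", 50)
  }
  w <- task_analysis_window(mk(20))
  expect_equal(c(w$start, w$end), c(125L, 875L))
  expect_false(w$truncated)
  ## exactly lead-in + window long
  w <- task_analysis_window(mk(17.5))
  expect_equal(c(w$start, w$end), c(125L, 875L))
  ## shorter recordings shift the window earlier, then truncate flagged
  w <- task_analysis_window(mk(16))
  expect_equal(c(w$start, w$end), c(50L, 800L))
  w <- task_analysis_window(mk(10))
  expect_equal(c(w$start, w$end), c(0L, 500L))
  expect_true(w$truncated)
  expect_error(task_analysis_window(mk(4)), "insufficient")
  expect_error(task_analysis_window(
    imu_recording(matrix(0, 1000, 6, dimnames = list(NULL, imu_channels())),
                  "left", "walk_10m", 50)), "tapping")
})

test_that("recording invariants are enforced", {
  m <- matrix(0, 100, 6, dimnames = list(NULL, imu_channels()))
  expect_error(imu_recording(m[, 1:5], "left", "walk_10m"), "gyr_z")
  m2 <- m; m2[5, 3] <- NA
  expect_error(imu_recording(m2, "left", "walk_10m"), "finite")
  expect_error(imu_recording(m, "left", "walk_10m",
                             passes = rbind(c(0, 60), c(50, 90))), "disjoint")
  expect_error(imu_recording(m, "left", "walk_10m",
                             passes = rbind(c(0, 120))), "within")
  ok <- imu_recording(m, "left", "walk_10m", passes = rbind(c(0, 50), c(60, 100)))
  expect_s3_class(ok, "imu_recording")
  expect_error(imu_cohort(list(constant_session(0, "a"),
                               constant_session(1, "a"))), "duplicate")
})
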