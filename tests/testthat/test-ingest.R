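# Epoching of raw accelerometer and RR streams, and the epoch-table dialect.

test_that("a resting watch yields zero G-values in every epoch", {
  ep <- epoch_activity(resting_trace(120))
  expect_equal(nrow(ep), 4)
  expect_equal(ep$g_value, rep(0, 4))
})

test_that("a single 1.5 g sample lands in its window as 500 milli-g", {
  t <- seq(0, 60, by = 0.5)
  az <- rep(1, length(t))
  az[t == 40] <- 1.5
  tr <- raw_accel_trace(t, rep(0, length(t)), rep(0, length(t)), az)
  ep <- epoch_activity(tr)
  expect_equal(ep$g_value, c(0, 500))
})

test_that("trailing partial windows are dropped", {
  ep <- epoch_activity(resting_trace(65))
  expect_equal(nrow(ep), 2)
  # and in general the epoch count is floor(duration / 30)
  for (secs in c(30, 59, 90, 124)) {
    expect_equal(nrow(epoch_activity(resting_trace(secs))),
                 floor(secs / 30))
  }
})

test_that("epoch activity is invariant to sample order within a window and linear in dynamic acceleration", {
  set.seed(41)
  t <- sort(runif(300, 0, 90))
  az <- 1 + runif(300, 0, 0.8)
  tr <- raw_accel_trace(t, rep(0, 300), rep(0, 300), az)
  ep <- epoch_activity(tr)
  # shuffle samples within each 30-s window (timestamps keep their slots)
  az_shuf <- az
  for (w in unique(floor(t / 30))) {
    sel <- which(floor(t / 30) == w)
    az_shuf[sel] <- az[sample(sel)]
  }
  expect_equal(epoch_activity(raw_accel_trace(t, rep(0, 300), rep(0, 300), az_shuf))$g_value,
               ep$g_value, tolerance = 1e-12)
  # scaling every dynamic component by k scales every G-value by k
  k <- 2.5
  tr_k <- raw_accel_trace(t, rep(0, 300), rep(0, 300), 1 + k * (az - 1))
  expect_equal(epoch_activity(tr_k)$g_value, k * ep$g_value, tolerance = 1e-9)
})

test_that("degenerate raw traces are rejected with the right error class", {
  expect_error(raw_accel_trace(numeric(0), numeric(0), numeric(0), numeric(0)),
               class = "somnograph_invalid_input")
  expect_error(raw_accel_trace(c(0, 2, 1), c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)),
               class = "somnograph_malformed_input")
})

test_that("heart rate per epoch is 60000 over the mean RR of the window's beats", {
  rr <- rr_series(seq(1, 59, by = 1), rep(1000, 59))
  expect_equal(epoch_heart_rate(rr, 2), c(60, 60), ignore_attr = TRUE)
  rr2 <- rr_series(c(5, 20), c(800, 1200))
  expect_equal(epoch_heart_rate(rr2, 1), 60, ignore_attr = TRUE)
})

test_that("empty epochs are filled from the nearest scored epoch, earlier on ties", {
  # beats only in epochs 0 and 4 (0-based); epoch 2 is equidistant
  rr <- rr_series(c(10, 20, 130, 140), c(1000, 1000, 500, 500))
  hr <- epoch_heart_rate(rr, 5)
  expect_equal(as.numeric(hr), c(60, 60, 60, 120, 120))
  expect_equal(attr(hr, "filled"), c(1L, 2L, 3L))
  # output never escapes the range of observed per-epoch rates
  expect_true(all(hr >= 60 & hr <= 120))
})

test_that("RR cleaning drops non-physiological intervals and empty series error out", {
  rr <- rr_series(c(1, 2, 3), c(1000, 5000, 100))
  expect_equal(rr$rr_ms, 1000)
  expect_error(rr_series(c(1, 2), c(5000, 100)), class = "somnograph_invalid_input")
  expect_error(epoch_heart_rate(rr_series(1, 1000), 0), class = "somnograph_invalid_input")
})

test_that("epoch tables round-trip losslessly, with stages", {
  ep <- epoch_series(c(0, 12.25, 1 / 3, 4500), c(55.5, NA, 70.1, 88),
                     epoch_seconds = 30)
  hyp <- hypnogram(c("WAKE", "LIGHT", "DEEP", "REM"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_epoch_table(ep, path, hyp)
  back <- read_epoch_table(path)
  expect_identical(back$epochs$g_value, ep$g_value)
  expect_identical(back$epochs$heart_rate_bpm, ep$heart_rate_bpm)
  expect_identical(as.character(back$hypnogram), as.character(hyp))
})

test_that("external stage dialects map onto the four-label set", {
  expect_equal(map_stage_labels(c("0", "N2", "N3", "R", "W", "2")),
               c("WAKE", "LIGHT", "DEEP", "REM", "WAKE", "LIGHT"))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("epoch_index,g_value,heart_rate_bpm,stage",
               "0,10,60,N2", "1,20,61,5"), path)
  out <- read_epoch_table(path)
  expect_equal(as.character(out$hypnogram), c("LIGHT", "REM"))
  expect_error(map_stage_labels("MOVEMENT"), class = "somnograph_malformed_input")
})

test_that("broken epoch tables report the defect and its line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("epoch_index,g_value,heart_rate_bpm",
               "0,10,60", "2,20,61"), path)
  expect_error(read_epoch_table(path), "gap-free",
               class = "somnograph_malformed_input")
  writeLines(c("epoch_index,g_value,heart_rate_bpm",
               "0,10,60", "0,20,61"), path)
  expect_error(read_epoch_table(path), class = "somnograph_malformed_input")
  writeLines(c("epoch_index,g_value,heart_rate_bpm",
               "0,10,60", "1,twenty,61"), path)
  expect_error(read_epoch_table(path), "line 3",
               class = "somnograph_malformed_input")
  writeLines(c("epoch_index,g_value", "0,10"), path)
  expect_error(read_epoch_table(path), "heart_rate_bpm",
               class = "somnograph_malformed_input")
})
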