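test_that("time_series validates and reports duration", {
  ts <- time_series(1:5, 10, t0_s = 2)
  expect_equal(ts_duration(ts), 0.4)
  expect_equal(ts_times(ts), 2 + (0:4) / 10)
  expect_error(time_series(numeric(0), 10), "at least one")
  expect_error(time_series(1:3, 0), "positive")
})

test_that("trial_table enforces event ordering and rt consistency", {
  expect_error(trial_table(1, "Go", t_cue_s = 2, t_pt_start_s = 1,
                           t_pt_end_s = 3), "t_cue_s < t_pt_start_s")
  expect_error(trial_table(1, "Go", 1, 2, 4, outcome = "Hit"),
               "rt_s must be present")
  expect_error(trial_table(1, "Go", 1, 2, 4, outcome = "Miss", rt_s = 0.7),
               "rt_s must be present")
  tr <- trial_table(1:2, c("Go", "NoGo"), c(1, 10), c(2, 11), c(4, 13),
                    outcome = c("Hit", "CR"), rt_s = c(0.9, NA))
  expect_s3_class(tr, "trial_table")
})

test_that("marker CSV parses circles, rejects empty/misordered input, and round-trips", {
  # 3 frames with markers on a circle of radius 10
  pts <- ellipse_points(10, 10, n = 8)
  markers <- array(rep(t(pts), each = 0), c(3, 8, 2))
  for (i in 1:3) markers[i, , ] <- pts
  fr <- pupil_frames((0:2) / 20, markers, cbind(rep(50, 3), rep(60, 3)))
  f <- tempfile(fileext = ".csv")
  write_marker_csv(fr, f)
  back <- read_marker_csv(f)
  expect_equal(length(back$t_s), 3)
  expect_identical(as.numeric(back$markers), as.numeric(markers))
  expect_identical(as.numeric(back$ref_marker), as.numeric(fr$ref_marker))

  # missing column is named
  df <- utils::read.csv(f, check.names = FALSE)
  df$top_x <- NULL
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(df, f2, row.names = FALSE)
  expect_error(read_marker_csv(f2), "top_x")

  # empty data section
  writeLines(readLines(f)[1], f2)
  expect_error(read_marker_csv(f2), "no frames")

  # non-monotone frame index
  df <- utils::read.csv(f, check.names = FALSE)
  df$frame <- c(0, 2, 1)
  utils::write.csv(df, f2, row.names = FALSE)
  expect_error(read_marker_csv(f2), "increasing")
})

test_that("session bundles round-trip bit-exactly, including a full synthetic session", {
  # minimal one-trial bundle
  tr1 <- trial_table(1, "Go", 1, 2, 4, lick_times_s = list(c(2.7, 2.91)),
                     outcome = "Hit", rt_s = 0.7)
  b1 <- session_bundle(trials = tr1, params = list(note = "mini", v = 1.5))
  d <- file.path(tempdir(), "mini_bundle")
  write_session(b1, d)
  r1 <- read_session(d)
  expect_identical(r1$trials$rt_s, tr1$rt_s)
  expect_identical(r1$trials$lick_times_s, tr1$lick_times_s)
  expect_equal(r1$params$note, "mini")

  # 150-trial synthetic session with traces and sweeps
  task <- task_params()
  tr <- simulate_trial_schedule(task, learning_curve_params(), 5, seed = 42)
  ph <- simulate_photometry(tr, signal_model_params(), 1.5, seed = 43)
  sw <- simulate_psp_sweeps("PPR", synapse_model_params(), seed = 44)
  b <- session_bundle(trials = tr,
                      traces = list(act = ph$session$act,
                                    iso = ph$session$iso),
                      sweeps = list(ppr = sw$sweeps),
                      params = list(seed = 42))
  d2 <- file.path(tempdir(), "full_bundle")
  write_session(b, d2)
  r <- read_session(d2)
  expect_identical(r$trials$t_pt_start_s, tr$t_pt_start_s)
  expect_identical(r$trials$outcome, tr$outcome)
  expect_identical(unlist(r$trials$lick_times_s), unlist(tr$lick_times_s))
  expect_identical(r$traces$act$values, ph$session$act$values)
  expect_identical(r$traces$iso$values, ph$session$iso$values)
  expect_identical(as.numeric(r$sweeps$ppr$sweeps),
                   as.numeric(sw$sweeps$sweeps))
  expect_identical(r$sweeps$ppr$stim_times_s, sw$sweeps$stim_times_s)
  expect_equal(r$sweeps$ppr$protocol, "PPR")

  # unknown schema version is an explicit error
  mf <- jsonlite::read_json(file.path(d2, "manifest.json"))
  mf$schema_version <- "someone-elses-format-9"
  jsonlite::write_json(mf, file.path(d2, "manifest.json"), auto_unbox = TRUE)
  expect_error(read_session(d2), "schema version")
})

test_that("sweep_set enforces protocol pulse counts and bounds", {
  m <- matrix(0, 2, 2000)
  expect_error(sweep_set(m, c(0.01, 0.02), "SP"), "requires 1")
  expect_error(sweep_set(m, 5, "SP", rate_hz = 20000), "outside sweep")
  s <- sweep_set(m, 0.05, "SP", rate_hz = 20000)
  expect_equal(s$protocol, "SP")
})
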