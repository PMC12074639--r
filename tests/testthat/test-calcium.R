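test_that("auroc handles ties, extremes, and worked examples", {
  x <- rnorm(50)
  expect_identical(auroc(x, x), 0.5)
  expect_equal(auroc(1:5, 6:10), 1.0)
  expect_equal(auroc(6:10, 1:5), 0.0)
  expect_equal(auroc(c(1, 2, 3), c(2, 3, 4)), 7 / 9)
  expect_error(auroc(numeric(0), 1:3), "empty")
})

test_that("auroc equals the brute-force pairwise count on random instances", {
  set.seed(404)
  for (i in 1:1000) {
    n <- sample(1:30, 1); m <- sample(1:30, 1)
    b <- sample(round(rnorm(n, 0, 2), 1))   # rounding induces ties
    w <- sample(round(rnorm(m, 0.5, 2), 1))
    expect_equal(auroc(b, w), brute_auroc(b, w), tolerance = 1e-12)
    expect_equal(auroc(b, w) + auroc(w, b), 1, tolerance = 1e-12)
  }
})

test_that("auroc agrees with the Wilcoxon rank-sum statistic", {
  set.seed(407)
  for (i in 1:50) {
    b <- rnorm(sample(5:40, 1)); w <- rnorm(sample(5:40, 1), 0.7)
    W <- suppressWarnings(stats::wilcox.test(w, b)$statistic)
    expect_equal(auroc(b, w), unname(W) / (length(b) * length(w)),
                 tolerance = 1e-12)
  }
})

test_that("auroc is invariant under strictly monotone transforms", {
  set.seed(405)
  b <- rnorm(40); w <- rnorm(40, 1)
  a0 <- auroc(b, w)
  expect_identical(auroc(exp(b), exp(w)), a0)
  expect_identical(auroc(atan(b), atan(w)), a0)
})

test_that("sliding auROC is null on white noise and localizes real transients", {
  # white noise: observed max within the permutation null band
  set.seed(406)
  n_tr <- 30
  mat <- matrix(rnorm(n_tr * 81), n_tr)
  tr <- tiny_trials(n_tr, period = 10)
  x <- time_series(rnorm(50 * (max(tr$t_pt_end_s) + 5)), 50)
  w <- align_streams(tr, list(x = x), pre_s = 0.8, post_s = 0.8)
  au <- sliding_auroc(w, "x", baseline_s = c(-0.8, -0.4), win_s = 0.3)
  perm_max <- replicate(99, {
    w2 <- w
    w2$traces$x$mat[] <- sample(w$traces$x$mat)
    sliding_auroc(w2, "x", baseline_s = c(-0.8, -0.4), win_s = 0.3)$max_auroc
  })
  expect_lte(au$max_auroc, quantile(perm_max, 0.99) + 0.02)

  # transients at PT start: curve max within 0.25 s of the anchor
  task <- task_params(n_trials = 60)
  trs <- simulate_trial_schedule(task, learning_curve_params(), 6, seed = 61)
  sim <- simulate_photometry(trs, signal_model_params(), amp = 2, seed = 62)
  corr <- photometry_correct(sim$session)
  wins <- align_streams(trs, list(calcium = corr), pre_s = 2, post_s = 2)
  au2 <- sliding_auroc(wins, "calcium", baseline_s = c(-2, -1))
  expect_lt(abs(au2$t_max_s), 0.25)
  expect_gt(au2$max_auroc, 0.7)

  # rank invariance of the whole curve
  w3 <- wins
  w3$traces$calcium$mat <- exp(w3$traces$calcium$mat / 3)
  au3 <- sliding_auroc(w3, "calcium", baseline_s = c(-2, -1))
  expect_identical(au3$auroc, au2$auroc)
})

test_that("trial_max_amplitude is shift-equivariant and zero on flat traces", {
  tr <- tiny_trials(5, period = 10)
  z <- time_series(numeric(50 * 50), 50)
  w <- align_streams(tr, list(x = z), pre_s = 1, post_s = 1)
  tm <- trial_max_amplitude(w, "x", c(-1, 1))
  expect_true(all(tm$trial_max == 0))
  w$traces$x$mat <- w$traces$x$mat + 3.5
  tm2 <- trial_max_amplitude(w, "x", c(-1, 1))
  expect_equal(tm2$trial_max, tm$trial_max + 3.5)
})

test_that("event_filter applies the percentile and prominence rules", {
  # 9 unit peaks and one 10-high peak on a zero baseline: only the tall one
  # clears the 90th-percentile height cut
  v <- numeric(210)
  pos <- seq(10, 190, by = 20)
  v[pos] <- c(rep(1, 9), 10)
  ev <- event_filter(time_series(v, 10), percentile = 90, min_prominence = 2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$height, 10)
  expect_equal(ev$t_s, (pos[10] - 1) / 10)

  # prominence gate: all peaks below prominence 2 -> nothing retained
  v2 <- numeric(210); v2[pos] <- 1.5
  expect_equal(nrow(event_filter(time_series(v2, 10), 90, 2)), 0)

  # no peaks at all -> empty, not an error
  expect_equal(nrow(event_filter(time_series(seq(0, 1, 0.01), 10))), 0)
})

test_that("event capture grows with stage amplitude", {
  task <- task_params(n_trials = 40)
  curve <- learning_curve_params()
  sig <- signal_model_params()
  means <- vapply(c(Shaping = 0.5, LateLearning = 1.5, Expert = 2.0),
                  function(amp) {
    tr <- simulate_trial_schedule(task, curve, 6, seed = 71)
    sim <- simulate_photometry(tr, sig, amp = amp, seed = 72)
    corr <- photometry_correct(sim$session)
    cap <- window_capture(event_filter(corr), tr, task)
    cap$mean_target
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("rt_aligned_average splits pre and post means around the grand RT", {
  tr <- trial_table(1:4, rep("Go", 4), 5 + (0:3) * 12, 6 + (0:3) * 12,
                    8 + (0:3) * 12)
  rate <- 50
  x <- time_series(numeric(12 * 5 * rate), rate)
  w <- align_streams(tr, list(x = x), pre_s = 3, post_s = 3)
  rts <- c(0.8, 1.0, 1.2, 1.0)   # grand mean 1.0
  # step function: height 2 before the grand RT, 0 after
  rel <- w$traces$x$offsets_s - 1.0
  w$traces$x$mat[] <- rep(ifelse(rel < 0, 2, 0), each = 4)
  r <- rt_aligned_average(w, rts, "x", pre_s = 1, post_s = 1)
  expect_equal(r$grand_rt_s, 1.0)
  expect_equal(r$pre_mean, 2)
  expect_equal(r$post_mean, 0)

  # symmetric pulse centered at the grand RT: equal means
  w$traces$x$mat[] <- rep(exp(-rel^2 / 0.02), each = 4)
  r2 <- rt_aligned_average(w, rts, "x", pre_s = 1, post_s = 1)
  expect_equal(r2$pre_mean, r2$post_mean, tolerance = 0.02)

  expect_true(is.na(rt_aligned_average(w, numeric(0), "x")$pre_mean))
})

test_that("xcorr_lag recovers pure shifts and the generator pupil lag", {
  rate <- 20
  t <- seq(0, 60, by = 1 / rate)
  x <- time_series(sin(2 * pi * 0.11 * t) + 0.5 * sin(2 * pi * 0.31 * t), rate)
  y <- time_series(c(rep(0, 5), x$values[1:(length(t) - 5)]), rate)
  xc <- xcorr_lag(x, y, 2)
  expect_equal(xc$lag_s, 0.25)
  expect_gt(xc$peak_r, 0.97)
  xc0 <- xcorr_lag(x, x, 2)
  expect_equal(xc0$lag_s, 0)
  expect_equal(xc0$peak_r, 1)

  # generator lag of 0.25 s recovered within one frame period
  task <- task_params(n_trials = 40)
  tr <- simulate_trial_schedule(task, learning_curve_params(), 6, seed = 81)
  sig <- signal_model_params()
  ph <- simulate_photometry(tr, sig, amp = 2, seed = 82)
  pp <- simulate_pupil(tr, ph$truth$transient_component, sig, seed = 83)
  ar <- area_series(pp$frames)
  xc2 <- xcorr_lag(pp$truth$lowpassed_drive, ar$area, 1)
  expect_lte(abs(xc2$lag_s - pp$truth$lag_s), 1 / sig$pupil_fps + 1e-9)

  expect_error(xcorr_lag(x, time_series(1:10, rate, t0_s = 500), 1),
               "overlap")
})
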