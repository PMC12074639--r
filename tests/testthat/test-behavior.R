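test_that("score_outcomes applies the grace rule and reaction-time definition", {
  task <- task_params()
  tr <- trial_table(1:4, c("Go", "NoGo", "Go", "NoGo"),
                    t_cue_s = c(1, 11, 21, 31),
                    t_pt_start_s = c(2, 12, 22, 32),
                    t_pt_end_s = c(4, 14, 24, 34))
  licks <- c(2.9,          # Go trial 1: post-grace -> Hit, rt = 0.9
             12.1, 12.3,   # NoGo trial 2: inside grace only -> CR
                           # Go trial 3: no licks -> Miss
             32.5)         # NoGo trial 4: exactly at grace end -> FA
  sc <- score_outcomes(tr, licks, task)
  expect_equal(sc$outcome, c("Hit", "CR", "Miss", "FA"))
  expect_equal(sc$rt_s, c(0.9, NA, NA, 0.5))
  # responded trials truncate at the triggering lick
  expect_equal(sc$t_pt_end_s[1], 2.9)
  expect_equal(sc$t_pt_end_s[2], 14)
  # exactly one outcome per trial, partition by texture
  expect_equal(sum(sc$outcome %in% c("Hit", "Miss")), sum(sc$texture == "Go"))
  expect_equal(sum(sc$outcome %in% c("FA", "CR")), sum(sc$texture == "NoGo"))
})

test_that("score_outcomes rejects overlapping trial windows", {
  tr <- trial_table(1:2, c("Go", "Go"), c(1, 2.5), c(2, 3.5), c(4, 5.5))
  expect_error(score_outcomes(tr, numeric(0)), "overlapping")
})

test_that("sdt_metrics matches the standard-normal quantile oracle", {
  m <- sdt_metrics(list(hit = 80, miss = 20, fa = 30, cr = 70))
  expect_equal(m$hit_rate, 0.80)
  expect_equal(m$fa_rate, 0.30)
  expect_equal(m$d_prime, 1.3660, tolerance = 1e-4)
  expect_equal(m$bias, 0.1586, tolerance = 1e-4)

  # HR = FA = 0.5 is fully symmetric
  m0 <- sdt_metrics(list(hit = 50, miss = 50, fa = 50, cr = 50))
  expect_equal(m0$d_prime, 0)
  expect_equal(m0$bias, 0)

  # quantile oracle on random count tables, including extreme rates
  set.seed(101)
  for (i in 1:1000) {
    ngo <- sample(1:200, 1); nng <- sample(1:200, 1)
    h <- sample(0:ngo, 1); f <- sample(0:nng, 1)
    m <- sdt_metrics(list(hit = h, miss = ngo - h, fa = f, cr = nng - f))
    clamp <- function(r, n) min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))
    zh <- qnorm(clamp(h / ngo, ngo)); zf <- qnorm(clamp(f / nng, nng))
    expect_equal(m$d_prime, zh - zf, tolerance = 1e-12)
    expect_equal(m$bias, 0.5 * (zh + zf), tolerance = 1e-12)
  }

  expect_error(sdt_metrics(list(hit = 0, miss = 0, fa = 3, cr = 7)),
               "undefined")
})

test_that("d-prime is antisymmetric and monotone", {
  dp <- function(h, f) sdt_metrics(list(hit = round(100 * h),
                                        miss = round(100 * (1 - h)),
                                        fa = round(100 * f),
                                        cr = round(100 * (1 - f))))$d_prime
  for (h in c(0.2, 0.55, 0.9)) for (f in c(0.1, 0.4, 0.8)) {
    expect_equal(dp(h, f), -dp(f, h), tolerance = 1e-12)
  }
  grid <- seq(0.05, 0.95, by = 0.05)
  d_in_h <- vapply(grid, dp, numeric(1), f = 0.3)
  expect_true(all(diff(d_in_h) > 0))
  d_in_f <- vapply(grid, dp, numeric(1), h = 0.7)
  expect_true(all(diff(d_in_f) < 0))
})

test_that("classify_expert matches a brute-force scan and respects boundaries", {
  # worked examples
  expect_equal(classify_expert(c(0.9, 0.85), c(0.2, 0.25))$expert_index, 2L)
  expect_equal(classify_expert(c(0.9, 0.85, 0.9), c(0.4, 0.25, 0.2))$expert_index, 3L)
  expect_true(is.na(classify_expert(rep(0.79, 5), rep(0.1, 5))$expert_index))

  # strict boundary behavior: >= 0.80 and <= 0.30
  expect_equal(classify_expert(c(0.80, 0.80), c(0.30, 0.30))$expert_index, 2L)
  expect_true(is.na(classify_expert(c(0.79, 0.80), c(0.30, 0.30))$expert_index))
  expect_true(is.na(classify_expert(c(0.80, 0.80), c(0.31, 0.30))$expert_index))

  set.seed(202)
  for (i in 1:1000) {
    n <- sample(2:12, 1)
    hr <- sample(c(0.75, 0.79, 0.80, 0.81, 0.9), n, replace = TRUE)
    fa <- sample(c(0.25, 0.30, 0.31, 0.35, 0.1), n, replace = TRUE)
    expect_identical(classify_expert(hr, fa)$expert_index,
                     brute_expert_scan(hr, fa))
  }
})

test_that("classify_expert labels learning phases", {
  cls <- classify_expert(c(0.5, 0.45, 0.6, 0.72, 0.85, 0.9, 0.9),
                         c(0.5, 0.50, 0.45, 0.38, 0.28, 0.2, 0.2),
                         is_shaping = c(TRUE, rep(FALSE, 6)),
                         is_reward = c(rep(FALSE, 6), TRUE))
  expect_equal(cls$expert_index, 6L)
  expect_equal(cls$phase,
               c("Shaping", "EarlyLearning", "EarlyLearning", "LateLearning",
                 "LateLearning", "Expert", "Reward"))
})

test_that("reaction_times averages responded trials only", {
  tr <- trial_table(1:4, c("Go", "Go", "NoGo", "NoGo"),
                    c(1, 11, 21, 31), c(2, 12, 22, 32), c(4, 14, 24, 34),
                    outcome = c("Hit", "Miss", "FA", "CR"),
                    rt_s = c(0.8, NA, 1.0, NA))
  rt <- reaction_times(tr)
  expect_equal(rt$mean_rt_s, 0.9)
  expect_equal(sort(rt$rt_s), c(0.8, 1.0))
  tr2 <- trial_table(1, "Go", 1, 2, 4, outcome = "Miss")
  expect_true(is.na(reaction_times(tr2)$mean_rt_s))
})

test_that("lick_density integrates to one and is flat for uniform licks", {
  # single lick -> one occupied bin with unit area
  tr <- trial_table(1, "Go", 1, 2, 4, lick_times_s = list(2.95))
  d <- lick_density(tr, bin_s = 0.1)
  expect_equal(sum(d$density) * 0.1, 1, tolerance = 1e-9)
  expect_equal(sum(d$density > 0), 1)

  # uniform licks over 2 s -> density 0.5/s
  tr2 <- trial_table(1, "Go", 1, 2, 4,
                     lick_times_s = list(2 + seq(0.005, 1.995, by = 0.01)))
  d2 <- lick_density(tr2, bin_s = 0.1, range_s = c(0, 2))
  expect_equal(sum(d2$density) * 0.1, 1, tolerance = 1e-9)
  expect_true(all(abs(d2$density[d2$t_s > 0 & d2$t_s < 2] - 0.5) < 1e-9))

  # unit area holds on simulated sessions too
  trs <- simulate_trial_schedule(task_params(n_trials = 50),
                                 learning_curve_params(), 4, seed = 9)
  d3 <- lick_density(trs, bin_s = 0.25)
  expect_equal(sum(d3$density) * 0.25, 1, tolerance = 1e-9)
})
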