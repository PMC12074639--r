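test_that("baseline subtraction zeroes each sweep independently", {
  rate <- 20000
  n <- 30000
  m <- rbind(rep(-80, n), rep(-78, n))
  m[1, 15000:15200] <- m[1, 15000:15200] + 5   # kernel after the baseline
  sw <- sweep_set(m, 0.7, "SP", rate_hz = rate)
  out <- baseline_subtract(sw)
  expect_equal(out$sweeps[2, ], numeric(n))
  expect_equal(max(out$sweeps[1, ]), 5)
  expect_equal(out$sweeps[1, 1], 0)
  expect_equal(attr(out, "baseline_mv"), c(-80, -78))

  # constant 5 mV sweep (too short for the full baseline) -> all zero
  one <- sweep_set(matrix(5, 1, 8000), 0.3, "SP", rate_hz = rate)
  expect_warning(z <- baseline_subtract(one), "shorter")
  expect_true(all(z$sweeps == 0))
})

test_that("qc_baseline applies the holding-range and evoked-spike rules", {
  rate <- 20000
  m <- rbind(rep(-80.5, 15000), rep(-75, 15000))
  sw <- sweep_set(m, 0.6, "SP", rate_hz = rate)
  qc <- qc_baseline(sw)
  expect_identical(qc$include, c(TRUE, FALSE))
  expect_false(qc$cell_excluded)

  # a spike in an SP sweep excludes the cell
  m2 <- m
  m2[1, 13000:13010] <- 10
  qc2 <- qc_baseline(sweep_set(m2, 0.6, "SP", rate_hz = rate))
  expect_true(qc2$cell_excluded)

  # adding an excluded sweep never changes the average
  syn <- synapse_model_params()
  sim <- simulate_psp_sweeps("PPR", syn, seed = 91)
  bs <- baseline_subtract(sim$sweeps)
  avg1 <- average_sweeps(bs)
  drifted <- sim$sweeps
  drifted$sweeps <- rbind(drifted$sweeps, drifted$sweeps[1, ] + 10)
  qc3 <- qc_baseline(drifted)
  expect_false(qc3$include[nrow(drifted$sweeps)])
  avg2 <- average_sweeps(baseline_subtract(drifted), include = qc3$include)
  expect_equal(avg2$values, avg1$values)
})

test_that("average_sweeps is permutation-invariant and reduces noise as 1/sqrt(n)", {
  set.seed(92)
  m <- matrix(rnorm(20 * 10000), 20)
  sw <- sweep_set(m, numeric(0), "STEPS", rate_hz = 20000)
  a1 <- average_sweeps(sw)
  sw2 <- sw; sw2$sweeps <- m[sample(20), ]
  expect_equal(average_sweeps(sw2)$values, a1$values)
  expect_equal(sd(a1$values), 1 / sqrt(20), tolerance = 0.05)
  expect_error(average_sweeps(sw, include = rep(FALSE, 20)), "no included")
})

test_that("sp_metrics reads amplitude and latency off the averaged trace", {
  avg <- superpose_kernels(7, 0.5, rise = 0.002, decay = 0.02)
  m <- sp_metrics(avg, 0.5)
  expect_equal(m$amplitude_mv, 7, tolerance = 1e-4)
  # double-exponential peak time for rise 2 ms, decay 20 ms
  lat_true <- log(0.02 / 0.002) * 0.002 * 0.02 / (0.02 - 0.002) * 1000
  expect_equal(m$latency_ms, lat_true, tolerance = 0.05)
  expect_false(m$edge_warning)

  expect_warning(m0 <- sp_metrics(time_series(numeric(20000), 20000), 0.5),
                 "flat")
  expect_equal(m0$amplitude_mv, 0)
  expect_true(is.na(m0$latency_ms))

  # shift and scale equivariance
  shifted <- time_series(avg$values + 2, avg$rate_hz)
  expect_equal(sp_metrics(shifted, 0.5)$amplitude_mv, 9, tolerance = 1e-4)
  scaled <- time_series(avg$values * 3, avg$rate_hz)
  expect_equal(sp_metrics(scaled, 0.5)$amplitude_mv, 21, tolerance = 1e-4)
})

test_that("single-pulse amplitude recovers under generator noise", {
  syn <- synapse_model_params(a1_mv = 10, noise_sd_mv = 0.2)
  sim <- simulate_psp_sweeps("SP", syn, seed = 93)
  qc <- qc_baseline(sim$sweeps)
  avg <- average_sweeps(baseline_subtract(sim$sweeps), include = qc$include)
  m <- sp_metrics(avg, sim$sweeps$stim_times_s)
  expect_lt(abs(m$amplitude_mv - 10), 0.15)
})

test_that("pulse_amplitudes is exact on noise-free superpositions", {
  truth <- c(10, 7, 5, 4, 3.5)
  pt <- 0.5 + (0:4) * 0.05
  avg <- superpose_kernels(truth, pt, rise = 0.002, decay = 0.02)
  pa <- pulse_amplitudes(avg, pt)
  expect_true(all(abs(pa$amplitudes_mv - truth) / truth < 0.01))
  expect_equal(ppr(pa), 0.7, tolerance = 0.01)

  # no-overlap limit: amplitudes equal raw local maxima
  pt2 <- c(0.5, 1.0)
  avg2 <- superpose_kernels(c(6, 6), pt2, 0.002, 0.02)
  pa2 <- pulse_amplitudes(avg2, pt2)
  expect_equal(pa2$amplitudes_mv, c(6, 6), tolerance = 0.005)
  expect_equal(ppr(pa2), 1.0, tolerance = 0.002)
})

test_that("ratio summaries follow their definitions", {
  pa <- structure(list(amplitudes_mv = c(10, 7), pulse_times_s = c(0, 0.05)),
                  class = "pulse_amplitudes")
  expect_equal(ppr(pa), 0.7)
  pa30 <- structure(list(amplitudes_mv = c(10, rep(3, 29))),
                    class = "pulse_amplitudes")
  expect_equal(train_relative(pa30), 0.3)
  flat <- structure(list(amplitudes_mv = rep(4, 30)), class = "pulse_amplitudes")
  expect_equal(train_relative(flat), 1.0)
  bad <- structure(list(amplitudes_mv = c(0, 3)), class = "pulse_amplitudes")
  expect_error(ppr(bad), "noise floor")
})

test_that("full chain recovers depression ratios at generator noise", {
  # PPR protocol tuned to A2/A1 = 0.73
  syn_ppr <- synapse_model_params(
    depression_u = depression_u_for_ppr(0.73, 0.05, 1), noise_sd_mv = 0.2)
  sim <- simulate_psp_sweeps("PPR", syn_ppr, seed = 94)
  qc <- qc_baseline(sim$sweeps)
  avg <- average_sweeps(baseline_subtract(sim$sweeps), include = qc$include)
  pa <- pulse_amplitudes(avg, sim$sweeps$stim_times_s)
  expect_equal(ppr(pa), 0.73, tolerance = 0.02)

  # TRAIN protocol tuned so that mean(A5..A15)/A1 = 0.49
  ratio_for_u <- function(u) {
    a <- psp_true_amplitudes(30, 0.0642,
                             synapse_model_params(depression_u = u))
    mean(a[5:15]) / a[1]
  }
  u49 <- uniroot(function(u) ratio_for_u(u) - 0.49, c(0.02, 0.6))$root
  syn_tr <- synapse_model_params(depression_u = u49, noise_sd_mv = 0.2)
  simt <- simulate_psp_sweeps("TRAIN", syn_tr, seed = 95)
  truth_ratio <- mean(simt$truth$amplitudes_mv[5:15]) /
    simt$truth$amplitudes_mv[1]
  expect_equal(truth_ratio, 0.49, tolerance = 0.001)
  avgt <- average_sweeps(baseline_subtract(simt$sweeps))
  pat <- pulse_amplitudes(avgt, simt$sweeps$stim_times_s)
  expect_equal(train_relative(pat), truth_ratio, tolerance = 0.03)
})

test_that("intrinsic features recover the synthetic template", {
  # noise-free geometry: linear rise/fall make the widths analytic
  sim0 <- simulate_intrinsic_sweeps(list(noise_sd_mv = 0), seed = 96)
  f0 <- intrinsic_features(sim0$sweeps)
  h <- sim0$truth$peak_mv - sim0$truth$thr_mv
  hhw_true <- 0.5 * sim0$truth$rise_ms +
    (sim0$truth$peak_mv - (sim0$truth$thr_mv + 0.5 * h)) /
    (sim0$truth$peak_mv - sim0$truth$ahp_min_mv) * sim0$truth$fall_ms
  expect_equal(f0$ap_threshold_mv, sim0$truth$thr_mv, tolerance = 1e-9)
  expect_equal(f0$ap_peak_mv, h, tolerance = 1e-9)
  expect_equal(f0$hhw_ms, hhw_true, tolerance = 0.06)
  expect_equal(f0$rise_ms, 0.8 * sim0$truth$rise_ms, tolerance = 0.06)
  expect_equal(f0$ahp_mv, sim0$truth$thr_mv - sim0$truth$ahp_min_mv,
               tolerance = 1e-9)

  # default noise: threshold within 1 mV; spike count and max rate exact
  sim <- simulate_intrinsic_sweeps(seed = 97)
  f <- intrinsic_features(sim$sweeps)
  i350 <- which(sim$truth$currents_pa == 350)
  expect_equal(f$n_spikes, length(sim$truth$spike_times_s[[i350]]))
  expect_lt(abs(f$ap_threshold_mv - sim$truth$thr_mv), 1)

  # 10 evenly spaced spikes over the 500 ms step -> 20 Hz
  sim10 <- simulate_intrinsic_sweeps(list(hz_per_pa = 0.07, noise_sd_mv = 0),
                                     seed = 98)
  f10 <- intrinsic_features(sim10$sweeps)
  expect_equal(f10$n_spikes, 10L)
  expect_equal(f10$max_freq_hz, 20, tolerance = 0.01)

  # 0 pA step: flat trace at rest, no spikes
  v0 <- sim$sweeps$sweeps[which(sim$truth$currents_pa == 0), ]
  expect_equal(mean(v0), -80, tolerance = 0.05)
  f_zero <- intrinsic_features(sim$sweeps, at_pa = 0)
  expect_equal(f_zero$n_spikes, 0L)
  expect_true(is.na(f_zero$ap_threshold_mv))
})
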