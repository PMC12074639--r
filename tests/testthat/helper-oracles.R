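# independent oracles and small fixture builders used across test files

# brute-force pairwise auROC: P(w > b) + 0.5 P(w == b)
brute_auroc <- function(baseline, window) {
  cmp <- outer(window, baseline, FUN = function(w, b)
    (w > b) + 0.5 * (w == b))
  mean(cmp)
}

# points sampled exactly on an ellipse (no noise)
ellipse_points <- function(a, b, angle = 0, center = c(0, 0), n = 8) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(cbind(a * cos(phi), b * sin(phi)) %*% t(R), 2, center, "+")
}

# minimal hand-built trial table
tiny_trials <- function(n = 3, texture = rep("Go", n), period = 10) {
  t_cue <- (seq_len(n) - 1) * period + 1
  trial_table(seq_len(n), texture, t_cue, t_cue + 1, t_cue + 3)
}

# noise-free superposition of unit-peak double-exponential kernels
superpose_kernels <- function(amps, pulse_times, rise, decay,
                              dur = 1.5, rate = 20000) {
  t <- seq(0, dur, by = 1 / rate)
  s_pk <- log(decay / rise) * rise * decay / (decay - rise)
  norm <- exp(-s_pk / decay) - exp(-s_pk / rise)
  v <- numeric(length(t))
  for (k in seq_along(amps)) {
    s <- t - pulse_times[k]
    p <- s >= 0
    v[p] <- v[p] + amps[k] * (exp(-s[p] / decay) - exp(-s[p] / rise)) / norm
  }
  time_series(v, rate)
}

# brute-force scan for the expert criterion: second session of the first
# consecutive qualifying pair
brute_expert_scan <- function(hr, fa, hr_min = 0.80, fa_max = 0.30) {
  for (i in 2:length(hr)) {
    if (hr[i - 1] >= hr_min && fa[i - 1] <= fa_max &&
        hr[i] >= hr_min && fa[i] <= fa_max) return(i)
  }
  NA_integer_
}
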