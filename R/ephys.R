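#' Zero the baseline of every sweep
#'
#' Subtracts from each sweep the mean of its first \code{n_baseline}
#' samples (10,000 samples = 0.5 s at 20 kHz), setting the pre-stimulus
#' baseline to zero sweep by sweep.
#'
#' @param sweeps a \code{\link{sweep_set}}.
#' @param n_baseline samples to average; sweeps shorter than this fall back
#'   to the full pre-first-stimulus extent with a warning.
#' @return baseline-subtracted \code{sweep_set}.
#' @export
baseline_subtract <- function(sweeps, n_baseline = 10000L) {
  m <- sweeps$sweeps
  if (ncol(m) < n_baseline) {
    n_baseline <- if (length(sweeps$stim_times_s))
      max(1L, floor(min(sweeps$stim_times_s) * sweeps$rate_hz)) else ncol(m)
    warning("baseline_subtract: sweeps shorter than requested baseline; using ",
            n_baseline, " samples")
  }
  base <- rowMeans(m[, seq_len(n_baseline), drop = FALSE])
  out <- sweeps
  out$sweeps <- m - base
  attr(out, "baseline_mv") <- base
  out
}

#' Baseline quality control
#'
#' Flags sweeps whose raw baseline drifts outside the holding range
#' (-80 +/- 2 mV by default) for exclusion, and flags the whole cell when
#' any SP sweep contains an action potential (membrane potential excursion
#' above the spike criterion): such cells are excluded from PSP analysis.
#'
#' @param sweeps a raw (pre-subtraction) \code{sweep_set}.
#' @param target_mv,tol_mv holding potential and tolerance (mV).
#' @param n_baseline baseline samples per sweep.
#' @param spike_mv excursions above this flag an evoked spike.
#' @return list: \code{include} (logical per sweep), \code{baseline_mv},
#'   \code{cell_excluded} (TRUE if an SP sweep spiked).
#' @export
qc_baseline <- function(sweeps, target_mv = -80, tol_mv = 2,
                        n_baseline = 10000L, spike_mv = -20) {
  m <- sweeps$sweeps
  nb <- min(n_baseline, ncol(m))
  base <- rowMeans(m[, seq_len(nb), drop = FALSE])
  include <- base >= target_mv - tol_mv & base <= target_mv + tol_mv
  spiked <- sweeps$protocol == "SP" && any(apply(m, 1L, max) > spike_mv)
  list(include = include, baseline_mv = base, cell_excluded = spiked)
}

#' Average sweeps
#'
#' Pointwise mean over the included sweeps of a (baseline-subtracted)
#' sweep set.
#'
#' @param sweeps a \code{sweep_set}.
#' @param include logical per-sweep inclusion flags (default all).
#' @return a \code{time_series} at the sweep rate.
#' @export
average_sweeps <- function(sweeps, include = NULL) {
  m <- sweeps$sweeps
  if (!is.null(include)) m <- m[include, , drop = FALSE]
  if (nrow(m) == 0L) stop("average_sweeps: no included sweeps")
  time_series(colMeans(m), sweeps$rate_hz, 0)
}

#' Single-pulse PSP amplitude and latency
#'
#' Amplitude is the maximum of the averaged, zero-baselined trace in the
#' post-stimulus search window, relative to the zero baseline; latency is
#' the time from photostimulation onset to that maximum.
#'
#' @param avg averaged \code{time_series} (baseline-subtracted, mV).
#' @param stim_t stimulus onset (s).
#' @param search_s search window length after the stimulus (s).
#' @return list: \code{amplitude_mv}, \code{latency_ms} (NA with a warning
#'   for a flat trace), \code{edge_warning} (TRUE when the maximum sits on
#'   the search-window boundary).
#' @export
sp_metrics <- function(avg, stim_t, search_s = 0.06) {
  i0 <- round((stim_t - avg$t0_s) * avg$rate_hz) + 1L
  i1 <- min(length(avg$values), i0 + round(search_s * avg$rate_hz))
  if (i0 < 1L || i0 >= length(avg$values)) stop("sp_metrics: stimulus outside trace")
  seg <- avg$values[i0:i1]
  amp <- max(seg)
  if (all(seg == seg[1])) {
    warning("sp_metrics: flat trace in search window; latency undefined")
    return(list(amplitude_mv = amp, latency_ms = NA_real_, edge_warning = TRUE))
  }
  k <- which.max(seg)
  edge <- k == 1L || k == length(seg)
  if (edge) warning("sp_metrics: maximum at search-window edge")
  list(amplitude_mv = amp, latency_ms = (k - 1L) / avg$rate_hz * 1000,
       edge_warning = edge)
}

# fit v ~ A * exp(-(t - t0)/tau) on a decay segment; returns list(A, tau,
# t0), or NULL when no usable fit can be obtained
.fit_decay <- function(t, v) {
  if (length(v) < 4L) return(NULL)
  t0 <- t[1]
  A <- NA_real_; tau <- NA_real_
  if (all(v > 0)) {
    co <- stats::coef(stats::lm(log(v) ~ I(t - t0)))
    if (co[2] < 0) { A <- exp(co[[1]]); tau <- -1 / co[[2]] }
  }
  if (!is.finite(tau)) { A <- max(v); tau <- diff(range(t)) / 2 }
  # refine by nonlinear least squares on the original scale
  fit <- tryCatch(stats::nls(v ~ A * exp(-(t - t0) / tau),
                             start = list(A = A, tau = tau)),
                  error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    if (cf[["tau"]] > 0 && cf[["A"]] > 0)
      return(list(A = cf[["A"]], tau = cf[["tau"]], t0 = t0))
  }
  if (is.finite(tau) && tau > 0 && is.finite(A) && A > 0)
    return(list(A = A, tau = tau, t0 = t0))
  NULL
}

#' Per-pulse PSP amplitudes by iterative decay subtraction
#'
#' Processes the pulses of a PPR or train average in order: for pulse k the
#' single-exponential decays fitted to all preceding PSPs are extrapolated
#' and subtracted, and the amplitude is the residual maximum in the pulse's
#' response window relative to the residual level just before the pulse.
#' The decay of each PSP is fitted from 80% of its peak on the falling
#' phase to the next pulse onset.
#'
#' @param avg averaged baseline-subtracted \code{time_series} (mV).
#' @param pulse_times stimulus onsets (s), >= 2 pulses.
#' @param search_s response window after each pulse, capped at the next
#'   pulse onset (s).
#' @param min_latency_s amplitude search starts this long after the pulse.
#' @param smooth_ms centered boxcar applied to the trace before
#'   measurement (ms); suppresses the positive bias of reading maxima off a
#'   noisy average while attenuating a 2/20 ms kernel peak by < 0.5%. Set 0
#'   to disable.
#' @return list of class \code{pulse_amplitudes}: \code{amplitudes_mv},
#'   \code{pulse_times_s}, \code{decay_fits} (A, tau or NA per pulse), and
#'   \code{fallback} flags for pulses whose decay fit failed (pre-pulse
#'   value subtraction was used downstream of them).
#' @export
pulse_amplitudes <- function(avg, pulse_times, search_s = 0.06,
                             min_latency_s = 0.001, smooth_ms = 2) {
  k_n <- length(pulse_times)
  if (k_n < 2L) stop("pulse_amplitudes: need at least 2 pulses")
  rate <- avg$rate_hz
  t <- ts_times(avg)
  w_half <- ceiling(round(smooth_ms / 1000 * rate) / 2)
  resid <- .boxcar(avg$values, smooth_ms / 1000 * rate)
  amps <- numeric(k_n)
  fallback <- logical(k_n)
  fits <- vector("list", k_n)
  for (k in seq_len(k_n)) {
    t_on <- pulse_times[k]
    t_next <- if (k < k_n) pulse_times[k + 1L] else t_on + search_s
    i_on <- round((t_on - avg$t0_s) * rate) + 1L
    i_lo <- i_on + max(1L, round(min_latency_s * rate))
    i_hi <- min(length(resid), round((min(t_next, t_on + search_s) - avg$t0_s) * rate) + 1L)
    if (i_lo >= i_hi) stop("pulse_amplitudes: empty response window for pulse ", k)
    # read the pre-pulse level clear of the measurement boxcar's reach
    pre_level <- resid[max(1L, i_on - w_half - 1L)]
    seg <- resid[i_lo:i_hi]
    i_pk <- i_lo + which.max(seg) - 1L
    amps[k] <- resid[i_pk] - pre_level
    # fit this PSP's decay on the falling phase for subtraction under
    # subsequent pulses
    if (k < k_n) {
      h80 <- pre_level + 0.8 * amps[k]
      j <- i_pk
      i_next <- round((t_next - avg$t0_s) * rate) + 1L
      while (j < i_next && resid[j] > h80) j <- j + 1L
      dec <- .fit_decay(t[j:(i_next - 1L)], resid[j:(i_next - 1L)])
      sub_idx <- j:length(resid)
      if (is.null(dec)) {
        fallback[k] <- TRUE
        # constant continuation at the last pre-next-pulse level
        resid[sub_idx] <- resid[sub_idx] - resid[i_next - 1L]
        fits[[k]] <- c(A = NA_real_, tau = NA_real_)
      } else {
        resid[sub_idx] <- resid[sub_idx] -
          dec$A * exp(-(t[sub_idx] - dec$t0) / dec$tau)
        fits[[k]] <- c(A = dec$A, tau = dec$tau)
      }
    }
  }
  structure(list(amplitudes_mv = amps, pulse_times_s = pulse_times,
                 decay_fits = fits, fallback = fallback),
            class = "pulse_amplitudes")
}

#' Paired-pulse ratio
#'
#' Amplitude of the second evoked PSP over the first; values below one
#' indicate short-term synaptic depression.
#'
#' @param pa a \code{\link{pulse_amplitudes}} result.
#' @param noise_floor_mv A1 at or below this is treated as undefined.
#' @return A2 / A1.
#' @export
ppr <- function(pa, noise_floor_mv = 0) {
  a <- pa$amplitudes_mv
  if (length(a) < 2L) stop("ppr: need at least 2 amplitudes")
  if (a[1] <= noise_floor_mv) stop("ppr: first-pulse amplitude at or below noise floor")
  a[2] / a[1]
}

#' Relative steady-state train amplitude
#'
#' Mean of pulses 5 through 15 (1-indexed, inclusive) over pulse 1, the
#' steady-state depression measure of the 30-pulse train protocol.
#'
#' @param pa a \code{pulse_amplitudes} result with 30 amplitudes.
#' @param noise_floor_mv A1 at or below this is treated as undefined.
#' @return mean(A5..A15) / A1.
#' @export
train_relative <- function(pa, noise_floor_mv = 0) {
  a <- pa$amplitudes_mv
  if (length(a) < 15L) stop("train_relative: need at least 15 amplitudes")
  if (a[1] <= noise_floor_mv)
    stop("train_relative: first-pulse amplitude at or below noise floor")
  mean(a[5:15]) / a[1]
}

# centered boxcar with edge padding; w in samples (rounded up to odd)
.boxcar <- function(x, w) {
  w <- round(w)
  if (w <= 1L) return(x)
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[(h + 1L):(h + length(x))]
}

# linear interpolation of the time where x crosses `level` between samples
# i and i+1
.cross_time <- function(t, x, i, level) {
  t[i] + (level - x[i]) / (x[i + 1L] - x[i]) * (t[i + 1L] - t[i])
}

#' Intrinsic action-potential features at a current step
#'
#' Detects spikes in the sweep at the requested current step and extracts,
#' per spike: threshold by a derivative criterion (first sample before the
#' peak where dV/dt reaches the criterion), peak height
#' (threshold to maximum), half-height width and 10-90% rise time (both by
#' linear interpolation between samples), and AHP depth (threshold value to
#' the post-spike minimum). Features are averaged over all spikes; maximum
#' firing frequency is the reciprocal of the smallest inter-spike interval.
#'
#' The derivative criterion defaults to 10 mV/ms; a literal 10 mV/s
#' criterion (which fires on recording noise) can be requested explicitly.
#'
#' @param steps a \code{sweep_set} with \code{protocol = "STEPS"} and
#'   per-sweep \code{step_currents_pa}.
#' @param at_pa current step to analyze (pA), default +350.
#' @param dvdt_mv_per_ms spike-threshold derivative criterion (mV/ms).
#' @param detect_mv spike detection level (mV): excursions above it are
#'   spikes.
#' @param ahp_window_s post-peak extent searched for the AHP minimum when
#'   no further spike follows (s).
#' @return list of class \code{intrinsic_features}: \code{n_spikes},
#'   \code{ap_threshold_mv}, \code{ap_peak_mv}, \code{hhw_ms},
#'   \code{rise_ms}, \code{ahp_mv}, \code{max_freq_hz}; all feature fields
#'   are NA with \code{n_spikes = 0} when the step evoked no spikes.
#' @export
intrinsic_features <- function(steps, at_pa = 350, dvdt_mv_per_ms = 10,
                               detect_mv = -20, ahp_window_s = 0.025) {
  stopifnot(inherits(steps, "sweep_set"), steps$protocol == "STEPS")
  i_sweep <- which(steps$step_currents_pa == at_pa)
  if (!length(i_sweep)) stop("intrinsic_features: no sweep at ", at_pa, " pA")
  v <- steps$sweeps[i_sweep[1], ]
  rate <- steps$rate_hz
  t <- (seq_along(v) - 1) / rate
  n <- length(v)
  above <- v > detect_mv
  starts <- which(above & !c(FALSE, above[-n]))
  if (!length(starts))
    return(structure(list(n_spikes = 0L, ap_threshold_mv = NA_real_,
                          ap_peak_mv = NA_real_, hhw_ms = NA_real_,
                          rise_ms = NA_real_, ahp_mv = NA_real_,
                          max_freq_hz = NA_real_),
                     class = "intrinsic_features"))
  # one peak per suprathreshold excursion
  peaks <- vapply(starts, function(s) {
    e <- s
    while (e < n && above[e + 1L]) e <- e + 1L
    s + which.max(v[s:e]) - 1L
  }, integer(1))
  dvdt <- c(NA, diff(v)) * rate / 1000  # mV/ms
  crit <- dvdt_mv_per_ms
  # walk back from each peak through the sustained suprathreshold rise: the
  # threshold sits at the last sample whose derivative is below criterion
  # (immune to isolated noise crossings earlier in the sweep)
  thr_idx <- vapply(seq_along(peaks), function(si) {
    p <- peaks[si]
    lo <- if (si > 1L) peaks[si - 1L] + 1L else 2L
    i <- p
    while (i > lo && dvdt[i] >= crit) i <- i - 1L
    i
  }, integer(1))
  per <- lapply(seq_along(peaks), function(si) {
    p <- peaks[si]; th <- thr_idx[si]
    v_thr <- v[th]; v_pk <- v[p]
    height <- v_pk - v_thr
    lev <- function(frac) v_thr + frac * height
    # rising-phase crossings (search th..p)
    up_t <- function(level) {
      i <- th + which(v[th:(p - 1L)] < level & v[(th + 1L):p] >= level)[1] - 1L
      if (is.na(i)) return(NA_real_)
      .cross_time(t, v, i, level)
    }
    # falling-phase crossing (search p..end of spike)
    e <- p
    nxt <- if (si < length(peaks)) thr_idx[si + 1L] else
      min(n, p + round(ahp_window_s * rate))
    dn_t <- function(level) {
      i <- p + which(v[p:(nxt - 1L)] >= level & v[(p + 1L):nxt] < level)[1] - 1L
      if (is.na(i)) return(NA_real_)
      .cross_time(t, v, i, level)
    }
    hhw <- (dn_t(lev(0.5)) - up_t(lev(0.5))) * 1000
    rise <- (up_t(lev(0.9)) - up_t(lev(0.1))) * 1000
    ahp <- v_thr - min(v[p:nxt])
    c(thr = v_thr, height = height, hhw = hhw, rise = rise, ahp = ahp)
  })
  feat <- colMeans(do.call(rbind, per), na.rm = TRUE)
  max_freq <- if (length(peaks) >= 2L) 1 / (min(diff(peaks)) / rate) else NA_real_
  structure(list(n_spikes = length(peaks),
                 ap_threshold_mv = feat[["thr"]],
                 ap_peak_mv = feat[["height"]],
                 hhw_ms = feat[["hhw"]], rise_ms = feat[["rise"]],
                 ahp_mv = feat[["ahp"]], max_freq_hz = max_freq),
            class = "intrinsic_features")
}
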