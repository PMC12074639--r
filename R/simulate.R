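#' Learning-trajectory parameters for the synthetic study
#'
#' Defines, per simulated session, the target hit and false-alarm rates, the
#' Go-texture probability, and the designed stage label; and, per stage, the
#' mean trial-locked calcium transient amplitude (raw trace units), the
#' reaction-time distribution, and the impulsive (pre-PT) lick rate. The
#' defaults trace a seven-session trajectory - one Shaping session, five
#' Learning sessions whose last two meet the expert criterion, and one
#' post-training Reward session - with transient amplitudes growing across
#' learning and collapsing back at Reward.
#'
#' @param stage designed stage label per session.
#' @param hit_rate,fa_rate per-session target outcome rates, in (0, 1).
#' @param go_prob per-session Go-texture probability.
#' @param transient_amp_by_stage named mean transient amplitudes per stage.
#' @param rt_mean_s,rt_sd_s named reaction-time mean/sd per stage (s).
#' @param impulsive_rate_hz named pre-PT lick rates per stage (Hz).
#' @return list of class \code{learning_curve_params}.
#' @export
learning_curve_params <- function(
    stage = c("Shaping", "EarlyLearning", "EarlyLearning", "LateLearning",
              "LateLearning", "Expert", "Reward"),
    hit_rate = c(0.55, 0.45, 0.60, 0.72, 0.85, 0.90, NA),
    fa_rate = c(0.55, 0.50, 0.45, 0.38, 0.28, 0.20, NA),
    go_prob = c(0.75, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    transient_amp_by_stage = c(Shaping = 0.5, EarlyLearning = 1.0,
                               LateLearning = 1.5, Expert = 2.0,
                               Reward = 0.5),
    rt_mean_s = c(Shaping = 0.95, EarlyLearning = 0.95, LateLearning = 0.87,
                  Expert = 0.80, Reward = NA),
    rt_sd_s = c(Shaping = 0.20, EarlyLearning = 0.18, LateLearning = 0.15,
                Expert = 0.12, Reward = NA),
    impulsive_rate_hz = c(Shaping = 0.40, EarlyLearning = 0.30,
                          LateLearning = 0.15, Expert = 0.05,
                          Reward = 0.30)) {
  n <- length(stage)
  if (length(hit_rate) != n || length(fa_rate) != n || length(go_prob) != n)
    stop("learning_curve_params: per-session arrays must share length")
  notrew <- stage != "Reward"
  if (any(!is.na(hit_rate[notrew]) &
          (hit_rate[notrew] < 0 | hit_rate[notrew] > 1)) ||
      any(!is.na(fa_rate[notrew]) & (fa_rate[notrew] < 0 | fa_rate[notrew] > 1)))
    stop("learning_curve_params: rates must lie in [0, 1]")
  if (any(transient_amp_by_stage < 0))
    stop("learning_curve_params: amplitudes must be >= 0")
  structure(list(stage = stage, hit_rate = hit_rate, fa_rate = fa_rate,
                 go_prob = go_prob,
                 transient_amp_by_stage = transient_amp_by_stage,
                 rt_mean_s = rt_mean_s, rt_sd_s = rt_sd_s,
                 impulsive_rate_hz = impulsive_rate_hz),
            class = "learning_curve_params")
}

#' Photometry and pupil signal-model parameters
#'
#' Generative model for the two-channel photometry trace (per-channel
#' exponential photobleaching, motion artifacts shared between channels,
#' trial-locked double-exponential calcium transients, white sensor noise)
#' and the pupil (a low-passed, delayed copy of the arousal drive with
#' marker jitter and inserted blinks).
#'
#' @param rate_hz photometry sampling rate (Hz).
#' @param noise_sd per-channel white-noise sd (raw units).
#' @param act_f0,iso_f0 initial fluorescence level per channel.
#' @param bleach_frac,bleach_tau_s activity-channel bleach fraction and
#'   time constant.
#' @param iso_bleach_frac,iso_bleach_tau_s isosbestic-channel bleach model.
#' @param artifact_rate_hz,artifact_amp,artifact_width_s shared motion
#'   artifact Poisson rate, amplitude scale, and Gaussian width.
#' @param transient_rise_s,transient_decay_s calcium kernel time constants.
#' @param pupil_lag_s delay of pupil dilation behind the arousal drive (s).
#' @param pupil_lowpass_tau_s first-order low-pass time constant (s).
#' @param blink_rate_hz,blink_dur_s blink event rate and duration.
#' @param pupil_fps pupil camera frame rate.
#' @param marker_jitter_px marker coordinate noise sd (px).
#' @param pupil_base_px2,pupil_gain_px2 latent area baseline and dynamic
#'   range (px^2); their sum stays below the 450 px^2 blink threshold.
#' @return list of class \code{signal_model_params}.
#' @export
signal_model_params <- function(rate_hz = 20, noise_sd = 0.5,
                                act_f0 = 10, bleach_frac = 0.3,
                                bleach_tau_s = 1200,
                                iso_f0 = 6, iso_bleach_frac = 0.2,
                                iso_bleach_tau_s = 1500,
                                artifact_rate_hz = 0.05, artifact_amp = 2.5,
                                artifact_width_s = 0.15,
                                transient_rise_s = 0.1,
                                transient_decay_s = 0.4,
                                pupil_lag_s = 0.25,
                                pupil_lowpass_tau_s = 0.5,
                                blink_rate_hz = 0.02, blink_dur_s = 0.15,
                                pupil_fps = 20, marker_jitter_px = 0.2,
                                pupil_base_px2 = 200, pupil_gain_px2 = 150) {
  if (bleach_frac < 0 || bleach_frac >= 1 || iso_bleach_frac < 0 ||
      iso_bleach_frac >= 1)
    stop("signal_model_params: bleach fractions must lie in [0, 1)")
  if (any(c(bleach_tau_s, iso_bleach_tau_s, transient_rise_s,
            transient_decay_s, pupil_lowpass_tau_s) <= 0))
    stop("signal_model_params: time constants must be positive")
  structure(as.list(environment()), class = "signal_model_params")
}

#' Synaptic response model parameters
#'
#' PSPs are double-exponential kernels scaled by per-pulse amplitudes from
#' a resource-depletion model of short-term depression: the first pulse
#' releases amplitude \code{a1_mv}; each pulse consumes a fraction
#' \code{depression_u} of the available resource, which recovers toward one
#' with time constant \code{recovery_tau_s}.
#'
#' @param rise_ms,decay_ms kernel time constants (ms).
#' @param a1_mv first-pulse PSP amplitude (mV).
#' @param depression_u per-pulse resource utilization, in (0, 1].
#' @param recovery_tau_s resource recovery time constant (s).
#' @param noise_sd_mv sweep noise sd (mV).
#' @param resting_mv holding potential (mV).
#' @return list of class \code{synapse_model_params}.
#' @export
synapse_model_params <- function(rise_ms = 2, decay_ms = 20, a1_mv = 7,
                                 depression_u = 0.28, recovery_tau_s = 1,
                                 noise_sd_mv = 0.2, resting_mv = -80) {
  if (depression_u <= 0 || depression_u > 1)
    stop("synapse_model_params: depression_u must be in (0, 1]")
  if (a1_mv <= 0) stop("synapse_model_params: a1_mv must be positive")
  structure(as.list(environment()), class = "synapse_model_params")
}

#' Utilization giving a target paired-pulse ratio
#'
#' Inverts the resource-depletion recurrence for two pulses: returns the
#' \code{depression_u} for which A2/A1 equals \code{target_ppr} at the
#' given inter-pulse interval.
#'
#' @param target_ppr desired A2/A1.
#' @param ipi_s inter-pulse interval (s).
#' @param recovery_tau_s recovery time constant (s).
#' @return utilization fraction in (0, 1].
#' @export
depression_u_for_ppr <- function(target_ppr, ipi_s = 0.05,
                                 recovery_tau_s = 1) {
  e <- exp(-ipi_s / recovery_tau_s)
  u <- 1 - (target_ppr - 1 + e) / e
  if (u <= 0 || u > 1) stop("depression_u_for_ppr: target unreachable")
  u
}

# truncated-normal draw by rejection with uniform fallback
.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- NA_real_
    for (try in 1:50) {
      x <- stats::rnorm(1, mean, sd)
      if (x > lo && x <= hi) break
      x <- NA_real_
    }
    out[i] <- if (is.na(x)) stats::runif(1, lo, hi) else x
  }
  out
}

#' Simulate one session's trial schedule and licks
#'
#' Textures are drawn at the session's Go probability under the
#' max-consecutive constraint; outcomes are drawn per texture from the
#' session's target hit/FA rates; responded trials receive a reaction time
#' from a truncated normal on (grace, PT window] and a consumption lick
#' train; impulsive licks are placed between cue and grace end at the
#' stage's impulsive rate, where they cannot trigger outcomes. In a Reward
#' session no lick triggers an outcome and licks cluster at PT end, where
#' water is delivered automatically.
#'
#' @param task a \code{\link{task_params}}.
#' @param curve a \code{\link{learning_curve_params}}.
#' @param session_idx which session of the curve to generate.
#' @param seed RNG seed; the same seed reproduces the table exactly.
#' @return a scored \code{trial_table} with attribute \code{stage}; Reward
#'   sessions carry outcome \code{"none"} throughout.
#' @export
simulate_trial_schedule <- function(task, curve, session_idx = 1, seed = 1) {
  stage <- curve$stage[session_idx]
  go_p <- curve$go_prob[session_idx]
  if (go_p <= 0 || go_p >= 1)
    stop("simulate_trial_schedule: go_prob must be in (0,1) under the run-length constraint")
  hr <- curve$hit_rate[session_idx]; fa <- curve$fa_rate[session_idx]
  reward <- stage == "Reward"
  rt_m <- curve$rt_mean_s[[stage]]; rt_s <- curve$rt_sd_s[[stage]]
  imp <- curve$impulsive_rate_hz[[stage]]
  with_seed(seed, {
    n <- task$n_trials
    tex <- character(n)
    run <- 0L
    for (i in seq_len(n)) {
      if (i > 1L && run >= task$max_consecutive_same) {
        tex[i] <- if (tex[i - 1L] == "Go") "NoGo" else "Go"
      } else {
        tex[i] <- if (stats::runif(1) < go_p) "Go" else "NoGo"
      }
      run <- if (i > 1L && tex[i] == tex[i - 1L]) run + 1L else 1L
    }
    t_cue <- t_pt0 <- t_pt1 <- numeric(n)
    outcome <- rep("none", n)
    rt <- rep(NA_real_, n)
    licks <- vector("list", n)
    t <- 0
    for (i in seq_len(n)) {
      t_cue[i] <- t + task$pre_task_s
      t_pt0[i] <- t_cue[i] + task$cue_s + task$travel_s
      t_pt1[i] <- t_pt0[i] + task$pt_window_s
      l <- numeric(0)
      n_imp <- stats::rpois(1, imp * (t_pt0[i] + task$grace_s - t_cue[i]))
      if (n_imp > 0)
        l <- stats::runif(n_imp, t_cue[i], t_pt0[i] + task$grace_s - 1e-6)
      if (reward) {
        # consumption licks after automatic water delivery at PT end
        n_cons <- 3L + stats::rpois(1, 3)
        l <- c(l, t_pt1[i] + 0.1 + cumsum(abs(stats::rnorm(n_cons, 0.14, 0.02))))
      } else {
        go <- tex[i] == "Go"
        responded <- stats::runif(1) < (if (go) hr else fa)
        if (responded) {
          outcome[i] <- if (go) "Hit" else "FA"
          rt[i] <- .rtrunc_norm(1, rt_m, rt_s, task$grace_s, task$pt_window_s)
          n_cons <- 3L + stats::rpois(1, 3)
          l <- c(l, t_pt0[i] + rt[i] +
                   c(0, cumsum(abs(stats::rnorm(n_cons, 0.14, 0.02)))))
        } else {
          outcome[i] <- if (go) "Miss" else "CR"
        }
      }
      licks[[i]] <- sort(l)
      t <- t_pt1[i] + task$iti_s + if (identical(outcome[i], "FA")) task$timeout_s else 0
    }
    tr <- trial_table(seq_len(n), tex, t_cue, t_pt0, t_pt1,
                      lick_times_s = licks, outcome = outcome, rt_s = rt)
    attr(tr, "stage") <- stage
    tr
  })
}

# double-exponential kernel normalized to unit peak; s >= 0
.dexp_kernel <- function(s, rise, decay) {
  k <- exp(-s / decay) - exp(-s / rise)
  s_pk <- log(decay / rise) * rise * decay / (decay - rise)
  k / (exp(-s_pk / decay) - exp(-s_pk / rise))
}

# time from kernel onset to its peak
.dexp_peak_s <- function(rise, decay) log(decay / rise) * rise * decay / (decay - rise)

#' Simulate a two-channel photometry session
#'
#' The activity channel is the sum of an exponential bleach trend, motion
#' artifacts shared with the isosbestic channel, trial-locked calcium
#' transients (double-exponential kernel peaking at PT start, per-trial
#' amplitude Normal(amp, 0.1 amp) truncated at zero), and white noise. The
#' isosbestic channel carries its own bleach trend, the same artifacts, and
#' noise - no transients.
#'
#' @param trials a \code{trial_table}.
#' @param sig a \code{\link{signal_model_params}}.
#' @param amp mean transient amplitude (raw trace units, >= 0).
#' @param seed RNG seed.
#' @return list: \code{session} (a \code{photometry_session}) and
#'   \code{truth} with per-trial amplitudes, transient onset/peak times,
#'   artifact times/amplitudes, and the noise-free transient component.
#' @export
simulate_photometry <- function(trials, sig, amp, seed = 1) {
  if (amp < 0) stop("simulate_photometry: amp must be >= 0")
  dur <- max(trials$t_pt_end_s) + 5
  if (min(trials$t_cue_s) < 0)
    stop("simulate_photometry: trial events outside trace span")
  with_seed(seed, {
    n <- floor(dur * sig$rate_hz) + 1L
    t <- (seq_len(n) - 1) / sig$rate_hz
    bleach_act <- sig$act_f0 *
      (1 - sig$bleach_frac * (1 - exp(-t / sig$bleach_tau_s)))
    bleach_iso <- sig$iso_f0 *
      (1 - sig$iso_bleach_frac * (1 - exp(-t / sig$iso_bleach_tau_s)))
    n_art <- stats::rpois(1, sig$artifact_rate_hz * dur)
    art_t <- sort(stats::runif(n_art, 0, dur))
    art_a <- sig$artifact_amp * stats::runif(n_art, 0.7, 1.3) *
      sample(c(-1, 1), n_art, replace = TRUE)
    artifacts <- numeric(n)
    for (j in seq_len(n_art))
      artifacts <- artifacts +
        art_a[j] * exp(-(t - art_t[j])^2 / (2 * sig$artifact_width_s^2))
    n_tr <- nrow(trials)
    amp_i <- pmax(0, stats::rnorm(n_tr, amp, 0.1 * amp))
    s_pk <- .dexp_peak_s(sig$transient_rise_s, sig$transient_decay_s)
    onset <- trials$t_pt_start_s - s_pk
    transients <- numeric(n)
    for (j in seq_len(n_tr)) {
      i0 <- max(1L, floor(onset[j] * sig$rate_hz) + 1L)
      i1 <- min(n, i0 + ceiling((s_pk + 6 * sig$transient_decay_s) * sig$rate_hz))
      s <- t[i0:i1] - onset[j]
      sel <- s >= 0
      transients[(i0:i1)[sel]] <- transients[(i0:i1)[sel]] +
        amp_i[j] * .dexp_kernel(s[sel], sig$transient_rise_s,
                                sig$transient_decay_s)
    }
    act <- bleach_act + artifacts + transients +
      stats::rnorm(n, 0, sig$noise_sd)
    iso <- bleach_iso + artifacts + stats::rnorm(n, 0, sig$noise_sd)
    list(session = photometry_session(time_series(iso, sig$rate_hz),
                                      time_series(act, sig$rate_hz), trials),
         truth = list(trial_amp = amp_i, onset_s = onset,
                      peak_s = trials$t_pt_start_s,
                      artifact_times_s = art_t, artifact_amps = art_a,
                      transient_component = time_series(transients,
                                                        sig$rate_hz)))
  })
}

#' Simulate pupil marker frames
#'
#' The latent pupil area is a baseline plus a gain times the low-passed
#' arousal drive delayed by the pupil lag. Markers sit on an ellipse of
#' that area (session-fixed axis ratio <= 1.2 and orientation) with
#' coordinate jitter; blink frames overwrite the markers with a wide
#' eyelid configuration whose fitted area exceeds 450 px^2.
#'
#' @param trials a \code{trial_table} (defines session duration).
#' @param arousal_drive a \code{time_series} covering the session.
#' @param sig a \code{signal_model_params}.
#' @param seed RNG seed.
#' @return list: \code{frames} (a \code{pupil_frames}) and \code{truth}
#'   with the latent area \code{time_series}, blink frame indices, and the
#'   generative lag.
#' @export
simulate_pupil <- function(trials, arousal_drive, sig, seed = 1) {
  dur <- max(trials$t_pt_end_s) + 5
  if (arousal_drive$t0_s > 0 || ts_duration(arousal_drive) < dur - 1 / sig$pupil_fps)
    stop("simulate_pupil: arousal drive does not cover the session")
  with_seed(seed, {
    dr <- arousal_drive$values
    dt <- 1 / arousal_drive$rate_hz
    a <- dt / (sig$pupil_lowpass_tau_s + dt)
    lp <- dr
    for (i in seq_along(lp)[-1]) lp[i] <- lp[i - 1] + a * (dr[i] - lp[i - 1])
    if (max(lp) > 0) lp <- lp / max(lp)
    t_frame <- seq(0, dur, by = 1 / sig$pupil_fps)
    lp_at <- stats::approx(ts_times(arousal_drive), lp,
                           xout = pmax(0, t_frame - sig$pupil_lag_s),
                           rule = 2)$y
    area <- sig$pupil_base_px2 + sig$pupil_gain_px2 * lp_at
    nf <- length(t_frame)
    n_blink <- stats::rpois(1, sig$blink_rate_hz * dur)
    blink_frames <- integer(0)
    if (n_blink > 0) {
      starts <- sort(sample.int(nf, n_blink))
      len <- max(1L, round(sig$blink_dur_s * sig$pupil_fps))
      blink_frames <- unique(unlist(lapply(starts, function(s)
        s:min(nf, s + len - 1L))))
    }
    ratio <- stats::runif(1, 1.0, 1.2)
    theta <- stats::runif(1, 0, pi)
    center <- c(115, 138)
    phi <- (0:7) * pi / 4 + pi / 2       # top, top-right, ..., top-left
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    markers <- array(NA_real_, c(nf, 8L, 2L))
    for (i in seq_len(nf)) {
      if (i %in% blink_frames) {
        a_px <- 30
        b_px <- stats::runif(1, 500, 650) / (pi * a_px)
        pts <- cbind(a_px * cos(phi), b_px * sin(phi))   # eyelid-wide
      } else {
        a_px <- sqrt(area[i] * ratio / pi)
        b_px <- area[i] / (pi * a_px)
        pts <- cbind(a_px * cos(phi), b_px * sin(phi)) %*% t(rot)
      }
      markers[i, , ] <- sweep(pts, 2L, center, "+") +
        matrix(stats::rnorm(16, 0, sig$marker_jitter_px), 8L, 2L)
    }
    ref <- cbind(50 + stats::rnorm(nf, 0, 0.1), 200 + stats::rnorm(nf, 0, 0.1))
    list(frames = pupil_frames(t_frame, markers, ref),
         truth = list(latent_area = time_series(area, sig$pupil_fps, 0),
                      # low-passed but undelayed drive: the reference against
                      # which the pure lag is recoverable
                      lowpassed_drive = time_series(lp, arousal_drive$rate_hz,
                                                    arousal_drive$t0_s),
                      blink_frames = sort(blink_frames),
                      lag_s = sig$pupil_lag_s))
  })
}

#' Simulate evoked-PSP sweep sets
#'
#' Generates sweeps for the optical stimulation protocols: SP (one 2.5 ms
#' pulse, 20 sweeps), PPR (five pulses at 50 ms intervals, 20 sweeps), and
#' TRAIN (thirty pulses at 64.2 ms intervals, 5 sweeps). True per-pulse
#' amplitudes follow the resource-depletion model; each sweep is the
#' resting potential plus the superposed double-exponential kernels plus
#' white noise, with a stimulus-free first 0.5 s.
#'
#' @param protocol "SP", "PPR", or "TRAIN".
#' @param syn a \code{\link{synapse_model_params}}.
#' @param seed RNG seed.
#' @param n_sweeps sweep count (protocol default when NULL).
#' @param rate_hz sampling rate (Hz).
#' @return list: \code{sweeps} (a \code{sweep_set}) and \code{truth} with
#'   the per-pulse amplitudes and kernel constants.
#' @export
simulate_psp_sweeps <- function(protocol = c("SP", "PPR", "TRAIN"), syn,
                                seed = 1, n_sweeps = NULL, rate_hz = 20000) {
  protocol <- match.arg(protocol)
  spec <- switch(protocol,
                 SP = list(n_pulse = 1L, ipi = NA, n_sweeps = 20L, dur = 1.5),
                 PPR = list(n_pulse = 5L, ipi = 0.050, n_sweeps = 20L, dur = 1.5),
                 TRAIN = list(n_pulse = 30L, ipi = 0.0642, n_sweeps = 5L, dur = 3.0))
  if (is.null(n_sweeps)) n_sweeps <- spec$n_sweeps
  t_pulse <- 0.5 + (seq_len(spec$n_pulse) - 1L) * (if (is.na(spec$ipi)) 0 else spec$ipi)
  if (max(t_pulse) + 0.05 > spec$dur)
    stop("simulate_psp_sweeps: pulse train longer than sweep")
  amps <- psp_true_amplitudes(spec$n_pulse,
                              if (is.na(spec$ipi)) 0 else spec$ipi, syn)
  rise <- syn$rise_ms / 1000; decay <- syn$decay_ms / 1000
  with_seed(seed, {
    n <- floor(spec$dur * rate_hz) + 1L
    t <- (seq_len(n) - 1) / rate_hz
    clean <- rep(syn$resting_mv, n)
    for (k in seq_along(t_pulse)) {
      s <- t - t_pulse[k]
      sel <- s >= 0
      clean[sel] <- clean[sel] + amps[k] * .dexp_kernel(s[sel], rise, decay)
    }
    m <- matrix(stats::rnorm(n_sweeps * n, 0, syn$noise_sd_mv),
                n_sweeps, n, byrow = TRUE) +
      matrix(clean, n_sweeps, n, byrow = TRUE)
    list(sweeps = sweep_set(m, t_pulse, protocol, rate_hz = rate_hz),
         truth = list(amplitudes_mv = amps, pulse_times_s = t_pulse,
                      rise_s = rise, decay_s = decay,
                      clean_trace = time_series(clean, rate_hz)))
  })
}

#' True per-pulse amplitudes of the depression model
#'
#' @param n_pulse number of pulses.
#' @param ipi_s inter-pulse interval (s).
#' @param syn a \code{synapse_model_params}.
#' @return amplitude vector (mV).
#' @export
psp_true_amplitudes <- function(n_pulse, ipi_s, syn) {
  r <- 1
  amps <- numeric(n_pulse)
  for (k in seq_len(n_pulse)) {
    amps[k] <- syn$a1_mv * r
    r_post <- r * (1 - syn$depression_u)
    r <- 1 + (r_post - 1) * exp(-ipi_s / syn$recovery_tau_s)
  }
  amps
}

#' Simulate current-step sweeps with known spikes
#'
#' Subthreshold sweeps follow an RC charging curve toward
#' \code{rest + I * R}; suprathreshold steps (I >= rheobase) ride at a
#' depolarized plateau with stereotyped spike waveforms of known threshold,
#' peak, width and AHP inserted at known, evenly spaced times. Step
#' protocol: -300 to +400 pA in 50 pA steps, 500 ms, 15 sweeps.
#'
#' @param params list of model constants; see defaults in the function.
#' @param seed RNG seed.
#' @return list: \code{sweeps} (a STEPS \code{sweep_set}) and \code{truth}
#'   with per-sweep spike times and the template geometry (threshold, peak,
#'   AHP minimum, rise/fall durations).
#' @export
simulate_intrinsic_sweeps <- function(params = list(), seed = 1) {
  p <- utils::modifyList(list(
    resting_mv = -80, r_gohm = 0.08, tau_m_s = 0.02,
    rheobase_pa = 150, hz_per_pa = 0.1,
    thr_mv = -45, peak_mv = 20, ahp_min_mv = -55,
    rise_ms = 0.4, fall_ms = 1.0, ahp_tau_ms = 8,
    approach_ms = 3, noise_sd_mv = 0.1,
    step_on_s = 0.5, step_dur_s = 0.5, sweep_dur_s = 1.5,
    rate_hz = 20000, currents_pa = seq(-300, 400, by = 50)), params)
  rate <- p$rate_hz
  n <- floor(p$sweep_dur_s * rate) + 1L
  t <- (seq_len(n) - 1) / rate
  on <- p$step_on_s; off <- p$step_on_s + p$step_dur_s
  currents <- p$currents_pa
  # spike template sampled at the sweep rate, starting at the threshold kink
  n_rise <- max(2L, round(p$rise_ms / 1000 * rate))
  n_fall <- max(2L, round(p$fall_ms / 1000 * rate))
  n_ahp <- round(6 * p$ahp_tau_ms / 1000 * rate)
  template <- function(base_mv) {
    rec <- p$ahp_min_mv + (base_mv - p$ahp_min_mv) *
      (1 - exp(-(seq_len(n_ahp)) / (p$ahp_tau_ms / 1000 * rate)))
    c(seq(p$thr_mv, p$peak_mv, length.out = n_rise + 1L),
      seq(p$peak_mv, p$ahp_min_mv, length.out = n_fall + 1L)[-1],
      rec)
  }
  with_seed(seed, {
    sweeps <- matrix(p$resting_mv, length(currents), n)
    spike_times <- vector("list", length(currents))
    for (si in seq_along(currents)) {
      i_pa <- currents[si]
      v_inf <- p$resting_mv + i_pa * p$r_gohm
      sub_target <- min(v_inf, p$thr_mv - 3)
      v <- rep(p$resting_mv, n)
      inside <- t >= on & t < off
      v[inside] <- p$resting_mv + (sub_target - p$resting_mv) *
        (1 - exp(-(t[inside] - on) / p$tau_m_s))
      after <- t >= off
      v_off <- p$resting_mv + (sub_target - p$resting_mv) *
        (1 - exp(-p$step_dur_s / p$tau_m_s))
      v[after] <- p$resting_mv + (v_off - p$resting_mv) *
        exp(-(t[after] - off) / p$tau_m_s)
      st <- numeric(0)
      if (i_pa >= p$rheobase_pa) {
        n_spk <- max(1L, round(p$hz_per_pa * (i_pa - p$rheobase_pa) / 2) + 3L)
        freq <- n_spk / p$step_dur_s
        st <- on + (seq_len(n_spk) - 0.5) / freq
        n_app <- round(p$approach_ms / 1000 * rate)
        # between spikes the membrane recovers toward a depolarized plateau
        # above the AHP floor, so the designed AHP depth is the true one
        plateau <- p$thr_mv - 5
        for (ts_k in st) {
          i_thr <- round(ts_k * rate) + 1L
          # gentle approach ramp up to threshold, then the template
          i_app <- max(1L, i_thr - n_app)
          v[i_app:i_thr] <- seq(v[i_app], p$thr_mv,
                                length.out = i_thr - i_app + 1L)
          tpl <- template(plateau)
          i_end <- min(n, i_thr + length(tpl) - 1L)
          v[i_thr:i_end] <- tpl[seq_len(i_end - i_thr + 1L)]
        }
      }
      sweeps[si, ] <- v + stats::rnorm(n, 0, p$noise_sd_mv)
      spike_times[[si]] <- st
    }
    list(sweeps = sweep_set(sweeps, numeric(0), "STEPS", rate_hz = rate,
                            step_currents_pa = currents),
         truth = list(spike_times_s = spike_times, currents_pa = currents,
                      thr_mv = p$thr_mv, peak_mv = p$peak_mv,
                      ahp_min_mv = p$ahp_min_mv,
                      rise_ms = p$rise_ms, fall_ms = p$fall_ms,
                      params = p))
  })
}

#' Simulate a full multi-session study
#'
#' Composes the session generators across the learning trajectory of the
#' curve parameters: for every session a trial schedule, a two-channel
#' photometry session whose transient amplitude is the stage's, a piezo
#' lick-voltage trace, and pupil frames driven by the session's noise-free
#' transient train. The Reward session has automatic water at PT end and
#' no outcome-triggering licks.
#'
#' @param task a \code{task_params}.
#' @param curve a \code{learning_curve_params}.
#' @param sig a \code{signal_model_params}.
#' @param seed study seed; per-session streams are derived from it.
#' @param piezo_rate_hz piezo sampling rate (Hz).
#' @return list of class \code{study_bundle}: \code{sessions} (per session:
#'   trials, photometry, pupil, piezo, stage, truth) and \code{design}
#'   (stage labels, target rates, designed expert session index).
#' @export
simulate_study <- function(task = task_params(),
                           curve = learning_curve_params(),
                           sig = signal_model_params(), seed = 1,
                           piezo_rate_hz = 1000) {
  n_sess <- length(curve$stage)
  if (length(curve$hit_rate) != n_sess || length(curve$go_prob) != n_sess)
    stop("simulate_study: inconsistent per-session parameter lengths")
  missing_stage <- setdiff(setdiff(unique(curve$stage), "Reward"),
                           names(curve$transient_amp_by_stage))
  if (length(setdiff(unique(curve$stage),
                     names(curve$transient_amp_by_stage))))
    stop("simulate_study: no transient amplitude for stage(s): ",
         paste(missing_stage, collapse = ", "))
  sessions <- vector("list", n_sess)
  for (i in seq_len(n_sess)) {
    s_seed <- seed + 7919L * i
    stage <- curve$stage[i]
    trials <- simulate_trial_schedule(task, curve, i, seed = s_seed)
    amp <- curve$transient_amp_by_stage[[stage]]
    phot <- simulate_photometry(trials, sig, amp, seed = s_seed + 1L)
    drive <- phot$truth$transient_component
    pup <- simulate_pupil(trials, drive, sig, seed = s_seed + 2L)
    piezo <- .piezo_from_licks(trials, max(trials$t_pt_end_s) + 5,
                               piezo_rate_hz, seed = s_seed + 3L)
    sessions[[i]] <- list(trials = trials, photometry = phot$session,
                          pupil = pup$frames, piezo = piezo,
                          stage = stage,
                          truth = list(photometry = phot$truth,
                                       pupil = pup$truth))
  }
  # designed expert index: second session of the first qualifying pair
  q <- !is.na(curve$hit_rate) & curve$hit_rate >= 0.80 &
    !is.na(curve$fa_rate) & curve$fa_rate <= 0.30 & curve$stage != "Shaping"
  pair <- which(q[-1] & q[-n_sess]) + 1L
  structure(list(sessions = sessions,
                 design = list(stage = curve$stage,
                               hit_rate = curve$hit_rate,
                               fa_rate = curve$fa_rate,
                               expert_session_index =
                                 if (length(pair)) min(pair) else NA_integer_)),
            class = "study_bundle")
}

# synthesize a piezo voltage trace with a biphasic deflection per lick
.piezo_from_licks <- function(trials, dur, rate_hz, seed = 1) {
  with_seed(seed, {
    n <- floor(dur * rate_hz) + 1L
    v <- stats::rnorm(n, 0, 0.05)
    n_up <- max(1L, round(0.005 * rate_hz))
    pulse <- c(rep(0.8, n_up), rep(-0.6, n_up))
    for (lt in unlist(trials$lick_times_s)) {
      i0 <- round(lt * rate_hz) + 1L
      i1 <- min(n, i0 + length(pulse) - 1L)
      if (i0 >= 1L && i0 <= n)
        v[i0:i1] <- v[i0:i1] + pulse[seq_len(i1 - i0 + 1L)]
    }
    time_series(v, rate_hz, 0)
  })
}
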