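#' Uniformly sampled time series
#'
#' Container for every continuous signal in the pipeline: photometry
#' channels (raw fluorescence or ZMAD units), pupil area (px^2), piezo lick
#' voltage (V), and membrane potential (mV). Time is seconds from session
#' start; the time of sample \code{i} is \code{t0_s + (i - 1) / rate_hz}.
#'
#' @param values numeric vector of samples (length >= 1, finite or NA).
#' @param rate_hz sampling rate in Hz (> 0).
#' @param t0_s time of the first sample in seconds (default 0).
#' @return An object of class \code{time_series}.
#' @export
time_series <- function(values, rate_hz, t0_s = 0) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("time_series: need at least one sample")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("time_series: rate_hz must be a positive scalar")
  structure(list(values = values, rate_hz = as.numeric(rate_hz),
                 t0_s = as.numeric(t0_s)),
            class = "time_series")
}

#' Sample times of a time series
#' @param ts a \code{time_series}.
#' @return numeric vector of sample times (s).
#' @export
ts_times <- function(ts) {
  ts$t0_s + (seq_along(ts$values) - 1) / ts$rate_hz
}

#' Duration of a time series
#' @param ts a \code{time_series}.
#' @return duration in seconds, \code{(n - 1) / rate_hz}.
#' @export
ts_duration <- function(ts) (length(ts$values) - 1) / ts$rate_hz

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> n=%d  rate=%g Hz  t0=%g s  duration=%g s\n",
              length(x$values), x$rate_hz, x$t0_s, ts_duration(x)))
  invisible(x)
}

#' Go/NoGo task timing parameters
#'
#' Trial structure of the whisker-based discrimination paradigm: a 1 s
#' pre-task interval, a 100 ms cue tone accompanying texture movement, a 2 s
#' presentation-time (PT) window whose first 500 ms is a no-consequence
#' grace period, a 12 s timeout after false alarms, and a 2 s intertrial
#' interval. Sessions have 150 trials; textures are drawn pseudorandomly
#' with at most three consecutive presentations of the same texture.
#'
#' @param pre_task_s pre-task interval (s).
#' @param cue_s cue tone duration (s).
#' @param travel_s cue onset to texture-at-endpoint (PT start) interval (s).
#' @param pt_window_s presentation-time window length (s).
#' @param grace_s grace period at the start of the PT window (s).
#' @param timeout_s timeout after a false alarm (s).
#' @param iti_s intertrial interval (s).
#' @param n_trials trials per session.
#' @param go_prob probability of a Go texture, in (0, 1).
#' @param max_consecutive_same maximum run length of one texture.
#' @return list of class \code{task_params}.
#' @export
task_params <- function(pre_task_s = 1.0, cue_s = 0.1, travel_s = 0.9,
                        pt_window_s = 2.0, grace_s = 0.5, timeout_s = 12.0,
                        iti_s = 2.0, n_trials = 150L, go_prob = 0.5,
                        max_consecutive_same = 3L) {
  if (grace_s >= pt_window_s) stop("task_params: grace_s must be < pt_window_s")
  if (go_prob <= 0 || go_prob >= 1) stop("task_params: go_prob must be in (0,1)")
  if (n_trials < 1L) stop("task_params: n_trials must be >= 1")
  structure(list(pre_task_s = pre_task_s, cue_s = cue_s, travel_s = travel_s,
                 pt_window_s = pt_window_s, grace_s = grace_s,
                 timeout_s = timeout_s, iti_s = iti_s,
                 n_trials = as.integer(n_trials), go_prob = go_prob,
                 max_consecutive_same = as.integer(max_consecutive_same)),
            class = "task_params")
}

#' Per-trial table
#'
#' One row per trial. \code{t_pt_start_s} (texture at endpoint, the TTL
#' synchronization flag) anchors all trial-aligned analysis. \code{outcome}
#' is \code{"none"} before scoring; \code{rt_s} (first outcome-triggering
#' lick minus PT start) is present only for Hit and FA trials.
#'
#' @param trial_index integer trial numbers.
#' @param texture character, "Go" or "NoGo".
#' @param t_cue_s cue onsets (s).
#' @param t_pt_start_s PT-window starts (s).
#' @param t_pt_end_s PT-window ends (s).
#' @param lick_times_s list of numeric vectors, licks per trial (s).
#' @param outcome character: Hit, Miss, FA, CR, or none.
#' @param rt_s reaction times (s), NA where undefined.
#' @return data.frame of class \code{trial_table}.
#' @export
trial_table <- function(trial_index, texture, t_cue_s, t_pt_start_s,
                        t_pt_end_s, lick_times_s = NULL,
                        outcome = "none", rt_s = NA_real_) {
  n <- length(trial_index)
  if (is.null(lick_times_s)) lick_times_s <- rep(list(numeric(0)), n)
  stopifnot(all(texture %in% c("Go", "NoGo")),
            all(outcome %in% c("Hit", "Miss", "FA", "CR", "none")))
  if (any(!(t_cue_s < t_pt_start_s & t_pt_start_s < t_pt_end_s)))
    stop("trial_table: need t_cue_s < t_pt_start_s < t_pt_end_s for every trial")
  df <- data.frame(trial_index = as.integer(trial_index),
                   texture = rep_len(texture, n),
                   t_cue_s = t_cue_s, t_pt_start_s = t_pt_start_s,
                   t_pt_end_s = t_pt_end_s,
                   outcome = rep_len(outcome, n),
                   rt_s = rep_len(as.numeric(rt_s), n),
                   stringsAsFactors = FALSE)
  df$lick_times_s <- lick_times_s
  ok <- df$outcome %in% c("Hit", "FA")
  if (any(ok & is.na(df$rt_s)) || any(!ok & !is.na(df$rt_s)))
    stop("trial_table: rt_s must be present iff outcome is Hit or FA")
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Two-channel photometry session
#'
#' Pairs the calcium-insensitive isosbestic channel (405 nm excitation) with
#' the activity channel (470 nm) and the trial table of the same session.
#' Both channels must share sampling grid and length.
#'
#' @param iso,act \code{time_series}, isosbestic and activity channels.
#' @param trials a \code{trial_table}.
#' @return list of class \code{photometry_session}.
#' @export
photometry_session <- function(iso, act, trials) {
  stopifnot(inherits(iso, "time_series"), inherits(act, "time_series"),
            inherits(trials, "trial_table"))
  if (length(iso$values) != length(act$values) || iso$rate_hz != act$rate_hz)
    stop("photometry_session: iso and act must share rate and length")
  structure(list(iso = iso, act = act, trials = trials),
            class = "photometry_session")
}

.marker_names <- c("top", "top_right", "right", "bottom_right",
                   "bottom", "bottom_left", "left", "top_left")

#' Per-frame pupil marker series
#'
#' Eight pose-estimation markers circumscribing the pupil (top, top-right,
#' right, bottom-right, bottom, bottom-left, left, top-left) plus a static
#' reference marker, per video frame. Coordinates are image pixels.
#'
#' @param t_s strictly increasing frame timestamps (s).
#' @param markers numeric array \code{[n_frames, 8, 2]} of (x, y).
#' @param ref_marker numeric matrix \code{[n_frames, 2]}.
#' @param likelihood optional \code{[n_frames, 8]} marker confidences.
#' @return list of class \code{pupil_frames}.
#' @export
pupil_frames <- function(t_s, markers, ref_marker, likelihood = NULL) {
  n <- length(t_s)
  if (n < 1L) stop("pupil_frames: no frames")
  if (any(diff(t_s) <= 0)) stop("pupil_frames: timestamps must be strictly increasing")
  stopifnot(length(dim(markers)) == 3L, dim(markers)[1] == n,
            dim(markers)[2] == 8L, dim(markers)[3] == 2L,
            nrow(ref_marker) == n, ncol(ref_marker) == 2L)
  structure(list(t_s = as.numeric(t_s), markers = markers,
                 ref_marker = ref_marker, likelihood = likelihood),
            class = "pupil_frames")
}

#' Set of patch-clamp sweeps
#'
#' Membrane-potential sweeps digitized at 20 kHz with the optical stimulus
#' times of the protocol: SP (1 pulse), PPR (5 pulses, 50 ms IPI), TRAIN
#' (30 pulses, 64.2 ms IPI), or STEPS (current steps, no optical pulses).
#'
#' @param sweeps numeric matrix \code{[n_sweeps, n_samples]} (mV).
#' @param stim_times_s optical pulse onsets (s from sweep start).
#' @param protocol one of "SP", "PPR", "TRAIN", "STEPS".
#' @param rate_hz sampling rate (Hz).
#' @param step_currents_pa injected currents per sweep (pA), STEPS only.
#' @return list of class \code{sweep_set}.
#' @export
sweep_set <- function(sweeps, stim_times_s, protocol,
                      rate_hz = 20000, step_currents_pa = NULL) {
  protocol <- match.arg(protocol, c("SP", "PPR", "TRAIN", "STEPS"))
  sweeps <- as.matrix(sweeps)
  dur <- (ncol(sweeps) - 1) / rate_hz
  if (length(stim_times_s) && any(stim_times_s < 0 | stim_times_s > dur))
    stop("sweep_set: stim_times_s outside sweep duration")
  need <- c(SP = 1L, PPR = 5L, TRAIN = 30L, STEPS = 0L)[[protocol]]
  if (need > 0L && length(stim_times_s) != need)
    stop(sprintf("sweep_set: protocol %s requires %d pulses, got %d",
                 protocol, need, length(stim_times_s)))
  if (protocol == "STEPS" && !is.null(step_currents_pa) &&
      length(step_currents_pa) != nrow(sweeps))
    stop("sweep_set: step_currents_pa must match number of sweeps")
  structure(list(sweeps = sweeps, rate_hz = rate_hz,
                 stim_times_s = as.numeric(stim_times_s), protocol = protocol,
                 step_currents_pa = step_currents_pa),
            class = "sweep_set")
}

#' Per-session behavioral metrics
#'
#' @param hit_rate,fa_rate,d_prime,bias signal-detection metrics.
#' @param n_trials_by_outcome named counts (hit, miss, fa, cr).
#' @param mean_rt_s session-mean reaction time (s) or NA.
#' @param phase_label one of Shaping, EarlyLearning, Learning, LateLearning,
#'   Expert, Reward.
#' @return list of class \code{session_metrics}.
#' @export
session_metrics <- function(hit_rate, fa_rate, d_prime, bias,
                            n_trials_by_outcome, mean_rt_s = NA_real_,
                            phase_label = "Learning") {
  structure(list(hit_rate = hit_rate, fa_rate = fa_rate, d_prime = d_prime,
                 bias = bias, n_trials_by_outcome = n_trials_by_outcome,
                 mean_rt_s = mean_rt_s, phase_label = phase_label),
            class = "session_metrics")
}

# run code with a temporary RNG state seeded by `seed`; the caller's RNG
# stream is untouched, so generators are pure functions of (params, seed)
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
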