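#' Default pipeline configuration
#'
#' Collects every stage's parameters in one validated list. Unknown keys
#' are rejected so configuration typos surface immediately.
#'
#' @param ... overrides for any default entry (partial lists are merged).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  default <- list(
    seed = 1L,
    task = task_params(),
    curve = learning_curve_params(),
    sig = signal_model_params(),
    detrend_model = "line",
    lick_upper_v = 0.5, lick_lower_v = -0.5,
    align_pre_s = 2, align_post_s = 2,
    baseline_s = c(-2, -1),
    auroc_win_s = 0.5, auroc_step_n = 2L,
    target_s = c(-2, 2),
    event_percentile = 90, event_min_prominence = 2,
    blink_threshold_px = 450,
    xcorr_max_lag_s = 2,
    out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(default))
  if (length(unknown))
    stop("pipeline_config: unknown key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(default, over)
  structure(cfg, class = "pipeline_config")
}

# behavioral + calcium + pupil analysis of one simulated session
.analyze_session <- function(sess, cfg) {
  task <- cfg$task
  licks <- suppressWarnings(
    detect_licks(sess$piezo, cfg$lick_upper_v, cfg$lick_lower_v))
  scored <- score_outcomes(sess$trials, lick_times = as.numeric(licks),
                           task = task)
  is_reward <- sess$stage == "Reward"
  counts <- outcome_counts(scored)
  sdt <- if (!is_reward && counts$hit + counts$miss > 0 &&
             counts$fa + counts$cr > 0) sdt_metrics(counts) else
               list(hit_rate = NA_real_, fa_rate = NA_real_,
                    d_prime = NA_real_, bias = NA_real_)
  rt <- reaction_times(scored)
  corrected <- photometry_correct(sess$photometry, model = cfg$detrend_model)
  win <- align_streams(scored, list(calcium = corrected),
                       pre_s = cfg$align_pre_s, post_s = cfg$align_post_s)
  tma <- trial_max_amplitude(win, "calcium", cfg$target_s)
  auc <- sliding_auroc(win, "calcium", baseline_s = cfg$baseline_s,
                       win_s = cfg$auroc_win_s, step_n = cfg$auroc_step_n)
  events <- event_filter(corrected, cfg$event_percentile,
                         cfg$event_min_prominence)
  capture <- window_capture(events, scored, task,
                            target_pre_s = abs(cfg$target_s[1]),
                            target_post_s = cfg$target_s[2])
  rt_avg <- rt_aligned_average(win, rt$rt_s, "calcium")
  pup <- area_series(sess$pupil, cfg$blink_threshold_px)
  pup_rs <- resample_to(pup$area, corrected$rate_hz)
  xc <- xcorr_lag(corrected, pup_rs, cfg$xcorr_max_lag_s)
  list(stage = sess$stage, counts = counts, sdt = sdt,
       mean_rt_s = rt$mean_rt_s,
       mean_trial_max = tma$mean, sem_trial_max = tma$sem,
       max_auroc = auc$max_auroc, t_max_auroc_s = auc$t_max_s,
       n_events = nrow(events),
       mean_event_control = capture$mean_control,
       mean_event_target = capture$mean_target,
       rt_pre_mean = rt_avg$pre_mean, rt_post_mean = rt_avg$post_mean,
       pupil_lag_s = xc$lag_s, pupil_r = xc$peak_r,
       n_blinks = sum(pup$blink_mask))
}

#' Run the full pipeline on a simulated study
#'
#' simulate -> lick detection -> outcome scoring -> signal-detection
#' metrics -> photometry correction -> trial alignment -> calcium and pupil
#' statistics -> expert classification, deterministically from the
#' configuration seed. When \code{out_dir} is set, the per-session metric
#' table (CSV) and the report (JSON) are written there.
#'
#' @param cfg a \code{\link{pipeline_config}}.
#' @return list of class \code{pipeline_report}: \code{sessions} (one row
#'   per session), \code{expert_session_index}, \code{phase} labels, and
#'   \code{stage_summary} (mean trial-max amplitude and max auROC per
#'   designed stage).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  study <- simulate_study(cfg$task, cfg$curve, cfg$sig, seed = cfg$seed)
  per <- lapply(study$sessions, .analyze_session, cfg = cfg)
  tab <- data.frame(
    session = seq_along(per),
    stage = vapply(per, `[[`, character(1), "stage"),
    hit_rate = vapply(per, function(p) p$sdt$hit_rate, numeric(1)),
    fa_rate = vapply(per, function(p) p$sdt$fa_rate, numeric(1)),
    d_prime = vapply(per, function(p) p$sdt$d_prime, numeric(1)),
    bias = vapply(per, function(p) p$sdt$bias, numeric(1)),
    mean_rt_s = vapply(per, `[[`, numeric(1), "mean_rt_s"),
    mean_trial_max = vapply(per, `[[`, numeric(1), "mean_trial_max"),
    max_auroc = vapply(per, `[[`, numeric(1), "max_auroc"),
    t_max_auroc_s = vapply(per, `[[`, numeric(1), "t_max_auroc_s"),
    n_events = vapply(per, `[[`, integer(1), "n_events"),
    mean_event_target = vapply(per, `[[`, numeric(1), "mean_event_target"),
    mean_event_control = vapply(per, `[[`, numeric(1), "mean_event_control"),
    rt_pre_mean = vapply(per, `[[`, numeric(1), "rt_pre_mean"),
    rt_post_mean = vapply(per, `[[`, numeric(1), "rt_post_mean"),
    pupil_lag_s = vapply(per, `[[`, numeric(1), "pupil_lag_s"),
    pupil_r = vapply(per, `[[`, numeric(1), "pupil_r"),
    n_blinks = vapply(per, `[[`, integer(1), "n_blinks"),
    stringsAsFactors = FALSE)
  cls <- classify_expert(tab$hit_rate, tab$fa_rate,
                         is_shaping = tab$stage == "Shaping",
                         is_reward = tab$stage == "Reward")
  stage_order <- unique(tab$stage)
  stage_summary <- data.frame(
    stage = stage_order,
    mean_trial_max = vapply(stage_order, function(s)
      mean(tab$mean_trial_max[tab$stage == s]), numeric(1)),
    max_auroc = vapply(stage_order, function(s)
      mean(tab$max_auroc[tab$stage == s]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  report <- structure(list(sessions = tab,
                           expert_session_index = cls$expert_index,
                           phase = cls$phase,
                           stage_summary = stage_summary,
                           seed = cfg$seed),
                      class = "pipeline_report")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(cfg$out_dir, "session_metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(sessions = tab, expert_session_index = cls$expert_index,
           phase = cls$phase, stage_summary = stage_summary,
           seed = cfg$seed),
      file.path(cfg$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (seed", x$seed, ")\n")
  cat("Expert session index:", x$expert_session_index, "\n")
  cat("Phases:", paste(x$phase, collapse = ", "), "\n\n")
  print(x$stage_summary)
  invisible(x)
}
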