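#' Score trials into Hit / Miss / FA / CR
#'
#' The first lick falling strictly after the grace period and no later than
#' the PT-window end triggers the outcome: Hit on Go trials, FA on NoGo
#' trials, with reaction time measured from PT start. Licks inside the grace
#' period (the first 500 ms of the PT window by default) never trigger
#' outcomes. Trials without a qualifying lick are Miss (Go) or CR (NoGo).
#' A lick exactly at the grace boundary counts as post-grace.
#'
#' @param schedule a \code{\link{trial_table}} (outcomes are overwritten).
#' @param lick_times optional numeric vector of lick times on the session
#'   clock; if NULL, the table's own \code{lick_times_s} column is used.
#' @param task a \code{\link{task_params}}.
#' @return the scored \code{trial_table}; responded trials end at the
#'   triggering lick (the texture retreats immediately after a lick), which
#'   truncates \code{t_pt_end_s} for downstream trace extraction.
#' @export
score_outcomes <- function(schedule, lick_times = NULL, task = task_params()) {
  stopifnot(inherits(schedule, "trial_table"))
  n <- nrow(schedule)
  if (n > 1L) {
    o <- order(schedule$t_pt_start_s)
    if (any(schedule$t_pt_end_s[o][-n] > schedule$t_cue_s[o][-1]))
      stop("score_outcomes: overlapping trial windows in schedule")
  }
  use_column <- is.null(lick_times)
  out <- schedule
  for (i in seq_len(n)) {
    licks <- if (use_column) schedule$lick_times_s[[i]] else
      lick_times[lick_times >= schedule$t_cue_s[i] - task$pre_task_s &
                 lick_times <= schedule$t_pt_end_s[i]]
    out$lick_times_s[[i]] <- sort(licks)
    t0 <- schedule$t_pt_start_s[i]
    qualifying <- licks[licks >= t0 + task$grace_s & licks <= schedule$t_pt_end_s[i]]
    go <- schedule$texture[i] == "Go"
    if (length(qualifying)) {
      first <- min(qualifying)
      out$outcome[i] <- if (go) "Hit" else "FA"
      out$rt_s[i] <- first - t0
      out$t_pt_end_s[i] <- first
    } else {
      out$outcome[i] <- if (go) "Miss" else "CR"
      out$rt_s[i] <- NA_real_
    }
  }
  out
}

#' Count trial outcomes
#'
#' @param trials a scored \code{trial_table}.
#' @return list of class \code{outcome_counts} with fields hit, miss, fa, cr.
#' @export
outcome_counts <- function(trials) {
  structure(list(hit = sum(trials$outcome == "Hit"),
                 miss = sum(trials$outcome == "Miss"),
                 fa = sum(trials$outcome == "FA"),
                 cr = sum(trials$outcome == "CR")),
            class = "outcome_counts")
}

#' Signal-detection metrics for one session
#'
#' Hit rate = Hit / (Hit + Miss); FA rate = FA / (FA + CR). Sensitivity
#' d' = Z(HR) - Z(FA) and bias = 0.5 (Z(HR) + Z(FA)), with Z the standard
#' normal quantile. Rates of exactly 0 or 1 are clamped to 1/(2N) and
#' 1 - 1/(2N) (N = trials of that type) before the quantile transform.
#' Note the classical criterion c is the negative of this bias; set
#' \code{bias_half_sum = FALSE} for the reading 0.5 Z(HR) + Z(FA) of the
#' same formula.
#'
#' @param counts an \code{\link{outcome_counts}} (or compatible list).
#' @param bias_half_sum if TRUE (default) the 0.5 factor multiplies the
#'   whole sum of quantiles.
#' @return list with hit_rate, fa_rate, d_prime, bias.
#' @export
sdt_metrics <- function(counts, bias_half_sum = TRUE) {
  n_go <- counts$hit + counts$miss
  n_nogo <- counts$fa + counts$cr
  if (n_go == 0 || n_nogo == 0)
    stop("sdt_metrics: undefined metrics (zero Go or NoGo trials)")
  hr <- counts$hit / n_go
  far <- counts$fa / n_nogo
  clamp <- function(r, n) min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))
  zh <- stats::qnorm(clamp(hr, n_go))
  zf <- stats::qnorm(clamp(far, n_nogo))
  bias <- if (bias_half_sum) 0.5 * (zh + zf) else 0.5 * zh + zf
  list(hit_rate = hr, fa_rate = far, d_prime = zh - zf, bias = bias)
}

#' Expert classification and learning-phase labels
#'
#' A subject reaches Expert at the second session of the first pair of
#' consecutive non-Shaping sessions with hit rate >= 0.80 and FA rate
#' <= 0.30. Early Learning is the first two Learning-phase sessions; Late
#' Learning the last two Learning-phase sessions before the Expert session.
#'
#' @param hit_rates,fa_rates per-session rates, in session order.
#' @param is_shaping logical flags for Shaping sessions (default none).
#' @param is_reward logical flags for post-training Reward sessions.
#' @param hr_min,fa_max expert thresholds.
#' @return list with \code{expert_index} (NA if the criterion is never met)
#'   and a character vector \code{phase} of per-session labels.
#' @export
classify_expert <- function(hit_rates, fa_rates,
                            is_shaping = rep(FALSE, length(hit_rates)),
                            is_reward = rep(FALSE, length(hit_rates)),
                            hr_min = 0.80, fa_max = 0.30) {
  n <- length(hit_rates)
  stopifnot(length(fa_rates) == n, length(is_shaping) == n,
            length(is_reward) == n)
  eligible <- !is_shaping & !is_reward
  qual <- eligible & hit_rates >= hr_min & fa_rates <= fa_max
  pair <- which(qual[-1] & qual[-n] & eligible[-1] & eligible[-n]) + 1L
  expert_index <- if (length(pair)) min(pair) else NA_integer_
  phase <- rep("Learning", n)
  phase[is_shaping] <- "Shaping"
  phase[is_reward] <- "Reward"
  learning <- which(eligible & (is.na(expert_index) |
                                  seq_len(n) < expert_index))
  if (length(learning)) {
    phase[utils::head(learning, 2L)] <- "EarlyLearning"
    phase[utils::tail(learning, 2L)] <- "LateLearning"
  }
  if (!is.na(expert_index))
    phase[eligible & seq_len(n) >= expert_index] <- "Expert"
  list(expert_index = expert_index, phase = phase)
}

#' Reaction times of responded trials
#'
#' RT is defined only on Hit and FA trials (time of the first
#' outcome-triggering lick minus PT start).
#'
#' @param trials a scored \code{trial_table}.
#' @return list with \code{rt_s} (per responded trial) and \code{mean_rt_s}
#'   (NA when no trial was responded).
#' @export
reaction_times <- function(trials) {
  rts <- trials$rt_s[trials$outcome %in% c("Hit", "FA")]
  rts <- rts[!is.na(rts)]
  list(rt_s = rts,
       mean_rt_s = if (length(rts)) mean(rts) else NA_real_)
}

#' Lick-time probability density aligned to PT start
#'
#' Histogram of all lick times relative to texture arrival, normalized so
#' that the returned density integrates to one.
#'
#' @param trials a \code{trial_table} with per-trial lick times.
#' @param bin_s bin width (s).
#' @param range_s alignment window \code{c(lo, hi)} relative to PT start;
#'   defaults to the span of the observed licks.
#' @return data.frame with bin centers \code{t_s} and \code{density} (1/s).
#' @export
lick_density <- function(trials, bin_s = 0.1, range_s = NULL) {
  if (bin_s <= 0) stop("lick_density: bin_s must be positive")
  rel <- unlist(Map(function(l, t0) l - t0,
                    trials$lick_times_s, trials$t_pt_start_s))
  if (!length(rel)) return(data.frame(t_s = numeric(0), density = numeric(0)))
  if (is.null(range_s)) range_s <- range(rel)
  lo <- floor(range_s[1] / bin_s) * bin_s
  hi <- ceiling(range_s[2] / bin_s + 1e-9) * bin_s
  if (hi <= lo) hi <- lo + bin_s
  breaks <- seq(lo, hi, by = bin_s)
  h <- graphics::hist(rel[rel >= lo & rel <= hi], breaks = breaks, plot = FALSE)
  data.frame(t_s = h$mids, density = h$counts / (sum(h$counts) * bin_s))
}
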