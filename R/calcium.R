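#' Area under the ROC curve between two sample sets
#'
#' Probability that a sample from the comparison window exceeds a sample
#' from the baseline, ties counted one-half (the Mann-Whitney U statistic
#' normalized by n*m, computed from midranks). 0.50 means the two sets are
#' indistinguishable; identical sets return exactly 0.50.
#'
#' @param baseline,window numeric vectors (non-empty).
#' @return value in [0, 1].
#' @export
auroc <- function(baseline, window) {
  n <- length(baseline); m <- length(window)
  if (n == 0L || m == 0L) stop("auroc: empty sample set")
  r <- rank(c(baseline, window))
  u <- sum(r[(n + 1):(n + m)]) - m * (m + 1) / 2
  u / (as.numeric(n) * m)
}

#' Sliding-window auROC against a pooled baseline
#'
#' Pools baseline samples across trials from a fixed interval of the
#' trial-aligned window, then slides a short window across the aligned time
#' axis, pooling its samples across trials and computing the auROC of each
#' position against the baseline. The curve maximum summarizes how strongly
#' and when the signal departs from baseline.
#'
#' @param windows a \code{trial_windows} object.
#' @param trace name of the trace to analyze.
#' @param baseline_s baseline interval \code{c(lo, hi)} in aligned time (s,
#'   relative to the anchor); must not overlap the slid windows it is
#'   compared to (overlap only dilutes contrast, it is not checked).
#' @param win_s sliding window length (s).
#' @param step_n step between window starts, in samples.
#' @return list of class \code{auroc_curve}: \code{t_s} (window centers),
#'   \code{auroc}, \code{max_auroc}, \code{t_max_s}, \code{baseline_s}.
#' @export
sliding_auroc <- function(windows, trace = names(windows$traces)[1],
                          baseline_s, win_s = 0.5, step_n = 1L) {
  tw <- windows$traces[[trace]]
  if (is.null(tw)) stop("sliding_auroc: unknown trace '", trace, "'")
  off <- tw$offsets_s
  w_n <- round(win_s * tw$rate_hz)
  if (w_n < 1L || w_n > length(off)) stop("sliding_auroc: window longer than trace span")
  base_cols <- which(off >= baseline_s[1] & off <= baseline_s[2])
  if (!length(base_cols)) stop("sliding_auroc: empty baseline interval")
  base <- as.numeric(tw$mat[, base_cols])
  starts <- seq(1L, length(off) - w_n + 1L, by = step_n)
  vals <- vapply(starts, function(s)
    auroc(base, as.numeric(tw$mat[, s:(s + w_n - 1L)])), numeric(1))
  centers <- off[starts] + (w_n - 1) / (2 * tw$rate_hz)
  i <- which.max(vals)
  structure(list(t_s = centers, auroc = vals, max_auroc = vals[i],
                 t_max_s = centers[i], baseline_s = baseline_s),
            class = "auroc_curve")
}

#' Per-trial maximum amplitude in a target window
#'
#' @param windows a \code{trial_windows} object.
#' @param trace trace name.
#' @param target_s interval \code{c(lo, hi)} in aligned time (s).
#' @return list: \code{trial_max} (per trial), \code{mean}, \code{sem}.
#' @export
trial_max_amplitude <- function(windows, trace = names(windows$traces)[1],
                                target_s = c(-2, 2)) {
  tw <- windows$traces[[trace]]
  cols <- which(tw$offsets_s >= target_s[1] & tw$offsets_s <= target_s[2])
  tm <- apply(tw$mat[, cols, drop = FALSE], 1L, max)
  list(trial_max = tm, mean = mean(tm),
       sem = stats::sd(tm) / sqrt(length(tm)))
}

# local maxima (strictly above both neighbors; plateaus take the first
# sample) and their topographic prominence
.find_peaks <- function(x) {
  n <- length(x)
  if (n < 3L) return(data.frame(index = integer(0), height = numeric(0),
                                prominence = numeric(0)))
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) idx <- c(idx, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  prom <- vapply(idx, function(p) {
    h <- x[p]
    lmin <- h
    k <- p
    while (k > 1L) {
      k <- k - 1L
      if (x[k] > h) break
      if (x[k] < lmin) lmin <- x[k]
    }
    left <- lmin
    rmin <- h
    k <- p
    while (k < n) {
      k <- k + 1L
      if (x[k] > h) break
      if (x[k] < rmin) rmin <- x[k]
    }
    h - max(left, rmin)
  }, numeric(1))
  data.frame(index = idx, height = x[idx], prominence = prom)
}

#' Filter calcium events by percentile and prominence
#'
#' Detects local maxima of a session trace and retains those whose height
#' reaches the given percentile of all detected peak heights in the session
#' and whose topographic prominence reaches the minimum.
#'
#' @param ts session \code{time_series} (ZMAD units).
#' @param percentile height percentile over detected peak heights (0-100).
#' @param min_prominence minimum peak prominence (ZMAD units).
#' @return data.frame with \code{t_s}, \code{height}, \code{prominence} of
#'   the retained peaks (zero rows when nothing qualifies).
#' @export
event_filter <- function(ts, percentile = 90, min_prominence = 2) {
  pk <- .find_peaks(ts$values)
  if (!nrow(pk))
    return(data.frame(t_s = numeric(0), height = numeric(0),
                      prominence = numeric(0)))
  cutoff <- stats::quantile(pk$height, percentile / 100, names = FALSE)
  keep <- pk$height >= cutoff & pk$prominence >= min_prominence
  data.frame(t_s = ts$t0_s + (pk$index[keep] - 1) / ts$rate_hz,
             height = pk$height[keep], prominence = pk$prominence[keep])
}

#' Capture retained events in control and target windows
#'
#' For every trial, takes the maximum retained peak (if any) inside the
#' control window (trial start to cue) and the target window (2 s before to
#' 2 s after PT start), then averages the captured values over the session.
#'
#' @param events data.frame from \code{\link{event_filter}}.
#' @param trials a \code{trial_table}.
#' @param task a \code{task_params} (defines trial start = cue - pre-task).
#' @param target_pre_s,target_post_s target window extent around PT start.
#' @return list: per-trial \code{control} and \code{target} maxima (NA when
#'   no event fell in the window), and session means \code{mean_control},
#'   \code{mean_target} over the captured values.
#' @export
window_capture <- function(events, trials, task = task_params(),
                           target_pre_s = 2, target_post_s = 2) {
  cap <- function(lo, hi) {
    vapply(seq_len(nrow(trials)), function(i) {
      sel <- events$t_s >= lo[i] & events$t_s <= hi[i]
      if (any(sel)) max(events$height[sel]) else NA_real_
    }, numeric(1))
  }
  ctrl <- cap(trials$t_cue_s - task$pre_task_s, trials$t_cue_s)
  targ <- cap(trials$t_pt_start_s - target_pre_s,
              trials$t_pt_start_s + target_post_s)
  list(control = ctrl, target = targ,
       mean_control = if (all(is.na(ctrl))) NA_real_ else mean(ctrl, na.rm = TRUE),
       mean_target = if (all(is.na(targ))) NA_real_ else mean(targ, na.rm = TRUE))
}

#' Mean activity before and after the grand-average reaction time
#'
#' Realigns the trial windows to the session's grand-average RT (anchor +
#' mean RT) and averages the trace over \code{[-pre_s, 0)} and
#' \code{(0, +post_s]}.
#'
#' @param windows a \code{trial_windows} object (PT-start anchored).
#' @param rts reaction times (s) of the responded trials.
#' @param trace trace name.
#' @param pre_s,post_s averaging extent (s).
#' @return list: \code{pre_mean}, \code{post_mean}, \code{grand_rt_s}.
#' @export
rt_aligned_average <- function(windows, rts, trace = names(windows$traces)[1],
                               pre_s = 2, post_s = 2) {
  rts <- rts[!is.na(rts)]
  if (!length(rts)) return(list(pre_mean = NA_real_, post_mean = NA_real_,
                                grand_rt_s = NA_real_))
  grand <- mean(rts)
  tw <- windows$traces[[trace]]
  rel <- tw$offsets_s - grand
  pre_cols <- which(rel >= -pre_s & rel < 0)
  post_cols <- which(rel > 0 & rel <= post_s)
  if (!length(pre_cols) || !length(post_cols))
    stop("rt_aligned_average: window does not cover the RT-aligned extent")
  list(pre_mean = mean(tw$mat[, pre_cols]),
       post_mean = mean(tw$mat[, post_cols]),
       grand_rt_s = grand)
}

#' Cross-correlation lag between two traces
#'
#' Pearson correlation over the overlapping segment at every integer-sample
#' lag in \code{[-max_lag_s, +max_lag_s]}. A positive reported lag means
#' \code{y} follows \code{x}.
#'
#' @param x,y \code{time_series} at a common rate (resample first).
#' @param max_lag_s maximum lag magnitude (s).
#' @return list: \code{lag_s} at the correlation peak, \code{peak_r},
#'   \code{lags_s}, \code{r} (full curve).
#' @export
xcorr_lag <- function(x, y, max_lag_s) {
  if (abs(x$rate_hz / y$rate_hz - 1) > 1e-9)
    stop("xcorr_lag: traces must share a sampling rate (resample first)")
  rate <- x$rate_hz
  # clip to the common time span
  t_lo <- max(x$t0_s, y$t0_s)
  t_hi <- min(x$t0_s + ts_duration(x), y$t0_s + ts_duration(y))
  if (t_hi <= t_lo) stop("xcorr_lag: traces do not overlap in time")
  xi <- x$values[round((t_lo - x$t0_s) * rate) + seq_len(floor((t_hi - t_lo) * rate) + 1L)]
  yi <- y$values[round((t_lo - y$t0_s) * rate) + seq_len(floor((t_hi - t_lo) * rate) + 1L)]
  n <- min(length(xi), length(yi))
  xi <- xi[seq_len(n)]; yi <- yi[seq_len(n)]
  kmax <- min(round(max_lag_s * rate), n - 2L)
  lags <- (-kmax):kmax
  r <- vapply(lags, function(k) {
    if (k >= 0) stats::cor(xi[1:(n - k)], yi[(1 + k):n])
    else stats::cor(xi[(1 - k):n], yi[1:(n + k)])
  }, numeric(1))
  i <- which.max(r)
  list(lag_s = lags[i] / rate, peak_r = r[i], lags_s = lags / rate, r = r)
}
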