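#' Detect licks from piezo voltage
#'
#' A lick is a voltage excursion crossing either an upper or a lower
#' threshold once; crossings of either polarity within a refractory window
#' of the previous detected lick merge into that lick (the mechanical
#' deflection of one lick is biphasic).
#'
#' @param piezo a \code{time_series} of piezo voltage.
#' @param upper_v,lower_v thresholds; \code{upper_v > lower_v}.
#' @param refractory_s merge window after each detected lick (s); the
#'   default 30 ms sits below the minimum inter-lick interval of rodent
#'   licking (~100-150 ms).
#' @return numeric vector of lick times (s). If the sustained event rate
#'   exceeds 20 events/s the thresholds are likely inside the noise floor
#'   and attribute \code{noise_warning} is set to TRUE.
#' @export
detect_licks <- function(piezo, upper_v, lower_v, refractory_s = 0.03) {
  if (upper_v <= lower_v) stop("detect_licks: upper_v must exceed lower_v")
  v <- piezo$values
  n <- length(v)
  up <- which(v[-1] > upper_v & v[-n] <= upper_v) + 1L
  dn <- which(v[-1] < lower_v & v[-n] >= lower_v) + 1L
  cross <- sort(unique(c(up, dn)))
  if (!length(cross)) return(numeric(0))
  t_cross <- piezo$t0_s + (cross - 1) / piezo$rate_hz
  kept <- t_cross[1]
  for (tt in t_cross[-1])
    if (tt - kept[length(kept)] > refractory_s) kept <- c(kept, tt)
  out <- kept
  rate <- length(t_cross) / max(ts_duration(piezo), 1 / piezo$rate_hz)
  attr(out, "noise_warning") <- rate > 20
  if (rate > 20)
    warning("detect_licks: sustained crossing rate > 20/s; thresholds may sit in the noise floor")
  out
}

#' Extract trial-aligned windows from continuous traces
#'
#' Cuts every trace into per-trial segments aligned to the PT-start TTL
#' flag (texture at endpoint), spanning \code{[-pre_s, +post_s]} around it.
#' Off-grid event times round to the nearest sample; the anchor sample
#' index is identical across trials for each trace.
#'
#' @param trials a \code{trial_table}.
#' @param traces named list of \code{time_series}.
#' @param pre_s,post_s window extent before/after the anchor (s).
#' @param anchor "pt_start" (default) or "cue".
#' @return object of class \code{trial_windows}: per-trace list with the
#'   segment matrix \code{[n_trials, n_samples]}, offsets (s) relative to
#'   the anchor, and the anchor column index; plus the trial label table.
#' @export
align_streams <- function(trials, traces, pre_s, post_s,
                          anchor = c("pt_start", "cue")) {
  anchor <- match.arg(anchor)
  t_anchor <- if (anchor == "pt_start") trials$t_pt_start_s else trials$t_cue_s
  out <- list()
  for (nm in names(traces)) {
    ts <- traces[[nm]]
    n_pre <- round(pre_s * ts$rate_hz)
    n_post <- round(post_s * ts$rate_hz)
    centers <- round((t_anchor - ts$t0_s) * ts$rate_hz) + 1L
    lo <- centers - n_pre
    hi <- centers + n_post
    bad <- which(lo < 1L | hi > length(ts$values))
    if (length(bad))
      stop("align_streams: trials outside span of trace '", nm, "': ",
           paste(trials$trial_index[bad], collapse = ", "))
    mat <- t(vapply(seq_along(centers),
                    function(i) ts$values[lo[i]:hi[i]],
                    numeric(n_pre + n_post + 1L)))
    out[[nm]] <- list(mat = mat, rate_hz = ts$rate_hz,
                      offsets_s = (seq_len(n_pre + n_post + 1L) - 1L - n_pre) /
                        ts$rate_hz,
                      anchor_index = n_pre + 1L)
  }
  labels <- data.frame(trial_index = trials$trial_index,
                       texture = trials$texture, outcome = trials$outcome,
                       rt_s = trials$rt_s, stringsAsFactors = FALSE)
  if (!is.null(attr(trials, "phase"))) labels$phase <- attr(trials, "phase")
  structure(list(traces = out, labels = labels, anchor = anchor),
            class = "trial_windows")
}

#' Partition trial windows by label
#'
#' @param windows a \code{trial_windows} object.
#' @param by "texture", "outcome", or "phase".
#' @return named list of \code{trial_windows}, one per label value; group
#'   sizes sum to the original trial count and within-group order is
#'   preserved.
#' @export
segment_windows <- function(windows, by = c("texture", "outcome", "phase")) {
  by <- match.arg(by)
  if (!by %in% names(windows$labels))
    stop("segment_windows: label '", by, "' not present")
  labs <- windows$labels[[by]]
  groups <- unique(labs)
  out <- lapply(groups, function(g) {
    sel <- which(labs == g)
    tr <- lapply(windows$traces, function(tw) {
      tw$mat <- tw$mat[sel, , drop = FALSE]
      tw
    })
    structure(list(traces = tr, labels = windows$labels[sel, , drop = FALSE],
                   anchor = windows$anchor),
              class = "trial_windows")
  })
  names(out) <- groups
  out
}
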