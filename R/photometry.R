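#' Remove photobleaching trend
#'
#' Fits a line (default) or a single decaying exponential plus offset to the
#' whole trace by least squares and subtracts the fit. A failed exponential
#' fit falls back to the line with a warning.
#'
#' @param ts a \code{\link{time_series}}.
#' @param model "line" or "exponential".
#' @return detrended \code{time_series}; the fitted model is attached as
#'   attribute \code{detrend}.
#' @export
detrend <- function(ts, model = c("line", "exponential")) {
  model <- match.arg(model)
  x <- ts$values
  n <- length(x)
  if (n < 3L) stop("detrend: need at least 3 samples")
  t <- ts_times(ts) - ts$t0_s
  trend <- NULL
  coefs <- NULL
  if (model == "exponential") {
    # y = c + a * exp(-t / tau): profile (a, c) out by linear regression and
    # minimize the residual sum of squares over log(tau); robust even when
    # the input is an exact exponential (zero residual)
    rss <- function(log_tau) {
      basis <- exp(-t / exp(log_tau))
      sum(stats::resid(stats::lm(x ~ basis))^2)
    }
    opt <- tryCatch(
      stats::optimize(rss, interval = log(c(max(t) / 1e3, max(t) * 1e2))),
      error = function(e) NULL)
    if (!is.null(opt)) {
      tau <- exp(opt$minimum)
      fit <- stats::lm(x ~ exp(-t / tau))
      # degenerate tau (basis numerically constant) cannot beat a line
      if (all(is.finite(stats::coef(fit)))) {
        trend <- as.numeric(stats::fitted(fit))
        coefs <- c(c = unname(stats::coef(fit)[1]),
                   a = unname(stats::coef(fit)[2]), tau = tau)
      }
    }
    if (is.null(trend)) {
      warning("detrend: exponential fit failed; falling back to line")
      model <- "line"
    }
  }
  if (model == "line") {
    fit <- stats::lm(x ~ t)
    trend <- as.numeric(stats::fitted(fit))
    coefs <- stats::coef(fit)
  }
  out <- time_series(x - trend, ts$rate_hz, ts$t0_s)
  attr(out, "detrend") <- list(model = model, coef = coefs)
  out
}

#' Robust z-score (ZMAD)
#'
#' Centers a trace on its median and scales by the raw median absolute
#' deviation: \code{(x - median(x)) / median(|x - median(x)|)}. No Gaussian
#' consistency constant is applied by default.
#'
#' @param ts a \code{time_series}.
#' @param consistency multiplier applied to the MAD (set 1.4826 for a
#'   Gaussian-consistent scale; default 1).
#' @return \code{time_series} in ZMAD units, with the center and scale used
#'   attached as attribute \code{zmad}.
#' @export
zmad <- function(ts, consistency = 1) {
  x <- ts$values
  med <- stats::median(x)
  mad_raw <- stats::median(abs(x - med)) * consistency
  if (mad_raw == 0) stop("zmad: degenerate signal (MAD is zero)")
  out <- time_series((x - med) / mad_raw, ts$rate_hz, ts$t0_s)
  attr(out, "zmad") <- list(center = med, scale = mad_raw)
  out
}

#' Isosbestic subtraction
#'
#' Subtracts the ZMAD-scaled isosbestic channel from the ZMAD-scaled
#' activity channel to remove calcium-independent (motion/bleach) artifacts
#' shared between the two excitation wavelengths.
#'
#' @param act_z,iso_z \code{time_series} in ZMAD units, same grid.
#' @param flip_sign if TRUE compute iso - act instead.
#' @return a \code{time_series} of class \code{corrected_trace} with a
#'   \code{provenance} attribute recording the detrend/ZMAD parameters of
#'   both inputs.
#' @export
isosbestic_correct <- function(act_z, iso_z, flip_sign = FALSE) {
  if (length(act_z$values) != length(iso_z$values) ||
      act_z$rate_hz != iso_z$rate_hz)
    stop("isosbestic_correct: channels differ in length or rate")
  d <- act_z$values - iso_z$values
  if (flip_sign) d <- -d
  out <- time_series(d, act_z$rate_hz, act_z$t0_s)
  class(out) <- c("corrected_trace", class(out))
  attr(out, "provenance") <- list(act_detrend = attr(act_z, "detrend"),
                                  iso_detrend = attr(iso_z, "detrend"),
                                  act_zmad = attr(act_z, "zmad"),
                                  iso_zmad = attr(iso_z, "zmad"),
                                  flip_sign = flip_sign)
  out
}

#' Full photometry correction chain
#'
#' detrend -> ZMAD -> isosbestic subtraction on both channels of a session.
#'
#' @param session a \code{\link{photometry_session}}.
#' @param model detrend model, "line" or "exponential".
#' @param consistency MAD consistency constant (see \code{\link{zmad}}).
#' @return a \code{corrected_trace}.
#' @export
photometry_correct <- function(session, model = "line", consistency = 1) {
  act_z <- zmad(detrend(session$act, model), consistency)
  iso_z <- zmad(detrend(session$iso, model), consistency)
  isosbestic_correct(act_z, iso_z)
}
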