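#' Direct least-squares ellipse fit
#'
#' Fits a conic constrained to be an ellipse (4AC - B^2 > 0) to a set of
#' points by the numerically stable direct least-squares formulation, then
#' converts to geometric parameters. Exact (to numerical precision) on
#' noise-free points sampled from any ellipse.
#'
#' @param points numeric matrix \code{[n, 2]} of (x, y); n >= 5, not
#'   collinear.
#' @param weights optional non-negative per-point weights.
#' @return list of class \code{ellipse_fit}: \code{center} (px),
#'   \code{a} >= \code{b} (semi-axes, px), \code{angle} (rad, major-axis
#'   direction), \code{area} = pi a b (px^2).
#' @export
fit_ellipse <- function(points, weights = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 5L) stop("fit_ellipse: need at least 5 points")
  x <- points[, 1]; y <- points[, 2]
  # center/scale for conditioning; undone analytically below
  mx <- mean(x); my <- mean(y)
  s <- max(stats::sd(x), stats::sd(y), 1e-12)
  u <- (x - mx) / s; v <- (y - my) / s
  D1 <- cbind(u^2, u * v, v^2)
  D2 <- cbind(u, v, 1)
  if (!is.null(weights)) {
    w <- sqrt(pmax(weights, 0))
    D1 <- D1 * w; D2 <- D2 * w
  }
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("fit_ellipse: degenerate point configuration"))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vec <- ev$vectors
  if (is.complex(vec)) {
    keep <- abs(Im(ev$values)) < 1e-8 * (1 + abs(Re(ev$values)))
    vec <- Re(vec); vec[, !keep] <- NA_real_
  }
  cond <- 4 * vec[1, ] * vec[3, ] - vec[2, ]^2
  ok <- which(is.finite(cond) & cond > 0)
  if (!length(ok)) stop("fit_ellipse: no elliptical solution (degenerate input)")
  a1 <- vec[, ok[1]]
  coefs <- c(a1, as.numeric(Tm %*% a1))        # A B C D E F in (u, v)
  # map conic back to original coordinates: u = (x - mx)/s, v = (y - my)/s
  A <- coefs[1] / s^2
  B <- coefs[2] / s^2
  C <- coefs[3] / s^2
  D <- coefs[4] / s - 2 * A * mx - B * my
  E <- coefs[5] / s - 2 * C * my - B * mx
  Fc <- coefs[6] + A * mx^2 + B * mx * my + C * my^2 -
    coefs[4] * mx / s - coefs[5] * my / s
  den <- B^2 - 4 * A * C
  x0 <- (2 * C * D - B * E) / den
  y0 <- (2 * A * E - B * D) / den
  F0 <- A * x0^2 + B * x0 * y0 + C * y0^2 + D * x0 + E * y0 + Fc
  if (F0 > 0) { A <- -A; B <- -B; C <- -C; F0 <- -F0 }
  if (F0 == 0) stop("fit_ellipse: degenerate conic")
  M2 <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  e2 <- eigen(M2, symmetric = TRUE)           # values decreasing
  if (any(e2$values <= 0)) stop("fit_ellipse: non-elliptical conic")
  semi <- sqrt(-F0 / e2$values)               # increasing: minor then major
  vmaj <- e2$vectors[, 2]                     # eigenvector of smaller value
  structure(list(center = c(x0, y0), a = semi[2], b = semi[1],
                 angle = atan2(vmaj[2], vmaj[1]) %% pi,
                 area = pi * semi[1] * semi[2]),
            class = "ellipse_fit")
}

#' Pupil-area series with blink interpolation
#'
#' Fits an ellipse to the eight pupil markers of every frame and thresholds
#' the fitted area: frames whose area exceeds the blink threshold (eyelid
#' closure drives the markers onto abnormally wide configurations) are
#' masked and replaced by linear interpolation between the nearest unmasked
#' neighbors; masked runs at the edges take the nearest valid value.
#'
#' @param frames a \code{\link{pupil_frames}}.
#' @param blink_threshold_px areas above this (px^2) are treated as blinks.
#' @param use_likelihood if TRUE, marker likelihoods weight the fit.
#' @return list: \code{area} (cleaned \code{time_series}, px^2, at the
#'   median frame rate), \code{raw_area} (pre-interpolation values),
#'   \code{blink_mask} (logical), \code{t_s} (frame timestamps).
#' @export
area_series <- function(frames, blink_threshold_px = 450,
                        use_likelihood = FALSE) {
  n <- length(frames$t_s)
  if (n < 2L) stop("area_series: need at least 2 frames")
  raw <- vapply(seq_len(n), function(i) {
    w <- if (use_likelihood && !is.null(frames$likelihood))
      frames$likelihood[i, ] else NULL
    fit_ellipse(frames$markers[i, , ], weights = w)$area
  }, numeric(1))
  mask <- raw > blink_threshold_px
  if (all(mask)) stop("area_series: all frames masked as blinks")
  cleaned <- raw
  if (any(mask)) {
    idx <- seq_len(n)
    cleaned[mask] <- stats::approx(idx[!mask], raw[!mask], xout = idx[mask],
                                   rule = 2)$y
  }
  rate <- 1 / stats::median(diff(frames$t_s))
  list(area = time_series(cleaned, rate, frames$t_s[1]),
       raw_area = raw, blink_mask = mask, t_s = frames$t_s)
}

# best rational approximation p/q to r with q <= max_den (exhaustive over q)
.rat_approx <- function(r, max_den = 1000L) {
  q <- seq_len(max_den)
  p <- round(r * q)
  err <- abs(r - p / q)
  i <- which(err <= min(err) + 1e-15)[1]
  c(p = p[i], q = q[i])
}

#' Resample a time series by rational-fraction approximation
#'
#' Approximates the rate ratio by the best fraction p/q with denominator at
#' most \code{max_den} and converts the rate with a polyphase FIR resampler.
#'
#' @param ts a \code{time_series}.
#' @param target_hz desired rate (> 0).
#' @param max_den largest allowed denominator of the rate ratio.
#' @return resampled \code{time_series} at rate \code{rate_hz * p / q}; the
#'   output duration is within one output sample of the input duration.
#' @export
resample_to <- function(ts, target_hz, max_den = 1000L) {
  if (target_hz <= 0) stop("resample_to: target_hz must be positive")
  if (abs(target_hz / ts$rate_hz - 1) < 1e-9)
    return(time_series(ts$values, target_hz, ts$t0_s))
  pq <- .rat_approx(target_hz / ts$rate_hz, max_den)
  # edge-replicate padding keeps the polyphase FIR from ringing at the ends
  pad <- min(length(ts$values), 60L)
  xp <- c(rep(ts$values[1], pad), ts$values,
          rep(ts$values[length(ts$values)], pad))
  out <- as.numeric(signal::resample(xp, pq[["p"]], pq[["q"]]))
  # normalize the per-phase DC gain of the polyphase filter so a constant
  # input resamples to the same constant
  gain <- as.numeric(signal::resample(rep(1, length(xp)), pq[["p"]], pq[["q"]]))
  out <- out / gain
  new_rate <- ts$rate_hz * pq[["p"]] / pq[["q"]]
  skip <- round(pad * pq[["p"]] / pq[["q"]])
  # keep the output span within one sample of the input duration
  n_keep <- min(length(out) - skip, floor(ts_duration(ts) * new_rate) + 1L)
  time_series(out[skip + seq_len(n_keep)], new_rate, ts$t0_s)
}

#' Express a trace as a percentage of a reference
#'
#' @param ts a \code{time_series}.
#' @param reference "max" (session maximum, the default) or "baseline".
#' @param baseline_value reference value when \code{reference = "baseline"}.
#' @return \code{time_series} in percent of the reference.
#' @export
normalize_percent <- function(ts, reference = c("max", "baseline"),
                              baseline_value = NULL) {
  reference <- match.arg(reference)
  ref <- if (reference == "max") max(ts$values) else baseline_value
  if (is.null(ref) || !is.finite(ref) || ref <= 0)
    stop("normalize_percent: reference must be a positive value")
  time_series(100 * ts$values / ref, ts$rate_hz, ts$t0_s)
}
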