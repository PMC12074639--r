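#!/usr/bin/env Rscript
# Pupillometry: fit an ellipse to the eight pupil markers of every video
# frame, remove blinks (fitted area > 450 px^2) by interpolation, resample
# the cleaned area to the photometry rate, normalize it to the session
# maximum, and cross-correlate it with the corrected calcium trace to
# estimate how far pupil dilation lags axonal calcium activity.

library(senphys)

study_dir <- "results/study"
paths <- sort(list.files(study_dir, pattern = "^session_[0-9]+$",
                         full.names = TRUE))

rows <- lapply(paths, function(p) {
  b <- read_session(p)
  frames <- read_marker_csv(paste0(p, "_markers.csv"))
  ar <- area_series(frames, blink_threshold_px = 450)
  session <- photometry_session(b$traces$iso, b$traces$act, b$trials)
  corr <- photometry_correct(session)
  area_rs <- resample_to(ar$area, corr$rate_hz)
  xc <- xcorr_lag(corr, area_rs, max_lag_s = 2)
  pct <- normalize_percent(ar$area, "max")
  data.frame(session = b$params$session, stage = b$params$stage,
             n_frames = length(frames$t_s), n_blinks = sum(ar$blink_mask),
             mean_area_px2 = mean(ar$area$values),
             mean_area_pct = mean(pct$values),
             pupil_lag_s = xc$lag_s, peak_r = xc$peak_r,
             generator_lag_s = b$params$pupil_lag_s)
})
tab <- do.call(rbind, rows)

write.csv(tab, "results/pupil_metrics.csv", row.names = FALSE)
print(tab, digits = 3)
cat("\nNote: the measured calcium->pupil lag combines the generative delay\n")
cat("with the low-pass smearing of the pupil response, so it exceeds the\n")
cat("pure delay parameter, as it does for a real pupil.\n")
cat("wrote results/pupil_metrics.csv\n")
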