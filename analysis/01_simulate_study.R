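#!/usr/bin/env Rscript
# Generate the synthetic learning study that all downstream analyses consume:
# seven sessions (Shaping -> five Learning sessions -> Reward) of 150 Go/NoGo
# trials each, with two-channel photometry, pupil marker frames, and a piezo
# lick trace per session. Everything is written as plain-text bundles under
# results/study/ so later scripts only touch serialized data.

library(senphys)

seed <- 1L
out_dir <- "results/study"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

task <- task_params()                 # 150 trials, 2 s PT, 0.5 s grace
curve <- learning_curve_params()      # default learning trajectory
sig <- signal_model_params()          # photometry + pupil generative model

study <- simulate_study(task, curve, sig, seed = seed)

for (i in seq_along(study$sessions)) {
  s <- study$sessions[[i]]
  bundle <- session_bundle(
    trials = s$trials,
    traces = list(act = s$photometry$act, iso = s$photometry$iso,
                  piezo = s$piezo),
    params = list(seed = seed, session = i, stage = s$stage,
                  true_mean_amp = mean(s$truth$photometry$trial_amp),
                  pupil_lag_s = s$truth$pupil$lag_s))
  write_session(bundle, file.path(out_dir, sprintf("session_%02d", i)))
  write_marker_csv(s$pupil,
                   file.path(out_dir, sprintf("session_%02d_markers.csv", i)))
  cat(sprintf("session %d (%s): %d trials, %d photometry samples, %d frames\n",
              i, s$stage, nrow(s$trials), length(s$photometry$act$values),
              length(s$pupil$t_s)))
}

jsonlite::write_json(study$design, file.path(out_dir, "design.json"),
                     auto_unbox = TRUE, digits = NA, na = "null")
cat("designed expert session:", study$design$expert_session_index, "\n")
cat("study written to", out_dir, "\n")
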