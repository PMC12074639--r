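#!/usr/bin/env Rscript
# Behavioral scoring: detect licks from the piezo voltage, score every trial
# into Hit/Miss/FA/CR under the grace-period rule, compute per-session
# signal-detection metrics (hit rate, FA rate, d', bias) and reaction times,
# and classify when the subject reaches the expert criterion (hit rate >=
# 0.80 and FA rate <= 0.30 on two consecutive sessions).

library(senphys)

study_dir <- "results/study"
task <- task_params()
paths <- sort(list.files(study_dir, pattern = "^session_[0-9]+$",
                         full.names = TRUE))
stopifnot(length(paths) > 0)

rows <- lapply(paths, function(p) {
  b <- read_session(p)
  licks <- suppressWarnings(detect_licks(b$traces$piezo, 0.5, -0.5))
  scored <- score_outcomes(b$trials, lick_times = as.numeric(licks),
                           task = task)
  counts <- outcome_counts(scored)
  reward <- b$params$stage == "Reward"
  sdt <- if (!reward) sdt_metrics(counts) else
    list(hit_rate = NA, fa_rate = NA, d_prime = NA, bias = NA)
  rt <- reaction_times(scored)
  data.frame(session = b$params$session, stage = b$params$stage,
             n_licks = length(licks), hit = counts$hit, miss = counts$miss,
             fa = counts$fa, cr = counts$cr,
             hit_rate = sdt$hit_rate, fa_rate = sdt$fa_rate,
             d_prime = sdt$d_prime, bias = sdt$bias,
             mean_rt_s = rt$mean_rt_s)
})
tab <- do.call(rbind, rows)

cls <- classify_expert(tab$hit_rate, tab$fa_rate,
                       is_shaping = tab$stage == "Shaping",
                       is_reward = tab$stage == "Reward")
tab$phase <- cls$phase

dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/behavior_metrics.csv", row.names = FALSE)
print(tab[, c("session", "stage", "phase", "hit_rate", "fa_rate",
              "d_prime", "mean_rt_s")], digits = 3)
cat("\nexpert reached at session:", cls$expert_index, "\n")
cat("wrote results/behavior_metrics.csv\n")
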