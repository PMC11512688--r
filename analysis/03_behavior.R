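#!/usr/bin/env Rscript
# Score parent alternating gaze from the coded event logs (first minute
# discarded, infant-object-infant sequences with each look capped at 2 s)
# and estimate inter-rater reliability of the metric from a simulated
# secondary coder on 25% of the sessions.
#
# Usage: Rscript analysis/03_behavior.R [jitter_sd]

suppressPackageStartupMessages(library(mseeg))

args <- commandArgs(trailingOnly = TRUE)
jitter_sd <- if (length(args) >= 1) as.numeric(args[1]) else 0.25

data_dir <- "results/cohort"
logs <- list.files(data_dir, pattern = "_gaze\\.csv$", full.names = TRUE)
if (!length(logs)) stop("run analysis/01_simulate.R first")

gaze <- do.call(rbind, lapply(logs, function(f) {
  log <- read.csv(f)
  agd <- alternating_gaze_duration(log)
  data.frame(subject = sub("_gaze\\.csv$", "", basename(f)),
             gaze_duration = agd$duration, n_sequences = agd$n_sequences)
}))
write.csv(gaze, "results/gaze_summary.csv", row.names = FALSE)
cat(sprintf("alternating gaze over %d dyads: median %.1f s (range %.1f-%.1f)\n",
            nrow(gaze), median(gaze$gaze_duration),
            min(gaze$gaze_duration), max(gaze$gaze_duration)))

# secondary coder on a 25% subsample (at least 5 dyads for a stable ICC)
set.seed(42)
second <- sample(logs, max(5, ceiling(length(logs) / 4)))
ratings <- t(sapply(second, function(f) {
  log <- read.csv(f)
  c(alternating_gaze_duration(log)$duration,
    alternating_gaze_duration(generate_coder_pair(log, jitter_sd))$duration)
}))
icc <- icc_two_way_random(ratings)
cat(sprintf("inter-rater ICC(2,1) with %.2f s boundary jitter: %.2f [%.2f, %.2f]\n",
            jitter_sd, icc$icc, icc$lower, icc$upper))
write.csv(data.frame(icc = icc$icc, lower = icc$lower, upper = icc$upper,
                     n_dyads = icc$n),
          "results/gaze_icc.csv", row.names = FALSE)
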