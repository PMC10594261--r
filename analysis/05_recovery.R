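#!/usr/bin/env Rscript
# Parameter-recovery simulation: replicate cohorts with the crude-model CAI
# slopes injected as truth (0.54 / 0.82 / 0.22), refit the crude mixed model
# and report bias and CI coverage per outcome.

source("analysis/_common.R")
seed <- arg_seed()
reps <- 25L

truth <- c(depression = 0.54, anxiety = 0.82, loneliness = 0.22)
est <- matrix(NA_real_, reps, 3, dimnames = list(NULL, names(truth)))
covered <- matrix(NA, reps, 3, dimnames = list(NULL, names(truth)))
for (r in seq_len(reps)) {
  cfg <- recovery_config(n_participants = 500, seed = seed * 10000L + r)
  rows <- suppressMessages(build_long_table(generate_cohort(cfg)))
  for (o in names(truth)) {
    cr <- coef_row(fit_mixed_model(rows, o, "crude"))
    est[r, o] <- cr$estimate
    covered[r, o] <- cr$ci_low <= truth[o] && truth[o] <= cr$ci_high
  }
}

tab <- data.frame(
  outcome = names(truth), truth = unname(truth),
  mean_estimate = colMeans(est),
  bias = colMeans(est) - truth,
  mc_se = apply(est, 2, sd) / sqrt(reps),
  ci_coverage = colMeans(covered)
)
print(tab, digits = 3, row.names = FALSE)
write.csv(tab, file.path(results_dir(), "recovery.csv"), row.names = FALSE)
cat(sprintf("\n%d replicates at n = 500; bias within Monte-Carlo error and\n", reps))
cat("coverage near the nominal 95% indicate an unbiased pipeline.\n")
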