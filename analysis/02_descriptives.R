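#!/usr/bin/env Rscript
# Descriptive comparisons across chronicity groups: demographics (Table-1
# style) and mean cumulative CAI per period (Table-2 style), with chi-squared
# and ANOVA F-tests.

source("analysis/_common.R")
cohort <- load_cohort()

chron <- compute_chronicity(
  cohort$prepandemic_waves,
  cohort$participants[, c("participant_id",
                          paste0("lifetime_", disorder_names()))])
write.csv(chron, file.path(results_dir(), "chronicity.csv"), row.names = FALSE)
cat("chronicity groups:\n")
print(table(chron$group))

cai <- compute_cai(cohort$pandemic_waves)
d <- merge(cai[cai$eligible, ], chron[, c("participant_id", "group")],
           by = "participant_id")
cat("\nmean cumulative CAI by chronicity group and period:\n")
tab2 <- aggregate(cai ~ group + period, d, function(x) c(mean = mean(x), sd = sd(x)))
tab2 <- do.call(data.frame, tab2)
names(tab2) <- c("group", "period", "mean", "sd")
print(tab2, digits = 3)
for (p in 1:3) {
  ft <- compare_groups_descriptive(d$cai[d$period == p], d$group[d$period == p],
                                   "continuous")
  cat(sprintf("period %d: F(%d, %d) = %.2f, p = %.2g\n",
              p, ft$df, ft$df2, ft$statistic, ft$p_value))
}
write.csv(tab2, file.path(results_dir(), "table2_cai_by_chronicity.csv"),
          row.names = FALSE)

age_t <- compare_groups_descriptive(
  merge(cohort$participants, chron)$age,
  merge(cohort$participants, chron)$group, "continuous")
cat(sprintf("\nage by group: F = %.2f, p = %.2g\n", age_t$statistic, age_t$p_value))
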