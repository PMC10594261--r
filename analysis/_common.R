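# Shared settings for the numbered analysis scripts. Each script is a thin
# driver over the caindex package; all computation lives in R/.

suppressMessages(library(caindex))

arg_seed <- function(default = 1L) {
  args <- commandArgs(trailingOnly = TRUE)
  i <- which(args == "--seed")
  if (length(i) && length(args) > i) as.integer(args[i + 1]) else default
}

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

cohort_paths <- function() {
  d <- file.path("results", "cohort")
  list(participants = file.path(d, "participants.csv"),
       prepandemic_waves = file.path(d, "prepandemic_waves.csv"),
       pandemic_waves = file.path(d, "pandemic_waves.csv"))
}

load_cohort <- function() {
  p <- cohort_paths()
  if (!file.exists(p$participants)) {
    stop("run analysis/01_simulate.R first (no cohort under results/cohort)")
  }
  read_cohort_csvs(p)
}
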