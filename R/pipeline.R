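#' Read and validate a run configuration
#'
#' A run configuration is a YAML (or already-parsed list) with either a
#' `generate` block (arguments for [generator_config()]; `seed` mandatory)
#' or an `external_data` block (paths to `participants`, `prepandemic_waves`
#' and `pandemic_waves` CSVs) -- exactly one of the two -- plus optional
#' `weight_table` (CSV path), `tiers` (subset of [model_tiers()]) and
#' `sensitivity` (logical; run both sensitivity analyses).
#'
#' @param config path to a YAML file, or a list.
#' @return validated list of class `"run_config"`.
#' @export
read_run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  has_gen <- !is.null(cfg$generate)
  has_ext <- !is.null(cfg$external_data)
  if (has_gen == has_ext) {
    stop("run config: exactly one of 'generate' or 'external_data' must be set")
  }
  if (has_gen && is.null(cfg$generate$seed)) {
    stop("run config: 'generate' mode requires a seed")
  }
  if (has_ext) {
    need <- c("participants", "prepandemic_waves", "pandemic_waves")
    miss <- setdiff(need, names(cfg$external_data))
    if (length(miss)) {
      stop("run config: external_data missing paths: ",
           paste(miss, collapse = ", "))
    }
  }
  if (is.null(cfg$tiers)) cfg$tiers <- model_tiers()
  if (!all(cfg$tiers %in% model_tiers())) {
    stop("run config: unknown model tier(s): ",
         paste(setdiff(cfg$tiers, model_tiers()), collapse = ", "))
  }
  if (is.null(cfg$sensitivity)) cfg$sensitivity <- FALSE
  structure(cfg, class = c("run_config", "list"))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

write_stage_csv <- function(df, dir, file) {
  path <- file.path(dir, file)
  utils::write.csv(df, path, row.names = FALSE)
  message(sprintf("  wrote %s (%d rows)", file, nrow(df)))
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate (or load) -> instrument scoring -> CAI construction
#' -> chronicity classification -> mixed models -> descriptive tables, and
#' writes every stage output as CSV plus a JSON run manifest (seed, config
#' hash, package version, md5 of every output). Identical configuration and
#' seed give identical outputs and manifest hashes.
#'
#' @param config a run configuration (path, list, or `run_config`).
#' @param out_dir output directory (created if needed).
#' @return the manifest (invisibly), with all stage results attached as
#'   attribute `"results"`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- if (!is.null(cfg$weight_table)) read_weight_table(cfg$weight_table)
       else canonical_weight_table()

  message("stage simulate/load:")
  cohort <- stage("simulate", {
    if (!is.null(cfg$generate)) {
      gen_args <- cfg$generate
      gen_args$n_participants <- gen_args$n_participants %||% 500
      do.call(generator_config, gen_args) |> generate_cohort(weights = w)
    } else {
      read_cohort_csvs(cfg$external_data)
    }
  })
  write_stage_csv(cohort$participants, out_dir, "participants.csv")
  write_stage_csv(cohort$prepandemic_waves, out_dir, "prepandemic_waves.csv")
  write_stage_csv(cohort$pandemic_waves, out_dir, "pandemic_waves.csv")

  message("stage score:")
  scores <- stage("score", score_wave_instruments(cohort$pandemic_waves))
  write_stage_csv(scores$waves, out_dir, "instrument_scores.csv")
  write_stage_csv(scores$alphas, out_dir, "cronbach_alpha.csv")

  message("stage cai:")
  cai <- stage("cai", compute_cai(cohort$pandemic_waves, w))
  elig <- filter_eligible(cai)
  write_stage_csv(cai, out_dir, "cai_scores.csv")
  message(sprintf("  eligibility: %d participants kept, %d excluded",
                  length(unique(elig$participant_id)), attr(elig, "n_excluded")))

  message("stage chronicity:")
  chron <- stage("chronicity", compute_chronicity(
    cohort$prepandemic_waves,
    cohort$participants[, c("participant_id",
                            paste0("lifetime_", disorder_names()))]))
  write_stage_csv(chron, out_dir, "chronicity.csv")

  message("stage fit:")
  rows <- stage("fit", build_long_table(cohort, cai, chron))
  models <- stage("fit", {
    res <- list()
    for (o in outcome_names()) {
      res[[o]] <- lapply(stats::setNames(cfg$tiers, cfg$tiers),
                         function(tr) fit_mixed_model(rows, o, tr))
    }
    res
  })
  t3 <- do.call(rbind, lapply(outcome_names(), function(o) {
    do.call(rbind, lapply(cfg$tiers, function(tr) {
      fx <- models[[o]][[tr]]$fixed
      cbind(outcome = o, tier = tr, fx)
    }))
  }))
  write_stage_csv(t3, out_dir, "table3_models.csv")

  tab1 <- stage("fit", descriptives_table(cohort, chron))
  write_stage_csv(tab1, out_dir, "table1_descriptives.csv")
  tab2 <- stage("fit", cai_by_chronicity_table(cai, chron))
  write_stage_csv(tab2, out_dir, "table2_cai_by_chronicity.csv")

  sens <- NULL
  if (isTRUE(cfg$sensitivity)) {
    message("stage sensitivity:")
    sens <- stage("sensitivity", {
      lt <- cohort$participants[, c("participant_id",
                                    paste0("lifetime_", disorder_names()))]
      list(
        disorder = lapply(stats::setNames(outcome_names(), outcome_names()),
                          function(o) sensitivity_disorder_interactions(rows, lt, o)),
        alternative = run_alternative_cai_models(cohort, chron, w, cfg$tiers)
      )
    })
    sd_tab <- do.call(rbind, lapply(outcome_names(), function(o) {
      fx <- sens$disorder[[o]]$fixed
      cbind(outcome = o, reference = sens$disorder[[o]]$reference_disorder, fx)
    }))
    write_stage_csv(sd_tab, out_dir, "sensitivity_disorder_interactions.csv")
    write_stage_csv(sens$alternative$comparison, out_dir,
                    "sensitivity_alternative_cai.csv")
  }

  manifest <- list(
    package = "caindex",
    version = as.character(utils::packageVersion("caindex")),
    created = "run",  # no timestamp: manifests of identical runs are identical
    seed = if (!is.null(cfg$generate)) cfg$generate$seed else NA,
    config_hash = hash_object(unclass(cfg)),
    n_participants = nrow(cohort$participants),
    n_eligible = length(unique(elig$participant_id)),
    outputs = file_hashes(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  attr(manifest, "results") <- list(cohort = cohort, cai = cai, chron = chron,
                                    rows = rows, models = models, sens = sens)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

hash_object <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

file_hashes <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$"))
  as.list(stats::setNames(unname(tools::md5sum(file.path(dir, files))), files))
}

#' Score instrument items in a wave table
#'
#' Applies the QIDS, BAI and loneliness scorers to the synthesized item
#' responses of each wave (columns `q1..q16`, `b1..b21`, `l1..l6`) and
#' reports per-subperiod Cronbach's alpha for each instrument. When item
#' columns are absent (items were not synthesized), the stored totals are
#' passed through and alphas are NA.
#'
#' @param pandemic_waves wave table.
#' @return list with `waves` (ids, stored totals and item-derived totals)
#'   and `alphas` (instrument x subperiod).
#' @export
score_wave_instruments <- function(pandemic_waves) {
  pw <- pandemic_waves
  out <- pw[, c("participant_id", "wave_index", "date", "subperiod",
                "qids_total", "bai_total", "lonely_total")]
  have_items <- all(paste0("q", 1:16) %in% names(pw))
  if (have_items) {
    qm <- as.matrix(pw[, paste0("q", 1:16)])
    bm <- as.matrix(pw[, paste0("b", 1:21)])
    lm_ <- as.matrix(pw[, paste0("l", 1:6)])
    out$qids_scored <- as.numeric(score_qids(qm))
    out$bai_scored <- as.numeric(score_bai(bm))
    out$lonely_scored <- as.numeric(score_loneliness(lm_))
    alphas <- do.call(rbind, lapply(1:3, function(p) {
      sel <- pw$subperiod == p
      a <- function(m) if (sum(sel) >= 3) tryCatch(cronbach_alpha(m[sel, ]),
                                                   error = function(e) NA_real_)
           else NA_real_
      lp <- matrix(as.integer(lm_[sel, ] == "yes" | lm_[sel, ] == "more_or_less"),
                   ncol = 6)
      # positive items reversed before alpha, matching the scorer
      lp[, 4:6] <- matrix(as.integer(lm_[sel, 4:6] != "yes"), ncol = 3)
      data.frame(subperiod = p,
                 qids = a(qm), bai = a(bm),
                 loneliness = if (sum(sel) >= 3)
                   tryCatch(cronbach_alpha(lp), error = function(e) NA_real_)
                 else NA_real_)
    }))
  } else {
    alphas <- data.frame(subperiod = 1:3, qids = NA_real_, bai = NA_real_,
                         loneliness = NA_real_)
  }
  list(waves = out, alphas = alphas)
}

descriptives_table <- function(cohort, chron) {
  p <- merge(cohort$participants, chron[, c("participant_id", "group")],
             by = "participant_id")
  by_g <- split(p, p$group)
  fmt_n <- vapply(by_g, nrow, integer(1))
  age_t <- compare_groups_descriptive(p$age, p$group, "continuous")
  sex_t <- compare_groups_descriptive(p$gender, p$group, "categorical")
  edu_t <- compare_groups_descriptive(p$education, p$group, "categorical")
  par_t <- compare_groups_descriptive(p$partner, p$group, "categorical")
  data.frame(
    variable = c("n", "age_mean", "age_sd", "female_pct", "partner_pct",
                 "education_high_pct", "test_statistic", "test_p"),
    rbind(
      fmt_n,
      vapply(by_g, function(d) mean(d$age), numeric(1)),
      vapply(by_g, function(d) stats::sd(d$age), numeric(1)),
      vapply(by_g, function(d) 100 * mean(d$gender == "female"), numeric(1)),
      vapply(by_g, function(d) 100 * mean(d$partner == "yes"), numeric(1)),
      vapply(by_g, function(d) 100 * mean(d$education == "high"), numeric(1)),
      c(age_t$statistic, sex_t$statistic, edu_t$statistic, par_t$statistic),
      c(age_t$p_value, sex_t$p_value, edu_t$p_value, par_t$p_value)
    )
  )
}

cai_by_chronicity_table <- function(cai, chron) {
  d <- merge(cai, chron[, c("participant_id", "group")], by = "participant_id")
  do.call(rbind, lapply(1:3, function(p) {
    dp <- d[d$period == p & d$eligible, ]
    stats_g <- vapply(split(dp$cai, dp$group), function(x)
      c(mean = mean(x), sd = stats::sd(x), n = length(x)), numeric(3))
    ft <- compare_groups_descriptive(dp$cai, dp$group, "continuous")
    data.frame(period = p, group = colnames(stats_g),
               mean = stats_g["mean", ], sd = stats_g["sd", ],
               n = stats_g["n", ],
               F_statistic = ft$statistic, df1 = ft$df, df2 = ft$df2,
               p_value = ft$p_value, row.names = NULL)
  }))
}

#' Read a cohort from external CSV files
#'
#' @param paths named list with `participants`, `prepandemic_waves`,
#'   `pandemic_waves` CSV paths (schema as written by [run_pipeline()]).
#' @return a `synthetic_cohort`-shaped list.
#' @export
read_cohort_csvs <- function(paths) {
  part <- utils::read.csv(paths$participants, stringsAsFactors = FALSE)
  for (cl in grep("^lifetime_", names(part), value = TRUE)) {
    part[[cl]] <- as.logical(part[[cl]])
  }
  pre <- utils::read.csv(paths$prepandemic_waves, stringsAsFactors = FALSE)
  pw <- utils::read.csv(paths$pandemic_waves, stringsAsFactors = FALSE)
  pw$date <- as.Date(pw$date)
  if (!"subperiod" %in% names(pw)) pw$subperiod <- assign_subperiod(pw$date)
  structure(list(participants = part, prepandemic_waves = pre,
                 pandemic_waves = pw, cai = NULL, true_effects = NULL,
                 config = NULL),
            class = "synthetic_cohort")
}

#' Summarise a completed pipeline run
#'
#' Renders the stage outputs of a run directory into a plain-markdown
#' report: cohort counts, eligibility, model tables per outcome, and (when
#' truth is known from a generator manifest) recovery diagnostics. Missing
#' outputs are listed, not fatal.
#'
#' @param out_dir a directory written by [run_pipeline()].
#' @param truth optional named vector of true CAI slopes per outcome, for
#'   recovery diagnostics.
#' @return character vector of report lines (also written to `report.md`).
#' @export
summarize_run <- function(out_dir, truth = NULL) {
  lines <- c("# Pipeline run summary", "")
  man_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(man_path)) {
    lines <- c(lines, "Missing artifact: manifest.json")
  } else {
    man <- jsonlite::read_json(man_path)
    lines <- c(lines, sprintf("- package %s %s, seed %s", man$package,
                              man$version, man$seed),
               sprintf("- participants: %s, eligible: %s",
                       man$n_participants, man$n_eligible), "")
  }
  expect <- c("participants.csv", "cai_scores.csv", "chronicity.csv",
              "table1_descriptives.csv", "table2_cai_by_chronicity.csv",
              "table3_models.csv")
  missing <- expect[!file.exists(file.path(out_dir, expect))]
  if (length(missing)) {
    lines <- c(lines, "Missing artifacts:", paste0("- ", missing), "")
  }
  t3_path <- file.path(out_dir, "table3_models.csv")
  if (file.exists(t3_path)) {
    t3 <- utils::read.csv(t3_path)
    for (o in unique(t3$outcome)) {
      lines <- c(lines, sprintf("## Models: %s", o), "")
      sub <- t3[t3$outcome == o, ]
      lines <- c(lines, "tier | term | estimate | 95% CI | p",
                 "---- | ---- | -------- | ------ | --")
      lines <- c(lines, sprintf("%s | %s | %.3f | %.3f..%.3f | %.3g",
                                sub$tier, sub$term, sub$estimate,
                                sub$ci_low, sub$ci_high, sub$p_value), "")
      if (!is.null(truth) && o %in% names(truth)) {
        est <- sub$estimate[sub$term == "cai" & sub$tier == "crude"][1]
        lines <- c(lines, sprintf(
          "Recovery: true CAI slope %.3f, crude estimate %.3f, bias %.3f",
          truth[[o]], est, est - truth[[o]]), "")
      }
    }
  }
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(lines)
}
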