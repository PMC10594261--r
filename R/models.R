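#' Build the period-level long analysis table
#'
#' One row per eligible participant and period with at least one observed
#' wave. Outcomes are the mean of the observed wave scores in the period;
#' the cumulative CAI is the time-varying predictor; the pre-pandemic mean
#' of each instrument (across attended pre-pandemic waves from 2006 onwards)
#' and the demographic covariates complete the row. Joins are validated: an
#' outcome row without a matching CAI row is an error, and row counts in and
#' out are reported via `message()`.
#'
#' @param cohort a `synthetic_cohort` (or a list with `participants`,
#'   `prepandemic_waves`, `pandemic_waves` in the same layout).
#' @param cai_scores output of [compute_cai()]; computed from the cohort's
#'   pandemic waves when `NULL`.
#' @param chronicity output of [compute_chronicity()]; computed from the
#'   cohort when `NULL`.
#' @return data frame with columns `participant_id`, `period`,
#'   `period_code` (factor 0/1/2), `cai`, `depression`, `anxiety`,
#'   `loneliness`, `chronicity_group`, `age`, `gender`, `education`,
#'   `partner`, `n_waves`, `pre_depression`, `pre_anxiety`,
#'   `pre_loneliness`.
#' @export
build_long_table <- function(cohort, cai_scores = NULL, chronicity = NULL) {
  pw <- cohort$pandemic_waves
  if (is.null(cai_scores)) {
    cai_scores <- if (!is.null(cohort$cai)) cohort$cai else compute_cai(pw)
  }
  cai_scores <- filter_eligible(cai_scores)
  if (is.null(chronicity)) {
    chronicity <- compute_chronicity(
      cohort$prepandemic_waves,
      cohort$participants[, c("participant_id",
                              paste0("lifetime_", disorder_names()))]
    )
  }

  # period outcome means over observed waves
  pw <- pw[pw$participant_id %in% unique(cai_scores$participant_id), ,
           drop = FALSE]
  key <- interaction(pw$participant_id, pw$subperiod, drop = TRUE)
  per <- data.frame(
    participant_id = as.vector(tapply(pw$participant_id, key, `[`, 1L)),
    period = as.integer(tapply(pw$subperiod, key, `[`, 1L)),
    depression = as.numeric(tapply(pw$qids_total, key, mean)),
    anxiety = as.numeric(tapply(pw$bai_total, key, mean)),
    loneliness = as.numeric(tapply(pw$lonely_total, key, mean))
  )

  ix <- match(paste(per$participant_id, per$period),
              paste(cai_scores$participant_id, cai_scores$period))
  if (anyNA(ix)) {
    stop("consistency error: ", sum(is.na(ix)),
         " outcome row(s) have no matching CAI score")
  }
  per$cai <- cai_scores$cai[ix]
  per$n_waves <- cai_scores$n_waves[ix]

  # pre-pandemic means
  prew <- cohort$prepandemic_waves
  prew <- prew[prew$year >= 2006, , drop = FALSE]
  fid <- factor(prew$participant_id)
  pre <- data.frame(
    participant_id = as.numeric(levels(fid)),
    pre_depression = as.numeric(tapply(prew$qids_total, fid, mean)),
    pre_anxiety = as.numeric(tapply(prew$bai_total, fid, mean)),
    pre_loneliness = as.numeric(tapply(prew$lonely_total, fid, mean))
  )

  out <- merge(per, pre, by = "participant_id", all.x = TRUE)
  out <- merge(out,
               chronicity[, c("participant_id", "chronicity_pct", "group")],
               by = "participant_id", all.x = TRUE)
  names(out)[names(out) == "group"] <- "chronicity_group"
  out <- merge(out,
               cohort$participants[, c("participant_id", "age", "gender",
                                       "education", "partner")],
               by = "participant_id", all.x = TRUE)
  if (nrow(out) != nrow(per)) {
    stop("consistency error: joins changed the row count (", nrow(per),
         " -> ", nrow(out), ")")
  }
  out$period_code <- factor(out$period - 1L, levels = 0:2)
  out$gender <- factor(out$gender, levels = c("male", "female"))
  out$education <- factor(out$education, levels = c("low", "middle", "high"))
  out$partner <- factor(out$partner, levels = c("yes", "no"))
  out <- out[order(out$participant_id, out$period), ]
  rownames(out) <- NULL
  message(sprintf(
    "build_long_table: %d rows from %d eligible participants (%d excluded by the two-subperiod filter)",
    nrow(out), length(unique(out$participant_id)),
    attr(cai_scores, "n_excluded")))
  out
}

model_tiers <- function() c("crude", "adjusted", "interaction")

tier_formula <- function(outcome, tier, adjust_all_prepandemic = FALSE) {
  pre_term <- if (adjust_all_prepandemic) {
    "pre_depression + pre_anxiety + pre_loneliness"
  } else {
    paste0("pre_", outcome)
  }
  rhs <- switch(tier,
    crude = paste("cai +", pre_term),
    adjusted = paste("cai + chronicity_group +", pre_term,
                     "+ age + gender + education + partner + period_code + n_waves"),
    interaction = paste("cai * chronicity_group +", pre_term,
                        "+ age + gender + education + partner + period_code + n_waves"),
    stop("unknown model tier: ", tier)
  )
  stats::as.formula(paste(outcome, "~", rhs, "+ (1 | participant_id)"))
}

#' Fit a linear mixed model for one outcome and tier
#'
#' Linear mixed model with a participant-level random intercept, estimated
#' by REML ([lme4::lmer()]); incomplete periods contribute their observed
#' rows. Tiers: `crude` (cumulative CAI plus the outcome's pre-pandemic
#' mean), `adjusted` (adds chronicity group, age, gender, education, partner
#' status, period coded 0/1/2, and waves attended per period), and
#' `interaction` (adds CAI x chronicity group). Wald 95% confidence
#' intervals and normal-approximation p-values are reported; convergence or
#' singularity messages are captured on the result, never silently dropped.
#'
#' @param rows long table from [build_long_table()].
#' @param outcome one of [outcome_names()].
#' @param tier `"crude"`, `"adjusted"` or `"interaction"`.
#' @param adjust_all_prepandemic adjust for all three pre-pandemic means
#'   instead of the outcome's own.
#' @return object of class `"cai_model_result"`: list with `outcome`,
#'   `tier`, `fixed` (term, estimate, se, ci_low, ci_high, p_value),
#'   `varcomp` (random-intercept and residual variances), `n_obs`,
#'   `n_participants`, `converged`, `messages`, and the underlying `fit`.
#' @export
fit_mixed_model <- function(rows, outcome = outcome_names(),
                            tier = model_tiers(),
                            adjust_all_prepandemic = FALSE) {
  outcome <- match.arg(outcome)
  tier <- match.arg(tier)
  n_part <- length(unique(rows$participant_id))
  if (n_part < 30L) {
    warning("fit_mixed_model: only ", n_part,
            " participants; estimates may be unstable")
  }
  fm <- tier_formula(outcome, tier, adjust_all_prepandemic)
  need <- all.vars(fm)
  if (tier != "crude" && anyNA(rows[, setdiff(need, outcome)])) {
    stop("fit_mixed_model: missing covariate values in the adjusted tiers")
  }

  msgs <- character(0)
  fit <- withCallingHandlers(
    tryCatch(
      lme4::lmer(fm, data = rows, REML = TRUE),
      error = function(e) e
    ),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    }
  )
  if (inherits(fit, "error")) {
    stop("fit_mixed_model: estimation failed for ", outcome, "/", tier, ": ",
         conditionMessage(fit))
  }
  converged <- !any(grepl("failed to converge", msgs, fixed = TRUE))

  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  fixed <- data.frame(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    ci_low = unname(est - stats::qnorm(0.975) * se),
    ci_high = unname(est + stats::qnorm(0.975) * se),
    p_value = unname(2 * stats::pnorm(-abs(z))),
    stringsAsFactors = FALSE
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- c(
    intercept_var = vc$vcov[vc$grp == "participant_id"][1],
    residual_var = vc$vcov[vc$grp == "Residual"][1]
  )
  structure(list(
    outcome = outcome, tier = tier, fixed = fixed, varcomp = varcomp,
    n_obs = nrow(stats::model.frame(fit)), n_participants = n_part,
    converged = converged, messages = msgs, fit = fit
  ), class = "cai_model_result")
}

#' @export
print.cai_model_result <- function(x, digits = 3, ...) {
  cat(sprintf("Linear mixed model (%s tier), outcome: %s\n", x$tier, x$outcome))
  cat(sprintf("  %d observations, %d participants; converged: %s\n",
              x$n_obs, x$n_participants, x$converged))
  fx <- x$fixed
  fx[, -1] <- lapply(fx[, -1], round, digits = digits)
  print(fx, row.names = FALSE)
  cat(sprintf("  Random-intercept variance %.3f, residual variance %.3f\n",
              x$varcomp["intercept_var"], x$varcomp["residual_var"]))
  if (length(x$messages)) cat("  notes:", paste(unique(x$messages), collapse = "; "), "\n")
  invisible(x)
}

#' Extract one coefficient from a model result
#'
#' @param result a `cai_model_result`.
#' @param term coefficient name (e.g. `"cai"`).
#' @return one-row data frame with estimate, CI and p-value.
#' @export
coef_row <- function(result, term = "cai") {
  row <- result$fixed[result$fixed$term == term, , drop = FALSE]
  if (!nrow(row)) stop("term not in model: ", term)
  row
}

#' Descriptive group comparison across chronicity groups
#'
#' Pearson chi-squared test (no continuity correction) for categorical
#' variables; one-way ANOVA F-test for continuous ones.
#'
#' @param values vector of per-participant values.
#' @param groups chronicity group labels (same length).
#' @param kind `"categorical"` or `"continuous"`.
#' @return list with `statistic`, `df` (and `df2` for ANOVA), `p_value`,
#'   `method`.
#' @export
compare_groups_descriptive <- function(values, groups,
                                       kind = c("categorical", "continuous")) {
  kind <- match.arg(kind)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(factor(groups[ok]))
  if (nlevels(groups) < 2L) stop("need at least 2 non-empty groups")
  if (kind == "categorical") {
    tab <- table(values, groups)
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expd == 0)) {
      stop("degenerate table: an expected cell count is zero")
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = unname(ct$p.value), method = "Pearson chi-squared")
  } else {
    fit <- stats::aov(values ~ groups)
    s <- summary(fit)[[1]]
    list(statistic = s$`F value`[1], df = s$Df[1], df2 = s$Df[2],
         p_value = s$`Pr(>F)`[1], method = "one-way ANOVA F")
  }
}

#' Disorder-specific CAI interactions (sensitivity analysis)
#'
#' Refits the mixed model with lifetime indicators for each of the seven
#' disorders and their interactions with CAI. A preliminary fit including
#' all disorder terms selects as reference the disorder whose CAI
#' interaction coefficient is closest to zero; the final model omits that
#' disorder's terms. Disorders with zero prevalence are dropped with a
#' warning. No multiplicity correction is applied across the 18 interaction
#' tests (3 outcomes x 6 non-reference disorders); this caveat is recorded
#' in the result metadata.
#'
#' @param rows long table from [build_long_table()].
#' @param lifetime data frame with `participant_id` and
#'   `lifetime_<disorder>` columns.
#' @param outcome one of [outcome_names()].
#' @return a `cai_model_result` with extra fields `reference_disorder`,
#'   `disorders_used`, `interaction_terms`, `multiplicity_note`.
#' @export
sensitivity_disorder_interactions <- function(rows, lifetime,
                                              outcome = outcome_names()) {
  outcome <- match.arg(outcome)
  dis <- disorder_names()
  ltcols <- paste0("lifetime_", dis)
  miss <- setdiff(ltcols, names(lifetime))
  if (length(miss)) stop("lifetime table missing columns: ",
                         paste(miss, collapse = ", "))
  d <- merge(rows, lifetime[, c("participant_id", ltcols)],
             by = "participant_id", sort = FALSE)
  for (cl in ltcols) d[[cl]] <- as.numeric(d[[cl]])

  prevalent <- dis[vapply(ltcols, function(cl) any(d[[cl]] > 0), logical(1))]
  dropped <- setdiff(dis, prevalent)
  if (length(dropped)) {
    warning("dropping zero-prevalence disorder(s): ",
            paste(dropped, collapse = ", "))
  }
  if (!length(prevalent)) stop("no prevalent disorders to model")

  terms_for <- function(ds) {
    paste(c(paste0("lifetime_", ds),
            paste0("cai:lifetime_", ds)), collapse = " + ")
  }
  base <- paste0(outcome, " ~ cai + pre_", outcome, " + ")
  prelim_fm <- stats::as.formula(paste0(base, terms_for(prevalent),
                                        " + (1 | participant_id)"))
  prelim <- suppressMessages(suppressWarnings(
    lme4::lmer(prelim_fm, data = d, REML = TRUE)))
  fe <- lme4::fixef(prelim)
  inter <- fe[grepl("^cai:lifetime_", names(fe))]
  ref <- sub("^cai:lifetime_", "", names(inter)[which.min(abs(inter))])

  final_dis <- setdiff(prevalent, ref)
  fm <- stats::as.formula(paste0(base, terms_for(final_dis),
                                 " + (1 | participant_id)"))
  res <- fit_mixed_model_formula(fm, d, outcome, "disorder_interaction")
  res$reference_disorder <- ref
  res$disorders_used <- prevalent
  res$interaction_terms <- paste0("cai:lifetime_", final_dis)
  res$multiplicity_note <- paste(
    "18 interaction effects tested across outcomes without multiple-testing",
    "correction; isolated significant interactions may be chance findings.")
  res
}

# shared fitting/reporting backend for non-tier formulas
fit_mixed_model_formula <- function(fm, data, outcome, tier_label) {
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(fm, data = data, REML = TRUE),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, trimws(conditionMessage(m))); invokeRestart("muffleMessage")
    }
  )
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  fixed <- data.frame(
    term = names(est), estimate = unname(est), se = unname(se),
    ci_low = unname(est - stats::qnorm(0.975) * se),
    ci_high = unname(est + stats::qnorm(0.975) * se),
    p_value = unname(2 * stats::pnorm(-abs(est / se))),
    stringsAsFactors = FALSE
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    outcome = outcome, tier = tier_label, fixed = fixed,
    varcomp = c(intercept_var = vc$vcov[vc$grp == "participant_id"][1],
                residual_var = vc$vcov[vc$grp == "Residual"][1]),
    n_obs = nrow(stats::model.frame(fit)),
    n_participants = length(unique(data$participant_id)),
    converged = !any(grepl("failed to converge", msgs, fixed = TRUE)),
    messages = msgs, fit = fit
  ), class = "cai_model_result")
}

#' Refit all model tiers with the perceived-impact alternative CAI
#'
#' Recomputes the cumulative index with empirical per-type weights derived
#' from the perceived mental health impact regression
#' ([derive_impact_weights()]) and refits the three model tiers for each
#' outcome, returning main and alternative results side by side.
#'
#' @param cohort a `synthetic_cohort`.
#' @param chronicity output of [compute_chronicity()] (computed when `NULL`).
#' @param w weight table for the main index.
#' @param tiers subset of [model_tiers()] to fit.
#' @return list with `weights` (the empirical type weights), `main` and
#'   `alternative` (nested lists of `cai_model_result` by outcome and tier),
#'   and `comparison` (data frame of CAI slopes under both indices).
#' @export
run_alternative_cai_models <- function(cohort, chronicity = NULL,
                                       w = canonical_weight_table(),
                                       tiers = model_tiers()) {
  cai_main <- compute_cai(cohort$pandemic_waves, w)
  ts <- attr(cai_main, "type_scores")
  types <- exposure_types()
  fid <- factor(ts$participant_id)
  cum_type <- data.frame(participant_id = as.numeric(levels(fid)))
  for (ty in types) {
    cum_type[[ty]] <- as.numeric(tapply(ts[[ty]], fid, sum))
  }
  impact <- score_perceived_impact(
    as.matrix(cohort$participants[, paste0("impact_", 1:9)]))
  ix <- match(cum_type$participant_id, cohort$participants$participant_id)
  w_alt <- derive_impact_weights(cum_type[, types], impact[ix])

  cai_alt <- compute_cai(cohort$pandemic_waves, w, type_weights = w_alt)
  if (stats::sd(cai_alt$cai) < 1e-10) {
    stop("degenerate predictor: alternative CAI has (near-)zero variance")
  }

  rows_main <- suppressMessages(build_long_table(cohort, cai_main, chronicity))
  rows_alt <- suppressMessages(build_long_table(cohort, cai_alt, chronicity))

  fit_all <- function(rows) {
    res <- list()
    for (o in outcome_names()) {
      res[[o]] <- lapply(stats::setNames(tiers, tiers), function(tr) {
        fit_mixed_model(rows, o, tr)
      })
    }
    res
  }
  main <- fit_all(rows_main)
  alternative <- fit_all(rows_alt)

  comparison <- do.call(rbind, lapply(outcome_names(), function(o) {
    do.call(rbind, lapply(tiers, function(tr) {
      data.frame(outcome = o, tier = tr,
                 cai_main = coef_row(main[[o]][[tr]], "cai")$estimate,
                 cai_alternative = coef_row(alternative[[o]][[tr]], "cai")$estimate)
    }))
  }))
  list(weights = w_alt, main = main, alternative = alternative,
       comparison = comparison)
}
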