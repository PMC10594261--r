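#' Outcome names used throughout the package
#' @export
outcome_names <- function() c("depression", "anxiety", "loneliness")

#' True fixed effects injected by the synthetic cohort generator
#'
#' Per outcome (depression on the QIDS scale, anxiety on the BAI scale,
#' loneliness on the De Jong Gierveld scale) the generator produces
#' period-mean outcomes from
#' \deqn{y_{ip} = \alpha + \tau_p + \beta\,\mathrm{CAI}_{ip} + \delta_{g(i)}
#'   + \theta_{g(i)}\,\mathrm{CAI}_{ip} + \lambda\,\bar y^{pre}_i + b_i +
#'   e_{ip}}
#' with participant random intercept \eqn{b_i} and period-level residual
#' \eqn{e_{ip}}. The default CAI slopes are 0.54 / 0.82 / 0.22 outcome
#' points per CAI point; chronicity offsets, interactions and period offsets
#' default to modest, plausible values and are zeroed by the recovery preset
#' [recovery_config()].
#'
#' @param beta_cai named 3-vector: outcome change per CAI point.
#' @param delta_chronicity per-outcome named 3-vectors (`remitted`,
#'   `low_medium`, `high`): group offsets vs. no-lifetime.
#' @param theta_interaction per-outcome named 3-vectors: CAI-slope modifiers
#'   by group.
#' @param lambda_prepandemic named 3-vector: slope on the pre-pandemic mean
#'   score of the same outcome.
#' @param tau_period per-outcome named 2-vectors (`period2`, `period3`):
#'   period offsets vs. period 1.
#' @param alpha named 3-vector of intercepts.
#' @param disorder_theta optional per-outcome named vectors (by
#'   [disorder_names()]): extra CAI-slope modifiers for lifetime carriers of
#'   specific disorders, used by the disorder-specific sensitivity analysis.
#' @return list of class `"true_effects"`.
#' @export
true_effects <- function(
    beta_cai = c(depression = 0.54, anxiety = 0.82, loneliness = 0.22),
    delta_chronicity = list(
      depression = c(remitted = 1.0, low_medium = 2.5, high = 4.5),
      anxiety    = c(remitted = 1.0, low_medium = 2.5, high = 5.0),
      loneliness = c(remitted = 0.3, low_medium = 0.6, high = 1.0)
    ),
    theta_interaction = list(
      depression = c(remitted = 0, low_medium = 0, high = 0),
      anxiety    = c(remitted = 0, low_medium = 0, high = 0),
      loneliness = c(remitted = 0, low_medium = 0, high = 0)
    ),
    lambda_prepandemic = c(depression = 0.5, anxiety = 0.5, loneliness = 0.5),
    tau_period = list(
      depression = c(period2 = -0.3, period3 = -0.5),
      anxiety    = c(period2 = -0.3, period3 = -0.5),
      loneliness = c(period2 = 0.1, period3 = 0.2)
    ),
    alpha = c(depression = 5, anxiety = 4, loneliness = 1.5),
    disorder_theta = NULL) {
  eff <- list(beta_cai = beta_cai, delta_chronicity = delta_chronicity,
              theta_interaction = theta_interaction,
              lambda_prepandemic = lambda_prepandemic,
              tau_period = tau_period, alpha = alpha,
              disorder_theta = disorder_theta)
  vals <- unlist(eff[!vapply(eff, is.null, logical(1))])
  if (!all(is.finite(vals))) stop("true_effects: all effects must be finite")
  for (o in outcome_names()) {
    stopifnot(o %in% names(beta_cai), o %in% names(alpha),
              o %in% names(lambda_prepandemic),
              o %in% names(delta_chronicity), o %in% names(theta_interaction),
              o %in% names(tau_period))
  }
  structure(eff, class = "true_effects")
}

#' Default per-wave endorsement probabilities of the 15 adversity items
#'
#' Chosen once to emulate a realistic exposure regime: common mild stressors
#' (changed daily activities, prolonged confinement, living alone), uncommon
#' severe ones (own diagnosis, bereavement, job loss). Item 3 (course of
#' COVID-19) is the probability of reporting any course; its severity levels
#' are governed by `item3_level_probs`.
#'
#' @export
default_item_probabilities <- function() {
  c(item_1 = 0.10, item_2 = 0.03, item_3 = 0.02, item_4 = 0.25,
    item_5 = 0.08, item_6 = 0.03, item_7 = 0.015, item_8 = 0.015,
    item_9 = 0.15, item_10 = 0.50, item_11 = 0.40, item_12 = 0.08,
    item_13 = 0.12, item_14 = 0.03, item_15 = 0.04)
}

#' Default pandemic wave schedule: 15 questionnaires, 5/4/6 per subperiod
#' @export
default_pandemic_wave_dates <- function() {
  as.Date(c(
    "2020-04-01", "2020-05-06", "2020-06-03", "2020-07-08", "2020-08-12",
    "2020-09-09", "2020-10-07", "2020-11-04", "2020-11-25",
    "2020-12-16", "2021-01-20", "2021-03-03", "2021-04-14", "2021-05-26",
    "2021-07-07"
  ))
}

#' Synthetic cohort generator configuration
#'
#' Bundles and validates every parameter of the generator. Defaults emulate
#' the observed cohort: ~1377 participants, age truncated-normal (mean
#' 56.84, s.d. 13.01 on 28.5--86), about 62% female, four chronicity strata
#' with an adversity-exposure gradient, six biennial pre-pandemic diagnostic
#' waves (2006--2016) and 15 pandemic waves across three calendar subperiods.
#'
#' @param n_participants cohort size.
#' @param chronicity_proportions named 4-vector over
#'   [chronicity_levels()], summing to 1.
#' @param age_mean,age_sd,age_min,age_max truncated-normal age distribution
#'   (years).
#' @param prepandemic_wave_years calendar years of diagnostic waves.
#' @param pandemic_wave_dates 15 dates within the pandemic window.
#' @param item_base_probabilities named per-wave endorsement probabilities
#'   for items 1..15 (reference stratum, multiplier 1).
#' @param item3_level_probs probabilities of mild/severe/hospitalised course
#'   given any course reported.
#' @param chronicity_odds_multipliers named 4-vector: per-stratum multiplier
#'   on every item's endorsement odds (the exposure gradient).
#' @param exposure_odds_scalar global scalar on all item odds; tuned by
#'   [calibrate_exposure_multiplier()].
#' @param wave_response_probability per-wave pandemic participation
#'   probability in (0, 1].
#' @param prepandemic_response_probability per-wave pre-pandemic attendance
#'   probability in (0, 1].
#' @param female_prop,partner_prop,education_probs per-stratum demographic
#'   composition (columns/entries in stratum order).
#' @param true_effects a [true_effects()] object.
#' @param noise_sds list with named 3-vectors `intercept` (participant
#'   random-intercept s.d. per outcome) and `residual` (period-level residual
#'   s.d. per outcome), in outcome units.
#' @param prepandemic_outcome_means per-outcome named 4-vectors of stratum
#'   means for the pre-pandemic instrument scores.
#' @param bounded_outcomes clip generated outcomes to the instrument ranges
#'   (off by default: truncation biases slope recovery).
#' @param synthesize_items also synthesize instrument item responses per wave
#'   (consistent with the wave's outcome score) to exercise the scorers.
#' @param seed integer RNG seed (mandatory).
#' @return validated list of class `"generator_config"`.
#' @export
generator_config <- function(
    n_participants = 1377,
    chronicity_proportions = c(none = 0.25, remitted = 0.20,
                               low_medium = 0.30, high = 0.25),
    age_mean = 56.84, age_sd = 13.01, age_min = 28.5, age_max = 86,
    prepandemic_wave_years = seq(2006, 2016, by = 2),
    pandemic_wave_dates = default_pandemic_wave_dates(),
    item_base_probabilities = default_item_probabilities(),
    item3_level_probs = c(mild = 0.7, severe = 0.2, hospitalised = 0.1),
    chronicity_odds_multipliers = default_chronicity_multipliers(),
    exposure_odds_scalar = 1,
    wave_response_probability = 0.8,
    prepandemic_response_probability = 0.9,
    female_prop = c(none = 0.55, remitted = 0.60, low_medium = 0.64, high = 0.68),
    partner_prop = c(none = 0.76, remitted = 0.72, low_medium = 0.66, high = 0.58),
    education_probs = matrix(
      c(0.12, 0.38, 0.50,
        0.15, 0.40, 0.45,
        0.20, 0.42, 0.38,
        0.26, 0.44, 0.30),
      nrow = 3, dimnames = list(c("low", "middle", "high"), chronicity_levels())
    ),
    true_effects = caindex::true_effects(),
    noise_sds = list(
      intercept = c(depression = 2, anxiety = 2, loneliness = 2),
      residual  = c(depression = 2, anxiety = 2, loneliness = 2)
    ),
    prepandemic_outcome_means = list(
      depression = c(none = 3, remitted = 5, low_medium = 8, high = 11),
      anxiety    = c(none = 3, remitted = 5, low_medium = 9, high = 14),
      loneliness = c(none = 1, remitted = 1.5, low_medium = 2, high = 2.5)
    ),
    bounded_outcomes = FALSE,
    synthesize_items = TRUE,
    seed) {
  if (missing(seed)) stop("generator_config: 'seed' is mandatory")
  cfg <- as.list(environment())
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

#' Default per-stratum multipliers on adversity-item odds
#'
#' Fixed once at design time so that the analytic expected period-1 CAI
#' gradient across strata reproduces the observed high-vs-none mean ratio
#' (6.37 / 5.27) near the calibrated exposure regime; intermediate strata
#' interpolate geometrically.
#'
#' @export
default_chronicity_multipliers <- function() {
  c(none = 1, remitted = 1.14, low_medium = 1.30, high = 1.48)
}

validate_generator_config <- function(cfg) {
  cp <- cfg$chronicity_proportions
  if (length(cp) != 4L || abs(sum(cp) - 1) > 1e-9 || any(cp < 0)) {
    stop("invalid configuration field 'chronicity_proportions': must be 4 ",
         "non-negative values summing to 1")
  }
  probs <- c(cfg$item_base_probabilities, cfg$item3_level_probs,
             cfg$wave_response_probability, cfg$prepandemic_response_probability,
             cfg$female_prop, cfg$partner_prop, as.numeric(cfg$education_probs))
  if (any(probs < 0 | probs > 1)) {
    stop("invalid configuration field: all probabilities must lie in [0, 1]")
  }
  if (cfg$wave_response_probability <= 0) {
    stop("invalid configuration field 'wave_response_probability': must be in (0, 1]")
  }
  if (length(cfg$item_base_probabilities) != 15L) {
    stop("invalid configuration field 'item_base_probabilities': need 15 items")
  }
  if (abs(sum(cfg$item3_level_probs) - 1) > 1e-9) {
    stop("invalid configuration field 'item3_level_probs': must sum to 1")
  }
  d <- as.Date(cfg$pandemic_wave_dates)
  win <- subperiod_window()
  if (any(d < win[1] | d > win[2])) {
    stop("invalid configuration field 'pandemic_wave_dates': dates must lie in ",
         format(win[1]), "..", format(win[2]))
  }
  if (any(cfg$chronicity_odds_multipliers < 0) ||
      length(cfg$chronicity_odds_multipliers) != 4L) {
    stop("invalid configuration field 'chronicity_odds_multipliers'")
  }
  if (cfg$exposure_odds_scalar < 0) {
    stop("invalid configuration field 'exposure_odds_scalar': must be >= 0")
  }
  if (cfg$age_min >= cfg$age_max || cfg$age_sd <= 0) {
    stop("invalid configuration field: age bounds/sd inconsistent")
  }
  if (!inherits(cfg$true_effects, "true_effects")) {
    stop("invalid configuration field 'true_effects'")
  }
  sds <- c(cfg$noise_sds$intercept, cfg$noise_sds$residual)
  if (length(sds) != 6L || any(sds < 0) || !all(is.finite(sds))) {
    stop("invalid configuration field 'noise_sds'")
  }
  if (!(is.numeric(cfg$seed) && length(cfg$seed) == 1L && is.finite(cfg$seed))) {
    stop("invalid configuration field 'seed'")
  }
  invisible(cfg)
}

#' Parameter-recovery preset
#'
#' The recovery design places all systematic outcome variation in the CAI
#' and the pre-pandemic mean (chronicity offsets, CAI x chronicity
#' interactions and period offsets are zero), so the crude-tier mixed model
#' is the data-generating model and its slope estimator is unbiased for the
#' injected truth. Random-intercept and residual s.d. are 2 outcome points.
#'
#' @param n_participants cohort size (default 500).
#' @param seed RNG seed.
#' @param true_effects effects to inject; defaults to
#'   [recovery_true_effects()].
#' @param ... further arguments passed to [generator_config()].
#' @export
recovery_config <- function(n_participants = 500, seed,
                            true_effects = recovery_true_effects(), ...) {
  generator_config(n_participants = n_participants,
                   true_effects = true_effects, seed = seed, ...)
}

#' @describeIn recovery_config [true_effects()] with zero chronicity offsets,
#'   interactions and period offsets; `...` overrides (e.g. `beta_cai`,
#'   `disorder_theta`) are passed through.
#' @export
recovery_true_effects <- function(...) {
  zero3 <- c(remitted = 0, low_medium = 0, high = 0)
  args <- list(
    delta_chronicity = list(depression = zero3, anxiety = zero3,
                            loneliness = zero3),
    theta_interaction = list(depression = zero3, anxiety = zero3,
                             loneliness = zero3),
    tau_period = list(depression = c(period2 = 0, period3 = 0),
                      anxiety = c(period2 = 0, period3 = 0),
                      loneliness = c(period2 = 0, period3 = 0))
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(true_effects, args)
}

# truncated-normal draw via inverse CDF
rtruncnorm <- function(n, mean, sd, lo, hi) {
  stats::qnorm(stats::runif(n, stats::pnorm(lo, mean, sd),
                            stats::pnorm(hi, mean, sd)), mean, sd)
}

# sample() that does not treat a length-1 vector as 1:n
resample <- function(x, size = 1L) x[sample.int(length(x), size)]

# per-item endorsement probability after odds scaling (handles p = 0, 1)
scale_odds <- function(p, mult) {
  out <- p * mult / (1 - p + p * mult)
  out[rep_len(p, length(out)) >= 1] <- 1
  out
}

#' Generate a synthetic cohort
#'
#' Produces a participants table, a pre-pandemic diagnostic wave table and a
#' pandemic wave table with adversity-item responses and outcome scores.
#' Outcomes are generated directly on the period-mean scale from the
#' configured [true_effects()] (the quantity modelled downstream); every wave
#' in a period carries its period's outcome value, so the period mean of
#' observed waves reproduces it exactly. Instrument item responses are
#' additionally synthesized (approximately consistent with the wave score)
#' to exercise the scorers. Deterministic given `config$seed`.
#'
#' @param config a [generator_config()].
#' @param weights CAI weight table used to compute the true cumulative
#'   scores entering the outcome model.
#' @return list of class `"synthetic_cohort"`: `participants`,
#'   `prepandemic_waves`, `pandemic_waves`, precomputed `cai` scores, the
#'   `true_effects` used, and the `config`.
#' @export
generate_cohort <- function(config, weights = canonical_weight_table()) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_participants
  strata <- chronicity_levels()
  outs <- outcome_names()
  eff <- config$true_effects

  ## ---- participants ---------------------------------------------------------
  stratum <- factor(resample_strata(n, config$chronicity_proportions),
                    levels = strata)
  g_ix <- as.integer(stratum)
  age <- rtruncnorm(n, config$age_mean, config$age_sd,
                    config$age_min, config$age_max)
  gender <- ifelse(stats::runif(n) < config$female_prop[g_ix], "female", "male")
  partner <- ifelse(stats::runif(n) < config$partner_prop[g_ix], "yes", "no")
  education <- rownames(config$education_probs)[
    vapply(g_ix, function(g) sample.int(3L, 1L, prob = config$education_probs[, g]),
           integer(1))]
  dis <- disorder_names()
  primary <- rep(NA_character_, n)
  has_dx <- stratum != "none"
  primary[has_dx] <- dis[sample.int(7L, sum(has_dx), replace = TRUE,
                                    prob = c(0.35, 0.08, 0.15, 0.15, 0.12, 0.07, 0.08))]
  secondary <- rep(NA_character_, n)
  comorbid <- has_dx & stats::runif(n) < 0.25
  secondary[comorbid] <- vapply(primary[comorbid], function(p) resample(setdiff(dis, p)),
                                character(1))

  participants <- data.frame(
    participant_id = seq_len(n), age = age, gender = gender,
    education = education, partner = partner,
    chronicity_stratum = stratum, primary_disorder = primary,
    stringsAsFactors = FALSE
  )

  ## ---- pre-pandemic diagnostic waves ---------------------------------------
  years <- sort(config$prepandemic_wave_years)
  W <- length(years)
  att <- matrix(stats::runif(n * W) < config$prepandemic_response_probability, n, W)
  none_att <- rowSums(att) == 0
  att[none_att, 1L] <- TRUE
  # low_medium needs >= 2 attended waves for a percentage in (0, 50]
  lm_fix <- stratum == "low_medium" & rowSums(att) < 2L
  att[lm_fix, 1:2] <- TRUE

  dxw <- matrix(FALSE, n, W)  # primary-disorder current diagnosis by wave
  for (i in which(stratum %in% c("low_medium", "high"))) {
    k <- sum(att[i, ])
    half <- floor(k / 2)
    m <- if (stratum[i] == "low_medium") resample(seq_len(max(1L, half)))
         else resample(seq.int(half + 1L, k))
    dxw[i, resample(which(att[i, ]), m)] <- TRUE
  }

  prepan <- data.frame(
    participant_id = rep(seq_len(n), each = W),
    year = rep(years, times = n)
  )
  attended <- as.vector(t(att))
  prepan <- prepan[attended, , drop = FALSE]
  dx_flat <- as.vector(t(dxw))[attended]
  for (d in dis) {
    is_primary <- primary[prepan$participant_id] == d
    is_secondary <- secondary[prepan$participant_id] == d
    on <- dx_flat & (!is.na(is_primary) & is_primary)
    on2 <- dx_flat & (!is.na(is_secondary) & is_secondary) &
      stats::runif(nrow(prepan)) < 0.6
    prepan[[paste0("dx_", d)]] <- as.integer(on | on2)
  }
  for (d in dis) {
    ever_current <- tapply(prepan[[paste0("dx_", d)]],
                           factor(prepan$participant_id, levels = seq_len(n)),
                           function(x) any(x > 0))
    ever_current[is.na(ever_current)] <- FALSE
    lt <- ever_current | (!is.na(primary) & primary == d)
    participants[[paste0("lifetime_", d)]] <- as.logical(lt)
  }

  # pre-pandemic instrument scores: stratum-graded + participant RE + wave noise
  pre_mu <- config$prepandemic_outcome_means
  pre_re <- sapply(outs, function(o) stats::rnorm(n, 0, 1.2))
  maxes <- c(depression = 27, anxiety = 63, loneliness = 6)
  wave_sd <- c(depression = 2, anxiety = 2.5, loneliness = 0.8)
  for (o in outs) {
    base <- pre_mu[[o]][g_ix[prepan$participant_id]] +
      pre_re[prepan$participant_id, o] +
      stats::rnorm(nrow(prepan), 0, wave_sd[o])
    col <- c(depression = "qids_total", anxiety = "bai_total",
             loneliness = "lonely_total")[o]
    prepan[[col]] <- pmin(maxes[o], pmax(0, base))
  }
  rownames(prepan) <- NULL

  ## ---- pandemic waves: attendance and adversity items ----------------------
  dates <- sort(as.Date(config$pandemic_wave_dates))
  nw <- length(dates)
  sp_of_wave <- assign_subperiod(dates)
  att_p <- matrix(stats::runif(n * nw) < config$wave_response_probability, n, nw)
  pw <- data.frame(
    participant_id = rep(seq_len(n), each = nw),
    wave_index = rep(seq_len(nw), times = n),
    date = rep(dates, times = n),
    subperiod = rep(sp_of_wave, times = n)
  )
  pw <- pw[as.vector(t(att_p)), , drop = FALSE]
  rownames(pw) <- NULL
  m_row <- config$chronicity_odds_multipliers[g_ix[pw$participant_id]] *
    config$exposure_odds_scalar
  avail <- cbind(sp1 = tapply(weights$sp1, weights$item, `[`, 1L),
                 sp2 = tapply(weights$sp2, weights$item, `[`, 1L),
                 sp3 = tapply(weights$sp3, weights$item, `[`, 1L))
  p_base <- config$item_base_probabilities
  for (it in 1:15) {
    col <- paste0("item_", it)
    ok <- avail[it, pw$subperiod]
    p_it <- scale_odds(p_base[[it]], m_row)
    r <- ifelse(ok, as.integer(stats::runif(nrow(pw)) < p_it), NA_integer_)
    if (it == 3L) {
      lev <- findInterval(stats::runif(nrow(pw)),
                          cumsum(config$item3_level_probs), left.open = TRUE) + 1L
      r <- ifelse(!is.na(r) & r > 0L, lev, r)
    }
    pw[[col]] <- r
  }

  ## ---- true cumulative CAI and period-level outcomes -----------------------
  cai <- compute_cai(pw, weights)
  ids_in_cai <- unique(cai$participant_id)
  re_mat <- sapply(outs, function(o) stats::rnorm(n, 0, config$noise_sds$intercept[o]))
  pre_mean <- sapply(outs, function(o) {
    col <- c(depression = "qids_total", anxiety = "bai_total",
             loneliness = "lonely_total")[o]
    mn <- tapply(prepan[[col]], factor(prepan$participant_id, levels = seq_len(n)),
                 mean)
    as.numeric(mn)
  })

  lt_mat <- as.matrix(participants[paste0("lifetime_", dis)])
  y_period <- matrix(NA_real_, nrow(cai), length(outs),
                     dimnames = list(NULL, outs))
  id_c <- cai$participant_id
  g_c <- g_ix[id_c]
  for (o in outs) {
    delta <- c(0, eff$delta_chronicity[[o]])[g_c]
    theta <- c(0, eff$theta_interaction[[o]])[g_c]
    tau <- c(0, eff$tau_period[[o]])[cai$period]
    extra <- 0
    if (!is.null(eff$disorder_theta) && !is.null(eff$disorder_theta[[o]])) {
      dt <- eff$disorder_theta[[o]]
      extra <- as.numeric(lt_mat[id_c, paste0("lifetime_", names(dt)), drop = FALSE] %*%
                            as.numeric(dt)) * cai$cai
    }
    y <- eff$alpha[o] + tau + (eff$beta_cai[o] + theta) * cai$cai + delta +
      eff$lambda_prepandemic[o] * pre_mean[id_c, o] + re_mat[id_c, o] +
      stats::rnorm(nrow(cai), 0, config$noise_sds$residual[o]) + extra
    if (config$bounded_outcomes) y <- pmin(maxes[o], pmax(0, y))
    y_period[, o] <- y
  }

  # every wave carries its period's outcome value
  ckey <- paste(cai$participant_id, cai$period)
  wkey <- paste(pw$participant_id, pw$subperiod)
  ix <- match(wkey, ckey)
  pw$qids_total <- y_period[ix, "depression"]
  pw$bai_total <- y_period[ix, "anxiety"]
  pw$lonely_total <- y_period[ix, "loneliness"]

  if (isTRUE(config$synthesize_items)) {
    pw <- synthesize_instrument_items(pw)
  }

  ## ---- perceived-impact items ----------------------------------------------
  burden <- tapply(cai$cai, factor(cai$participant_id, levels = seq_len(n)),
                   max)
  burden[is.na(burden)] <- 0
  imp_mean <- pmin(5, pmax(1, 1 + 0.12 * as.numeric(burden) + stats::rnorm(n, 0, 0.5)))
  for (j in 1:9) {
    participants[[paste0("impact_", j)]] <-
      pmin(5L, pmax(1L, as.integer(round(imp_mean + stats::rnorm(n, 0, 0.7)))))
  }

  structure(list(
    participants = participants,
    prepandemic_waves = prepan,
    pandemic_waves = pw,
    cai = cai,
    true_effects = eff,
    config = config
  ), class = "synthetic_cohort")
}

# multinomial stratum assignment honouring the exact order of runif draws
resample_strata <- function(n, proportions) {
  chronicity_levels()[findInterval(stats::runif(n), cumsum(proportions),
                                   left.open = TRUE) + 1L]
}

# instrument item responses roughly consistent with the wave's outcome score
synthesize_instrument_items <- function(pw) {
  nr <- nrow(pw)
  rate_q <- pmin(1, pmax(0, pw$qids_total / 27))
  for (j in 1:16) {
    pw[[paste0("q", j)]] <- stats::rbinom(nr, 3L, rate_q)
  }
  rate_b <- pmin(1, pmax(0, pw$bai_total / 63))
  for (j in 1:21) {
    pw[[paste0("b", j)]] <- stats::rbinom(nr, 3L, rate_b)
  }
  rate_l <- pmin(1, pmax(0, pw$lonely_total / 6))
  pol <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  for (j in 1:6) {
    endorsed <- stats::runif(nr) < rate_l
    shade <- stats::runif(nr) < 0.3
    pw[[paste0("l", j)]] <- ifelse(
      endorsed, ifelse(shade, "more_or_less", if (pol[j]) "yes" else "no"),
      if (pol[j]) "no" else "yes"
    )
  }
  pw
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$participants), "participants;",
      nrow(x$prepandemic_waves), "pre-pandemic wave rows;",
      nrow(x$pandemic_waves), "pandemic wave rows\n")
  cat("Chronicity strata:\n")
  print(table(x$participants$chronicity_stratum))
  invisible(x)
}

#' Delete one subperiod of waves for a fraction of participants
#'
#' Exercises the two-subperiod eligibility filter: for a seeded random
#' subset of participants, all pandemic waves of one randomly chosen
#' observed subperiod are removed and the CAI scores are recomputed.
#'
#' @param cohort a `synthetic_cohort`.
#' @param fraction probability in `[0, 1)` that a participant loses one
#'   subperiod.
#' @param seed optional seed for the deletion draw (defaults to the current
#'   RNG stream).
#' @return the modified cohort.
#' @export
inject_missing_subperiods <- function(cohort, fraction, seed = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!(is.numeric(fraction) && length(fraction) == 1L &&
        fraction >= 0 && fraction < 1)) {
    stop("fraction must lie in [0, 1)")
  }
  if (fraction == 0) return(cohort)
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(cohort$pandemic_waves$participant_id)
  hit <- ids[stats::runif(length(ids)) < fraction]
  pw <- cohort$pandemic_waves
  drop <- rep(FALSE, nrow(pw))
  for (id in hit) {
    sel <- pw$participant_id == id
    sps <- unique(pw$subperiod[sel])
    sp_kill <- resample(sps)
    drop <- drop | (sel & pw$subperiod == sp_kill)
  }
  cohort$pandemic_waves <- pw[!drop, , drop = FALSE]
  rownames(cohort$pandemic_waves) <- NULL
  cohort$cai <- compute_cai(cohort$pandemic_waves)
  cohort
}
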