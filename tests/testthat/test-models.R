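test_that("period outcomes are means of observed waves with validated joins", {
  coh <- make_mini_cohort()
  rows <- suppressMessages(build_long_table(coh))
  p1 <- rows[rows$participant_id == 1 & rows$period == 1, ]
  expect_equal(p1$depression, (10 + 14) / 2)
  expect_equal(p1$anxiety, 21)
  expect_equal(p1$n_waves, 2L)
  expect_equal(p1$cai, 1)          # lives alone endorsed once in subperiod 1
  expect_equal(p1$pre_depression, 5)
  # no row for periods without observed waves
  expect_equal(rows$period[rows$participant_id == 1], c(1L, 2L))
  expect_equal(rows$period[rows$participant_id == 2], c(1L, 3L))
  expect_equal(as.character(rows$chronicity_group[rows$participant_id == 2][1]),
               "low_medium")
})

test_that("a complete cohort yields exactly participants x 3 period rows", {
  cfg <- generator_config(n_participants = 1000, seed = 5,
                          wave_response_probability = 1,
                          prepandemic_response_probability = 1)
  rows <- suppressMessages(build_long_table(generate_cohort(cfg)))
  expect_equal(nrow(rows), 3000)
})

test_that("noiseless data are recovered exactly by every tier", {
  zero <- c(depression = 0, anxiety = 0, loneliness = 0)
  eff <- true_effects(
    theta_interaction = list(
      depression = c(remitted = 0.1, low_medium = 0.2, high = 0.3),
      anxiety = c(remitted = 0.05, low_medium = 0.1, high = 0.2),
      loneliness = c(remitted = 0, low_medium = 0.05, high = 0.1))
  )
  cfg <- generator_config(n_participants = 400, seed = 5, true_effects = eff,
                          noise_sds = list(intercept = zero, residual = zero))
  rows <- suppressMessages(build_long_table(generate_cohort(cfg)))
  m <- fit_mixed_model(rows, "depression", "interaction")
  fx <- stats::setNames(m$fixed$estimate, m$fixed$term)
  expect_equal(unname(fx["cai"]), 0.54, tolerance = 1e-9)
  expect_equal(unname(fx["cai:chronicity_grouphigh"]), 0.3, tolerance = 1e-9)
  expect_equal(unname(fx["chronicity_grouphigh"]), 4.5, tolerance = 1e-9)
  expect_equal(unname(fx["pre_depression"]), 0.5, tolerance = 1e-9)
  crude <- fit_mixed_model(rows, "anxiety", "crude")
  # crude tier omits the interaction terms, so only zero-interaction outcomes
  # reproduce the slope; anxiety carries interactions here, depression check
  # above is the exact one. Confidence bounds must bracket the estimate.
  expect_true(all(crude$fixed$ci_low <= crude$fixed$estimate &
                  crude$fixed$estimate <= crude$fixed$ci_high))
})

test_that("with zero random-intercept variance the fit matches OLS", {
  zero <- c(depression = 0, anxiety = 0, loneliness = 0)
  cfg <- recovery_config(
    n_participants = 400, seed = 6,
    noise_sds = list(intercept = zero,
                     residual = c(depression = 2, anxiety = 2, loneliness = 2))
  )
  rows <- suppressMessages(build_long_table(generate_cohort(cfg)))
  for (o in outcome_names()) {
    m <- fit_mixed_model(rows, o, "crude")
    ols <- stats::lm(stats::as.formula(paste(o, "~ cai + pre_", o, sep = "")),
                     data = rows)
    expect_lt(max(abs(m$fixed$estimate - stats::coef(ols))), 1e-4)
    expect_lt(m$varcomp["intercept_var"], 0.2)
  }
})

test_that("crude tier is biased only when omitted chronicity drives outcomes", {
  reps <- 6
  bias_conf <- bias_clean <- numeric(reps)
  strong <- true_effects(delta_chronicity = list(
    depression = c(remitted = 2, low_medium = 6, high = 12),
    anxiety = c(remitted = 1, low_medium = 2.5, high = 5),
    loneliness = c(remitted = 0.3, low_medium = 0.6, high = 1)))
  for (r in seq_len(reps)) {
    cfg_c <- generator_config(n_participants = 800, seed = 700 + r,
                              true_effects = strong)
    rows_c <- suppressMessages(build_long_table(generate_cohort(cfg_c)))
    bias_conf[r] <- coef_row(fit_mixed_model(rows_c, "depression", "crude"))$estimate - 0.54
    cfg_u <- recovery_config(n_participants = 800, seed = 700 + r)
    rows_u <- suppressMessages(build_long_table(generate_cohort(cfg_u)))
    bias_clean[r] <- coef_row(fit_mixed_model(rows_u, "depression", "crude"))$estimate - 0.54
  }
  se_c <- stats::sd(bias_conf) / sqrt(reps)
  se_u <- stats::sd(bias_clean) / sqrt(reps)
  expect_gt(abs(mean(bias_conf)), 3 * se_c)   # confounding shifts the slope
  expect_lt(abs(mean(bias_clean)), 3 * se_u)  # clean design does not
})

test_that("descriptive comparisons reproduce hand-computed statistics", {
  vals <- rep(c("a", "b", "a", "b"), c(10, 20, 20, 10))
  grp <- rep(c("g1", "g2"), each = 30)
  res <- compare_groups_descriptive(vals, grp, "categorical")
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)  # chi-square 6.667
  expect_equal(res$df, 1)
  set.seed(9)
  f <- replicate(200, {
    compare_groups_descriptive(stats::rnorm(40), rep(letters[1:4], each = 10),
                               "continuous")$statistic
  })
  expect_gt(mean(f), 0.85)
  expect_lt(mean(f), 1.35)
  # an empty factor level yields a zero expected count
  expect_error(compare_groups_descriptive(
    factor(c("a", "b", "a", "b"), levels = c("a", "b", "c")),
    c("g1", "g1", "g2", "g2"), "categorical"), "degenerate")
  expect_error(compare_groups_descriptive(1:5, rep("g", 5), "continuous"),
               "2 non-empty groups")
})

test_that("disorder-interaction reference is the coefficient closest to zero", {
  zero <- c(depression = 0, anxiety = 0, loneliness = 0)
  # gad carries the smallest (zero) interaction and becomes the reference
  dtheta <- c(mdd = 0.3, dysthymia = 0.15, gad = 0, panic = 0.2,
              social_phobia = 0.25, agoraphobia = 0.1, ocd = 0.12)
  eff <- recovery_true_effects(disorder_theta = list(depression = dtheta,
                                                     anxiety = dtheta,
                                                     loneliness = dtheta))
  cfg <- generator_config(n_participants = 600, seed = 12, true_effects = eff,
                          noise_sds = list(intercept = zero, residual = zero))
  coh <- generate_cohort(cfg)
  rows <- suppressMessages(build_long_table(coh))
  lt <- coh$participants[, c("participant_id",
                             paste0("lifetime_", disorder_names()))]
  res <- sensitivity_disorder_interactions(rows, lt, "depression")
  expect_equal(res$reference_disorder, "gad")
  expect_match(res$multiplicity_note, "18 interaction")
  # noiseless data with a zero-effect reference are recovered exactly
  fx <- stats::setNames(res$fixed$estimate, res$fixed$term)
  expect_equal(unname(fx["cai:lifetime_mdd"]), 0.3, tolerance = 1e-6)
  expect_equal(unname(fx["cai:lifetime_social_phobia"]), 0.25, tolerance = 1e-6)
})

test_that("an injected social-phobia loneliness interaction is recovered", {
  reps <- 5
  est <- numeric(reps)
  eff <- recovery_true_effects(disorder_theta = list(
    loneliness = c(social_phobia = -0.14)))
  for (r in seq_len(reps)) {
    cfg <- recovery_config(n_participants = 700, seed = 900 + r,
                           true_effects = eff)
    coh <- generate_cohort(cfg)
    rows <- suppressMessages(build_long_table(coh))
    lt <- coh$participants[, c("participant_id",
                               paste0("lifetime_", disorder_names()))]
    res <- sensitivity_disorder_interactions(rows, lt, "loneliness")
    est[r] <- res$fixed$estimate[res$fixed$term == "cai:lifetime_social_phobia"]
  }
  mc_se <- stats::sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - (-0.14)), 3 * mc_se + 0.02)
})

test_that("alternative-CAI slopes satisfy the reparameterization identity", {
  zero <- c(depression = 0, anxiety = 0, loneliness = 0)
  cfg <- recovery_config(n_participants = 300, seed = 9,
                         noise_sds = list(intercept = zero, residual = zero))
  coh <- generate_cohort(cfg)
  k <- 2.5
  cai_k <- compute_cai(coh$pandemic_waves,
                       type_weights = stats::setNames(rep(k, 9), exposure_types()))
  rows_k <- suppressMessages(build_long_table(coh, cai_k))
  mk <- fit_mixed_model(rows_k, "depression", "crude")
  expect_equal(coef_row(mk)$estimate, 0.54 / k, tolerance = 1e-9)
  # zero weights are a degenerate predictor
  cai0 <- compute_cai(coh$pandemic_waves,
                      type_weights = stats::setNames(rep(0, 9), exposure_types()))
  expect_true(all(cai0$cai == 0))
})

test_that("impact-weighted models keep the sign of the main CAI effects", {
  cfg <- generator_config(n_participants = 500, seed = 77)
  coh <- generate_cohort(cfg)
  res <- run_alternative_cai_models(coh, tiers = "crude")
  expect_true(all(sign(res$comparison$cai_alternative) ==
                  sign(res$comparison$cai_main)))
  expect_length(res$weights, 9)
})
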