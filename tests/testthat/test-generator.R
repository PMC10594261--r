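test_that("generation is byte-identical under a fixed seed", {
  a <- generate_cohort(generator_config(n_participants = 80, seed = 7))
  b <- generate_cohort(generator_config(n_participants = 80, seed = 7))
  expect_identical(a$participants, b$participants)
  expect_identical(a$prepandemic_waves, b$prepandemic_waves)
  expect_identical(a$pandemic_waves, b$pandemic_waves)
  expect_identical(a$cai, b$cai)
  c2 <- generate_cohort(generator_config(n_participants = 80, seed = 8))
  expect_false(identical(a$pandemic_waves, c2$pandemic_waves))
})

test_that("configuration invariants are enforced with the field named", {
  expect_error(generator_config(n_participants = 10, seed = 1,
                                chronicity_proportions = c(0.5, 0.5, 0.1, 0.1)),
               "chronicity_proportions")
  expect_error(generator_config(n_participants = 10, seed = 1,
                                wave_response_probability = 0),
               "wave_response_probability")
  expect_error(generator_config(n_participants = 10, seed = 1,
                                pandemic_wave_dates = as.Date("2022-01-01")),
               "pandemic_wave_dates")
  expect_error(generator_config(n_participants = 10),
               "seed")
})

test_that("zero exposure probabilities give all-zero CAI", {
  cfg <- generator_config(
    n_participants = 60, seed = 2,
    item_base_probabilities = stats::setNames(rep(0, 15), paste0("item_", 1:15))
  )
  coh <- generate_cohort(cfg)
  expect_true(all(coh$cai$cai == 0))
})

test_that("cohort structure respects stratum and calendar invariants", {
  cfg <- generator_config(n_participants = 250, seed = 31)
  coh <- generate_cohort(cfg)
  # every pandemic wave date maps to a valid subperiod
  expect_identical(assign_subperiod(coh$pandemic_waves$date),
                   coh$pandemic_waves$subperiod)
  # "none" stratum: no diagnoses at any wave, no lifetime flags
  none_ids <- coh$participants$participant_id[
    coh$participants$chronicity_stratum == "none"]
  pre_none <- coh$prepandemic_waves[
    coh$prepandemic_waves$participant_id %in% none_ids, ]
  dxcols <- paste0("dx_", disorder_names())
  expect_true(all(rowSums(pre_none[, dxcols]) == 0))
  ltcols <- paste0("lifetime_", disorder_names())
  expect_true(all(rowSums(coh$participants[coh$participants$participant_id
                                           %in% none_ids, ltcols]) == 0))
  # realized chronicity matches the assigned stratum for everyone
  chron <- compute_chronicity(coh$prepandemic_waves,
                              coh$participants[, c("participant_id", ltcols)])
  expect_identical(as.character(chron$group),
                   as.character(coh$participants$chronicity_stratum))
})

test_that("stratum exposure gradient is monotone at large n", {
  cfg <- generator_config(
    n_participants = 5000, seed = 41,
    chronicity_odds_multipliers = c(none = 1.0, remitted = 1.05,
                                    low_medium = 1.12, high = 1.20)
  )
  coh <- generate_cohort(cfg)
  cai1 <- coh$cai[coh$cai$period == 1 & coh$cai$eligible, ]
  d <- merge(cai1, coh$participants[, c("participant_id", "chronicity_stratum")])
  means <- tapply(d$cai, d$chronicity_stratum, mean)
  # non-decreasing across strata within Monte-Carlo error (~0.06 per mean)
  expect_true(all(diff(means) > -0.15))
  # analytic expectation agrees with the simulated stratum means
  for (st in chronicity_levels()) {
    expect_equal(unname(means[st]), expected_subperiod_cai(cfg, st),
                 tolerance = 0.06)
  }
})

test_that("calibration solves targets monotonically and flags impossible ones", {
  cfg <- generator_config(n_participants = 100, seed = 3)
  # monotone: expected mean increases with the scalar until saturation
  e <- vapply(c(0, 0.25, 0.5, 1, 2, 4, 8), function(s)
    expected_subperiod_cai(cfg, "none", scalar = s), numeric(1))
  expect_true(all(diff(e) > 0))
  expect_equal(e[1], 0)
  cal <- calibrate_exposure_multiplier(cfg, c(none = 4.2), tolerance = 0.1)
  expect_equal(expected_subperiod_cai(cal, "none"), 4.2, tolerance = 1e-6)
  zero <- calibrate_exposure_multiplier(cfg, c(none = 0), tolerance = 0.01)
  expect_equal(zero$exposure_odds_scalar, 0)
  expect_error(calibrate_exposure_multiplier(cfg, c(none = 100)),
               "exceeds the attainable subperiod-1 maximum 15")
})

test_that("deleting one subperiod for a fraction exercises eligibility", {
  cfg <- generator_config(n_participants = 1000, seed = 13,
                          wave_response_probability = 1)
  coh <- generate_cohort(cfg)
  expect_identical(inject_missing_subperiods(coh, 0), coh)
  thin <- inject_missing_subperiods(coh, 0.3, seed = 99)
  nsp <- tapply(thin$cai$period, thin$cai$participant_id, length)
  n2 <- sum(nsp == 2)
  # binomial expectation 300; allow 4 sd (~58)
  expect_gt(n2, 240)
  expect_lt(n2, 360)
  expect_true(all(thin$cai$eligible))
  expect_error(inject_missing_subperiods(coh, 1), "\\[0, 1\\)")
})
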