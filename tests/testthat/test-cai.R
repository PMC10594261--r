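w_can <- canonical_weight_table()

test_that("dependency groups resolve to the highest endorsed weight", {
  # symptoms without diagnosis: one point
  expect_equal(score_exposure_type(c(`1` = 1, `2` = 0), 1, w_can), 1)
  # diagnosis alone: three points
  expect_equal(score_exposure_type(c(`1` = 0, `2` = 1), 1, w_can), 3)
  # diagnosis + symptoms: the diagnosis weight wins
  expect_equal(score_exposure_type(c(`1` = 1, `2` = 1), 1, w_can), 3)
  expect_equal(score_exposure_type(c(`1` = 0, `2` = 0), 1, w_can), 0)
  # hospitalised course outweighs diagnosis in subperiods 2-3
  expect_equal(score_exposure_type(c(`2` = 1, `3` = 3), 2, w_can), 5)
  expect_error(score_exposure_type(c(`3` = 1), 1, w_can), "not available")
  expect_error(score_exposure_type(c(`1` = 2), 1, w_can), "out of range")
  expect_error(score_exposure_type(c(`1` = 1, `4` = 1), 1, w_can),
               "dependency group")
})

test_that("subperiod aggregation takes per-type maxima across waves", {
  waves <- data.frame(participant_id = 1, subperiod = 2,
                      matrix(0L, 2, 15, dimnames = list(NULL, paste0("item_", 1:15))))
  waves$item_11 <- NA_integer_
  waves$item_1 <- c(1L, 0L)   # symptoms at wave 1 -> 1 point
  waves$item_2 <- c(0L, 1L)   # diagnosis at wave 2 -> 3 points
  ts <- wave_type_scores(waves, w_can)
  agg <- aggregate_subperiod(ts)
  expect_equal(unname(agg$per_type["own_infection"]), 3)
  expect_equal(agg$total, 3)
  expect_equal(agg$n_waves_observed, 2L)
  # zero observed waves: missing marker, not an error
  empty <- aggregate_subperiod(ts[0, ])
  expect_true(is.na(empty$total))
  expect_equal(empty$n_waves_observed, 0L)
  # idempotence: max aggregation is stable under duplication
  expect_equal(aggregate_subperiod(rbind(ts, ts))$total, agg$total)
})

test_that("cumulation runs forward sums and handles missing subperiods", {
  full <- cumulate(c(15, 16, 16))
  expect_equal(full$cai, c(15, 31, 47))
  expect_true(all(full$eligible))
  expect_equal(cumulate(c(0, 0, 0))$cai, c(0, 0, 0))
  gap <- cumulate(c(5, NA, 4))
  expect_equal(gap$period, c(1L, 3L))
  expect_equal(gap$cai, c(5, 9))
  expect_true(all(gap$eligible))
  one <- cumulate(c(NA, 7, NA))
  expect_false(any(one$eligible))
})

test_that("eligibility keeps exactly participants with two computable subperiods", {
  waves <- data.frame(
    participant_id = c(1, 2, 2, 3),
    subperiod = c(2, 1, 3, 1),
    matrix(0L, 4, 15, dimnames = list(NULL, paste0("item_", 1:15)))
  )
  waves$item_3 <- ifelse(waves$subperiod == 1, NA_integer_, 0L)
  waves$item_7 <- waves$item_3
  waves$item_15 <- waves$item_3
  waves$item_11 <- ifelse(waves$subperiod == 1, 0L, NA_integer_)
  cai <- compute_cai(waves, w_can)
  kept <- filter_eligible(cai)
  expect_setequal(unique(kept$participant_id), 2)
  expect_equal(attr(kept, "n_excluded"), 2)
  empty <- filter_eligible(cai[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "n_excluded"), 0)
})

test_that("endorsing an unavailable item raises an availability error", {
  waves <- data.frame(participant_id = 1, subperiod = 1,
                      matrix(0L, 1, 15, dimnames = list(NULL, paste0("item_", 1:15))))
  waves$item_15 <- 1L
  expect_error(compute_cai(waves, w_can), "not available")
})

test_that("pipeline scores equal the one-pass brute-force oracle", {
  set.seed(303)
  for (i in 1:40) {
    waves <- random_participant_waves(i)
    if (is.null(waves)) next
    oracle <- brute_cai(waves, w_can)
    got <- compute_cai(waves, w_can)
    expect_equal(got$period, oracle$periods)
    expect_equal(got$cai, oracle$cumulative)
    expect_equal(unique(got$eligible), oracle$eligible)
  }
})

test_that("scores are order-invariant, monotone in period, and bounded", {
  set.seed(404)
  cfg <- generator_config(n_participants = 120, seed = 17)
  coh <- generate_cohort(cfg)
  cai <- coh$cai
  # monotone non-decreasing cumulative score within participant
  mono <- tapply(cai$cai, cai$participant_id, function(x) all(diff(x) >= 0))
  expect_true(all(mono))
  expect_true(all(cai$cai <= max_possible_score(w_can)))
  # permuting wave order changes nothing
  pw <- coh$pandemic_waves
  perm <- pw[sample(nrow(pw)), ]
  cai_perm <- compute_cai(perm, w_can)
  expect_equal(cai_perm, compute_cai(pw, w_can), ignore_attr = TRUE)
})
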