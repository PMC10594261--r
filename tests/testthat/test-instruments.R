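test_that("QIDS domain-max scoring matches hand-scored patterns", {
  expect_equal(score_qids(rep(0, 16)), 0L)
  expect_equal(score_qids(rep(3, 16)), 27L)
  # all four sleep items collapse to one domain score
  expect_equal(score_qids(c(3, 0, 0, 0, rep(0, 12))), 3L)
  expect_equal(score_qids(c(3, 2, 1, 3, rep(0, 12))), 3L)
  # appetite/weight and psychomotor are also domain maxima
  expect_equal(score_qids(c(rep(0, 5), 2, 2, 2, 2, rep(0, 5), 1, 1)), 3L)
  expect_error(score_qids(c(rep(0, 15), 4)), "0\\.\\.3")
  expect_error(score_qids(rep(0, 15)), "16 items")
  miss <- score_qids(c(NA, rep(0, 15)))
  expect_true(is.na(miss))
  expect_match(attr(miss, "missing_reason"), "missing")
})

test_that("QIDS agrees with the brute-force nine-domain oracle", {
  set.seed(101)
  m <- matrix(sample(0:3, 1000 * 16, replace = TRUE), ncol = 16)
  expect_equal(as.integer(score_qids(m)),
               as.integer(apply(m, 1, brute_qids)))
})

test_that("BAI is a plain sum over 21 items", {
  expect_equal(score_bai(rep(0, 21)), 0L)
  expect_equal(score_bai(rep(3, 21)), 63L)
  expect_equal(score_bai(c(2, rep(0, 20))), 2L)
})

test_that("loneliness scoring reverses positively worded items", {
  neg_no_pos_yes <- c("no", "no", "no", "yes", "yes", "yes")
  expect_equal(score_loneliness(neg_no_pos_yes), 0L)
  expect_equal(score_loneliness(c("yes", "yes", "yes", "no", "no", "no")), 6L)
  # "more or less" scores 1 under both polarities
  expect_equal(score_loneliness(rep("more_or_less", 6)), 6L)
  # literal unreversed behaviour: mark all items negative
  expect_equal(score_loneliness(neg_no_pos_yes, polarity = rep(TRUE, 6)), 3L)
  expect_error(score_loneliness(c("maybe", rep("no", 5))), "unknown")
})

test_that("raising any single item never lowers a total score", {
  set.seed(202)
  for (rep_i in 1:50) {
    q <- sample(0:2, 16, replace = TRUE)
    j <- sample(16, 1)
    q2 <- q
    q2[j] <- q[j] + 1
    expect_gte(score_qids(q2), score_qids(q))
    b <- sample(0:2, 21, replace = TRUE)
    jb <- sample(21, 1)
    b2 <- b
    b2[jb] <- b[jb] + 1
    expect_gte(score_bai(b2), score_bai(b))
  }
})

test_that("Cronbach's alpha matches closed forms and limits", {
  x <- rnorm(20)
  expect_equal(cronbach_alpha(cbind(x, x)), 1)
  # exact sample covariance: equal variances 1, pairwise covariance 0.5
  set.seed(7)
  X <- scale(matrix(rnorm(50 * 3), 50, 3), center = TRUE, scale = FALSE)
  Xw <- X %*% solve(chol(stats::cov(X)))
  S <- matrix(0.5, 3, 3); diag(S) <- 1
  Xs <- Xw %*% chol(S)
  expect_equal(cronbach_alpha(Xs), 0.75, tolerance = 1e-10)
  # independent items: alpha -> 0 for large n
  set.seed(8)
  ind <- matrix(rnorm(5000 * 5), 5000, 5)
  expect_lt(abs(cronbach_alpha(ind)), 0.06)
  expect_error(cronbach_alpha(matrix(1, 10, 3)), "variance")
  expect_error(cronbach_alpha(matrix(rnorm(4), 2, 2)), "respondents")
})

test_that("perceived-impact score is the item mean on 1..5", {
  expect_equal(score_perceived_impact(rep(1, 9)), 1)
  expect_equal(score_perceived_impact(rep(5, 9)), 5)
  expect_equal(score_perceived_impact(c(1, 2, 3, 4, 5, 1, 2, 3, 4)), 25 / 9)
  expect_error(score_perceived_impact(rep(0, 9)), "1\\.\\.5")
})
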