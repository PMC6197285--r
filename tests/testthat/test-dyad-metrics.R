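test_that("accuracy counts private and joint correctness by hand", {
  # 3 of 4 private choices correct for member 1
  rec <- toy_records(target = c(2L, 2L, 1L, 1L),
                     choice_m1 = c(2L, 2L, 1L, 2L),
                     choice_m2 = c(2L, 1L, 1L, 1L),
                     joint_choice = c(2L, 1L, 1L, 2L))
  expect_equal(accuracy(rec, "member1"), 0.75)
  expect_equal(accuracy(rec, "member2"), 0.75)
  # joint: trials 1 and 3 correct, 2 and 4 wrong
  expect_equal(accuracy(rec, "joint"), 0.5)
  expect_error(accuracy(rec[0, ], "member1"), "empty")

  # all-agreement, all-correct log
  rec2 <- toy_records(target = c(1L, 2L), choice_m1 = c(1L, 2L),
                      choice_m2 = c(1L, 2L), joint_choice = c(1L, 2L))
  expect_equal(accuracy(rec2, "joint"), 1.0)
})

test_that("joint accuracy mixes agreement and disagreement trials", {
  # 2 agreement trials correct + 2 disagreement trials with wrong joint choice
  rec <- toy_records(target = c(2L, 1L, 2L, 1L),
                     choice_m1 = c(2L, 1L, 2L, 1L),
                     choice_m2 = c(2L, 1L, 1L, 2L),
                     joint_choice = c(2L, 1L, 1L, 2L))
  expect_equal(sum(rec$agree), 2L)
  expect_equal(accuracy(rec, "joint"), 0.5)
})

test_that("mean reaction times average the applicable trials only", {
  rec <- toy_records(target = c(2L, 1L, 2L),
                     choice_m1 = c(2L, 1L, 2L),
                     choice_m2 = c(1L, 2L, 2L),
                     joint_choice = c(2L, 1L, 2L),
                     rt_m1 = c(1, 2, 3), joint_rt = c(5, 7, NA))
  expect_equal(mean_rt(rec, "member1"), 2)
  expect_equal(mean_rt(rec, "joint"), 6)  # disagreement trials 1 and 2 only
  rec_agree <- toy_records(target = 2L, choice_m1 = 2L, choice_m2 = 2L,
                           joint_choice = 2L)
  expect_error(mean_rt(rec_agree, "joint"), "no disagreement")
  expect_equal(mean_rt(rec_agree, "member1"), 1)  # single trial: its RT
})

test_that("egocentric bias counts indicated joint decisions that matched own choice", {
  # member 1 indicates 4 disagreement trials; joint matches their choice on 2
  rec <- toy_records(target = rep(2L, 5),
                     choice_m1 = c(2L, 2L, 1L, 1L, 2L),
                     choice_m2 = c(1L, 1L, 2L, 2L, 2L),
                     joint_choice = c(2L, 1L, 2L, 1L, 2L),
                     joint_indicator = c(1L, 1L, 1L, 1L, 1L))
  expect_equal(egocentric_bias(rec, 1L), 0.5)
  # member 2 never indicated a joint decision: undefined, not zero
  expect_true(is.na(egocentric_bias(rec, 2L)))
  # joint always equals the indicator's private choice
  rec2 <- toy_records(target = rep(2L, 2), choice_m1 = c(2L, 1L),
                      choice_m2 = c(1L, 2L), joint_choice = c(2L, 1L),
                      joint_indicator = 1L)
  expect_equal(egocentric_bias(rec2, 1L), 1.0)
  # no disagreement trials at all: undefined
  rec3 <- toy_records(target = 2L, choice_m1 = 2L, choice_m2 = 2L,
                      joint_choice = 2L)
  expect_true(is.na(egocentric_bias(rec3, 1L)))
  # alternative denominator: all disagreement trials, indicated or not
  rec4 <- toy_records(target = rep(2L, 4),
                      choice_m1 = c(2L, 2L, 1L, 1L),
                      choice_m2 = c(1L, 1L, 2L, 2L),
                      joint_choice = c(2L, 1L, 2L, 1L),
                      joint_indicator = c(1L, 1L, 2L, 2L))
  expect_equal(egocentric_bias(rec4, 1L), 0.5)   # indicated 2, matched 1
  expect_equal(egocentric_bias(rec4, 1L, denominator = "all_disagreement"),
               0.25)                              # matched-and-indicated 1 of 4
})

test_that("similarity, WCS prediction, benefit and optimality follow their formulas", {
  expect_equal(similarity(2, 2), 1.0)
  expect_equal(similarity(1, 2), 0.5)
  expect_equal(similarity(2, 1), 0.5)
  expect_error(similarity(-1, 2), "positive")

  expect_equal(wcs_sensitivity(1, 1), sqrt(2))
  expect_equal(wcs_sensitivity(1, sqrt(2) - 1), 1.0)     # break-even with S_max
  expect_equal(wcs_sensitivity(1, 0.1), 1.1 / sqrt(2))   # predicted loss
  expect_lt(wcs_sensitivity(1, 0.1), 1)

  expect_equal(collective_benefit(2.5, 2, 1), 1.25)
  expect_equal(collective_benefit(2, 2, 1), 1.0)
  expect_equal(optimality((1 + 2) / sqrt(2), 1, 2), 1.0)
  expect_equal(optimality(1, 1, 1), 1 / sqrt(2))
  expect_error(optimality(1, 0, 1), "positive")
})

test_that("benefit = optimality x (1 + similarity)/sqrt(2) on arbitrary inputs", {
  set.seed(71)
  for (i in 1:50) {
    s1 <- runif(1, 0.2, 4); s2 <- runif(1, 0.2, 4); sd_ <- runif(1, 0.2, 5)
    expect_equal(
      collective_benefit(sd_, s1, s2),
      optimality(sd_, s1, s2) * (1 + similarity(s1, s2)) / sqrt(2),
      tolerance = 1e-12
    )
  }
})

test_that("the WCS break-even threshold sits exactly at similarity sqrt(2) - 1", {
  for (s2 in seq(0.05, 1, by = 0.05)) {
    sim <- similarity(1, s2)
    gains <- wcs_sensitivity(1, s2) >= max(1, s2)
    expect_identical(gains, sim >= sqrt(2) - 1)
  }
})

test_that("the exclusion rule is inclusive at the accuracy threshold and names reasons", {
  ok_fit <- list(slope_coef = 5, converged = TRUE)
  neg_fit <- list(slope_coef = -2, converged = TRUE)
  bad_fit <- list(slope_coef = 5, converged = FALSE)

  res <- apply_exclusion(0.55, 0.80, ok_fit, ok_fit)
  expect_true(res$excluded)   # "55% accuracy or lower" is inclusive
  expect_match(res$reason, "accuracy member1")

  expect_false(apply_exclusion(0.551, 0.80, ok_fit, ok_fit)$excluded)

  res <- apply_exclusion(0.90, 0.90, ok_fit, neg_fit)
  expect_true(res$excluded)
  expect_match(res$reason, "negative sensitivity member2")

  res <- apply_exclusion(0.90, 0.90, bad_fit, ok_fit)
  expect_true(res$excluded)
  expect_match(res$reason, "non-converged fit member1")

  # monotonicity: raising the threshold can only exclude more
  for (acc in c(0.5, 0.6, 0.7)) {
    lo <- apply_exclusion(acc, 0.9, ok_fit, ok_fit, accuracy_threshold = 0.55)
    hi <- apply_exclusion(acc, 0.9, ok_fit, ok_fit, accuracy_threshold = 0.65)
    expect_true(hi$excluded >= lo$excluded)
  }
})

test_that("compute_dyad_summary fills every field consistently on simulated data", {
  res <- quick_dyad(sigma1 = 0.18, sigma2 = 0.22, design_seed = 81,
                    behav_seed = 82)
  s <- res$summary
  expect_false(s$excluded)
  expect_equal(s$n_trials, 256L)
  expect_equal(s$S_min, min(s$s1, s$s2))
  expect_equal(s$S_max, max(s$s1, s$s2))
  expect_equal(s$similarity, s$S_min / s$S_max)
  expect_equal(s$S_wcs, (s$s1 + s$s2) / sqrt(2))
  expect_equal(s$benefit, s$S_dyad / s$S_max)
  expect_equal(s$optimality, s$S_dyad / s$S_wcs)
  expect_equal(s$benefit, s$optimality * (1 + s$similarity) / sqrt(2),
               tolerance = 1e-9)
  expect_equal(s$n_disagree, sum(!res$log$agree))

  # session scope restricts to that session's 128 trials, fits recomputed
  s1 <- compute_dyad_summary(res$log, session = 1)
  expect_equal(s1$n_trials, 128L)
  expect_false(isTRUE(all.equal(s1$s1, s$s1)))
  expect_error(compute_dyad_summary(res$log, session = 99), "no trials")
})

test_that("a member responding at chance gets the dyad excluded, not crashed", {
  res <- quick_dyad(sigma1 = 0.2, sigma2 = 50, design_seed = 83,
                    behav_seed = 84)
  s <- res$summary
  expect_true(s$excluded)
  expect_match(s$exclusion_reason, "accuracy member2")
})
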