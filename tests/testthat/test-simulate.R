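test_that("private choice probabilities follow the generative psychometric curve", {
  # b = 0, sigma = 0.2, delta_c = 0.2: P(choice 2) = H(1); numeric integration
  # of the standard normal density as the oracle
  oracle <- stats::integrate(stats::dnorm, -Inf, 1)$value
  set.seed(101)
  resp <- simulate_private(observer_params(b = 0, sigma = 0.2), rep(0.2, 1e5))
  expect_equal(mean(resp$choice == 2L), oracle, tolerance = 0.005)

  # delta_c = -b: P(choice 2) = 1/2
  set.seed(102)
  resp <- simulate_private(observer_params(b = 0.1, sigma = 0.2), rep(-0.1, 1e5))
  expect_equal(mean(resp$choice == 2L), 0.5, tolerance = 0.01)

  # noiseless limit: delta_c + b > 0 forces choice 2
  set.seed(103)
  resp <- simulate_private(observer_params(b = 0.05, sigma = 1e-9), rep(0.1, 100))
  expect_true(all(resp$choice == 2L))
})

test_that("observer parameters are validated", {
  expect_error(observer_params(sigma = 0), "positive")
  expect_error(observer_params(sigma = -0.1), "positive")
  expect_error(joint_rule("majority_vote"), "unknown joint rule")
})

test_that("agreement forces the joint choice and disagreement follows the rule", {
  des <- data.frame(session = 1L, block = 1L, trial = 1L, target_interval = 2L,
                    target_location = 1L, increment = 0.3, delta_c = 0.3,
                    joint_indicator = 1L)
  # strong positive evidence for both: agreement on interval 2
  set.seed(7)
  rec <- simulate_dyad_trial(observer_params(b = 1, sigma = 1e-6),
                             observer_params(b = 1, sigma = 1e-6), des)
  expect_true(rec$agree)
  expect_equal(rec$joint_choice, 2L)
  expect_equal(rec$joint_choice, rec$choice_m1)
  expect_true(is.na(rec$joint_rt))

  # opposite strong biases: disagreement; higher confidence wins under WCS
  set.seed(8)
  rec <- simulate_dyad_trial(observer_params(b = 2, sigma = 1e-6),
                             observer_params(b = -1, sigma = 1e-6), des,
                             rule = joint_rule("wcs_confidence"))
  expect_false(rec$agree)
  expect_gt(rec$conf_m1, rec$conf_m2)
  expect_equal(rec$joint_choice, rec$choice_m1)

  # always_member1 imposes member 1's choice on disagreement
  set.seed(9)
  rec <- simulate_dyad_trial(observer_params(b = -2, sigma = 1e-6),
                             observer_params(b = 1, sigma = 1e-6), des,
                             rule = joint_rule("always_member1"))
  expect_false(rec$agree)
  expect_equal(rec$joint_choice, rec$choice_m1)
})

test_that("seeded simulations are exactly reproducible", {
  obs <- observer_params(b = 0.01, sigma = 0.2)
  cfg <- experiment_config(seed = 5)
  a <- simulate_experiment(obs, obs, cfg, joint_rule("coin_flip"), seed = 77)
  b <- simulate_experiment(obs, obs, cfg, joint_rule("coin_flip"), seed = 77)
  expect_identical(a, b)
  c <- simulate_experiment(obs, obs, cfg, joint_rule("coin_flip"), seed = 78)
  expect_false(identical(a, c))
})

test_that("trial records satisfy their structural invariants", {
  res <- quick_dyad(sigma1 = 0.18, sigma2 = 0.25, design_seed = 21,
                    behav_seed = 22)
  log <- res$log
  expect_equal(nrow(log), 256L)
  expect_identical(log$agree, log$choice_m1 == log$choice_m2)
  expect_true(all(log$joint_choice[log$agree] == log$choice_m1[log$agree]))
  expect_identical(log$correct_m1, log$choice_m1 == log$target_interval)
  expect_identical(log$correct_joint, log$joint_choice == log$target_interval)
  expect_true(all(is.na(log$joint_rt[log$agree])))
  expect_true(all(!is.na(log$joint_rt[!log$agree])))
})

test_that("disagreement frequency matches the binomial closed form", {
  # identical members: P(disagree | delta_c) = 2 p (1 - p), p = H(delta_c/sigma)
  sigma <- 0.2
  cfg <- experiment_config(seed = 31)
  des <- make_design(cfg)
  p <- pnorm(des$delta_c / sigma)
  expected <- mean(2 * p * (1 - p))
  obs <- observer_params(b = 0, sigma = sigma)
  set.seed(32)
  frac <- vapply(1:50, function(i) {
    log <- simulate_experiment(obs, obs, cfg, seed = sample.int(2^31 - 2, 1))
    mean(!log$agree)
  }, numeric(1))
  expect_equal(mean(frac), expected, tolerance = 0.015)
})

test_that("baseline joint rules land at their predicted sensitivities", {
  # coin flip between identical members: the joint series has the members'
  # own psychometric curve, so optimality ~ S / ((2S)/sqrt(2)) = 1/sqrt(2)
  set.seed(41)
  opt <- vapply(1:30, function(i) {
    quick_dyad(rule = joint_rule("coin_flip"),
               design_seed = sample.int(2^31 - 2, 1),
               behav_seed = sample.int(2^31 - 2, 1))$summary$optimality
  }, numeric(1))
  expect_equal(mean(opt), 1 / sqrt(2), tolerance = 0.03)

  # oracle rule: the dyad tracks its better member, so benefit ~ 1
  set.seed(42)
  ben <- vapply(1:30, function(i) {
    quick_dyad(sigma1 = 0.15, sigma2 = 0.3,
               rule = joint_rule("best_member_oracle"),
               design_seed = sample.int(2^31 - 2, 1),
               behav_seed = sample.int(2^31 - 2, 1))$summary$benefit
  }, numeric(1))
  expect_equal(mean(ben), 1, tolerance = 0.05)
})
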