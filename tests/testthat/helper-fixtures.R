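# Hand-constructable trial records for exact-count tests. Correctness flags
# and the agreement flag are derived, never passed, so fixtures stay
# internally consistent.
toy_records <- function(target, choice_m1, choice_m2, joint_choice,
                        joint_indicator = 1L, delta_c = NULL,
                        rt_m1 = 1, rt_m2 = 1, joint_rt = NA_real_,
                        session = 1L) {
  n <- length(target)
  agree <- choice_m1 == choice_m2
  if (is.null(delta_c)) delta_c <- ifelse(target == 2L, 0.15, -0.15)
  data.frame(
    dyad_id = "toy", group = "toy",
    session = rep_len(session, n), block = 1L, trial = seq_len(n),
    target_interval = target, target_location = 1L,
    increment = abs(delta_c), delta_c = delta_c,
    choice_m1 = choice_m1, choice_m2 = choice_m2,
    rt_m1 = rep_len(rt_m1, n), rt_m2 = rep_len(rt_m2, n),
    agree = agree,
    joint_indicator = rep_len(joint_indicator, n),
    joint_choice = joint_choice,
    joint_rt = ifelse(agree, NA_real_, rep_len(joint_rt, n)),
    correct_m1 = choice_m1 == target,
    correct_m2 = choice_m2 == target,
    correct_joint = joint_choice == target
  )
}

# Simulate one dyad on the standard 256-trial design and summarise it.
quick_dyad <- function(sigma1 = 0.2, sigma2 = 0.2, b1 = 0, b2 = 0,
                       rule = joint_rule("wcs_confidence"),
                       design_seed = 1L, behav_seed = 2L, ...) {
  log <- simulate_experiment(
    observer_params(b = b1, sigma = sigma1),
    observer_params(b = b2, sigma = sigma2),
    experiment_config(seed = design_seed, ...),
    rule = rule, seed = behav_seed
  )
  list(log = log, summary = compute_dyad_summary(log))
}

# Exhaustive probit likelihood maximisation by iterated grid refinement:
# a coarse (beta0, beta1) grid is searched and re-centred on its argmax, with
# a finer step when the argmax is interior and a widened window when it sits
# on a grid edge (flat, near-separated likelihoods put the optimum far out).
# Independent of the glm fitting path.
grid_refine_fit <- function(delta_c, chose_second,
                            beta0_span = c(-3, 3), beta1_span = c(-30, 30),
                            k = 41L, stages = 12L) {
  b0 <- seq(beta0_span[1L], beta0_span[2L], length.out = k)
  b1 <- seq(beta1_span[1L], beta1_span[2L], length.out = k)
  fit <- NULL
  for (s in seq_len(stages)) {
    fit <- fit_psychometric_grid(delta_c, chose_second, b0, b1)
    step0 <- diff(b0[1:2])
    step1 <- diff(b1[1:2])
    at_edge <- fit$intercept_coef %in% range(b0) ||
      fit$slope_coef %in% range(b1)
    half0 <- if (at_edge) k * step0 else 2 * step0
    half1 <- if (at_edge) k * step1 else 2 * step1
    b0 <- seq(fit$intercept_coef - half0, fit$intercept_coef + half0,
              length.out = k)
    b1 <- seq(fit$slope_coef - half1, fit$slope_coef + half1, length.out = k)
  }
  fit
}
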