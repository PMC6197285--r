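#' Generative parameters of one observer
#'
#' A signal-detection observer for the 2IFC task. On a trial with signed
#' contrast difference `delta_c` the observer draws internal evidence
#' `d ~ Normal(delta_c + b, sigma^2)` and chooses interval 2 when `d > 0`,
#' so the implied psychometric curve is exactly the cumulative-Gaussian model
#' fitted by [fit_psychometric()]: `P(choose 2 | delta_c) = H((delta_c + b)/sigma)`.
#' Confidence is the absolute evidence z-score `|d|/sigma`.
#'
#' Private reaction times are drawn from a lognormal distribution; they are a
#' simulation convenience only and never enter sensitivity computations.
#'
#' @param b Decision bias in contrast units (shifts the psychometric curve).
#' @param sigma Internal noise standard deviation in contrast units; must be
#'   strictly positive.
#' @param rt_log_mean,rt_log_sd Log-scale mean and SD of the private reaction
#'   time distribution (seconds).
#' @return An object of class `observer_params`.
#' @export
#' @examples
#' obs <- observer_params(b = 0, sigma = 0.2)
observer_params <- function(b = 0, sigma, rt_log_mean = log(1.4), rt_log_sd = 0.35) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("parameter error: sigma must be a single positive number")
  }
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b)) {
    stop("parameter error: b must be a single finite number")
  }
  structure(
    list(b = b, sigma = sigma, rt_log_mean = rt_log_mean, rt_log_sd = rt_log_sd),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(
    "observer: b = %.4f, sigma = %.4f (sensitivity S = %.3f)\n",
    x$b, x$sigma, slope_from_sigma(x$sigma)
  ))
  invisible(x)
}

#' Joint-decision rule for disagreement trials
#'
#' How a simulated dyad resolves disagreement (the members privately chose
#' different intervals):
#' \describe{
#'   \item{`wcs_confidence`}{the member with the larger confidence
#'     (`|d|/sigma`) imposes their choice. This implements the behaviour the
#'     Weighted Confidence Sharing benchmark assumes: each opinion weighted by
#'     its communicated confidence, which for two members reduces to siding
#'     with the more confident one. A dyad following this rule attains joint
#'     sensitivity `(s1 + s2)/sqrt(2)`.}
#'   \item{`coin_flip`}{a fair coin; a no-communication baseline.}
#'   \item{`always_member1`}{member 1 always prevails; a dominance baseline.}
#'   \item{`best_member_oracle`}{the generatively more sensitive member
#'     (smaller `sigma`) prevails; upper-bounds "follow the better member".}
#' }
#' Confidence ties (and sensitivity ties under the oracle rule) are broken by
#' a seeded fair coin so that simulations stay reproducible.
#'
#' @param kind One of `"wcs_confidence"`, `"coin_flip"`, `"always_member1"`,
#'   `"best_member_oracle"`.
#' @return An object of class `joint_rule`.
#' @export
joint_rule <- function(kind = c("wcs_confidence", "coin_flip", "always_member1",
                                "best_member_oracle")) {
  kind <- tryCatch(match.arg(kind), error = function(e) {
    stop(sprintf("configuration error: unknown joint rule kind '%s'", kind[1L]))
  })
  structure(list(kind = kind, tie_break = "coin_flip"), class = "joint_rule")
}

#' Simulate private decisions of one observer
#'
#' Draws internal evidence `d ~ Normal(delta_c + b, sigma^2)` for each element
#' of `delta_c` and returns the induced choice (2 if `d > 0`, else 1),
#' confidence `|d|/sigma`, and a lognormal reaction time. Over many draws the
#' empirical probability of choosing interval 2 converges to
#' `pnorm((delta_c + b)/sigma)`. Uses R's global random number stream; seed it
#' with `set.seed()` for reproducibility.
#'
#' @param observer An [observer_params()].
#' @param delta_c Numeric vector of signed contrast differences.
#' @return A data frame with columns `choice`, `confidence`, `rt`.
#' @export
#' @examples
#' set.seed(1)
#' simulate_private(observer_params(sigma = 0.2), c(-0.15, 0.15))
simulate_private <- function(observer, delta_c) {
  if (!inherits(observer, "observer_params")) {
    observer <- do.call(observer_params, observer)
  }
  n <- length(delta_c)
  d <- stats::rnorm(n, mean = delta_c + observer$b, sd = observer$sigma)
  data.frame(
    choice = ifelse(d > 0, 2L, 1L),
    confidence = abs(d) / observer$sigma,
    rt = stats::rlnorm(n, observer$rt_log_mean, observer$rt_log_sd)
  )
}

# Resolve joint choices on disagreement trials (vectorised over trials).
resolve_joint <- function(choice_m1, choice_m2, conf_m1, conf_m2,
                          rule, obs1, obs2) {
  joint <- choice_m1
  dis <- which(choice_m1 != choice_m2)
  if (length(dis) == 0L) {
    return(joint)
  }
  coin <- function(k) sample(c(TRUE, FALSE), k, replace = TRUE)
  switch(rule$kind,
    wcs_confidence = {
      m1_wins <- conf_m1[dis] > conf_m2[dis]
      tie <- conf_m1[dis] == conf_m2[dis]
      if (any(tie)) m1_wins[tie] <- coin(sum(tie))
      joint[dis] <- ifelse(m1_wins, choice_m1[dis], choice_m2[dis])
    },
    coin_flip = {
      joint[dis] <- ifelse(coin(length(dis)), choice_m1[dis], choice_m2[dis])
    },
    always_member1 = {
      joint[dis] <- choice_m1[dis]
    },
    best_member_oracle = {
      if (obs1$sigma < obs2$sigma) {
        joint[dis] <- choice_m1[dis]
      } else if (obs2$sigma < obs1$sigma) {
        joint[dis] <- choice_m2[dis]
      } else {
        joint[dis] <- ifelse(coin(length(dis)), choice_m1[dis], choice_m2[dis])
      }
    },
    stop(sprintf("configuration error: unknown joint rule kind '%s'", rule$kind))
  )
  joint
}

#' Simulate one dyadic trial
#'
#' Simulates both members' private responses with [simulate_private()] and, on
#' disagreement, resolves the joint choice under the given rule. On agreement
#' the joint choice is the shared private choice and no joint decision is
#' made, so the joint reaction time is absent (`NA`). Uses the global random
#' number stream.
#'
#' @param obs1,obs2 [observer_params()] for the two members.
#' @param design A one-row data frame (or list) with at least `delta_c` and
#'   `target_interval`; typically a row of [make_design()] output.
#' @param rule A [joint_rule()].
#' @return A one-row data frame: the design fields plus private choices,
#'   confidences and RTs, `agree`, `joint_choice`, `joint_rt`, and the three
#'   correctness flags.
#' @export
simulate_dyad_trial <- function(obs1, obs2, design, rule = joint_rule()) {
  design <- as.data.frame(design)[1L, , drop = FALSE]
  p1 <- simulate_private(obs1, design$delta_c)
  p2 <- simulate_private(obs2, design$delta_c)
  joint <- resolve_joint(p1$choice, p2$choice, p1$confidence, p2$confidence,
                         rule, obs1, obs2)
  agree <- p1$choice == p2$choice
  out <- design
  out$choice_m1 <- p1$choice
  out$choice_m2 <- p2$choice
  out$conf_m1 <- p1$confidence
  out$conf_m2 <- p2$confidence
  out$rt_m1 <- p1$rt
  out$rt_m2 <- p2$rt
  out$agree <- agree
  out$joint_choice <- joint
  out$joint_rt <- NA_real_
  out$correct_m1 <- p1$choice == design$target_interval
  out$correct_m2 <- p2$choice == design$target_interval
  out$correct_joint <- joint == design$target_interval
  rownames(out) <- NULL
  out
}

#' Simulate a full dyad experiment
#'
#' Generates the trial schedule with [make_design()] (driven by the seed in
#' `config`) and then simulates every trial of the dyad under `seed`: private
#' evidence, choices, confidences and RTs for both members, agreement,
#' and the joint decision under `rule`. Joint reaction times are drawn
#' lognormal on disagreement trials only (on agreement no joint decision is
#' made and the joint RT is `NA`); their default scale reflects that joint
#' decisions take several seconds of discussion.
#'
#' @param obs1,obs2 [observer_params()] for members 1 and 2.
#' @param config An [experiment_config()].
#' @param rule A [joint_rule()].
#' @param seed Integer seed for the behavioural randomness (evidence, RTs,
#'   tie-breaks). The design randomness is governed separately by
#'   `config$seed`.
#' @param dyad_id,group Identifier columns copied into every record.
#' @param joint_rt_log_mean,joint_rt_log_sd Log-scale parameters of the joint
#'   (deliberation) RT distribution, seconds.
#' @return A trial-log data frame, one row per trial, in the schema written by
#'   [write_trial_log()].
#' @export
#' @examples
#' obs <- observer_params(sigma = 0.2)
#' log <- simulate_experiment(obs, obs, experiment_config(seed = 3), seed = 11)
#' nrow(log)        # 256
#' mean(!log$agree) # disagreement fraction
simulate_experiment <- function(obs1, obs2, config, rule = joint_rule(),
                                seed, dyad_id = "dyad1", group = NA_character_,
                                joint_rt_log_mean = log(9), joint_rt_log_sd = 0.4) {
  if (!inherits(config, "experiment_config")) {
    stop("config must be an experiment_config object")
  }
  if (missing(seed)) stop("seed is required for a reproducible simulation")
  seed <- as.integer(seed)  # force now: make_design() reseeds the global RNG
  des <- make_design(config)
  set.seed(seed)
  p1 <- simulate_private(obs1, des$delta_c)
  p2 <- simulate_private(obs2, des$delta_c)
  joint <- resolve_joint(p1$choice, p2$choice, p1$confidence, p2$confidence,
                         rule, obs1, obs2)
  agree <- p1$choice == p2$choice
  joint_rt <- rep(NA_real_, nrow(des))
  n_dis <- sum(!agree)
  if (n_dis > 0L) {
    joint_rt[!agree] <- stats::rlnorm(n_dis, joint_rt_log_mean, joint_rt_log_sd)
  }
  out <- cbind(
    data.frame(dyad_id = dyad_id, group = group),
    des,
    data.frame(
      choice_m1 = p1$choice, choice_m2 = p2$choice,
      conf_m1 = p1$confidence, conf_m2 = p2$confidence,
      rt_m1 = p1$rt, rt_m2 = p2$rt,
      agree = agree,
      joint_choice = joint,
      joint_rt = joint_rt,
      correct_m1 = p1$choice == des$target_interval,
      correct_m2 = p2$choice == des$target_interval,
      correct_joint = joint == des$target_interval
    )
  )
  rownames(out) <- NULL
  out
}
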