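#' Choice accuracy of a dyad member or of the dyad
#'
#' Fraction of trials on which the private (member) or joint choice matched
#' the target interval. Joint accuracy counts all trials: on agreement trials
#' the joint choice is the shared private choice, on disagreement trials it is
#' the negotiated decision.
#'
#' @param records Trial-log data frame (see [simulate_experiment()] /
#'   [read_trial_log()]).
#' @param who `"member1"`, `"member2"` or `"joint"`.
#' @return A fraction in `[0, 1]`.
#' @export
accuracy <- function(records, who = c("member1", "member2", "joint")) {
  who <- match.arg(who)
  if (nrow(records) == 0L) stop("data error: empty record set")
  choice <- switch(who,
    member1 = records$choice_m1,
    member2 = records$choice_m2,
    joint = records$joint_choice
  )
  mean(choice == records$target_interval)
}

#' Mean reaction time
#'
#' Mean private RT of a member over all trials, or mean joint
#' (deliberation) RT over disagreement trials only — agreement trials involve
#' no joint decision and carry no joint RT.
#'
#' @inheritParams accuracy
#' @return Seconds.
#' @export
mean_rt <- function(records, who = c("member1", "member2", "joint")) {
  who <- match.arg(who)
  if (nrow(records) == 0L) stop("data error: empty record set")
  if (who == "joint") {
    rts <- records$joint_rt[!records$agree]
    if (length(rts) == 0L) {
      stop("data error: no disagreement trials, joint RT undefined")
    }
    return(mean(rts))
  }
  mean(if (who == "member1") records$rt_m1 else records$rt_m2)
}

#' Egocentric bias of a dyad member
#'
#' Tendency of the member entering the joint response to impose their own
#' private choice. With `denominator = "indicated"` (default) it is the
#' fraction, among disagreement trials on which the member entered the joint
#' decision, of trials where the joint decision equalled that member's private
#' choice — a value near 0.5 means the entering member followed their own
#' choice about half of the time. With `denominator = "all_disagreement"` the
#' denominator is instead all disagreement trials.
#'
#' @inheritParams accuracy
#' @param member 1 or 2.
#' @param denominator `"indicated"` or `"all_disagreement"`.
#' @return A proportion, or `NA` when undefined (no disagreement trials, or
#'   the member never entered a joint decision).
#' @export
egocentric_bias <- function(records, member,
                            denominator = c("indicated", "all_disagreement")) {
  denominator <- match.arg(denominator)
  if (!member %in% c(1L, 2L)) stop("member must be 1 or 2")
  dis <- records[!records$agree, , drop = FALSE]
  if (nrow(dis) == 0L) return(NA_real_)
  own <- if (member == 1L) dis$choice_m1 else dis$choice_m2
  indicated <- dis$joint_indicator == member
  if (denominator == "indicated") {
    if (!any(indicated)) return(NA_real_)
    mean(dis$joint_choice[indicated] == own[indicated])
  } else {
    mean(indicated & dis$joint_choice == own)
  }
}

check_positive_sensitivities <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("domain error: sensitivities must be positive (dyads with non-positive sensitivity are excluded upstream)")
  }
}

#' Similarity of two sensitivities
#'
#' Ratio of the worse member's sensitivity to the better member's,
#' `S_min / S_max`; symmetric, in `(0, 1]`. Values near 1 mean members of
#' nearly equal sensitivity.
#'
#' @param s1,s2 Positive sensitivities.
#' @return `min(s1, s2) / max(s1, s2)`.
#' @export
similarity <- function(s1, s2) {
  check_positive_sensitivities(s1, s2)
  min(s1, s2) / max(s1, s2)
}

#' Weighted Confidence Sharing prediction of joint sensitivity
#'
#' Upper bound on joint sensitivity under the Weighted Confidence Sharing
#' model, in which each disagreement is resolved in favour of the more
#' confident member: `S_WCS = (s1 + s2) / sqrt(2)`. The dyad is predicted to
#' beat its better member exactly when similarity exceeds `sqrt(2) - 1`.
#'
#' @param s1,s2 Positive individual sensitivities.
#' @return Predicted joint sensitivity.
#' @export
#' @examples
#' wcs_sensitivity(1, 1)            # sqrt(2)
#' wcs_sensitivity(1, sqrt(2) - 1)  # 1: break-even with the better member
wcs_sensitivity <- function(s1, s2) {
  check_positive_sensitivities(s1, s2)
  (s1 + s2) / sqrt(2)
}

#' Collective benefit
#'
#' Ratio of the dyad's measured sensitivity to that of its more sensitive
#' member, `S_dyad / S_max`. Values above 1 indicate a collective benefit,
#' below 1 a collective loss.
#'
#' @param S_dyad Positive joint sensitivity.
#' @param s1,s2 Positive individual sensitivities.
#' @return The benefit ratio.
#' @export
collective_benefit <- function(S_dyad, s1, s2) {
  check_positive_sensitivities(S_dyad, s1, s2)
  S_dyad / max(s1, s2)
}

#' Optimality index
#'
#' Ratio of the dyad's measured sensitivity to the Weighted Confidence Sharing
#' prediction, `S_dyad / S_WCS`. Values of 1 mean the dyad extracts all the
#' information the benchmark allows; below 1 "sub-optimal", above 1
#' "supra-optimal". Related to collective benefit by the identity
#' `benefit = optimality * (1 + similarity) / sqrt(2)`.
#'
#' @inheritParams collective_benefit
#' @return The optimality ratio.
#' @export
optimality <- function(S_dyad, s1, s2) {
  check_positive_sensitivities(S_dyad, s1, s2)
  S_dyad / wcs_sensitivity(s1, s2)
}

#' Apply the dyad exclusion rule
#'
#' A dyad is excluded when one or both members performed at 55% accuracy or
#' lower (threshold inclusive) and/or had a negative sensitivity (negative
#' fitted probit slope). Non-converged fits are flagged as a distinct
#' exclusion reason rather than silently dropped.
#'
#' @param acc_m1,acc_m2 Member accuracies.
#' @param fit1,fit2 The members' [fit_psychometric()] results.
#' @param accuracy_threshold Exclude when accuracy is at or below this value.
#' @return A list with `excluded` (logical) and `reason` (text, `""` if kept).
#' @export
#' @examples
#' f <- list(slope_coef = 5, converged = TRUE)
#' apply_exclusion(0.55, 0.8, f, f)$excluded   # TRUE: threshold is inclusive
apply_exclusion <- function(acc_m1, acc_m2, fit1, fit2, accuracy_threshold = 0.55) {
  reasons <- character(0)
  accs <- c(acc_m1, acc_m2)
  fits <- list(fit1, fit2)
  for (m in 1:2) {
    if (accs[m] <= accuracy_threshold) {
      reasons <- c(reasons, sprintf("accuracy member%d (%.3f <= %.2f)",
                                    m, accs[m], accuracy_threshold))
    }
    if (fits[[m]]$slope_coef < 0) {
      reasons <- c(reasons, sprintf("negative sensitivity member%d", m))
    }
    if (!isTRUE(fits[[m]]$converged)) {
      reasons <- c(reasons, sprintf("non-converged fit member%d", m))
    }
  }
  list(excluded = length(reasons) > 0L, reason = paste(reasons, collapse = "; "))
}

#' Compute all per-dyad measures from a trial log
#'
#' Fits the psychometric model to each member's private choices and to the
#' joint-choice series, and derives every per-dyad measure: individual and
#' joint sensitivities, similarity, the Weighted Confidence Sharing
#' prediction, collective benefit, optimality, accuracies, reaction times,
#' egocentric biases, and the exclusion flag.
#'
#' By default the joint psychometric fit uses the joint response on all
#' trials, defining the joint response on agreement trials as the shared
#' private choice (the same trial set over which joint accuracy is defined);
#' set `include_agreement = FALSE` to fit disagreement trials only.
#'
#' The ratio measures (similarity, benefit, optimality) are reported whenever
#' both member sensitivities are positive, and are `NA` otherwise; the
#' `excluded` flag and `exclusion_reason` record whether the dyad would be
#' dropped from group-level analyses.
#'
#' @param records One dyad's trial-log data frame.
#' @param session Optional session index; when given, only that session's
#'   trials are analysed (fits recomputed on the subset).
#' @param include_agreement Include agreement trials in the joint fit?
#' @param ego_denominator Passed to [egocentric_bias()].
#' @param accuracy_threshold Passed to [apply_exclusion()].
#' @return A one-row data frame of class `dyad_metrics` with fields `s1`,
#'   `s2`, `S_min`, `S_max`, `S_dyad`, `similarity`, `S_wcs`, `benefit`,
#'   `optimality`, `acc_m1`, `acc_m2`, `acc_joint`, `rt_m1`, `rt_m2`,
#'   `joint_rt`, `ego_m1`, `ego_m2`, `n_trials`, `n_disagree`, `excluded`,
#'   `exclusion_reason`.
#' @export
compute_dyad_summary <- function(records, session = NULL,
                                 include_agreement = TRUE,
                                 ego_denominator = c("indicated", "all_disagreement"),
                                 accuracy_threshold = 0.55) {
  ego_denominator <- match.arg(ego_denominator)
  if (!is.null(session)) {
    records <- records[records$session == session, , drop = FALSE]
  }
  if (nrow(records) == 0L) {
    stop("data error: no trials in the requested scope")
  }

  fit_or_null <- function(dc, y) {
    tryCatch(fit_psychometric(dc, y), error = function(e) e)
  }
  fit1 <- fit_or_null(records$delta_c, records$choice_m1 == 2L)
  fit2 <- fit_or_null(records$delta_c, records$choice_m2 == 2L)
  joint_set <- if (include_agreement) records else records[!records$agree, , drop = FALSE]
  fitj <- if (nrow(joint_set) > 0L) {
    fit_or_null(joint_set$delta_c, joint_set$joint_choice == 2L)
  } else {
    simpleError("no disagreement trials for the joint fit")
  }

  failed <- vapply(list(fit1, fit2, fitj), inherits, logical(1), "error")
  degenerate_reason <- if (any(failed)) {
    paste(sprintf("degenerate fit (%s): %s",
                  c("member1", "member2", "joint")[failed],
                  vapply(list(fit1, fit2, fitj)[failed], conditionMessage, character(1))),
          collapse = "; ")
  } else {
    ""
  }

  acc_m1 <- accuracy(records, "member1")
  acc_m2 <- accuracy(records, "member2")
  n_dis <- sum(!records$agree)

  s1 <- if (failed[1L]) NA_real_ else fit1$S_signed
  s2 <- if (failed[2L]) NA_real_ else fit2$S_signed
  S_dyad <- if (failed[3L]) NA_real_ else fitj$S_signed

  if (any(failed)) {
    excluded <- TRUE
    reason <- degenerate_reason
  } else {
    excl <- apply_exclusion(acc_m1, acc_m2, fit1, fit2, accuracy_threshold)
    if (!isTRUE(fitj$converged)) {
      excl$excluded <- TRUE
      excl$reason <- paste(c(excl$reason[nzchar(excl$reason)],
                             "non-converged joint fit"), collapse = "; ")
    }
    excluded <- excl$excluded
    reason <- excl$reason
  }

  ratios_ok <- !anyNA(c(s1, s2, S_dyad)) && s1 > 0 && s2 > 0
  out <- data.frame(
    s1 = s1,
    s2 = s2,
    S_min = if (ratios_ok) min(s1, s2) else NA_real_,
    S_max = if (ratios_ok) max(s1, s2) else NA_real_,
    S_dyad = S_dyad,
    similarity = if (ratios_ok) similarity(s1, s2) else NA_real_,
    S_wcs = if (ratios_ok) wcs_sensitivity(s1, s2) else NA_real_,
    benefit = if (ratios_ok) S_dyad / max(s1, s2) else NA_real_,
    optimality = if (ratios_ok) S_dyad / wcs_sensitivity(s1, s2) else NA_real_,
    acc_m1 = acc_m1,
    acc_m2 = acc_m2,
    acc_joint = accuracy(records, "joint"),
    rt_m1 = mean_rt(records, "member1"),
    rt_m2 = mean_rt(records, "member2"),
    joint_rt = if (n_dis > 0L) mean_rt(records, "joint") else NA_real_,
    ego_m1 = egocentric_bias(records, 1L, ego_denominator),
    ego_m2 = egocentric_bias(records, 2L, ego_denominator),
    n_trials = nrow(records),
    n_disagree = n_dis,
    excluded = excluded,
    exclusion_reason = reason,
    stringsAsFactors = FALSE
  )
  class(out) <- c("dyad_metrics", class(out))
  out
}

#' @export
print.dyad_metrics <- function(x, ...) {
  cat(sprintf(
    "dyad metrics over %d trials (%d disagreements)%s\n",
    x$n_trials, x$n_disagree,
    if (x$excluded) paste0(" [EXCLUDED: ", x$exclusion_reason, "]") else ""
  ))
  cat(sprintf("  sensitivities: s1 = %.3f, s2 = %.3f, S_dyad = %.3f\n",
              x$s1, x$s2, x$S_dyad))
  if (!is.na(x$optimality)) {
    cat(sprintf(
      "  similarity = %.3f, S_wcs = %.3f, benefit = %.3f, optimality = %.3f\n",
      x$similarity, x$S_wcs, x$benefit, x$optimality
    ))
  }
  cat(sprintf("  accuracy: m1 = %.3f, m2 = %.3f, joint = %.3f\n",
              x$acc_m1, x$acc_m2, x$acc_joint))
  invisible(x)
}
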