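trial_log_required_cols <- c(
  "dyad_id", "group", "session", "block", "trial", "target_interval",
  "target_location", "increment", "delta_c", "choice_m1", "choice_m2",
  "rt_m1", "rt_m2", "agree", "joint_indicator", "joint_choice", "joint_rt",
  "correct_m1", "correct_m2", "correct_joint"
)

#' Write a trial log to CSV
#'
#' Writes records in the canonical trial-log schema. The joint RT is empty on
#' agreement trials (no joint decision is made there). Simulation-only
#' columns (`conf_m1`, `conf_m2`) are kept when present.
#'
#' @param records Trial-log data frame, e.g. from [simulate_experiment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(records, path) {
  missing_cols <- setdiff(trial_log_required_cols, names(records))
  if (length(missing_cols) > 0L) {
    stop("schema error: records lack required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a trial log
#'
#' Reads a trial-log CSV, checks the schema and the internal consistency of
#' every row: interval and choice codes in \{1, 2\}, the agreement flag
#' consistent with the private choices, the joint choice equal to the shared
#' choice on agreement trials, and correctness flags consistent with choices.
#' Violations are rejected with the offending row numbers.
#'
#' @param path CSV file path.
#' @return A validated data frame (all dyads; split on `dyad_id` for per-dyad
#'   analysis).
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) stop("schema error: file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("schema error: cannot parse trial log: ",
                             conditionMessage(e))
  )
  if (nrow(df) == 0L) stop("schema error: trial log has no rows")
  missing_cols <- setdiff(trial_log_required_cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df$dyad_id <- as.character(df$dyad_id)
  df$group <- as.character(df$group)
  df$agree <- as.logical(df$agree)
  for (col in c("correct_m1", "correct_m2", "correct_joint")) {
    df[[col]] <- as.logical(df[[col]])
  }

  bad <- function(cond) which(cond | is.na(cond))
  problems <- list(
    "target_interval not in {1,2}" = bad(!df$target_interval %in% c(1L, 2L)),
    "choice codes not in {1,2}" = bad(
      !df$choice_m1 %in% c(1L, 2L) | !df$choice_m2 %in% c(1L, 2L) |
        !df$joint_choice %in% c(1L, 2L)
    ),
    "agree flag inconsistent with choices" = bad(
      df$agree != (df$choice_m1 == df$choice_m2)
    ),
    "joint_choice differs from shared choice on agreement trial" = bad(
      df$agree & df$joint_choice != df$choice_m1
    ),
    "correctness flags inconsistent with choices" = bad(
      df$correct_m1 != (df$choice_m1 == df$target_interval) |
        df$correct_m2 != (df$choice_m2 == df$target_interval) |
        df$correct_joint != (df$joint_choice == df$target_interval)
    )
  )
  problems <- problems[vapply(problems, length, integer(1)) > 0L]
  if (length(problems) > 0L) {
    msgs <- vapply(seq_along(problems), function(i) {
      rows <- problems[[i]]
      sprintf("%s (rows %s)", names(problems)[i],
              paste(utils::head(rows, 10L), collapse = ", "))
    }, character(1))
    stop("validation error: ", paste(msgs, collapse = "; "))
  }
  df
}

#' Describe one group of simulated dyads
#'
#' Observer parameters for a group are drawn per member: sensitivity `S` from
#' `Normal(s_mean, s_sd)` truncated below at `s_min` (resampled), converted to
#' noise via `sigma = 1/(sqrt(2*pi) * S)`, and bias from
#' `Normal(b_mean, b_sd)`.
#'
#' @param label Group label.
#' @param n_dyads Number of dyads.
#' @param s_mean,s_sd Mean and SD of member sensitivity.
#' @param b_mean,b_sd Mean and SD of member bias (contrast units).
#' @param s_min Lower truncation for sensitivity draws.
#' @return A `dyad_group` list.
#' @export
dyad_group <- function(label, n_dyads, s_mean, s_sd,
                       b_mean = 0, b_sd = 0.02, s_min = 0.2) {
  if (n_dyads < 1L) stop("configuration error: n_dyads must be >= 1")
  if (s_mean <= 0 || s_sd < 0 || s_min <= 0) {
    stop("configuration error: sensitivity parameters must be positive")
  }
  structure(
    list(label = label, n_dyads = as.integer(n_dyads), s_mean = s_mean,
         s_sd = s_sd, b_mean = b_mean, b_sd = b_sd, s_min = s_min),
    class = "dyad_group"
  )
}

#' Configure a simulated study
#'
#' Bundles the group structure, the joint-decision rule, the experiment design
#' and the exclusion threshold into a single declarative configuration for
#' [run_study()]. The defaults emulate a two-group developmental study: a
#' "younger" group of 20 dyads with lower mean individual sensitivity and an
#' "older" group of 17 dyads with higher mean sensitivity, both performing the
#' default 256-trial design.
#'
#' @param groups List of [dyad_group()] specifications.
#' @param rule [joint_rule()] used on disagreement trials.
#' @param experiment [experiment_config()] shared by all dyads (its seed is
#'   re-derived per dyad from the study seed, so every dyad sees its own
#'   schedule).
#' @param seed Root seed; all randomness (parameter draws, designs,
#'   behaviour) is derived from it via per-dyad child seeds, so adding a dyad
#'   does not perturb the others.
#' @param accuracy_threshold Exclusion threshold on member accuracy
#'   (inclusive).
#' @return A `study_config` list.
#' @export
study_config <- function(groups = list(
                           dyad_group("younger", 20L, s_mean = 1.394, s_sd = 0.561),
                           dyad_group("older", 17L, s_mean = 2.128, s_sd = 0.716)
                         ),
                         rule = joint_rule("wcs_confidence"),
                         experiment = experiment_config(),
                         seed = 1L,
                         accuracy_threshold = 0.55) {
  if (length(groups) == 0L) stop("configuration error: at least one group")
  if (!all(vapply(groups, inherits, logical(1), "dyad_group"))) {
    stop("configuration error: groups must be dyad_group objects")
  }
  if (accuracy_threshold <= 0 || accuracy_threshold >= 1) {
    stop("configuration error: accuracy_threshold must be in (0, 1)")
  }
  structure(
    list(groups = groups, rule = rule, experiment = experiment,
         seed = as.integer(seed), accuracy_threshold = accuracy_threshold),
    class = "study_config"
  )
}

draw_observer <- function(grp) {
  s <- -1
  while (s < grp$s_min) s <- stats::rnorm(1, grp$s_mean, grp$s_sd)
  observer_params(
    b = stats::rnorm(1, grp$b_mean, grp$b_sd),
    sigma = 1 / (sqrt(2 * pi) * s)
  )
}

child_seeds <- function(root_seed, n) {
  set.seed(as.integer(root_seed))
  sample.int(2147483646L, n)
}

#' Analyse a multi-dyad trial log
#'
#' The measurement half of the pipeline: per-member psychometric fits,
#' per-dyad metrics at three scopes (all trials, session 1, session 2),
#' exclusions, and the group-level statistics — between-group t-tests on
#' individual measures (per member) and dyad measures, one-sample t-tests of
#' collective benefit and optimality against the null mean of 1 (overall and
#' per session), and mixed-design ANOVAs with session as within- and group as
#' between-factor.
#'
#' @param trials Trial-log data frame covering one or more dyads (columns as
#'   in [read_trial_log()]).
#' @param accuracy_threshold Exclusion threshold on member accuracy.
#' @param include_agreement,ego_denominator Passed to
#'   [compute_dyad_summary()].
#' @param sessions Session indices used for the per-session scopes.
#' @return A list with `member_fits`, `dyad_metrics` (rows for scopes
#'   `"all"`, `"session1"`, ...), and `stats` (one row per contrast).
#' @export
analyze_study <- function(trials, accuracy_threshold = 0.55,
                          include_agreement = TRUE,
                          ego_denominator = "indicated",
                          sessions = sort(unique(trials$session))) {
  by_dyad <- split(trials, trials$dyad_id)
  if (length(by_dyad) == 0L) stop("data error: no dyads in the trial log")

  member_fits <- list()
  metrics <- list()
  for (dyad_id in names(by_dyad)) {
    rec <- by_dyad[[dyad_id]]
    grp <- rec$group[1L]
    for (m in 1:2) {
      y <- (if (m == 1L) rec$choice_m1 else rec$choice_m2) == 2L
      fit <- tryCatch(fit_psychometric(rec$delta_c, y), error = function(e) NULL)
      member_fits[[length(member_fits) + 1L]] <- data.frame(
        dyad_id = dyad_id, group = grp, member = m,
        b = if (is.null(fit)) NA_real_ else fit$b,
        sigma = if (is.null(fit)) NA_real_ else fit$sigma,
        S_signed = if (is.null(fit)) NA_real_ else fit$S_signed,
        loglik = if (is.null(fit)) NA_real_ else fit$loglik,
        converged = if (is.null(fit)) FALSE else fit$converged,
        n_trials = nrow(rec),
        stringsAsFactors = FALSE
      )
    }
    scopes <- c(list(all = NULL), stats::setNames(
      as.list(sessions), paste0("session", sessions)
    ))
    for (scope in names(scopes)) {
      row <- tryCatch(
        compute_dyad_summary(rec, session = scopes[[scope]],
                             include_agreement = include_agreement,
                             ego_denominator = ego_denominator,
                             accuracy_threshold = accuracy_threshold),
        error = function(e) NULL
      )
      if (is.null(row)) next
      metrics[[length(metrics) + 1L]] <- cbind(
        data.frame(dyad_id = dyad_id, group = grp, scope = scope,
                   stringsAsFactors = FALSE),
        as.data.frame(row)
      )
    }
  }
  member_fits <- do.call(rbind, member_fits)
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL

  kept <- metrics[metrics$scope == "all" & !metrics$excluded, , drop = FALSE]
  if (nrow(kept) == 0L) {
    stop("pipeline error: all dyads excluded")
  }
  for (dd in setdiff(unique(metrics$dyad_id[metrics$scope == "all" &
                                            metrics$excluded]), NULL)) {
    reason <- metrics$exclusion_reason[metrics$dyad_id == dd &
                                       metrics$scope == "all"]
    warning(sprintf("dyad %s excluded: %s", dd, reason), call. = FALSE)
  }

  stats_tab <- build_stats_table(member_fits, metrics, kept, sessions)
  list(member_fits = member_fits, dyad_metrics = metrics, stats = stats_tab)
}

# Group-level statistics table; tests that cannot be computed for the data at
# hand (e.g. a single group, or too few kept dyads) are silently omitted.
build_stats_table <- function(member_fits, metrics, kept, sessions) {
  rows <- list()
  add <- function(contrast, res) {
    if (inherits(res, "error") || is.null(res)) return()
    if (inherits(res, "test_result")) {
      rows[[length(rows) + 1L]] <<- data.frame(
        contrast = contrast, test = res$test_name,
        statistic = res$statistic, df1 = res$df[1L],
        df2 = if (length(res$df) > 1L) res$df[2L] else NA_real_,
        p = res$p, effect_size = res$effect_size,
        effect_name = res$effect_name, stringsAsFactors = FALSE
      )
    }
  }
  try_test <- function(expr) tryCatch(expr, error = function(e) NULL)

  groups <- unique(kept$group)
  two_groups <- length(groups) == 2L

  kept_ids <- kept$dyad_id
  mf <- member_fits[member_fits$dyad_id %in% kept_ids, , drop = FALSE]
  kall <- kept

  # Individual (per-member) measures: accuracy, sensitivity, RT, ego bias.
  member_vals <- function(measure) {
    acc <- rbind(
      data.frame(group = kall$group, value = kall[[paste0(measure, "_m1")]]),
      data.frame(group = kall$group, value = kall[[paste0(measure, "_m2")]])
    )
    acc[!is.na(acc$value), , drop = FALSE]
  }
  if (two_groups) {
    for (measure in c("acc", "rt", "ego")) {
      mv <- member_vals(measure)
      add(paste0("individual_", measure, "_", groups[1L], "_vs_", groups[2L]),
          try_test(t_independent(mv$value[mv$group == groups[1L]],
                                 mv$value[mv$group == groups[2L]])))
    }
    add(paste0("individual_sensitivity_", groups[1L], "_vs_", groups[2L]),
        try_test(t_independent(mf$S_signed[mf$group == groups[1L]],
                               mf$S_signed[mf$group == groups[2L]])))
    for (measure in c("acc_joint", "joint_rt", "similarity", "benefit",
                      "optimality", "S_dyad")) {
      add(paste0("dyad_", measure, "_", groups[1L], "_vs_", groups[2L]),
          try_test(t_independent(kall[[measure]][kall$group == groups[1L]],
                                 kall[[measure]][kall$group == groups[2L]])))
    }
  }

  # One-sample tests of benefit/optimality against the null mean of 1.
  for (g in groups) {
    for (measure in c("benefit", "optimality")) {
      add(paste0(g, "_", measure, "_vs_1"),
          try_test(t_one_sample(kall[[measure]][kall$group == g], mu0 = 1)))
      for (s in sessions) {
        sk <- metrics[metrics$scope == paste0("session", s) &
                        metrics$dyad_id %in% kept_ids &
                        metrics$group == g, , drop = FALSE]
        add(paste0(g, "_", measure, "_session", s, "_vs_1"),
            try_test(t_one_sample(sk[[measure]][!is.na(sk[[measure]])], mu0 = 1)))
      }
    }
  }

  # Session-by-group mixed ANOVAs on dyad measures.
  if (two_groups && length(sessions) > 1L) {
    for (measure in c("benefit", "optimality")) {
      long <- metrics[metrics$scope != "all" & metrics$dyad_id %in% kept_ids,
                      c("dyad_id", "group", "scope", measure)]
      names(long) <- c("unit", "group", "session", "value")
      long <- long[!is.na(long$value), , drop = FALSE]
      complete <- names(which(table(long$unit) == length(sessions)))
      long <- long[long$unit %in% complete, , drop = FALSE]
      res <- try_test(mixed_anova(long)$interaction)
      add(paste0("anova_session_x_group_", measure), res)
    }
  }

  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate and analyse a full study
#'
#' End-to-end pipeline: draws observer parameters for every dyad in every
#' group, simulates each dyad's experiment, then runs the full measurement
#' battery via [analyze_study()]. All randomness descends from
#' `config$seed` through per-dyad child seeds. When `out_dir` is given,
#' writes `trials.csv`, `member_fits.csv`, `dyad_metrics.csv`, `stats.csv`
#' and a `manifest.txt` of key-value pairs describing the run.
#'
#' @param config A [study_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return Invisibly, a list with `trials`, `member_fits`, `dyad_metrics`,
#'   `stats`, `observers` (the generative parameters actually drawn) and
#'   `manifest`.
#' @export
run_study <- function(config, out_dir = NULL) {
  if (!inherits(config, "study_config")) stop("config must be a study_config")
  n_total <- sum(vapply(config$groups, `[[`, integer(1), "n_dyads"))
  seeds <- child_seeds(config$seed, n_total)

  trials <- list()
  observers <- list()
  k <- 0L
  for (grp in config$groups) {
    for (i in seq_len(grp$n_dyads)) {
      k <- k + 1L
      set.seed(seeds[k])
      obs1 <- draw_observer(grp)
      obs2 <- draw_observer(grp)
      design_seed <- sample.int(2147483646L, 1L)
      behav_seed <- sample.int(2147483646L, 1L)
      dyad_id <- sprintf("%s_%02d", grp$label, i)
      cfg <- config$experiment
      cfg$seed <- design_seed
      trials[[k]] <- simulate_experiment(
        obs1, obs2, cfg, rule = config$rule, seed = behav_seed,
        dyad_id = dyad_id, group = grp$label
      )
      observers[[k]] <- data.frame(
        dyad_id = dyad_id, group = grp$label,
        b_m1 = obs1$b, sigma_m1 = obs1$sigma, s_m1 = slope_from_sigma(obs1$sigma),
        b_m2 = obs2$b, sigma_m2 = obs2$sigma, s_m2 = slope_from_sigma(obs2$sigma),
        stringsAsFactors = FALSE
      )
    }
  }
  trials <- do.call(rbind, trials)
  observers <- do.call(rbind, observers)

  res <- analyze_study(trials,
                       accuracy_threshold = config$accuracy_threshold,
                       sessions = seq_len(config$experiment$n_sessions))

  all_scope <- res$dyad_metrics[res$dyad_metrics$scope == "all", , drop = FALSE]
  manifest <- c(
    package = "dyadwcs",
    package_version = as.character(utils::packageVersion("dyadwcs")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    rule = config$rule$kind,
    accuracy_threshold = config$accuracy_threshold,
    n_sessions = config$experiment$n_sessions,
    trials_per_dyad = config$experiment$n_sessions *
      config$experiment$blocks_per_session * config$experiment$trials_per_block,
    n_groups = length(config$groups),
    n_dyads = n_total,
    n_excluded = sum(all_scope$excluded),
    n_kept = sum(!all_scope$excluded)
  )

  out <- list(trials = trials, member_fits = res$member_fits,
              dyad_metrics = res$dyad_metrics, stats = res$stats,
              observers = observers, manifest = manifest, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trial_log(trials, file.path(out_dir, "trials.csv"))
    utils::write.csv(res$member_fits, file.path(out_dir, "member_fits.csv"),
                     row.names = FALSE)
    utils::write.csv(res$dyad_metrics, file.path(out_dir, "dyad_metrics.csv"),
                     row.names = FALSE)
    if (!is.null(res$stats)) {
      utils::write.csv(res$stats, file.path(out_dir, "stats.csv"),
                       row.names = FALSE)
    }
    writeLines(paste(names(manifest), manifest, sep = "="),
               file.path(out_dir, "manifest.txt"))
  }
  invisible(out)
}

#' Parameter-recovery diagnostics for the psychometric fit
#'
#' Simulates observers with known bias and noise on counterbalanced stimulus
#' schedules, refits each with [fit_psychometric()], and reports recovery
#' error per trial count: bias and RMSE of the estimates and the median
#' relative error of the noise SD. Recovery error should shrink as the trial
#' count grows.
#'
#' @param b_values,sigma_values Generative parameter grids; every combination
#'   is simulated `n_rep` times at every trial count.
#' @param n_trials Trial counts to compare.
#' @param n_rep Replicates per parameter combination.
#' @param increments Stimulus increments used to build the schedule.
#' @param seed Root seed.
#' @return A list of class `recovery_report`: `results` (one row per refitted
#'   simulation) and `summary` (per trial count: `median_rel_err_sigma`,
#'   `rmse_sigma`, `bias_sigma`, `rmse_b`).
#' @export
recovery_suite <- function(b_values = seq(-0.05, 0.05, length.out = 3),
                           sigma_values = seq(0.1, 0.4, length.out = 4),
                           n_trials = c(64L, 256L),
                           n_rep = 5L,
                           increments = c(0.075, 0.15, 0.20, 0.30),
                           seed = 1L) {
  set.seed(as.integer(seed))
  grid <- expand.grid(b = b_values, sigma = sigma_values, rep = seq_len(n_rep),
                      n = as.integer(n_trials))
  results <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    delta_c <- sample(c(-1, 1), g$n, replace = TRUE) *
      sample(rep(increments, length.out = g$n))
    obs <- observer_params(b = g$b, sigma = g$sigma)
    resp <- simulate_private(obs, delta_c)
    fit <- tryCatch(fit_psychometric(delta_c, resp$choice == 2L),
                    error = function(e) NULL)
    results[[i]] <- data.frame(
      b_true = g$b, sigma_true = g$sigma, n = g$n, rep = g$rep,
      b_hat = if (is.null(fit)) NA_real_ else fit$b,
      sigma_hat = if (is.null(fit)) NA_real_ else fit$sigma,
      converged = if (is.null(fit)) FALSE else fit$converged
    )
  }
  results <- do.call(rbind, results)
  ok <- results[results$converged & is.finite(results$sigma_hat), , drop = FALSE]
  summary_tab <- do.call(rbind, lapply(sort(unique(ok$n)), function(nn) {
    sub <- ok[ok$n == nn, , drop = FALSE]
    data.frame(
      n = nn,
      n_fits = nrow(sub),
      median_rel_err_sigma = stats::median(
        abs(sub$sigma_hat - sub$sigma_true) / sub$sigma_true),
      rmse_sigma = sqrt(mean((sub$sigma_hat - sub$sigma_true)^2)),
      bias_sigma = mean(sub$sigma_hat - sub$sigma_true),
      rmse_b = sqrt(mean((sub$b_hat - sub$b_true)^2))
    )
  }))
  structure(list(results = results, summary = summary_tab),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("psychometric parameter recovery\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
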