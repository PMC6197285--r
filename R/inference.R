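new_test_result <- function(test_name, statistic, df, p, effect_size,
                            effect_name = "cohens_d") {
  structure(
    list(test_name = test_name, statistic = statistic, df = df, p = p,
         effect_size = effect_size, effect_name = effect_name),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  df_txt <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(sprintf("%s: statistic(%s) = %.3f, p = %.4g, %s = %.3f\n",
              x$test_name, df_txt, x$statistic, x$p, x$effect_name,
              x$effect_size))
  invisible(x)
}

#' Independent-samples t-test with Cohen's d
#'
#' Pooled-variance Student t-test of two independent groups, two-sided, with
#' `df = nA + nB - 2` and Cohen's d computed from the pooled SD — the standard
#' between-group comparison for per-member and per-dyad measures.
#'
#' @param groupA,groupB Numeric vectors, each of length >= 2.
#' @return A `test_result` with `statistic`, `df`, `p`, `effect_size`
#'   (Cohen's d, sign = mean(A) - mean(B)).
#' @export
#' @examples
#' t_independent(c(1, 2, 3), c(2, 3, 4))   # t = -1.2247, df = 4
t_independent <- function(groupA, groupB) {
  groupA <- as.numeric(groupA); groupB <- as.numeric(groupB)
  if (length(groupA) < 2L || length(groupB) < 2L) {
    stop("data error: each group needs at least 2 observations")
  }
  nA <- length(groupA); nB <- length(groupB)
  sp2 <- ((nA - 1) * stats::var(groupA) + (nB - 1) * stats::var(groupB)) /
    (nA + nB - 2)
  if (sp2 <= 0) {
    stop("degenerate data: zero pooled variance")
  }
  ht <- stats::t.test(groupA, groupB, var.equal = TRUE)
  new_test_result(
    test_name = "independent-samples t-test",
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p = ht$p.value,
    effect_size = (mean(groupA) - mean(groupB)) / sqrt(sp2)
  )
}

#' One-sample t-test with Cohen's d
#'
#' Two-sided one-sample Student t-test of a sample mean against `mu0`,
#' `t = (mean - mu0) / (sd / sqrt(n))` with `df = n - 1` and
#' `d = (mean - mu0) / sd`. Used to test collective benefit and optimality
#' against the model null mean of 1.
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @param mu0 Null mean (default 1, the benchmark null).
#' @return A `test_result`.
#' @export
#' @examples
#' t_one_sample(c(1.1, 1.2, 1.3), mu0 = 1)   # t = 3.4641, df = 2
t_one_sample <- function(values, mu0 = 1) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("data error: need at least 2 observations")
  }
  s <- stats::sd(values)
  if (s == 0) {
    stop("degenerate data: zero variance")
  }
  n <- length(values)
  tstat <- (mean(values) - mu0) / (s / sqrt(n))
  new_test_result(
    test_name = "one-sample t-test",
    statistic = tstat,
    df = n - 1,
    p = 2 * stats::pt(-abs(tstat), df = n - 1),
    effect_size = (mean(values) - mu0) / s
  )
}

#' Mixed-design (split-plot) ANOVA: session within, group between
#'
#' Repeated-measures ANOVA with one within-unit factor (`session`) and one
#' between-unit factor (`group`), fitted with [stats::aov()] using an
#' `Error(unit)` stratum. For 2 sessions and 2 groups the group-by-session
#' interaction has `(1, N - 2)` degrees of freedom and its F statistic equals
#' the squared pooled t of the between-group comparison of within-unit session
#' differences. Requires complete, balanced data: every unit measured once per
#' session. Partial eta squared is reported per effect, computed within its
#' error stratum.
#'
#' @param data Data frame with columns `unit` (subject/dyad id), `group`,
#'   `session`, `value`.
#' @return An object of class `mixed_anova` containing `table` (one row per
#'   effect: `effect`, `F`, `df1`, `df2`, `p`, `partial_eta_sq`) and
#'   `interaction`, the group-by-session row as a `test_result`.
#' @export
mixed_anova <- function(data) {
  required <- c("unit", "group", "session", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("data error: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  d <- data.frame(
    unit = factor(data$unit),
    group = factor(data$group),
    session = factor(data$session),
    value = as.numeric(data$value)
  )
  if (anyNA(d$value)) stop("data error: missing values")
  counts <- table(d$unit, d$session)
  if (any(counts != 1L)) {
    stop("data error: every unit must have exactly one value per session")
  }
  units_per_group <- table(unique(d[, c("unit", "group")])$group)
  if (any(units_per_group < 2L)) {
    stop("data error: need at least 2 units per group")
  }

  fit <- stats::aov(value ~ group * session + Error(unit), data = d)
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1L]]
    terms <- trimws(rownames(tab))
    resid_row <- which(terms == "Residuals")
    ss_err <- tab[resid_row, "Sum Sq"]
    for (i in seq_along(terms)) {
      if (i == resid_row) next
      rows[[length(rows) + 1L]] <- data.frame(
        effect = terms[i],
        F = tab[i, "F value"],
        df1 = tab[i, "Df"],
        df2 = tab[resid_row, "Df"],
        p = tab[i, "Pr(>F)"],
        partial_eta_sq = tab[i, "Sum Sq"] / (tab[i, "Sum Sq"] + ss_err),
        stringsAsFactors = FALSE
      )
    }
  }
  table_out <- do.call(rbind, rows)
  rownames(table_out) <- NULL
  ia <- table_out[table_out$effect == "group:session", , drop = FALSE]
  interaction <- new_test_result(
    test_name = "mixed ANOVA group x session interaction",
    statistic = ia$F,
    df = c(ia$df1, ia$df2),
    p = ia$p,
    effect_size = ia$partial_eta_sq,
    effect_name = "partial_eta_sq"
  )
  structure(list(table = table_out, interaction = interaction),
            class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("mixed-design ANOVA (session within, group between)\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Mean, SD and n of a sample
#'
#' The "mean +/- SD" summary used throughout group-level reporting. The SD
#' uses the n - 1 denominator and is `NA` for a single observation.
#'
#' @param values Non-empty numeric vector.
#' @return A list with `mean`, `sd`, `n`.
#' @export
summarize_group <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("data error: empty sample")
  list(
    mean = mean(values),
    sd = if (length(values) > 1L) stats::sd(values) else NA_real_,
    n = length(values)
  )
}
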