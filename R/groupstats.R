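## Group-level statistics: normality, ANOVA + Tukey, t-tests, mean +/- SEM.

#' Significance marks for p-values
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, empty otherwise.
#'
#' @param p Numeric vector of p-values.
#' @param symbol Symbol to repeat (`"*"` by default; the reporting convention
#'   uses `"#"` for some contrasts).
#' @return Character vector of marks.
#' @export
sig_marks <- function(p, symbol = "*") {
  cut_idx <- findInterval(p, c(0, 0.001, 0.01, 0.05), rightmost.closed = FALSE)
  vapply(cut_idx, function(i) strrep(symbol, max(0L, 4L - i)), character(1))
}

#' Compare a metric between groups
#'
#' The statistical reporting layer of the pipeline: group means with SEM, a
#' per-group Shapiro-Wilk normality check (reported, never blocking), and the
#' appropriate comparison for the design -- one-way ANOVA with Tukey HSD
#' pairwise post hoc tests for 3+ groups, an unpaired two-sample t-test
#' (equal-variance by default) for 2 groups, or a paired t-test on matched
#' subjects.
#'
#' @param data A data frame with one row per subject.
#' @param value Column name (string) of the metric.
#' @param group Column name (string) of the grouping factor.
#' @param design `"auto"` (ANOVA for 3+ groups, unpaired t for 2),
#'   `"anova_tukey"`, `"t_unpaired"` or `"t_paired"`.
#' @param subject Column name identifying subjects (required for the paired
#'   design; both groups must contain the same subjects).
#' @param var_equal Use the equal-variance (non-Welch) unpaired t-test.
#' @return A `group_comparison` object with `summary` (group, n, mean, sem),
#'   `normality`, `tests` (test, comparison, statistic, p_value) and
#'   `design`. Use [tidy()] / [glance()] to extract tibbles.
#' @export
compare_groups <- function(data, value, group,
                           design = c("auto", "anova_tukey", "t_unpaired",
                                      "t_paired"),
                           subject = NULL, var_equal = TRUE) {
  design <- match.arg(design)
  df <- tibble(value = data[[value]], group = as.character(data[[group]]))
  df <- df[is.finite(df$value), ]
  groups <- unique(df$group)
  counts <- table(df$group)
  if (any(counts < 2)) abort("At least 2 observations per group are required.")
  if (design == "auto") {
    design <- if (length(groups) >= 3) "anova_tukey" else "t_unpaired"
  }
  summary <- df |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sem = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  normality <- df |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(
      shapiro_p = if (dplyr::n() >= 3 && sd(.data$value) > 0)
        shapiro.test(.data$value)$p.value else NA_real_,
      .groups = "drop")
  tests <- switch(design,
    anova_tukey = {
      if (length(groups) < 3) abort("ANOVA design needs at least 3 groups.")
      fit <- aov(value ~ group, data = transform(df, group = factor(group)))
      av <- summary(fit)[[1]]
      tk <- TukeyHSD(fit)$group
      dplyr::bind_rows(
        tibble(test = "anova", comparison = "omnibus",
               statistic = unname(av[["F value"]][1]),
               p_value = unname(av[["Pr(>F)"]][1])),
        tibble(test = "tukey_hsd", comparison = rownames(tk),
               statistic = unname(tk[, "diff"]),
               p_value = unname(tk[, "p adj"]))
      )
    },
    t_unpaired = {
      if (length(groups) != 2) abort("Unpaired t-test needs exactly 2 groups.")
      tt <- t.test(value ~ group, data = df, var.equal = var_equal)
      tibble(test = "t_unpaired",
             comparison = paste(rev(sort(groups)), collapse = "-"),
             statistic = unname(tt$statistic), p_value = tt$p.value)
    },
    t_paired = {
      if (is.null(subject)) abort("Paired design requires a `subject` column.")
      if (length(groups) != 2) abort("Paired t-test needs exactly 2 groups.")
      wide <- tibble(value = data[[value]], group = as.character(data[[group]]),
                     subject = as.character(data[[subject]])) |>
        tidyr::pivot_wider(names_from = "group", values_from = "value")
      if (anyNA(wide[groups])) {
        abort("Paired design requires matched samples of equal length.")
      }
      tt <- t.test(wide[[groups[1]]], wide[[groups[2]]], paired = TRUE)
      tibble(test = "t_paired",
             comparison = paste(groups, collapse = "-"),
             statistic = unname(tt$statistic), p_value = tt$p.value)
    })
  structure(list(metric = value, summary = summary, normality = normality,
                 tests = tests, design = design),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (%s)\n", x$metric, x$design))
  print(x$summary)
  print(x$tests)
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return `tidy()`: the tests tibble with significance marks;
#'   `glance()`: a one-row tibble with the omnibus (or single) test.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  x$tests |>
    dplyr::mutate(metric = x$metric, design = x$design,
                  mark = sig_marks(.data$p_value), .before = 1)
}

#' @rdname tidy.group_comparison
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  head_test <- x$tests[1, ]
  tibble(metric = x$metric, design = x$design,
         n_groups = nrow(x$summary),
         statistic = head_test$statistic, p_value = head_test$p_value)
}

#' Mean +/- SEM report table with significance flags
#'
#' Formats a comparison the way study tables report it: per group
#' `mean +/- SEM` and, for every non-reference group, the significance mark
#' of its pairwise contrast against the reference group (Tukey-adjusted in
#' the ANOVA design).
#'
#' @param comparison A `group_comparison`.
#' @param reference Reference group name (defaults to the first group).
#' @param digits Digits for mean and SEM formatting.
#' @return A tibble with `group`, `n`, `mean`, `sem`, `label`, `flag`.
#' @export
summary_table <- function(comparison, reference = NULL, digits = 3) {
  stopifnot(inherits(comparison, "group_comparison"))
  s <- comparison$summary
  reference <- reference %||% s$group[1]
  pair <- comparison$tests |> dplyr::filter(.data$test != "anova")
  flag_for <- function(g) {
    if (g == reference) return("")
    hit <- grepl(g, pair$comparison, fixed = TRUE) &
      grepl(reference, pair$comparison, fixed = TRUE)
    if (!any(hit)) return("")
    sig_marks(pair$p_value[which(hit)[1]])
  }
  s |>
    dplyr::mutate(
      label = sprintf("%s ± %s", signif(.data$mean, digits),
                      signif(.data$sem, 2)),
      flag = vapply(.data$group, flag_for, character(1), USE.NAMES = FALSE)
    )
}
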