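# Group-comparison and spatial-trend statistics. Results are reported
# as mean +/- SEM per group; pairwise comparisons use a two-tailed
# t-test (Welch by default, pooled Student's as an option), multi-group
# comparisons a one-way ANOVA, and anterior-posterior trends an OLS
# slope test within position windows.

#' @noRd
group_summary <- function(values, label) {
  n <- length(values)
  data.frame(group = label, n = n, mean = mean(values),
             sem = stats::sd(values) / sqrt(n),
             stringsAsFactors = FALSE)
}

#' @noRd
new_comparison_result <- function(kind, statistic, df, p_value, groups,
                                  extra = list()) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stopf("internal: p-value %g outside [0, 1]", p_value)
  structure(c(list(kind = kind, statistic = statistic, df = df,
                   p_value = p_value, groups = groups), extra),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic = %.4g, p = %.3g\n",
              x$kind, x$statistic, x$p_value))
  print(x$groups, digits = 4)
  invisible(x)
}

#' Two-tailed t-test between two groups
#'
#' Requires at least 3 observations per group. Welch's
#' unequal-variance test is the default (robust when group variances
#' differ, as they typically do across age groups); the pooled
#' Student's test is available and the variant used is recorded in the
#' result.
#'
#' @param a,b numeric vectors of per-slice (or per-animal) index values.
#' @param method `"welch"` or `"student"`.
#' @param labels length-2 character, group names for the summary.
#' @return a `comparison_result` with `statistic` (t), `df`, `p_value`
#'   and a per-group mean +/- SEM table.
#' @export
compare_two_groups <- function(a, b, method = c("welch", "student"),
                               labels = c("a", "b")) {
  method <- match.arg(method)
  if (length(a) < 3 || length(b) < 3)
    stopf("each group needs n >= 3 (got %d and %d)", length(a), length(b))
  tt <- stats::t.test(a, b, var.equal = (method == "student"),
                      alternative = "two.sided")
  new_comparison_result("t",
                        statistic = unname(tt$statistic),
                        df = unname(tt$parameter),
                        p_value = tt$p.value,
                        groups = rbind(group_summary(a, labels[1]),
                                       group_summary(b, labels[2])),
                        extra = list(method = method))
}

#' One-way ANOVA across several groups
#'
#' @param groups named list of numeric vectors, one per group; every
#'   group needs n >= 3.
#' @return a `comparison_result` with `statistic` (F), `df` (numerator,
#'   denominator), `p_value` and per-group summaries. A fully degenerate
#'   input (zero variance within every group and identical means) is
#'   reported as F = 0, p = 1 and flagged.
#' @export
compare_many_groups <- function(groups) {
  if (length(groups) < 2) stopf("need at least 2 groups")
  ns <- lengths(groups)
  if (any(ns < 3)) stopf("each group needs n >= 3 (got %s)",
                         paste(ns, collapse = ", "))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  gf <- factor(rep(names(groups), ns), levels = names(groups))
  summaries <- do.call(rbind, Map(group_summary, groups, names(groups)))
  rownames(summaries) <- NULL

  within_var <- vapply(groups, stats::var, 0)
  means <- vapply(groups, mean, 0)
  if (all(within_var == 0) && max(means) - min(means) == 0) {
    return(new_comparison_result("anova", statistic = 0,
                                 df = c(length(groups) - 1,
                                        sum(ns) - length(groups)),
                                 p_value = 1, groups = summaries,
                                 extra = list(degenerate = TRUE)))
  }
  fit <- stats::aov(values ~ gf)
  tab <- summary(fit)[[1]]
  new_comparison_result("anova",
                        statistic = tab[["F value"]][1],
                        df = tab[["Df"]],
                        p_value = tab[["Pr(>F)"]][1],
                        groups = summaries,
                        extra = list(degenerate = FALSE))
}

#' Default anterior-posterior position windows
#'
#' The three coronal regions used for the spatial-trend analysis,
#' chosen at changes in the dominant brain component along the
#' anterior-posterior axis: 0-1000 um (isocortex/olfactory), 1000-2250
#' um (striatum growth), and 2250-4250 um (interbrain), positions
#' measured from the anterior reference.
#'
#' @return list of three length-2 numeric windows (um).
#' @export
default_position_windows <- function() {
  list(c(0, 1000), c(1000, 2250), c(2250, 4250))
}

#' Spatial trend of an index along the anterior-posterior axis
#'
#' Ordinary least squares of an index against the slice position,
#' restricted to a position window, with a two-sided test of zero
#' slope. For cross-slice comparability the area-normalized index
#' variants (`D_n_norm`, `K_m_norm`) are the intended inputs.
#'
#' @param table data frame with a `position_ap` column (um) and the
#'   index column named by `index`.
#' @param index name of the index column to regress.
#' @param window length-2 numeric, position window (um); slices with
#'   `window[1] <= position_ap <= window[2]` are used.
#' @return a `comparison_result` with `kind = "slope"`: `statistic` is
#'   the t statistic of the slope; `slope`, `slope_se` and `n_window`
#'   are included.
#' @export
spatial_trend <- function(table, index, window) {
  if (!"position_ap" %in% names(table))
    stopf("table has no position_ap column")
  if (!index %in% names(table)) stopf("table has no column '%s'", index)
  sel <- !is.na(table$position_ap) &
    table$position_ap >= window[1] & table$position_ap <= window[2]
  if (sum(sel) < 3)
    stopf("only %d slices inside window [%g, %g] um; need >= 3",
          sum(sel), window[1], window[2])
  x <- table$position_ap[sel]
  y <- table[[index]][sel]
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  slope <- sm["x", "Estimate"]
  se <- sm["x", "Std. Error"]
  pv <- sm["x", "Pr(>|t|)"]
  tv <- sm["x", "t value"]
  new_comparison_result("slope", statistic = unname(tv),
                        df = length(x) - 2, p_value = unname(pv),
                        groups = data.frame(group = sprintf("[%g,%g]um",
                                                            window[1],
                                                            window[2]),
                                            n = length(x),
                                            mean = mean(y),
                                            sem = stats::sd(y) /
                                              sqrt(length(y))),
                        extra = list(slope = unname(slope),
                                     slope_se = unname(se),
                                     window = window,
                                     n_window = length(x)))
}
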