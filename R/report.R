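# Report assembly: per-group summaries, pairwise and multi-group
# comparisons, optional spatial trends, written as deterministic CSVs
# with optional figure panels.

#' Assemble a summary report from a per-slice index table
#'
#' Takes the table produced by row-binding
#' [as.data.frame.stress_indices()] outputs (or any data frame with a
#' `group` column and numeric index columns) and writes:
#' \itemize{
#'   \item `summary.csv` -- mean +/- SEM and n per group per index;
#'   \item `comparisons.csv` -- all pairwise two-tailed t-tests per
#'     index, plus a one-way ANOVA row when there are more than two
#'     groups;
#'   \item `trends.csv` -- when `position_ap` is present, the
#'     OLS slope test per index in each position window;
#'   \item bar-plus-scatter panels per index (PNG, requires ggplot2).
#' }
#' CSV output is deterministic: re-running on the same table produces
#' byte-identical files.
#'
#' @param table per-slice data frame with `group` and index columns.
#' @param indices character vector of index column names to report.
#' @param out_dir output directory, created if missing.
#' @param config a [run_config()]; its hash is recorded in every CSV so
#'   panels can be traced to the exact pipeline settings.
#' @param t_method `"welch"` or `"student"`.
#' @param windows position windows for the trend analysis; default
#'   [default_position_windows()].
#' @param figures emit PNG panels (needs ggplot2). Default `TRUE` when
#'   ggplot2 is installed.
#' @return invisible list of the written file paths.
#' @export
build_report <- function(table, indices = c("D_n", "R_a", "K_m"),
                         out_dir = ".", config = run_config(),
                         t_method = c("welch", "student"),
                         windows = default_position_windows(),
                         figures = requireNamespace("ggplot2",
                                                    quietly = TRUE)) {
  t_method <- match.arg(t_method)
  if (!is.data.frame(table) || nrow(table) == 0)
    stopf("empty index table: nothing to report")
  if (!"group" %in% names(table)) stopf("table has no group column")
  miss <- setdiff(indices, names(table))
  if (length(miss)) stopf("table is missing index column(s): %s",
                          paste(miss, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- config_hash(config)
  written <- list()

  groups <- split(table, table$group)
  summary_rows <- do.call(rbind, lapply(indices, function(ix) {
    do.call(rbind, lapply(names(groups), function(g) {
      v <- groups[[g]][[ix]]
      data.frame(index = ix, group = g, n = length(v), mean = mean(v),
                 sem = stats::sd(v) / sqrt(length(v)),
                 config = cfg_hash, stringsAsFactors = FALSE)
    }))
  }))
  p_sum <- file.path(out_dir, "summary.csv")
  utils::write.csv(summary_rows, p_sum, row.names = FALSE)
  written$summary <- p_sum

  comp_rows <- list()
  gnames <- names(groups)
  for (ix in indices) {
    if (length(gnames) >= 2) {
      prs <- utils::combn(gnames, 2, simplify = FALSE)
      for (pr in prs) {
        va <- groups[[pr[1]]][[ix]]; vb <- groups[[pr[2]]][[ix]]
        if (length(va) < 3 || length(vb) < 3) next
        cr <- compare_two_groups(va, vb, method = t_method, labels = pr)
        comp_rows[[length(comp_rows) + 1]] <-
          data.frame(index = ix, test = paste0("t_", t_method),
                     group_a = pr[1], group_b = pr[2],
                     statistic = cr$statistic, df = cr$df,
                     p_value = cr$p_value, config = cfg_hash,
                     stringsAsFactors = FALSE)
      }
    }
    if (length(gnames) > 2 && all(lengths(lapply(groups, `[[`, ix)) >= 3)) {
      cr <- compare_many_groups(lapply(groups, `[[`, ix))
      comp_rows[[length(comp_rows) + 1]] <-
        data.frame(index = ix, test = "anova", group_a = "all",
                   group_b = "all", statistic = cr$statistic,
                   df = cr$df[1], p_value = cr$p_value,
                   config = cfg_hash, stringsAsFactors = FALSE)
    }
  }
  if (length(comp_rows)) {
    p_cmp <- file.path(out_dir, "comparisons.csv")
    utils::write.csv(do.call(rbind, comp_rows), p_cmp, row.names = FALSE)
    written$comparisons <- p_cmp
  }

  if ("position_ap" %in% names(table) &&
      any(!is.na(table$position_ap))) {
    trend_rows <- list()
    for (ix in indices) {
      for (w in windows) {
        res <- tryCatch(spatial_trend(table, ix, w), error = function(e) NULL)
        if (is.null(res)) next
        trend_rows[[length(trend_rows) + 1]] <-
          data.frame(index = ix, window_lo = w[1], window_hi = w[2],
                     slope = res$slope, slope_se = res$slope_se,
                     t = res$statistic, p_value = res$p_value,
                     n = res$n_window, config = cfg_hash,
                     stringsAsFactors = FALSE)
      }
    }
    if (length(trend_rows)) {
      p_tr <- file.path(out_dir, "trends.csv")
      utils::write.csv(do.call(rbind, trend_rows), p_tr, row.names = FALSE)
      written$trends <- p_tr
    }
  }

  if (isTRUE(figures) && requireNamespace("ggplot2", quietly = TRUE)) {
    for (ix in indices) {
      df <- data.frame(group = table$group, value = table[[ix]])
      sm <- summary_rows[summary_rows$index == ix, ]
      p <- ggplot2::ggplot(sm, ggplot2::aes(x = group,
                                            y = mean)) +
        ggplot2::geom_col(fill = "grey80", colour = "grey30",
                          width = 0.6) +
        ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sem,
                                            ymax = mean + sem),
                               width = 0.2) +
        ggplot2::geom_jitter(data = df,
                             ggplot2::aes(x = group,
                                          y = value),
                             width = 0.1, size = 1.5, alpha = 0.7) +
        ggplot2::labs(x = NULL, y = ix,
                      caption = paste("config", cfg_hash)) +
        ggplot2::theme_classic()
      fp <- file.path(out_dir, paste0("panel_", ix, ".png"))
      ggplot2::ggsave(fp, p, width = 3.2, height = 3.2, dpi = 150)
      written[[paste0("panel_", ix)]] <- fp
    }
  }
  invisible(written)
}

# Short deterministic hash of a run configuration, used as provenance
# in report output.
#' @noRd
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))),
             collapse = ";")
  # small polynomial rolling hash; short, stable, dependency-free
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 4294967296
  sprintf("%08x", h)
}
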