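# Baseline "Table 1" construction and unadjusted outcome proportions.

#' Unadjusted mortality (or event) proportion
#'
#' `100 * events / n`, rounded half-up to one decimal — the convention of
#' printed baseline tables.
#'
#' @param events event count (0 <= events <= n).
#' @param n group size (> 0).
#' @return percentage with one decimal.
#' @examples
#' mortality_proportion(318, 825)
#' @export
mortality_proportion <- function(events, n) {
  if (any(n <= 0)) stop_ccw("n must be positive")
  if (any(events < 0 | events > n)) stop_ccw("events must lie in [0, n]")
  round_half_up(100 * events / n, 1)
}

#' Baseline characteristics table by group
#'
#' Classic two-group "Table 1": continuous variables as mean (SD) with a
#' Welch two-sample t-test, categorical/binary variables as n (%) with a
#' chi-square test (continuity-corrected for 2x2). Means are printed with
#' two decimals and percentages with one, rounded half-up.
#'
#' @param data data frame of subjects.
#' @param group_by name of a two-level grouping column.
#' @param variables variable names to summarize (default: all columns except
#'   the group and identifiers).
#' @return data frame of class `ccw_table1`: `variable`, `level`, one summary
#'   column per group, `p_value` (repeated within a variable's levels).
#' @export
baseline_table <- function(data, group_by,
                           variables = setdiff(names(data),
                                               c(group_by, "subject_id"))) {
  g <- data[[group_by]]
  if (is.null(g)) stop_ccw("grouping column '", group_by, "' not found")
  g <- factor(g)
  if (nlevels(g) != 2L || any(table(g) == 0))
    stop_ccw("group_by must have exactly two non-empty levels")
  lv <- levels(g)
  rows <- list()
  for (v in variables) {
    x <- data[[v]]
    if (is.numeric(x) && length(unique(na.omit(x))) > 2L) {
      p <- tryCatch(t.test(x ~ g)$p.value, error = function(e) NA_real_)
      s <- vapply(lv, function(l) {
        xi <- x[g == l]
        sprintf("%s (%s)", fmt_num(mean(xi, na.rm = TRUE), 2),
                fmt_num(sd(xi, na.rm = TRUE), 2))
      }, character(1))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = "mean (SD)", g1 = s[1], g2 = s[2],
        p_value = p, stringsAsFactors = FALSE)
    } else {
      x <- factor(x)
      tab <- table(x, g)
      p <- tryCatch(suppressWarnings(chisq.test(tab)$p.value),
                    error = function(e) NA_real_)
      for (l in rownames(tab)) {
        cnt <- tab[l, ]
        pct <- mortality_proportion(cnt, colSums(tab))
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = l,
          g1 = sprintf("%d (%.1f)", cnt[1], pct[1]),
          g2 = sprintf("%d (%.1f)", cnt[2], pct[2]),
          p_value = p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "g1"] <- paste0(lv[1], " (N=", sum(g == lv[1]), ")")
  names(out)[names(out) == "g2"] <- paste0(lv[2], " (N=", sum(g == lv[2]), ")")
  class(out) <- c("ccw_table1", "data.frame")
  out
}

#' Write a baseline table as Markdown
#'
#' @param table1 a `ccw_table1`.
#' @param path output file; `NULL` returns the lines invisibly.
#' @return the Markdown lines, invisibly.
#' @export
write_table1_md <- function(table1, path = NULL) {
  df <- as.data.frame(table1)
  df$p_value <- ifelse(is.na(df$p_value), "",
                       ifelse(df$p_value < 0.001, "<0.001",
                              sprintf("%.3f", df$p_value)))
  hdr <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  body <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  lines <- c(hdr, sep, body)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
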