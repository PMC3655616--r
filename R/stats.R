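# The session-comparison battery: paired/unpaired t-tests and the Wilcoxon
# rank-sum test, plus the per-electrode significance screen. These wrap the
# classical implementations in stats:: and standardise the output into
# one-row tibbles with explicit degenerate-case flags.

comparison_row <- function(statistic, p_value, df = NA_real_, method,
                           degenerate = FALSE, n = NA_integer_) {
  tibble(statistic = statistic, p_value = p_value, df = df,
         method = method, degenerate = degenerate, n = n)
}

#' Paired t-test
#'
#' Classical paired t statistic with a two-sided p-value. Zero-variance
#' differences are flagged rather than erroring deep in a pipeline: equal
#' vectors give `t = 0, p = 1`; a constant non-zero difference is degenerate
#' (`p = NA`).
#'
#' @param x,y Paired numeric vectors of equal length (>= 2), finite.
#' @return A one-row tibble: `statistic`, `p_value`, `df`, `method`,
#'   `degenerate`, `n`.
#' @export
#' @examples
#' paired_t(c(1, 2, 3), c(2, 4, 6))   # t = -3.46
paired_t <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 2,
              "paired samples must have equal length >= 2")
  assert_that(all(is.finite(x)) && all(is.finite(y)), "values must be finite")
  d <- x - y
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(comparison_row(0, 1, length(d) - 1, "paired t-test", FALSE, length(d)))
    }
    return(comparison_row(sign(mean(d)) * Inf, NA_real_, length(d) - 1,
                          "paired t-test", TRUE, length(d)))
  }
  tt <- t.test(x, y, paired = TRUE)
  comparison_row(unname(tt$statistic), tt$p.value, unname(tt$parameter),
                 "paired t-test", FALSE, length(d))
}

#' Two-sample (unpaired) t-test
#'
#' Welch's t by default; set `var_equal = TRUE` for the pooled-variance
#' variant.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param var_equal Assume equal variances (default FALSE = Welch).
#' @return A one-row tibble as in [paired_t()].
#' @export
unpaired_t <- function(x, y, var_equal = FALSE) {
  assert_that(length(x) >= 2 && length(y) >= 2, "each group needs >= 2 values")
  assert_that(all(is.finite(x)) && all(is.finite(y)), "values must be finite")
  if (sd(x) == 0 && sd(y) == 0) {
    meth <- if (var_equal) "pooled t-test" else "Welch t-test"
    if (mean(x) == mean(y)) {
      return(comparison_row(0, 1, length(x) + length(y) - 2, meth, FALSE,
                            length(x) + length(y)))
    }
    return(comparison_row(sign(mean(x) - mean(y)) * Inf, NA_real_, NA_real_,
                          meth, TRUE, length(x) + length(y)))
  }
  tt <- t.test(x, y, var.equal = var_equal)
  comparison_row(unname(tt$statistic), tt$p.value, unname(tt$parameter),
                 tt$method, FALSE, length(x) + length(y))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact p-value when the combined sample size is at most 20 and there are
#' no ties; otherwise the normal approximation with tie correction. The
#' method actually used is recorded in the output.
#'
#' @param x,y Numeric vectors, each of length >= 1.
#' @return A one-row tibble as in [paired_t()]; `statistic` is the
#'   Mann-Whitney U of the first sample.
#' @export
wilcoxon_ranksum <- function(x, y) {
  assert_that(length(x) >= 1 && length(y) >= 1, "each group needs >= 1 value")
  assert_that(all(is.finite(x)) && all(is.finite(y)), "values must be finite")
  if (length(unique(c(x, y))) == 1) {
    return(comparison_row(length(x) * length(y) / 2, NA_real_, NA_real_,
                          "Wilcoxon rank-sum (degenerate)", TRUE,
                          length(x) + length(y)))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 20 && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  meth <- if (exact) "Wilcoxon rank-sum (exact)"
          else "Wilcoxon rank-sum (normal approximation, tie-corrected)"
  comparison_row(unname(wt$statistic), wt$p.value, NA_real_, meth, FALSE,
                 length(x) + length(y))
}

#' Per-cell significance screen
#'
#' Applies one of the comparison tests to every cell (by default every
#' channel-by-band combination) of a long table holding one value per
#' experimental unit and condition, and flags cells with `p < alpha`. No
#' multiplicity correction is applied by default (per-channel screens are
#' reported uncorrected); `adjust = "BH"` switches to Benjamini-Hochberg
#' FDR, and the choice is recorded in the output.
#'
#' @param df Long tibble with at least the grouping columns, a `unit`
#'   column identifying the experimental unit (e.g. rat), a condition
#'   column with exactly two levels, and a value column.
#' @param value Name of the value column (string).
#' @param condition Name of the two-level condition column (string).
#' @param unit Name of the unit column (string); used to pair observations
#'   for `test = "paired_t"`.
#' @param group_cols Character vector of cell-defining columns (default
#'   `c("channel", "band")`).
#' @param test `"paired_t"`, `"unpaired_t"` or `"wilcoxon"`.
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble with one row per cell: the grouping columns, test
#'   output columns, `p_adjusted`, `significant` and `adjust`.
#' @export
per_channel_screen <- function(df, value, condition, unit,
                               group_cols = c("channel", "band"),
                               test = c("paired_t", "unpaired_t", "wilcoxon"),
                               alpha = 0.05, adjust = c("none", "BH")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  assert_that(alpha >= 0 && alpha <= 1, "`alpha` must be in [0, 1]")
  assert_that(all(c(value, condition, unit, group_cols) %in% names(df)),
              "missing columns in `df`")
  levs <- unique(df[[condition]])
  assert_that(length(levs) == 2, "`condition` must have exactly two levels")
  units_per_cond <- df |>
    group_by(across(all_of(c(group_cols, condition)))) |>
    summarise(units = list(sort(unique(.data[[unit]]))), .groups = "drop")
  if (test == "paired_t") {
    consistent <- length(unique(units_per_cond$units)) == 1
    assert_that(consistent, "units must match across cells and conditions for pairing")
  }
  res <- df |>
    group_by(across(all_of(group_cols))) |>
    group_modify(function(g, key) {
      a <- g[g[[condition]] == levs[1], ]
      b <- g[g[[condition]] == levs[2], ]
      if (test == "paired_t") {
        a <- a[order(a[[unit]]), ]; b <- b[order(b[[unit]]), ]
      }
      switch(test,
        paired_t = paired_t(a[[value]], b[[value]]),
        unpaired_t = unpaired_t(a[[value]], b[[value]]),
        wilcoxon = wilcoxon_ranksum(a[[value]], b[[value]]))
    }) |>
    ungroup()
  res$p_adjusted <- if (adjust == "BH") p.adjust(res$p_value, "BH") else res$p_value
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted < alpha
  res$adjust <- adjust
  res
}
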