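# Two-sample t-tests from sufficient statistics or raw values, and
# panel-level comparison tables.
#
# The published baseline tables print only mean/SD/N per group, so the
# pooled-variance Student t is computed directly from those sufficient
# statistics; the raw-data route reduces to the same algebra, making the
# two exactly interchangeable.

.VARIANCE_MODELS <- c("pooled", "welch")
.TAILS <- c("two.sided", "less", "greater")

normalize_tails <- function(tails) {
  map <- c(two.sided = "two.sided", twosided = "two.sided", two_sided = "two.sided",
           less = "less", lower = "less", greater = "greater", upper = "greater")
  key <- gsub("[^a-z.]", "", tolower(tails[1]))
  if (is.na(map[key])) {
    abort(sprintf("unknown tails '%s'", tails[1]),
          class = "otcpanel_validation_error")
  }
  unname(map[key])
}

as_group_summary <- function(x, what = "group summary") {
  if (is.data.frame(x)) x <- as.list(x)
  need <- c("mean", "sd", "n")
  if (!all(need %in% names(x))) {
    abort(sprintf("%s must have elements mean, sd and n", what),
          class = "otcpanel_format_error")
  }
  out <- lapply(x[need], as.numeric)
  if (any(vapply(out, length, 0L) != 1L)) {
    abort(sprintf("%s must be a single (mean, sd, n) triple", what),
          class = "otcpanel_format_error")
  }
  if (out$n < 2) {
    abort(sprintf("%s has n < 2; a variance must be estimable", what),
          class = "otcpanel_validation_error")
  }
  if (out$sd < 0) {
    abort(sprintf("%s has negative sd", what),
          class = "otcpanel_validation_error")
  }
  out
}

#' Two-sample t-test from summary statistics
#'
#' Student (pooled-variance) or Welch two-sample t computed from each
#' group's sufficient statistics (mean, SD, N).  The statistic is oriented
#' as `t = (b$mean - a$mean) / SE`, so with `a` = wild type and `b` =
#' mutant, positive `t` means the analyte is higher in the mutant.
#'
#' Pooled: `sp^2 = ((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a + n_b - 2)`,
#' `df = n_a + n_b - 2`.  Welch uses the Satterthwaite df.  If both SDs are
#' zero and the means are equal the statistic is defined as `t = 0, p = 1`;
#' if both SDs are zero and the means differ the variance is degenerate and
#' an error is raised.
#'
#' @param a,b Group summaries: lists or one-row data frames with elements
#'   `mean`, `sd`, `n` (n >= 2 each).
#' @param variance `"pooled"` (default; reproduces the published P-values)
#'   or `"welch"`.
#' @param tails `"two.sided"` (default), `"less"`/`"lower"` (P(T <= t)) or
#'   `"greater"`/`"upper"`.
#' @return One-row tibble with `t, df, p, tails, variance, direction`
#'   (`direction` is the sign of `b$mean - a$mean`).
#' @export
#' @examples
#' # cerebral glutamine, WT vs mutant baseline
#' t_from_summary(list(mean = 235.0, sd = 18.7, n = 5),
#'                list(mean = 350.3, sd = 105.1, n = 5))
t_from_summary <- function(a, b, variance = c("pooled", "welch"),
                           tails = "two.sided") {
  variance <- match.arg(variance)
  tails <- normalize_tails(tails)
  a <- as_group_summary(a, "group 'a'")
  b <- as_group_summary(b, "group 'b'")
  diff <- b$mean - a$mean
  if (a$sd == 0 && b$sd == 0) {
    if (diff != 0) {
      abort("degenerate variance: both groups have sd = 0 but unequal means",
            class = "otcpanel_degenerate_error")
    }
    tt <- 0
    df <- if (variance == "pooled") a$n + b$n - 2 else a$n + b$n - 2
  } else if (variance == "pooled") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    tt <- diff / sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    tt <- diff / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  p <- switch(tails,
              two.sided = 2 * pt(-abs(tt), df),
              less = pt(tt, df),
              greater = pt(tt, df, lower.tail = FALSE))
  tibble(t = tt, df = df, p = p, tails = tails, variance = variance,
         direction = sign(diff))
}

#' Two-sample t-test from raw values
#'
#' Identical contract to [t_from_summary()] applied to the two samples'
#' sufficient statistics; the two routes agree exactly (algebraic identity).
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @inheritParams t_from_summary
#' @return One-row tibble as in [t_from_summary()]; `t` is positive when
#'   `mean(y) > mean(x)`.
#' @export
t_from_raw <- function(x, y, variance = c("pooled", "welch"),
                       tails = "two.sided") {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) {
    abort("each sample needs at least 2 observations",
          class = "otcpanel_validation_error")
  }
  t_from_summary(list(mean = mean(x), sd = sd(x), n = length(x)),
                 list(mean = mean(y), sd = sd(y), n = length(y)),
                 variance = variance, tails = tails)
}

#' Panel-level two-group comparison
#'
#' One two-sample t-test per analyte, wild type vs mutant, in table order.
#' No multiple-testing adjustment is applied by default (mirroring the
#' published tables); see [adjust_panel()] for an optional
#' Benjamini-Hochberg post-processor.
#'
#' @param wt Either a `panel_summary` table (from [read_summary_table()] /
#'   [panel_fixture()]), in which case `spfj` is ignored, or a tibble of
#'   wild-type group summaries with columns `analyte, mean, sd, n`.
#' @param spfj Mutant group summaries (same columns), when `wt` is not a
#'   `panel_summary`.  Analyte sets must match exactly.
#' @param alpha Significance threshold, in (0, 1); default 0.05.
#' @param variance Variance model passed to [t_from_summary()].
#' @return A `panel_comparison` tibble: one row per analyte with the group
#'   summaries, `t, df, p, direction, significant`, and attributes `alpha`,
#'   `variance` and (when known) `tissue`.
#' @export
#' @examples
#' cmp <- panel_compare(panel_fixture("cerebrum"))
#' count_significant(cmp, "increased")
panel_compare <- function(wt, spfj = NULL, alpha = 0.05,
                          variance = c("pooled", "welch")) {
  variance <- match.arg(variance)
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1)) {
    abort("alpha must be a single number in (0, 1)",
          class = "otcpanel_validation_error")
  }
  tissue <- NA_character_
  if (inherits(wt, "panel_summary")) {
    tissue <- attr(wt, "tissue")
    tab <- wt
    wt <- tibble(analyte = tab$analyte, mean = tab$wt_mean,
                 sd = tab$wt_sd, n = tab$wt_n)
    spfj <- tibble(analyte = tab$analyte, mean = tab$spfj_mean,
                   sd = tab$spfj_sd, n = tab$spfj_n)
  }
  wt <- as_tibble(wt)
  spfj <- as_tibble(spfj)
  only_wt <- setdiff(wt$analyte, spfj$analyte)
  only_spfj <- setdiff(spfj$analyte, wt$analyte)
  if (length(only_wt) > 0 || length(only_spfj) > 0) {
    abort(sprintf("analyte sets differ (wt only: %s; spfj only: %s)",
                  paste(only_wt, collapse = ", "),
                  paste(only_spfj, collapse = ", ")),
          class = "otcpanel_validation_error")
  }
  spfj <- spfj[match(wt$analyte, spfj$analyte), ]
  tests <- dplyr::bind_rows(lapply(seq_len(nrow(wt)), function(i) {
    t_from_summary(wt[i, c("mean", "sd", "n")], spfj[i, c("mean", "sd", "n")],
                   variance = variance)
  }))
  out <- tibble(analyte = wt$analyte,
                wt_mean = wt$mean, wt_sd = wt$sd, wt_n = wt$n,
                spfj_mean = spfj$mean, spfj_sd = spfj$sd, spfj_n = spfj$n,
                t = tests$t, df = tests$df, p = tests$p,
                direction = tests$direction,
                significant = tests$p < alpha)
  structure(out, alpha = alpha, variance = variance, tissue = tissue,
            class = c("panel_comparison", class(out)))
}

#' Count significant analytes in a panel comparison
#'
#' Number of analytes with `p < alpha` and, optionally, a required sign of
#' the mutant-minus-wild-type mean difference.
#'
#' @param cmp A `panel_comparison` from [panel_compare()].
#' @param direction `"any"` (ignore sign), `"increased"` (higher in mutant)
#'   or `"decreased"`.
#' @return Integer count.
#' @export
count_significant <- function(cmp, direction = c("any", "increased",
                                                 "decreased")) {
  direction <- match.arg(direction)
  keep <- cmp$significant & switch(direction,
                                   any = TRUE,
                                   increased = cmp$direction > 0,
                                   decreased = cmp$direction < 0)
  sum(keep)
}

#' Benjamini-Hochberg adjustment for a panel comparison
#'
#' Optional post-processor adding an FDR-adjusted p-value column; the
#' reproduction of the published tables never uses it (the original
#' analysis applied no multiple-testing correction).
#'
#' @param cmp A `panel_comparison`.
#' @return The comparison with an extra `p_adj` column; the `significant`
#'   column is left untouched.
#' @export
adjust_panel <- function(cmp) {
  cmp$p_adj <- p.adjust(cmp$p, method = "BH")
  cmp
}

#' Check a panel comparison against printed P-values
#'
#' Matches recomputed p-values against a published table's printed cells:
#' numeric cells must agree within `slack` (default +/-0.02, covering the
#' one-decimal rounding of printed means/SDs); `"<threshold"` bound cells
#' must satisfy `p < threshold`.
#'
#' @param cmp A `panel_comparison` computed from a summary table.
#' @param summary The `panel_summary` the comparison came from.
#' @param slack Absolute tolerance on numeric cells.
#' @return Tibble with one row per analyte: printed and recomputed values
#'   and a logical `ok`.
#' @export
check_printed_p <- function(cmp, summary, slack = 0.02) {
  stopifnot(identical(cmp$analyte, summary$analyte))
  ok <- ifelse(is.na(summary$printed_p_bound),
               abs(cmp$p - summary$printed_p_value) <= slack,
               cmp$p < summary$printed_p_bound)
  tibble(analyte = cmp$analyte, printed_p = summary$printed_p,
         p = cmp$p, ok = ok)
}
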