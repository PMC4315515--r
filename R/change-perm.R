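# Change-from-baseline t-statistics, the heat-map matrix, and the
# permutation test of the difference-in-change statistic
#
#   D = (mean mutant treated - mean mutant baseline)
#     - (mean WT treated     - mean WT baseline),
#
# an interaction contrast of the four cell means.  The null distribution
# is obtained by pooling all observations and reassigning them uniformly
# at random to the four cells, preserving the observed cell sizes; small
# designs are enumerated exactly.

.PERM_TAILS <- c("two.sided", "lower", "upper")

normalize_perm_tail <- function(tail) {
  map <- c(two.sided = "two.sided", twosided = "two.sided",
           two_sided = "two.sided", lower = "lower", less = "lower",
           upper = "upper", greater = "upper")
  key <- gsub("[^a-z.]", "", tolower(tail[1]))
  if (is.na(map[key])) {
    abort(sprintf("unknown tail '%s'", tail[1]),
          class = "otcpanel_validation_error")
  }
  unname(map[key])
}

#' Change-from-baseline t-statistic
#'
#' The t-statistic of treated vs baseline for one (analyte, tissue,
#' genotype) cell, signed positive when the treated mean exceeds baseline.
#' This is exactly the statistic plotted in the change heat maps.
#'
#' @param baseline,treated Numeric vectors (>= 2 values each).
#' @param variance Variance model (see [t_from_raw()]).
#' @return A single numeric t value.
#' @export
change_t <- function(baseline, treated, variance = c("pooled", "welch")) {
  t_from_raw(baseline, treated, variance = match.arg(variance))$t
}

#' Change-from-baseline heat-map matrix
#'
#' For each analyte in the tissue's canonical panel order and each
#' genotype, computes [change_t()] between the baseline and treated
#' animals.  A cell whose baseline or treated group is absent (or has
#' fewer than 2 animals) is an explicit `NA`, never silently dropped.
#'
#' @param cohort A cohort table containing both treatments.
#' @param tissue Tissue to build the matrix for.
#' @param variance Variance model for the per-cell t.
#' @return A `heatmap_matrix`: numeric matrix (analytes x genotypes,
#'   columns `WT`, `SPFJ`) with a `tissue` attribute.
#' @seealso [write_heatmap()], [plot.heatmap_matrix()]
#' @export
build_heatmap <- function(cohort, tissue, variance = c("pooled", "welch")) {
  variance <- match.arg(variance)
  tissue <- canonical_token(tissue, TISSUES, "tissue")
  cohort <- validate_cohort(cohort)
  cohort <- cohort[cohort$tissue == tissue, ]
  if (nrow(cohort) == 0) {
    abort(sprintf("cohort has no %s measurements", tolower(tissue)),
          class = "otcpanel_validation_error")
  }
  analytes <- intersect(panel_analytes(tissue), unique(cohort$analyte))
  m <- matrix(NA_real_, nrow = length(analytes), ncol = length(GENOTYPES),
              dimnames = list(analytes, GENOTYPES))
  for (a in analytes) {
    for (g in GENOTYPES) {
      base <- cohort$concentration[cohort$analyte == a & cohort$genotype == g &
                                   cohort$treatment == "BASELINE"]
      trt  <- cohort$concentration[cohort$analyte == a & cohort$genotype == g &
                                   cohort$treatment == "POLYIC"]
      if (length(base) >= 2 && length(trt) >= 2) {
        m[a, g] <- change_t(base, trt, variance = variance)
      }
    }
  }
  structure(m, tissue = tissue, class = c("heatmap_matrix", "matrix", "array"))
}

#' Write a heat-map matrix to TSV
#'
#' Lossless tab-separated export (analyte row names, genotype columns);
#' the TSV is the canonical artifact, plotting is cosmetic.
#'
#' @param x A `heatmap_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(x, path) {
  df <- data.frame(analyte = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE, row.names = NULL)
  readr::write_tsv(as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' Plot a change heat map
#'
#' Diverging-colour tile plot of the change-from-baseline t-statistics,
#' analytes on the vertical axis in panel order, genotypes on the
#' horizontal axis.
#'
#' @param x A `heatmap_matrix`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot.heatmap_matrix <- function(x, ...) {
  df <- tidyr::pivot_longer(
    tibble(analyte = rownames(x), WT = x[, "WT"], SPFJ = x[, "SPFJ"]),
    cols = c("WT", "SPFJ"), names_to = "genotype", values_to = "t_change")
  df$analyte <- factor(df$analyte, levels = rev(rownames(x)))
  df$genotype <- factor(df$genotype, levels = GENOTYPES)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genotype, y = .data$analyte,
                                   fill = .data$t_change)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                  high = "red3", midpoint = 0,
                                  name = "t (change)") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Change from baseline (%s)",
                                  tolower(attr(x, "tissue")))) +
    ggplot2::theme_minimal()
}

check_groups <- function(groups) {
  need <- c("wt_baseline", "wt_treated", "spfj_baseline", "spfj_treated")
  if (!all(need %in% names(groups))) {
    abort(sprintf("groups must be named %s", paste(need, collapse = ", ")),
          class = "otcpanel_format_error")
  }
  groups <- lapply(groups[need], as.numeric)
  if (any(vapply(groups, length, 0L) == 0)) {
    abort("all four groups must be nonempty",
          class = "otcpanel_validation_error")
  }
  groups
}

#' Difference-in-change statistic D
#'
#' `d_spfj = mean(spfj_treated) - mean(spfj_baseline)`, `d_wt` likewise
#' for wild type, and `d_obs = d_spfj - d_wt`: the 2x2 interaction
#' contrast of cell means quantifying how differently the mutant and the
#' wild type respond to treatment.
#'
#' @param wt_baseline,wt_treated,spfj_baseline,spfj_treated Numeric
#'   vectors of per-animal values (each nonempty).
#' @return One-row tibble with `d_spfj, d_wt, d_obs`.
#' @export
#' @examples
#' d_statistic(c(0, 0), c(2, 2), c(0, 0), c(1, 1))  # d_obs = -1
d_statistic <- function(wt_baseline, wt_treated, spfj_baseline, spfj_treated) {
  g <- check_groups(list(wt_baseline = wt_baseline, wt_treated = wt_treated,
                         spfj_baseline = spfj_baseline,
                         spfj_treated = spfj_treated))
  d_spfj <- mean(g$spfj_treated) - mean(g$spfj_baseline)
  d_wt <- mean(g$wt_treated) - mean(g$wt_baseline)
  tibble(d_spfj = d_spfj, d_wt = d_wt, d_obs = d_spfj - d_wt)
}

# Number of distinct assignments of the pooled observations to cells of
# the given sizes (multinomial coefficient).
n_assignments <- function(sizes) {
  round(exp(lfactorial(sum(sizes)) - sum(lfactorial(sizes))))
}

# D for every distinct assignment of `vals` to cells of sizes
# (wt_baseline, wt_treated, spfj_baseline, spfj_treated).
enumerate_d <- function(vals, sizes) {
  n <- length(vals)
  total <- sum(vals)
  res <- numeric(n_assignments(sizes))
  k <- 0L
  c1 <- combn(n, sizes[1])
  for (i in seq_len(ncol(c1))) {
    g1 <- c1[, i]
    s1 <- sum(vals[g1])
    r1 <- setdiff(seq_len(n), g1)
    c2 <- combn(length(r1), sizes[2])
    for (j in seq_len(ncol(c2))) {
      g2 <- r1[c2[, j]]
      s2 <- sum(vals[g2])
      r2 <- setdiff(r1, g2)
      c3 <- combn(length(r2), sizes[3])
      for (l in seq_len(ncol(c3))) {
        g3 <- r2[c3[, l]]
        s3 <- sum(vals[g3])
        s4 <- total - s1 - s2 - s3
        k <- k + 1L
        res[k] <- (s4 / sizes[4] - s3 / sizes[3]) -
                  (s2 / sizes[2] - s1 / sizes[1])
      }
    }
  }
  res
}

# B Monte-Carlo draws of D under random reassignment.
sample_d <- function(vals, sizes, B) {
  n <- length(vals)
  cs <- cumsum(sizes)
  idx <- vapply(seq_len(B), function(i) sample.int(n), integer(n))
  m <- matrix(vals[idx], nrow = n)
  g1 <- .colMeans(m[seq_len(cs[1]), , drop = FALSE], sizes[1], B)
  g2 <- .colMeans(m[(cs[1] + 1):cs[2], , drop = FALSE], sizes[2], B)
  g3 <- .colMeans(m[(cs[2] + 1):cs[3], , drop = FALSE], sizes[3], B)
  g4 <- .colMeans(m[(cs[3] + 1):cs[4], , drop = FALSE], sizes[4], B)
  (g4 - g3) - (g2 - g1)
}

#' Permutation test of the difference-in-change statistic
#'
#' Pools the observations of all four (genotype x treatment) cells,
#' reassigns them uniformly at random to the cells preserving the observed
#' cell sizes, and recomputes D each time.  When the number of distinct
#' assignments is at most `exact_threshold` the full permutation null is
#' enumerated instead of sampled (`exact = TRUE`; the identity assignment
#' is then included, so p > 0 by construction).
#'
#' Tail rules (tie-inclusive by default):
#' * `"lower"`: `p = #\{D_perm <= d_obs\} / B` -- the literal published rule,
#'   with ties counted;
#' * `"upper"`: symmetric;
#' * `"two.sided"` (default): `p = #\{|D_perm| >= |d_obs|\} / B`.
#'
#' `ties = "strict"` reproduces the literal strict-inequality reading,
#' which is anti-conservative (the degenerate all-equal case then returns
#' p = 0 instead of 1).
#'
#' @inheritParams d_statistic
#' @param B Number of Monte-Carlo permutations (default 100,000, the
#'   published budget).  Ignored when exact enumeration engages.
#' @param tail `"two.sided"`, `"lower"` or `"upper"`.
#' @param seed Optional integer seed for the Monte-Carlo draw; identical
#'   seed and inputs give identical results.
#' @param exact_threshold Enumerate exactly when the number of distinct
#'   assignments is at most this (default 200,000).
#' @param ties `"inclusive"` (default) or `"strict"`.
#' @return One-row tibble: `d_spfj, d_wt, d_obs, B, tail, p, seed, exact`.
#' @export
permutation_test <- function(wt_baseline, wt_treated, spfj_baseline,
                             spfj_treated, B = 100000,
                             tail = c("two.sided", "lower", "upper"),
                             seed = NULL, exact_threshold = 200000,
                             ties = c("inclusive", "strict")) {
  tail <- normalize_perm_tail(tail)
  ties <- match.arg(ties)
  if (!(is.numeric(B) && length(B) == 1 && B >= 1)) {
    abort("B must be a single integer >= 1",
          class = "otcpanel_validation_error")
  }
  g <- check_groups(list(wt_baseline = wt_baseline, wt_treated = wt_treated,
                         spfj_baseline = spfj_baseline,
                         spfj_treated = spfj_treated))
  d <- d_statistic(g$wt_baseline, g$wt_treated, g$spfj_baseline,
                   g$spfj_treated)
  # canonical (sorted-within-group) pooling so Monte-Carlo draws depend
  # only on the observed value multisets, not on input row order
  vals <- unlist(lapply(g, sort), use.names = FALSE)
  sizes <- vapply(g, length, 0L)
  exact <- n_assignments(sizes) <= exact_threshold
  if (exact) {
    dperm <- enumerate_d(vals, sizes)
    B <- length(dperm)
  } else {
    dperm <- with_seed(seed, sample_d(vals, sizes, as.integer(B)))
  }
  # absolute tolerance so that float round-off in regrouped means does not
  # flip a tie into a strict inequality
  eps <- 1e-9 * (max(abs(vals)) + 1)
  p <- switch(
    tail,
    lower = if (ties == "inclusive") mean(dperm <= d$d_obs + eps)
            else mean(dperm < d$d_obs - eps),
    upper = if (ties == "inclusive") mean(dperm >= d$d_obs - eps)
            else mean(dperm > d$d_obs + eps),
    two.sided = if (ties == "inclusive") mean(abs(dperm) >= abs(d$d_obs) - eps)
                else mean(abs(dperm) > abs(d$d_obs) + eps))
  tibble(d_spfj = d$d_spfj, d_wt = d$d_wt, d_obs = d$d_obs,
         B = as.integer(B), tail = tail, p = p,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         exact = exact)
}

#' Panel-wide permutation tests
#'
#' Runs [permutation_test()] for every analyte of a tissue that has all
#' four (genotype x treatment) cells.  Each analyte gets its own RNG
#' stream derived from the master seed, the tissue and the analyte name,
#' so results do not depend on processing order.
#'
#' @param cohort A cohort table covering both genotypes and treatments.
#' @param tissue Tissue to test.
#' @param B,tail,exact_threshold,ties Passed to [permutation_test()].
#' @param seed Master seed (integer).
#' @return Tibble with one row per analyte (panel order), the permutation
#'   result columns, and the tissue.
#' @export
panel_permutation <- function(cohort, tissue, B = 100000,
                              tail = c("two.sided", "lower", "upper"),
                              seed = 1, exact_threshold = 200000,
                              ties = c("inclusive", "strict")) {
  tail <- normalize_perm_tail(tail)
  ties <- match.arg(ties)
  tissue <- canonical_token(tissue, TISSUES, "tissue")
  cohort <- validate_cohort(cohort)
  cohort <- cohort[cohort$tissue == tissue, ]
  analytes <- intersect(panel_analytes(tissue), unique(cohort$analyte))
  rows <- lapply(analytes, function(a) {
    sub <- cohort[cohort$analyte == a, ]
    cell <- function(g, tr) {
      sub$concentration[sub$genotype == g & sub$treatment == tr]
    }
    g <- list(wt_baseline = cell("WT", "BASELINE"),
              wt_treated = cell("WT", "POLYIC"),
              spfj_baseline = cell("SPFJ", "BASELINE"),
              spfj_treated = cell("SPFJ", "POLYIC"))
    if (any(vapply(g, length, 0L) == 0)) {
      abort(sprintf("analyte %s lacks one of the four (genotype, treatment) cells", a),
            class = "otcpanel_validation_error")
    }
    res <- permutation_test(g$wt_baseline, g$wt_treated, g$spfj_baseline,
                            g$spfj_treated, B = B, tail = tail,
                            seed = derive_seed(seed, tissue, a),
                            exact_threshold = exact_threshold, ties = ties)
    dplyr::bind_cols(tibble(analyte = a, tissue = tissue), res)
  })
  dplyr::bind_rows(rows)
}
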