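# Simulation harness certifying the testing machinery: type-I error under
# the factorial null and power against an injected interaction, for both
# the permutation test of D and the two-sample t-test.  The raw
# immune-challenge data behind the published heat maps are unpublished,
# so the permutation procedure is validated by its operating
# characteristics rather than by value.

#' Type-I error of a test under the Gaussian factorial null
#'
#' Simulates `replicates` independent 2x2 cohorts of one analyte (all four
#' cells i.i.d. Gaussian with mean `mu`, SD `sigma`, plus `delta` added to
#' the mutant-treated cell) and reports the fraction of replicates with
#' `p <= alpha`, with an exact binomial 95% confidence interval.  With
#' `delta = 0` this is the size of the test; with `delta != 0` it is the
#' power against that interaction.
#'
#' @param test `"permutation"` (the difference-in-change test) or
#'   `"ttest"` (pooled two-sample t between the two treated cells).
#' @param n_per_group Animals per cell (default 5, the published design).
#' @param mu,sigma Cell mean and SD of the null distribution.
#' @param delta Interaction shift added to the mutant-treated cell mean.
#' @param alpha Nominal level.
#' @param replicates Number of simulated cohorts (>= 100).
#' @param B Monte-Carlo permutations per replicate (the harness default,
#'   2,000, trades the outer times inner simulation budget against
#'   p-value granularity 1/B).
#' @param tail,ties Permutation-test options (see [permutation_test()]).
#' @param variance Variance model for the t route.
#' @param seed Master seed; each replicate uses a derived stream.
#' @return One-row tibble of operating characteristics: `test, tail,
#'   alpha, delta, n_per_group, replicates, rejections, rejection_rate,
#'   ci_lo, ci_hi, seed`.
#' @export
type_one_error <- function(test = c("permutation", "ttest"),
                           n_per_group = 5, mu = 100, sigma = 10,
                           delta = 0, alpha = 0.05, replicates = 2000,
                           B = 2000, tail = "two.sided",
                           ties = c("inclusive", "strict"),
                           variance = c("pooled", "welch"), seed = 1) {
  test <- match.arg(test)
  ties <- match.arg(ties)
  variance <- match.arg(variance)
  tail <- normalize_perm_tail(tail)
  if (!(is.numeric(replicates) && length(replicates) == 1 &&
        replicates >= 100)) {
    abort("replicates must be >= 100 (the binomial CI is meaningless below)",
          class = "otcpanel_validation_error")
  }
  if (!(alpha >= 0 && alpha <= 1)) {
    abort("alpha must lie in [0, 1]", class = "otcpanel_validation_error")
  }
  rej <- with_seed(seed, {
    vapply(seq_len(replicates), function(i) {
      wb <- rnorm(n_per_group, mu, sigma)
      wt <- rnorm(n_per_group, mu, sigma)
      sb <- rnorm(n_per_group, mu, sigma)
      st <- rnorm(n_per_group, mu + delta, sigma)
      p <- if (test == "permutation") {
        permutation_test(wb, wt, sb, st, B = B, tail = tail, ties = ties,
                         exact_threshold = 0)$p
      } else {
        t_from_raw(wt, st, variance = variance)$p
      }
      p <= alpha
    }, logical(1))
  })
  k <- sum(rej)
  ci <- binom.test(k, replicates)$conf.int
  tibble(test = test, tail = tail, alpha = alpha, delta = delta,
         n_per_group = n_per_group, replicates = as.integer(replicates),
         rejections = k, rejection_rate = k / replicates,
         ci_lo = ci[1], ci_hi = ci[2], seed = as.integer(seed))
}

#' Power curve over a grid of interaction effects
#'
#' One [type_one_error()] run per value of `delta_grid`, on independent
#' derived RNG streams; the `delta = 0` entry reproduces the size of the
#' test.  Rejection rates are nondecreasing in `|delta|` up to
#' Monte-Carlo noise.
#'
#' @param delta_grid Nonempty numeric vector of interaction shifts.
#' @inheritParams type_one_error
#' @return Tibble with one operating-characteristics row per `delta`.
#' @export
power_curve <- function(delta_grid, test = c("permutation", "ttest"),
                        n_per_group = 5, mu = 100, sigma = 10,
                        alpha = 0.05, replicates = 2000, B = 2000,
                        tail = "two.sided", ties = c("inclusive", "strict"),
                        variance = c("pooled", "welch"), seed = 1) {
  if (length(delta_grid) == 0) {
    abort("delta_grid must be nonempty", class = "otcpanel_validation_error")
  }
  rows <- lapply(seq_along(delta_grid), function(i) {
    type_one_error(test = test, n_per_group = n_per_group, mu = mu,
                   sigma = sigma, delta = delta_grid[i], alpha = alpha,
                   replicates = replicates, B = B, tail = tail, ties = ties,
                   variance = variance,
                   seed = derive_seed(seed, "power", i))
  })
  dplyr::bind_rows(rows)
}
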