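# Synthetic cohort generator.  Emulates per-animal amino-acid
# concentrations as independent draws from per-cell distributions whose
# (mean, SD, N) come from the packaged baseline summary tables, with
# configurable 2x2 factorial effects (genotype main effect, treatment
# main effect, interaction added to the mutant-treated cell).

.DISTRIBUTIONS <- c("gaussian_clipped", "lognormal")

#' Build a generator specification from a summary table
#'
#' Copies each analyte's per-genotype (mean, SD, N) at baseline from a
#' `panel_summary` table and initialises the treated cells equal to
#' baseline (the factorial null) until effects are applied with
#' [apply_effects()].  Treated-group sizes default to 5 animals per
#' genotype, the design of the immune-challenge experiment.
#'
#' @param summary A `panel_summary` (see [panel_fixture()]).
#' @param n_baseline Optional named vector `c(WT = ..., SPFJ = ...)`
#'   overriding the table's baseline group sizes.
#' @param n_treated Treated-cell sizes, named as above (default 5 and 5).
#' @param distribution `"gaussian_clipped"` (Gaussian truncated at 0; a
#'   warning is emitted whenever clipping actually occurs) or
#'   `"lognormal"` (moment-matched, strictly positive).
#' @return A `generator_spec`: tibble of per-cell parameters (`tissue,
#'   analyte, genotype, treatment, mean, sd, n`) with a `distribution`
#'   attribute.
#' @export
#' @examples
#' spec <- generator_spec(panel_fixture("cerebrum"))
generator_spec <- function(summary, n_baseline = NULL,
                           n_treated = c(WT = 5, SPFJ = 5),
                           distribution = c("gaussian_clipped", "lognormal")) {
  distribution <- match.arg(distribution)
  if (!inherits(summary, "panel_summary")) {
    abort("summary must be a panel_summary table",
          class = "otcpanel_format_error")
  }
  tissue <- attr(summary, "tissue")
  nb <- c(WT = NA_real_, SPFJ = NA_real_)
  if (!is.null(n_baseline)) nb[names(n_baseline)] <- n_baseline
  nt <- c(WT = 5, SPFJ = 5)
  nt[names(n_treated)] <- n_treated
  cells <- expand.grid(genotype = GENOTYPES, treatment = TREATMENTS,
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(summary)), function(i) {
    r <- summary[i, ]
    mu <- c(WT = r$wt_mean, SPFJ = r$spfj_mean)
    sg <- c(WT = r$wt_sd, SPFJ = r$spfj_sd)
    nn <- c(WT = r$wt_n, SPFJ = r$spfj_n)
    tibble(tissue = tissue, analyte = r$analyte,
           genotype = cells$genotype, treatment = cells$treatment,
           mean = unname(mu[cells$genotype]),
           sd = unname(sg[cells$genotype]),
           n = unname(ifelse(cells$treatment == "BASELINE",
                             ifelse(is.na(nb[cells$genotype]),
                                    nn[cells$genotype],
                                    nb[cells$genotype]),
                             nt[cells$genotype])))
  })
  out <- dplyr::bind_rows(rows)
  if (any(out$n < 2)) {
    abort("all cell sizes must be >= 2", class = "otcpanel_validation_error")
  }
  if (any(out$mean <= 0)) {
    abort("all cell means must be positive",
          class = "otcpanel_validation_error")
  }
  structure(out, distribution = distribution, tissue = tissue,
            class = c("generator_spec", class(out)))
}

#' Apply 2x2 factorial effects to a generator specification
#'
#' Shifts cell means additively: `genotype_effect` is added to both mutant
#' cells, `treatment_effect` to both treated cells, and `interaction` to
#' the mutant-treated cell only (so `interaction` is exactly the expected
#' value of the difference-in-change statistic D).  An all-zero effect is
#' the identity.
#'
#' @param spec A `generator_spec`.
#' @param effects Data frame with column `analyte` and any of
#'   `genotype_effect`, `treatment_effect`, `interaction` (absent columns
#'   are taken as 0); one row per affected analyte.
#' @return The modified `generator_spec`.  A shifted cell mean that is not
#'   strictly positive is an error.
#' @export
apply_effects <- function(spec, effects) {
  if (!inherits(spec, "generator_spec")) {
    abort("spec must be a generator_spec", class = "otcpanel_format_error")
  }
  effects <- as_tibble(effects)
  if (!"analyte" %in% names(effects)) {
    abort("effects must have an 'analyte' column",
          class = "otcpanel_format_error")
  }
  for (col in c("genotype_effect", "treatment_effect", "interaction")) {
    if (!col %in% names(effects)) effects[[col]] <- 0
  }
  unknown <- setdiff(effects$analyte, unique(spec$analyte))
  if (length(unknown) > 0) {
    abort(sprintf("effects name analyte(s) absent from the spec: %s",
                  paste(unknown, collapse = ", ")),
          class = "otcpanel_validation_error")
  }
  m <- match(spec$analyte, effects$analyte)
  ge <- ifelse(is.na(m), 0, effects$genotype_effect[m])
  te <- ifelse(is.na(m), 0, effects$treatment_effect[m])
  ia <- ifelse(is.na(m), 0, effects$interaction[m])
  shift <- ge * (spec$genotype == "SPFJ") +
           te * (spec$treatment == "POLYIC") +
           ia * (spec$genotype == "SPFJ" & spec$treatment == "POLYIC")
  spec$mean <- spec$mean + shift
  if (any(spec$mean <= 0)) {
    bad <- unique(spec$analyte[spec$mean <= 0])
    abort(sprintf("effects drive cell mean(s) non-positive for: %s",
                  paste(bad, collapse = ", ")),
          class = "otcpanel_validation_error")
  }
  spec
}

# Draw n values from one cell's distribution.
draw_cell <- function(n, mu, sigma, distribution) {
  if (sigma == 0) return(rep(mu, n))
  if (distribution == "gaussian_clipped") {
    x <- rnorm(n, mu, sigma)
    clipped <- sum(x < 0)
    x[x < 0] <- 0
    attr(x, "clipped") <- clipped
    x
  } else {
    s2 <- log1p((sigma / mu)^2)
    rlnorm(n, meanlog = log(mu) - s2 / 2, sdlog = sqrt(s2))
  }
}

#' Generate a synthetic per-animal cohort
#'
#' Draws every animal's analyte values independently from its cell's
#' distribution.  Within a (genotype, treatment) cell the same synthetic
#' animals carry all analytes.  With the clipped-Gaussian distribution a
#' warning reports how many draws were truncated at 0 (this only matters
#' for analytes whose SD is comparable to their mean).  The same seed
#' always yields the identical table.
#'
#' @param spec A `generator_spec`, possibly after [apply_effects()].
#' @param seed Optional integer seed.
#' @return A validated cohort tibble.
#' @export
#' @examples
#' spec <- generator_spec(panel_fixture("cerebrum"))
#' cohort <- generate_cohort(spec, seed = 1)
generate_cohort <- function(spec, seed = NULL) {
  if (!inherits(spec, "generator_spec")) {
    abort("spec must be a generator_spec", class = "otcpanel_format_error")
  }
  distribution <- attr(spec, "distribution")
  tissue <- attr(spec, "tissue")
  panel <- panel_analytes(tissue)
  ord <- order(match(spec$genotype, GENOTYPES),
               match(spec$treatment, TREATMENTS),
               match(spec$analyte, panel))
  spec <- spec[ord, ]
  total_clipped <- 0L
  rows <- with_seed(seed, lapply(seq_len(nrow(spec)), function(i) {
    r <- spec[i, ]
    x <- draw_cell(r$n, r$mean, r$sd, distribution)
    total_clipped <<- total_clipped + (attr(x, "clipped") %||% 0L)
    tibble(animal_id = sprintf("%s_%s_%03d", tolower(r$genotype),
                               tolower(r$treatment), seq_len(r$n)),
           genotype = r$genotype, treatment = r$treatment,
           tissue = r$tissue, analyte = r$analyte,
           concentration = as.numeric(x))
  }))
  if (total_clipped > 0) {
    warn(sprintf("clipped %d negative Gaussian draw(s) at 0", total_clipped))
  }
  validate_cohort(dplyr::bind_rows(rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
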