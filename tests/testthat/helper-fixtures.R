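# Shared builders: small cohorts, hand-made summary tables, random DNA,
# and brute-force oracles kept deliberately independent of the package's
# own code paths.

# Long-format cohort from a named list of per-cell value vectors.
# cells = list(WT.BASELINE = c(...), WT.POLYIC = ..., SPFJ.BASELINE = ...,
#              SPFJ.POLYIC = ...)
cohort_from_cells <- function(cells, analyte = "Glutamine",
                              tissue = "PLASMA") {
  rows <- lapply(names(cells), function(key) {
    gt <- strsplit(key, ".", fixed = TRUE)[[1]]
    vals <- cells[[key]]
    tibble::tibble(
      animal_id = sprintf("%s_%s_%02d", tolower(gt[1]), tolower(gt[2]),
                          seq_along(vals)),
      genotype = gt[1], treatment = gt[2], tissue = tissue,
      analyte = analyte, concentration = vals)
  })
  dplyr::bind_rows(rows)
}

# Multi-analyte balanced cohort: independent N(mu, sd) everywhere (the
# factorial null), same synthetic animals across analytes.
null_cohort <- function(tissue = "CEREBRUM", n = 5, mu = 100, sd = 10,
                        analytes = panel_analytes(tissue)) {
  grid <- expand.grid(genotype = c("WT", "SPFJ"),
                      treatment = c("BASELINE", "POLYIC"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid$genotype[i]
    tr <- grid$treatment[i]
    dplyr::bind_rows(lapply(analytes, function(a) {
      tibble::tibble(
        animal_id = sprintf("%s_%s_%02d", tolower(g), tolower(tr),
                            seq_len(n)),
        genotype = g, treatment = tr, tissue = tissue, analyte = a,
        concentration = rnorm(n, mu, sd))
    }))
  })
  dplyr::bind_rows(rows)
}

# Hand-built panel_summary (bypasses CSV parsing on purpose).
make_summary <- function(analyte, wt_mean, wt_sd, wt_n, spfj_mean, spfj_sd,
                         spfj_n, tissue = "PLASMA", printed_p = "0.5") {
  out <- tibble::tibble(analyte = analyte, wt_mean = wt_mean, wt_sd = wt_sd,
                        wt_n = wt_n, spfj_mean = spfj_mean,
                        spfj_sd = spfj_sd, spfj_n = spfj_n,
                        printed_p = printed_p,
                        printed_p_value = suppressWarnings(as.numeric(printed_p)),
                        printed_p_bound = NA_real_)
  structure(out, tissue = tissue, class = c("panel_summary", class(out)))
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force motif scan (oracle for find_sites).
oracle_sites <- function(seq, recognition, cut_offset) {
  L <- nchar(seq)
  k <- nchar(recognition)
  if (L < k) return(integer(0))
  starts <- which(substring(seq, 1:(L - k + 1), k:L) == recognition)
  sort(starts - 1L + cut_offset)
}

# All permutations of a vector (oracle for the exact permutation null).
perms <- function(v) {
  if (length(v) <= 1) return(matrix(v, nrow = 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- perms(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# Oracle permutation p-value: enumerate every ordering of the pooled
# values, split into cells of the given sizes, and apply the tail rule.
oracle_perm_p <- function(vals, sizes, d_obs, tail = "two.sided",
                          inclusive = TRUE) {
  P <- perms(seq_along(vals))
  cs <- cumsum(sizes)
  d <- apply(P, 1, function(ix) {
    x <- vals[ix]
    (mean(x[(cs[3] + 1):cs[4]]) - mean(x[(cs[2] + 1):cs[3]])) -
      (mean(x[(cs[1] + 1):cs[2]]) - mean(x[seq_len(cs[1])]))
  })
  eps <- 1e-9 * (max(abs(vals)) + 1)
  switch(tail,
         lower = if (inclusive) mean(d <= d_obs + eps) else mean(d < d_obs - eps),
         upper = if (inclusive) mean(d >= d_obs - eps) else mean(d > d_obs + eps),
         two.sided = if (inclusive) mean(abs(d) >= abs(d_obs) - eps)
                     else mean(abs(d) > abs(d_obs) + eps))
}
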