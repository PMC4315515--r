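# Data model and I/O for per-animal cohort tables and published
# summary-statistic tables.
#
# Units: plasma concentrations are umol/L; liver and cerebrum are
# umol/100 g wet tissue.  Genotype, treatment and tissue are closed
# vocabularies; analyte names are canonicalised case-insensitively
# against the tissue's panel.

GENOTYPES  <- c("WT", "SPFJ")
TREATMENTS <- c("BASELINE", "POLYIC")
TISSUES    <- c("PLASMA", "LIVER", "CEREBRUM")

# Canonical panel, in published table row order.  The plasma panel carries
# three extra analytes (hydroxyproline, citrulline, homocystine) that the
# tissue panels do not report; citrulline in particular is excluded from
# tissue tables because of interference with its chromatographic detection
# in tissue extracts.
.PLASMA_PANEL <- c(
  "Taurine", "Aspartic Acid", "Hydroxyproline", "Threonine", "Serine",
  "Asparagine", "Glutamic Acid", "Glutamine", "Proline", "Glycine",
  "Alanine", "Citrulline", "Valine", "Methionine", "Isoleucine",
  "Leucine", "Tyrosine", "Phenylalanine", "Homocystine", "Ornithine",
  "Lysine", "Histidine", "Arginine")

.TISSUE_PANEL <- c(
  "Taurine", "Aspartic Acid", "Threonine", "Serine", "Asparagine",
  "Glutamic Acid", "Glutamine", "Proline", "Glycine", "Alanine",
  "Valine", "Methionine", "Isoleucine", "Leucine", "Tyrosine",
  "Phenylalanine", "Ornithine", "Lysine", "Histidine", "Arginine")

#' Canonical analyte panel for a tissue
#'
#' The measured amino-acid panel, in canonical (published table) row order.
#' Plasma reports 23 analytes; liver and cerebrum report 20 (hydroxyproline
#' and homocystine are not reported in tissue, and citrulline is excluded
#' from tissue panels due to detection interference).
#'
#' @param tissue One of `"PLASMA"`, `"LIVER"`, `"CEREBRUM"` (case-insensitive).
#' @return Character vector of canonical analyte names.
#' @export
#' @examples
#' panel_analytes("plasma")
panel_analytes <- function(tissue) {
  tissue <- canonical_token(tissue, TISSUES, "tissue")
  if (tissue == "PLASMA") .PLASMA_PANEL else .TISSUE_PANEL
}

# Map a user token onto a closed vocabulary (case/punctuation-insensitive).
canonical_token <- function(x, vocab, what) {
  squash <- function(s) gsub("[^A-Z0-9]", "", toupper(s))
  m <- match(squash(x), squash(vocab))
  if (anyNA(m)) {
    bad <- unique(x[is.na(m)])
    abort(sprintf("unknown %s token(s): %s (expected one of %s)", what,
                  paste(bad, collapse = ", "), paste(vocab, collapse = ", ")),
          class = "otcpanel_validation_error")
  }
  vocab[m]
}

# Canonicalise analyte names against the tissue panel; unknown names are
# errors, never warnings (silent typos would corrupt panel counts).
canonical_analyte <- function(x, tissue) {
  panel <- panel_analytes(tissue)
  squash <- function(s) gsub("[^A-Z]", "", toupper(s))
  m <- match(squash(x), squash(panel))
  if (anyNA(m)) {
    bad <- unique(x[is.na(m)])
    extra <- ""
    if (tissue != "PLASMA" && any(squash(bad) == "CITRULLINE")) {
      extra <- " (citrulline is representable in plasma only)"
    }
    abort(sprintf("analyte(s) not in the %s panel: %s%s", tolower(tissue),
                  paste(bad, collapse = ", "), extra),
          class = "otcpanel_validation_error")
  }
  panel[m]
}

.COHORT_COLS <- c("animal_id", "genotype", "treatment", "tissue",
                  "analyte", "concentration")

#' Validate a cohort table
#'
#' Checks the long-format per-animal measurement table: required columns,
#' closed vocabularies, canonical analyte names per tissue, non-negative
#' finite concentrations, no duplicate (animal, tissue, analyte) records,
#' and a single (genotype, treatment) cell per animal and tissue.
#'
#' @param cohort A data frame with columns `animal_id`, `genotype`,
#'   `treatment`, `tissue`, `analyte`, `concentration`.
#' @return The validated cohort as a tibble with canonicalised tokens,
#'   invisibly usable anywhere a cohort is expected.
#' @export
validate_cohort <- function(cohort) {
  missing <- setdiff(.COHORT_COLS, names(cohort))
  if (length(missing) > 0) {
    abort(sprintf("cohort table is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "otcpanel_format_error")
  }
  out <- as_tibble(cohort)[, .COHORT_COLS]
  out$animal_id <- as.character(out$animal_id)
  out$genotype  <- canonical_token(out$genotype, GENOTYPES, "genotype")
  out$treatment <- canonical_token(out$treatment, TREATMENTS, "treatment")
  out$tissue    <- canonical_token(out$tissue, TISSUES, "tissue")
  for (ti in unique(out$tissue)) {
    i <- out$tissue == ti
    out$analyte[i] <- canonical_analyte(out$analyte[i], ti)
  }
  conc <- out$concentration
  if (!is.numeric(conc)) {
    abort("column 'concentration' must be numeric",
          class = "otcpanel_format_error")
  }
  bad <- which(!is.finite(conc) | conc < 0)
  if (length(bad) > 0) {
    abort(sprintf("negative or non-finite concentration in row(s): %s",
                  paste(bad, collapse = ", ")),
          class = "otcpanel_validation_error")
  }
  key <- paste(out$animal_id, out$tissue, out$analyte, sep = "\r")
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate (animal_id, tissue, analyte) record(s) in row(s): %s",
                  paste(which(duplicated(key)), collapse = ", ")),
          class = "otcpanel_validation_error")
  }
  grp <- unique(out[, c("animal_id", "tissue", "genotype", "treatment")])
  ak  <- paste(grp$animal_id, grp$tissue, sep = "\r")
  if (anyDuplicated(ak)) {
    dup <- grp$animal_id[duplicated(ak)]
    abort(sprintf("animal(s) mapped to more than one (genotype, treatment) cell within a tissue: %s",
                  paste(unique(dup), collapse = ", ")),
          class = "otcpanel_validation_error")
  }
  out
}

#' Read a per-animal cohort CSV
#'
#' Long (tidy) format, one row per (animal, tissue, analyte) measurement,
#' columns `animal_id, genotype, treatment, tissue, analyte, concentration`.
#' Row order is preserved; tokens and analyte names are canonicalised.
#'
#' @param path Path to a CSV file.
#' @return A validated cohort tibble.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "otcpanel_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(.COHORT_COLS, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("cohort CSV %s is missing column(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "otcpanel_format_error")
  }
  raw$concentration <- as.numeric(raw$concentration)
  validate_cohort(raw)
}

#' Write a cohort table to CSV
#'
#' Deterministic column order (`animal_id, genotype, treatment, tissue,
#' analyte, concentration`), input row order, "." decimal separator, UTF-8.
#' `write_cohort(read_cohort(x))` is byte-identical for canonicalised files.
#'
#' @param cohort A cohort table (validated on the way out).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- validate_cohort(cohort)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

.SUMMARY_COLS <- c("analyte", "wt_mean", "wt_sd", "wt_n",
                   "spfj_mean", "spfj_sd", "spfj_n", "printed_p")

# Parse printed P-value tokens: numeric strings, or the bound form "<0.01".
# Bounds are kept as explicit (threshold) objects, never coerced to a number.
parse_printed_p <- function(x) {
  x <- trimws(as.character(x))
  value <- rep(NA_real_, length(x))
  bound <- rep(NA_real_, length(x))
  is_bound <- grepl("^<", x)
  bound[is_bound] <- suppressWarnings(as.numeric(sub("^<\\s*", "", x[is_bound])))
  value[!is_bound] <- suppressWarnings(as.numeric(x[!is_bound]))
  bad <- (!is_bound & (is.na(value) | value < 0 | value > 1)) |
         (is_bound & (is.na(bound) | bound <= 0 | bound > 1))
  if (any(bad)) {
    abort(sprintf("malformed printed_p token(s): %s",
                  paste(unique(x[bad]), collapse = ", ")),
          class = "otcpanel_format_error")
  }
  list(value = value, bound = bound)
}

#' Read a published summary-statistic table
#'
#' Reads a per-analyte baseline summary table (one row per analyte, the two
#' genotype groups side by side) with columns `analyte, wt_mean, wt_sd, wt_n,
#' spfj_mean, spfj_sd, spfj_n, printed_p`.  Printed P-values of the literal
#' form `"<0.01"` are parsed into an explicit bound column
#' (`printed_p_bound`), numeric strings into `printed_p_value`.
#'
#' @param path Path to the CSV file.
#' @param tissue Tissue of the table (`"PLASMA"`, `"LIVER"` or `"CEREBRUM"`).
#' @return A `panel_summary` tibble with a `tissue` attribute.
#' @seealso [panel_fixture()] for the packaged baseline tables.
#' @export
read_summary_table <- function(path, tissue) {
  tissue <- canonical_token(tissue, TISSUES, "tissue")
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "otcpanel_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(.SUMMARY_COLS, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("summary CSV %s is missing column(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "otcpanel_format_error")
  }
  out <- as_tibble(raw)[, .SUMMARY_COLS]
  out$analyte <- canonical_analyte(out$analyte, tissue)
  if (anyDuplicated(out$analyte)) {
    abort("duplicate analyte rows in summary table",
          class = "otcpanel_validation_error")
  }
  for (col in c("wt_mean", "wt_sd", "wt_n", "spfj_mean", "spfj_sd", "spfj_n")) {
    out[[col]] <- as.numeric(out[[col]])
  }
  if (any(out$wt_n < 2) || any(out$spfj_n < 2)) {
    abort("group sizes must be >= 2 (a variance must be estimable)",
          class = "otcpanel_validation_error")
  }
  if (any(out$wt_sd < 0) || any(out$spfj_sd < 0)) {
    abort("standard deviations must be non-negative",
          class = "otcpanel_validation_error")
  }
  pp <- parse_printed_p(out$printed_p)
  out$printed_p_value <- pp$value
  out$printed_p_bound <- pp$bound
  structure(out, tissue = tissue, class = c("panel_summary", class(out)))
}

#' Packaged baseline summary tables
#'
#' The three baseline amino-acid summary tables shipped with the package
#' (transcribed printed mean/SD/N/P cells): plasma (23 analytes, umol/L),
#' liver and cerebrum (20 analytes each, umol/100 g).
#'
#' @param tissue `"PLASMA"`, `"LIVER"` or `"CEREBRUM"` (case-insensitive).
#' @return A `panel_summary` tibble (see [read_summary_table()]).
#' @export
#' @examples
#' panel_fixture("cerebrum")
panel_fixture <- function(tissue) {
  tissue <- canonical_token(tissue, TISSUES, "tissue")
  file <- switch(tissue,
                 PLASMA   = "table1_plasma.csv",
                 LIVER    = "table2_liver.csv",
                 CEREBRUM = "table3_cerebrum.csv")
  path <- system.file("extdata", file, package = "otcpanel", mustWork = TRUE)
  read_summary_table(path, tissue)
}

#' Per-cell summary statistics of a cohort
#'
#' Collapses a per-animal cohort to one (mean, SD, n) row per occupied
#' (genotype, treatment, tissue, analyte) cell.  The SD uses the n - 1
#' (sample) denominator; every cell must contain at least two animals.
#'
#' @param cohort A cohort table.
#' @return Tibble with columns `genotype, treatment, tissue, analyte, mean,
#'   sd, n`.
#' @export
summarize_cohort <- function(cohort) {
  cohort <- validate_cohort(cohort)
  out <- dplyr::summarise(
    dplyr::group_by(cohort, .data$genotype, .data$treatment, .data$tissue,
                    .data$analyte),
    mean = mean(.data$concentration),
    sd = sd(.data$concentration),
    n = dplyr::n(),
    .groups = "drop")
  small <- out$n < 2
  if (any(small)) {
    cells <- paste(out$genotype[small], out$treatment[small], out$tissue[small],
                   out$analyte[small], sep = "/")
    abort(sprintf("cell(s) with fewer than 2 animals: %s",
                  paste(cells, collapse = "; ")),
          class = "otcpanel_validation_error")
  }
  out
}
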