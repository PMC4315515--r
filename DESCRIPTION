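Package: otcpanel
Title: Amino Acid Panel Statistics and In Silico Genotyping for a Mouse
    Model of Mild Ornithine Transcarbamylase Deficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical toolkit for targeted amino-acid panels from a
    two-factor (genotype x treatment) mouse cohort modelling mild
    ornithine transcarbamylase (OTC) deficiency.  Provides pooled and
    Welch two-sample t-tests computed either from raw per-animal values
    or from published summary statistics (mean, SD, N), panel-level
    comparison tables, change-from-baseline t-statistic heat maps, and a
    permutation test of the difference-in-change interaction statistic
    D = (mean mutant treated - mean mutant baseline) - (mean wild-type
    treated - mean wild-type baseline), with exact enumeration on small
    designs and seeded Monte-Carlo sampling otherwise.  A synthetic
    cohort generator parameterised by the packaged baseline summary
    tables, and a simulation harness for type-I error and power, allow
    the procedures to be certified when raw data are unpublished.  Also
    includes in silico PCR-RFLP genotyping (restriction digests and
    fragment-pattern genotype calls) and codon-level annotation of
    single-base coding substitutions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
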