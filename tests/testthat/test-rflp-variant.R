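test_that("find_sites reports EcoRI cut coordinates", {
  expect_equal(find_sites("AAAGAATTCCC"), 4L)
  expect_equal(find_sites("ACGTACGT"), integer(0))
  # overlapping recognition occurrences are all reported
  expect_equal(find_sites("AAAA", recognition = "AA", cut_offset = 1),
               c(1L, 2L, 3L))
  expect_error(find_sites("ACGN"), class = "otcpanel_validation_error")
  expect_error(find_sites("ACGT", cut_offset = 9),
               class = "otcpanel_validation_error")
})

test_that("find_sites agrees with a naive all-substrings scan", {
  set.seed(303)
  for (i in 1:1000) {
    s <- rand_dna(500)
    expect_identical(find_sites(s), oracle_sites(s, "GAATTC", 1L))
  }
})

test_that("digests split at interior cuts and conserve length", {
  d <- digest_sequence("AAAGAATTCCC")
  expect_equal(d$cut_positions, 4L)
  expect_equal(d$fragments, c(4L, 7L))
  expect_equal(digest_sequence("ACGTACGTAC")$fragments, 10L)
  # a cut on the boundary creates no empty fragment
  d0 <- digest_sequence("GAATTCAAA", recognition = "GAATTC", cut_offset = 0)
  expect_equal(d0$fragments, 9L)
  set.seed(71)
  for (i in 1:300) {
    s <- rand_dna(sample(50:400, 1))
    d <- digest_sequence(s)
    expect_equal(sum(d$fragments), nchar(s))
    expect_equal(length(d$fragments), length(d$cut_positions) + 1L)
    expect_true(all(d$fragments >= 1))
  }
})

test_that("fragment patterns classify into the published genotype calls", {
  expect_equal(classify_genotype(c(207, 128, 79))$call, "HETEROZYGOTE")
  expect_equal(classify_genotype(c(128, 79))$call, "HEMIZYGOTE_MUTANT")
  expect_equal(classify_genotype(207)$call, "WT")
  # both printed dialects of the WT pattern give the same call
  expect_equal(classify_genotype(c(207, 79))$call, "WT")
  expect_equal(classify_genotype(c(79, 50))$call, "UNINTERPRETABLE")
  # order-free, tolerant to gel smear within +/- 3 bp, strict at 0
  expect_equal(classify_genotype(c(79, 130, 205))$call, "HETEROZYGOTE")
  expect_equal(classify_genotype(c(79, 130, 205), tolerance = 0)$call,
               "UNINTERPRETABLE")
  expect_equal(classify_genotype(c(128, 79, 300, 12))$call,
               "HEMIZYGOTE_MUTANT")
  expect_error(classify_genotype(numeric(0)),
               class = "otcpanel_validation_error")
})

test_that("the packaged synthetic amplicons genotype correctly end to end", {
  fa <- read_fasta_seq(system.file("extdata", "synthetic_exon3_amplicons.fa",
                                   package = "otcpanel"))
  wt <- fa[[grep("wt", names(fa))]]
  mut <- fa[[grep("mutant", names(fa))]]
  expect_equal(digest_sequence(wt)$fragments, c(207L, 79L))
  expect_equal(digest_sequence(mut)$fragments, c(128L, 79L, 79L))
  expect_equal(genotype_amplicon(wt)$call, "WT")
  expect_equal(genotype_amplicon(mut)$call, "HEMIZYGOTE_MUTANT")
  expect_equal(genotype_amplicon(c(wt, mut))$call, "HETEROZYGOTE")
  # the two alleles differ by the single A>T that creates the EcoRI site
  diffs <- which(strsplit(wt, "")[[1]] != strsplit(mut, "")[[1]])
  expect_equal(length(diffs), 1L)
  expect_equal(substr(wt, diffs, diffs), "A")
  expect_equal(substr(mut, diffs, diffs), "T")
})

test_that("the hallmark K80N substitution annotates as missense", {
  cds <- paste(rep("GCT", 100), collapse = "")  # poly-Ala backbone
  substr(cds, 238, 240) <- "AAA"                # lysine codon at residue 80
  eff <- variant_effect(cds, 240, "T")
  expect_equal(eff$codon_index, 80L)
  expect_equal(eff$ref_codon, "AAA")
  expect_equal(eff$alt_codon, "AAT")
  expect_equal(eff$ref_residue, "K")
  expect_equal(eff$alt_residue, "N")
  expect_equal(eff$consequence, "MISSENSE")
  expect_equal(eff$label, "K80N")
})

test_that("synonymous and nonsense substitutions classify correctly", {
  cds <- "AAATACGGG"
  syn <- variant_effect(cds, 3, "G")  # AAA -> AAG, K -> K
  expect_equal(syn$consequence, "SYNONYMOUS")
  non <- variant_effect(cds, 6, "A")  # TAC -> TAA, Y -> stop
  expect_equal(non$consequence, "NONSENSE")
  expect_equal(non$alt_residue, "*")
})

test_that("variant annotation rejects invalid substitutions", {
  cds <- "AAATACGGG"
  expect_error(variant_effect(cds, 1, "A"), "alt equals",
               class = "otcpanel_validation_error")
  expect_error(variant_effect(cds, 10, "A"),
               class = "otcpanel_validation_error")
  expect_error(variant_effect(cds, 0, "A"),
               class = "otcpanel_validation_error")
  expect_error(variant_effect("AAAT", 1, "C"),
               class = "otcpanel_validation_error")
  expect_error(variant_effect("AANTAC", 1, "C"),
               class = "otcpanel_validation_error")
})

test_that("every single-base substitution of a toy CDS matches a translation oracle", {
  set.seed(12)
  # stop-free 30-nt toy CDS
  repeat {
    cds <- rand_dna(30)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                             no.init.codon = TRUE))
    if (!grepl("\\*", aa)) break
  }
  for (pos in 1:30) {
    ref <- substr(cds, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      eff <- variant_effect(cds, pos, alt)
      mutated <- cds
      substr(mutated, pos, pos) <- alt
      aa_mut <- as.character(Biostrings::translate(
        Biostrings::DNAString(mutated), no.init.codon = TRUE))
      ci <- ceiling(pos / 3)
      expect_equal(eff$codon_index, ci)
      expect_equal(eff$ref_residue, substr(aa, ci, ci))
      expect_equal(eff$alt_residue, substr(aa_mut, ci, ci))
      expected <- if (eff$alt_residue == eff$ref_residue) "SYNONYMOUS"
                  else if (eff$alt_residue == "*") "NONSENSE"
                  else "MISSENSE"
      expect_equal(eff$consequence, expected)
      # the inverse substitution restores the reference residue
      back <- variant_effect(mutated, pos, ref)
      expect_equal(back$alt_residue, eff$ref_residue)
      expect_equal(back$alt_codon, eff$ref_codon)
    }
  }
})
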