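# In silico PCR-RFLP genotyping and codon-level annotation of coding
# substitutions.
#
# The mutant allele of the Otc exon-3 amplicon carries an allele-specific
# EcoRI site (G^AATTC), so a digest yields diagnostic fragments: an
# uncut 207 bp product marks the wild-type allele and a 128 bp fragment
# marks the mutant allele (a constitutive 79 bp band, when present, is
# uninformative).  The classifier keys only on the two allele-diagnostic
# lengths, so both a one-site and a no-site wild-type amplicon classify
# identically.

#' EcoRI recognition sequence and cut offset
#'
#' EcoRI recognises GAATTC and cuts the top strand after the first base
#' (G^AATTC), i.e. at offset 1 from the match start.
#' @format `ECORI` is a list with elements `recognition` ("GAATTC") and
#'   `cut_offset` (1).
#' @export
ECORI <- list(recognition = "GAATTC", cut_offset = 1L)

check_dna <- function(seq, what = "sequence") {
  seq <- toupper(as.character(seq)[1])
  if (nchar(seq) == 0 || grepl("[^ACGT]", seq)) {
    abort(sprintf("%s must be a nonempty string over A, C, G, T (ambiguity codes are out of scope)",
                  what),
          class = "otcpanel_validation_error")
  }
  seq
}

#' Find restriction cut positions on a sequence
#'
#' Scans the given strand for every (possibly overlapping) occurrence of
#' the recognition sequence and returns the 0-based cut coordinates,
#' `match start + cut_offset`, in ascending order.  For a palindromic
#' recognition sequence such as EcoRI's GAATTC this forward scan already
#' yields the complete set of double-strand breaks.
#'
#' @param seq Nucleotide string over A/C/G/T.
#' @param recognition Recognition sequence (default EcoRI's GAATTC).
#' @param cut_offset Cut offset within the recognition site, between 0 and
#'   `nchar(recognition)` (default 1, EcoRI's G^AATTC).
#' @return Integer vector of 0-based cut coordinates (possibly empty).
#' @export
#' @examples
#' find_sites("AAAGAATTCCC")  # cut at position 4
find_sites <- function(seq, recognition = ECORI$recognition,
                       cut_offset = ECORI$cut_offset) {
  seq <- check_dna(seq)
  recognition <- check_dna(recognition, "recognition sequence")
  if (!(cut_offset >= 0 && cut_offset <= nchar(recognition))) {
    abort("cut_offset must lie between 0 and nchar(recognition)",
          class = "otcpanel_validation_error")
  }
  m <- Biostrings::matchPattern(recognition, Biostrings::DNAString(seq))
  sort(as.integer(Biostrings::start(m)) - 1L + as.integer(cut_offset))
}

#' Digest a sequence in silico
#'
#' Fragments are the maximal runs between consecutive interior cuts; their
#' lengths always sum to the input length, and every fragment has length
#' at least 1 (a cut falling on the sequence boundary creates no empty
#' fragment).
#'
#' @inheritParams find_sites
#' @return A `digest_result` list: `input_length`, `cut_positions`
#'   (0-based, interior, ascending) and `fragments` (ordered bp lengths).
#' @export
#' @examples
#' digest_sequence("AAAGAATTCCC")$fragments  # 4 and 7
digest_sequence <- function(seq, recognition = ECORI$recognition,
                            cut_offset = ECORI$cut_offset) {
  seq <- check_dna(seq)
  len <- nchar(seq)
  cuts <- find_sites(seq, recognition, cut_offset)
  cuts <- unique(cuts[cuts > 0 & cuts < len])
  structure(list(input_length = len, cut_positions = cuts,
                 fragments = as.integer(diff(c(0L, cuts, len)))),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("In-silico digest: %d bp, %d cut(s) -> fragments: %s bp\n",
              x$input_length, length(x$cut_positions),
              paste(x$fragments, collapse = ", ")))
  invisible(x)
}

#' Classify a genotype from digest fragment lengths
#'
#' Calls the genotype from the allele-diagnostic fragment lengths of the
#' exon-3 amplicon digest: a fragment within `tolerance` of 207 bp marks
#' the wild-type allele (uncut product) and one within `tolerance` of
#' 128 bp marks the mutant allele.  Both present: heterozygote (carrier
#' female); mutant only: hemizygote (affected male); wild type only: WT;
#' neither: uninterpretable.  Extra fragments (such as the constitutive
#' 79 bp band) never change a call, and fragment order is irrelevant.
#'
#' @param fragments Integer vector of observed fragment lengths (bp).
#' @param tolerance Band-matching tolerance in bp (default 3, reflecting
#'   agarose gel resolution; use 0 for exact matching).
#' @param wt_band,mutant_band Diagnostic lengths (defaults 207 and 128).
#' @return A `genotype_call` list: `call` (one of `"WT"`,
#'   `"HETEROZYGOTE"`, `"HEMIZYGOTE_MUTANT"`, `"UNINTERPRETABLE"`),
#'   `wt_band`, `mutant_band` (logical evidence), `fragments`,
#'   `tolerance`.
#' @export
#' @examples
#' classify_genotype(c(207, 128, 79))$call  # heterozygote
classify_genotype <- function(fragments, tolerance = 3,
                              wt_band = 207, mutant_band = 128) {
  fragments <- as.numeric(fragments)
  if (length(fragments) == 0 || any(!is.finite(fragments) | fragments < 1)) {
    abort("fragments must be a nonempty vector of positive lengths",
          class = "otcpanel_validation_error")
  }
  has_wt <- any(abs(fragments - wt_band) <= tolerance)
  has_mut <- any(abs(fragments - mutant_band) <= tolerance)
  call <- if (has_wt && has_mut) "HETEROZYGOTE"
          else if (has_wt) "WT"
          else if (has_mut) "HEMIZYGOTE_MUTANT"
          else "UNINTERPRETABLE"
  structure(list(call = call, wt_band = has_wt, mutant_band = has_mut,
                 fragments = fragments, tolerance = tolerance),
            class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("Genotype call: %s (207 bp band: %s; 128 bp band: %s; fragments: %s)\n",
              x$call, x$wt_band, x$mutant_band,
              paste(x$fragments, collapse = ", ")))
  invisible(x)
}

#' Annotate a single-base coding substitution
#'
#' Computes the codon-level consequence of substituting `alt` at 1-based
#' CDS `position` under the standard genetic code: the affected codon
#' (`ceiling(position / 3)`), reference and alternate codons and residues,
#' and the consequence class (`"SYNONYMOUS"`, `"MISSENSE"` or
#' `"NONSENSE"` when the alternate codon is a stop).
#'
#' The hallmark mutation of this model is the A-to-T transversion at CDS
#' position 240, turning the lysine codon AAA spanning positions 238-240
#' into AAT (asparagine): missense K80N.
#'
#' @param cds Coding sequence over A/C/G/T, length divisible by 3.
#' @param position 1-based position of the substituted base.
#' @param alt Alternate base (must differ from the reference base).
#' @return One-row tibble: `cds_position, ref, alt, codon_index,
#'   ref_codon, alt_codon, ref_residue, alt_residue, consequence, label`
#'   (`label` is the protein-level shorthand, e.g. `"K80N"`).
#' @export
variant_effect <- function(cds, position, alt) {
  cds <- check_dna(cds, "CDS")
  if (nchar(cds) %% 3 != 0) {
    abort("CDS length must be divisible by 3",
          class = "otcpanel_validation_error")
  }
  if (!(is.numeric(position) && length(position) == 1 &&
        position == as.integer(position) && position >= 1 &&
        position <= nchar(cds))) {
    abort(sprintf("position must be an integer in [1, %d]", nchar(cds)),
          class = "otcpanel_validation_error")
  }
  alt <- check_dna(alt, "alt base")
  if (nchar(alt) != 1) {
    abort("alt must be a single base", class = "otcpanel_validation_error")
  }
  ref <- substr(cds, position, position)
  if (alt == ref) {
    abort(sprintf("alt equals the reference base (%s) at position %d",
                  ref, position),
          class = "otcpanel_validation_error")
  }
  codon_index <- ceiling(position / 3)
  codon_start <- (codon_index - 1L) * 3L + 1L
  ref_codon <- substr(cds, codon_start, codon_start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, position - codon_start + 1L,
         position - codon_start + 1L) <- alt
  code <- Biostrings::GENETIC_CODE
  ref_residue <- unname(code[ref_codon])
  alt_residue <- unname(code[alt_codon])
  consequence <- if (alt_residue == ref_residue) "SYNONYMOUS"
                 else if (alt_residue == "*") "NONSENSE"
                 else "MISSENSE"
  tibble(cds_position = as.integer(position), ref = ref, alt = alt,
         codon_index = as.integer(codon_index), ref_codon = ref_codon,
         alt_codon = alt_codon, ref_residue = ref_residue,
         alt_residue = alt_residue, consequence = consequence,
         label = sprintf("%s%d%s", ref_residue, codon_index, alt_residue))
}

#' Read sequences from a FASTA file
#'
#' Thin convenience wrapper returning a named character vector of
#' uppercase sequences, suitable for [digest_sequence()] and
#' [variant_effect()].
#'
#' @param path Path to a FASTA file.
#' @return Named character vector.
#' @export
read_fasta_seq <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "otcpanel_io_error")
  }
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Genotype a digested amplicon
#'
#' Runs [digest_sequence()] on an amplicon and classifies the resulting
#' fragment pattern with [classify_genotype()].  For a female carrying
#' two different alleles, pass both allele amplicons; the observed band
#' pattern is the union of the two digests (as on a gel).
#'
#' @param amplicons Character vector of one (hemizygous male, or
#'   homozygous) or two (heterozygous female) allele amplicon sequences.
#' @inheritParams find_sites
#' @inheritParams classify_genotype
#' @return A `genotype_call`, with the per-allele `digest_result`s
#'   attached as attribute `digests`.
#' @export
genotype_amplicon <- function(amplicons, recognition = ECORI$recognition,
                              cut_offset = ECORI$cut_offset, tolerance = 3) {
  digests <- lapply(amplicons, digest_sequence, recognition = recognition,
                    cut_offset = cut_offset)
  bands <- unique(unlist(lapply(digests, `[[`, "fragments")))
  out <- classify_genotype(bands, tolerance = tolerance)
  attr(out, "digests") <- digests
  out
}
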