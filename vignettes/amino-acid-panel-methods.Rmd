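---
title: "Methods: amino-acid panel statistics, the difference-in-change permutation test, and in-silico genotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amino-acid panel statistics and the difference-in-change permutation test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otcpanel)
```

## The experimental design this package models

A hypomorphic mouse model of ornithine transcarbamylase (OTC) deficiency
(*spf-J*, carrying a missense K80N allele) is compared with wild-type
littermates in a 2×2 factorial design: genotype (WT vs mutant) crossed
with treatment (baseline vs a poly I:C immune challenge, a double-stranded
RNA viral mimic). The measured outcome is a targeted amino-acid panel in
three tissues — plasma (µmol/L), liver and cerebrum (µmol/100 g). Plasma
reports 23 analytes; the tissue panels report 20 (citrulline is excluded
from tissue tables because tissue extracts interfere with its detection,
and hydroxyproline/homocystine are plasma-only). The package treats these
vocabularies as closed: analyte names are canonicalised
case-insensitively, and unknown names are errors rather than warnings,
because a silently dropped or misspelt analyte would corrupt panel counts.

Two data representations are supported, with long (tidy) CSV as the
canonical raw format: per-animal measurements
(`animal_id, genotype, treatment, tissue, analyte, concentration`) and
per-analyte summary statistics (mean, SD, N per genotype), the form in
which baseline results are published. The three packaged baseline tables
(`panel_fixture()`) are verbatim transcriptions of the published cells,
including the `"<0.01"` P-value entries, which are stored as explicit
bound objects — never as 0.01 or any other number — because comparisons
against a bound need their own semantics.

## Baseline group comparisons

Each analyte is compared between genotypes with a two-sided two-sample
*t*-test. Because published tables print only (mean, SD, N), the test is
implemented from sufficient statistics; `t_from_raw()` reduces to the
same algebra, so the two routes agree to machine precision (this identity
is exercised against `stats::t.test` as an independent oracle in the test
suite).

**Pooled variance is the default.** The original analysis states only
that a two-sided Student *t*-test was used. Recomputing the printed
P-values from the printed summaries discriminates between the two
variance models: the pooled model reproduces the printed values (plasma
leucine 0.02 pooled vs 0.03 Welch; cerebral glutamine 0.04 pooled vs 0.07
Welch), so `variance = "pooled"` is the default and Welch is an option.
This is an inference from the numbers, not a documented fact about the
original software settings.

**No multiple-testing adjustment is applied by default**, mirroring the
original per-analyte reporting; `adjust_panel()` offers Benjamini–
Hochberg as an explicit post-processing step that never alters the
reproduction-mode `significant` column.

**Tolerance when matching printed values.** Printed means and SDs are
rounded to one decimal, which propagates into the recomputed P-value; a
±0.02 absolute tolerance absorbs this for analytes whose values are large
relative to the rounding unit. For low-abundance analytes whose printed
mean or SD is of the same magnitude as the rounding step (plasma
homocystine at 0.1 ± 0.3, liver arginine at 0.6 ± 0.3) the propagated
uncertainty exceeds any fixed small tolerance, and for cerebral taurine
no input values consistent with the printed rounding reproduce the
printed P at all; the acceptance checks report these cells as the
irreducible mismatches they are rather than widening the tolerance to
hide them.

## The difference-in-change statistic D and its permutation test

For one analyte, let the four cell means be indexed by genotype and
treatment. The per-genotype change is `d_spfj = mean(mutant treated) −
mean(mutant baseline)` and `d_wt` likewise; the statistic is their
difference,

\[ D = d_{spfj} - d_{wt}, \]

the classical interaction contrast of a 2×2 design: D is zero in
expectation under additive genotype and treatment effects, negative when
the mutant's response falls short of the wild type's (the depletion
pattern of interest in cerebrum), and equals the injected interaction
effect in expectation under the generator below. D is invariant under
adding a constant to all observations and antisymmetric under swapping
the genotype labels.

**Permutation scheme.** The null distribution is generated by pooling all
observations of the analyte and reassigning them uniformly at random to
the four cells, preserving the observed cell sizes, without replacement.
No blocking structure is imposed: animals are independent, and baseline
and treated groups are treated as independent samples (the design does
not pair them). The default budget is B = 100,000 random reassignments.
When the number of distinct assignments
(multinomial coefficient) is at most `exact_threshold` (default 200,000)
the full null is enumerated instead; the enumeration includes the
identity assignment, so exact p-values are strictly positive by
construction. Monte-Carlo draws are made on a canonical sorted-within-
group pooling of the data, so results depend only on the observed value
multisets, never on input row order.

**Tail convention.** A lower-tail rule (`p = #{D_perm ≤ D_obs}/B`)
expresses "most negative D is most extreme", the natural rule when the
hypothesis is mutant depletion. In practice effects in both directions
are of interest (plasma glutamine rises more in WT, glutamic acid more in
the mutant), so the package defaults to the two-sided rule
`p = #{|D_perm| ≥ |D_obs|}/B`, with `"lower"` and `"upper"` available.

**Ties.** Ties are counted in the p-value (`≤` / `≥`), the conservative
convention: under the strict-inequality reading the degenerate case where
all observations are equal would return p = 0 — a certain rejection from
data containing no information — whereas the tie-inclusive rule returns
p = 1. A `ties = "strict"` mode preserves the literal strict rule for
comparison. Comparisons use an absolute guard of
`1e-9 × (max |value| + 1)` so that floating-point round-off in regrouped
means cannot flip a genuine tie.

**Seeding.** Panel-wide runs derive one RNG stream per analyte by hashing
(master seed, tissue, analyte) with a base-31 polynomial hash modulo
2³¹ − 1, making results reproducible and independent of analyte
processing order.

## The synthetic cohort generator

`generator_spec()` copies per-cell (mean, SD, N) from a baseline summary
table and initialises treated cells at their baseline parameters (the
factorial null); `apply_effects()` shifts cell means additively by a
genotype main effect, a treatment main effect, and an interaction added
to the mutant-treated cell only — so the interaction parameter is exactly
the expected value of D. Group sizes default to the published design:
baseline Ns as printed (9/10 in plasma, 5/5 in tissues) and 5 animals per
genotype for the challenge arm.

Two cell distributions are offered. `"gaussian_clipped"` draws Gaussian
values truncated at zero, warning whenever clipping occurs — clipping is
negligible when the mean is several SDs above zero, which holds for every
analyte except the low-abundance plasma analytes (homocystine 0.1 ± 0.3
being the extreme case), where truncation biases the cell mean upward by
a predictable amount. `"lognormal"` is moment-matched (its mean and SD
equal the cell parameters exactly) and strictly positive; it is the
appropriate choice when sample-mean calibration against the input
parameters is itself the quantity under test, and it is what the
generator-calibration check uses, at 10⁵ draws per baseline cell and a 1%
tolerance.

Analytes are generated independently: the published tables carry no
correlation information, so none is emulated. Real panels are correlated
(amino acids share transporters and precursors), real measurement error
is not purely Gaussian, and real challenge responses need not be additive
on the concentration scale — passing simulations therefore certify the
statistical procedures under the stated model, not the biology of any
particular cohort.

## Certification by simulation

The per-animal challenge data behind the published change heat maps are
not available, so those p-values are validated by operating
characteristics rather than by value. The harness mirrors the smallest
published geometry — 5 animals per cell — so the certification speaks to
the procedure's actual operating regime:

* **Size.** Under the Gaussian factorial null, the two-sided
  tie-inclusive permutation test rejects at a rate statistically
  indistinguishable from α = 0.05 (2,000 replicates, exact binomial
  envelope). Inside the harness B is reduced to 2,000: the outer × inner
  Monte-Carlo budget is the binding constraint, and p-value granularity
  1/B = 0.0005 is far below the α being certified.
* **Exactness.** On designs small enough to enumerate, Monte-Carlo
  p-values agree with exact enumeration within three Monte-Carlo standard
  errors (and within 0.01 at B = 100,000).
* **Power.** Rejection rates are nondecreasing in the injected
  interaction up to Monte-Carlo noise, and an interaction of ten pooled
  SDs is detected essentially always at n = 5 per cell.

Test-suite problem sizes (replicate counts, B values, random-sequence
counts) are chosen to estimate each property to the precision its
assertion needs — e.g. 2,000 replicates bound the size estimate's
standard error at ~0.005 — while keeping the default suite comfortably
interactive.

## In-silico PCR-RFLP genotyping

The mutant allele creates an EcoRI site (G^AATTC, cut offset 1) in the
exon-3 amplicon. `find_sites()` scans the given strand for every —
possibly overlapping — occurrence of the recognition sequence and returns
0-based cut coordinates (match start + offset); for a palindromic
recognition sequence the forward scan already yields the complete set of
double-strand breaks, which is why no reverse-complement pass is made
(mapping the bottom-strand nick of a sticky-end cutter back to top-strand
coordinates would double-count the single break). `digest_sequence()`
splits at interior cuts only, so fragment lengths are always ≥ 1 and sum
to the input length.

`classify_genotype()` keys **only** on the two allele-diagnostic lengths:
207 bp (uncut wild-type product) and 128 bp (mutant-specific fragment).
The constitutive 79 bp band, when present, never changes a call — this
makes the classifier robust to whether the wild-type amplicon pattern is
described as {207} or {207, 79}, two dialects that both occur in
descriptions of this assay. Band matching uses a ±3 bp tolerance by
default, reflecting agarose-gel resolution; `tolerance = 0` gives exact
matching. Calls: both bands → heterozygote (carrier female), 128 only →
hemizygous mutant male, 207 only → WT, neither → uninterpretable.

`variant_effect()` annotates a single-base coding substitution under the
standard genetic code (1-based CDS coordinates, HGVS-style). The hallmark
mutation is modelled as A→T at CDS position 240 on a lysine codon
spanning positions 238–240: for a lysine codon (AAA/AAG), only a
third-position A→T (AAA→AAT) yields asparagine, so this is the unique
orientation consistent with the K80N protein change; notations that
reverse the transversion's direction are not compatible with the genetic
code, and the package adopts the consistent orientation rather than
silently propagating the conflict. The shipped
`synthetic_exon3_amplicons.fa` fixture is a *synthetic* 286 bp amplicon
pair (clearly labelled as such) constructed so that the wild-type allele
digests to 207 + 79 and the single A→T creates the mutant's 128 + 79 + 79
pattern; it stands in for the real amplicon, whose sequence is not
redistributed here.

## Known limitations

* Baseline reproduction is bounded by the precision of the printed
  summaries; three low-information cells cannot be matched to ±0.02 (see
  above), though every significance call and every `"<0.01"` bound is
  reproduced.
* The permutation test's Monte-Carlo p-value uses the plain `#/B`
  estimator; it can return 0, unlike the exact-enumeration path. The
  conservative `(k+1)/(B+1)` estimator can be recovered by the caller but
  is not the default, to keep the implemented rule explicit.
* The generator emulates marginal cell distributions only; no
  cross-analyte covariance, batch structure, or detection-limit censoring
  (a correlation hook would be a natural extension).
* Genotyping models the digest, not the PCR: primer binding, amplicon
  recovery and gel artefacts are out of scope, as is any genome-scale
  site search.
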