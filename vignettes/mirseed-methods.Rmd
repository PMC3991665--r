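---
title: "Methods: models, parameters and design choices in mirseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in mirseed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`mirseed` implements the classical two-library plant small RNA-seq
discovery cascade. This vignette records the models each stage assumes,
the parameters that matter (with units and defaults), the numerical and
design choices made where the procedure is genuinely underdetermined, and
what the synthetic-data tests do and do not demonstrate about real data.

## Read cleaning

Raw reads are eliminated in a fixed order — low quality, 5′ adapter
contamination, missing 3′ adapter, empty insert, polyA, insert length
outside 18–30 nt — and each read receives exactly one fate: the first
rule it fails. The ordering is part of the contract: an adapter dimer
whose (empty) insert is vacuously polyA-like is counted at the
empty-insert rule, never at the polyA rule.

Two of the rules have no standard operational definition, so they are
explicit knobs in `clean_opts()`:

* *Low quality*: more than 20 % of bases below Phred 10
  (`max_low_frac`, `quality_floor`). Sanger Phred+33 encoding is
  assumed.
* *polyA*: at least 80 % A or a run of 10 A's in the trimmed insert
  (`polya_frac`, `polya_run`).

The 3′ adapter is located by the leftmost occurrence of its first 10 nt
allowing 1 mismatch (one per 10 nt); reads without that seed are removed
at the missing-adapter rule. This also covers the degenerate case of an
adapter longer than the read. 5′ contamination is an exact match of any
5′-adapter suffix of ≥ 10 nt at the read start. Inserts longer than
30 nt after trimming are excluded together with the short ones (the
18–30 nt analysis window).

## Annotation and priority resolution

Genome mapping is exact-match only, on both strands, implemented with
Biostrings dictionaries; tags with more than 20 genomic copies are
flagged and excluded from novel-miRNA candidacy. Known-miRNA calls
require sequence identity to a reference mature (or exact substring of a
reference precursor) after T/U normalization — one mismatch already
disqualifies. Structural ncRNA classes match by exact substring;
exon/intron/repeat require ≥ 1 nt same-strand overlap between a genome
hit and an annotated interval. siRNA duplex candidates are pairs of
22–24 nt tags on opposite strands of one locus with both 3′ ends
overhanging by exactly 2 nt, which in coordinates means the minus-strand
hit starts and ends exactly 2 nt left of the plus-strand hit.

A tag may match several categories; one is chosen by the fixed priority
`GenBank ncRNA > Rfam ncRNA > known miRNA > repeat > exon > intron >
siRNA candidate`, else `unannotated`. The siRNA level is not part of the
classical chain; it is placed last so it can never shadow the database
levels. Resolution is a pure function of the category set and is tested
exhaustively over all 2^6 subsets of the six classical levels. The
repeat level is skipped when no repeat annotation is supplied.

## Novel miRNA prediction

For each unannotated hit two windows are excised so the star arm can lie
on either side: `tag + max_space + 2*flank` nt (defaults 300 and 20 nt).
Each window is folded once (MFE fold, ViennaRNA `RNAfold` behind the
narrow `rna_fold()` contract — structure prediction is delegated, never
re-derived); the star is projected from the mature's pairing partners
with the 2-nt 3′ overhang convention, standing in for the Dicer cleavage
geometry. The minimal precursor (mature-to-star span plus flanks) is then
re-excised, re-folded and measured. This two-stage excision matters: MFEI
is a per-length quantity, and scoring a hairpin diluted in a 360 nt
window would systematically underestimate it.

Duplex metrics from the dot-bracket structure: base pairs are mature
positions paired outside the mature itself; mismatches are the
complement; the bulge is the longest unpaired run within either strand's
paired span; asymmetry is the absolute difference of unpaired counts
between the two spans; the star must not straddle a terminal loop
(possible in branched folds) and the mature must not overlap one.

Acceptance requires all of: MFE ≤ −18 kcal/mol, ≥ 16 duplex pairs,
< 6 mismatches, bulge ≤ 4 nt, asymmetry ≤ 4 nt, spacing ≤ 300 nt,
mature 18–25 nt, star 20–23 nt, A+U fraction in [0.30, 0.70], and
MFEI ≥ `mfei_min`. Choices worth recording:

* **MFEI** uses the standard definition (|MFE|/length × 100)/GC%. No
  cutoff is printed in the source procedure ("higher MFEIs"); the
  default 0.85 is common plant practice and is configurable.
* **Star length bounds** 20–23 nt implement the ambiguous
  "reference sequence length" parameters as star-length limits.
* **Homology filter** (≤ 4 substitutions against a supplied set of
  known plant matures) is implemented but OFF by default: requiring
  similarity to known matures conflicts with novelty, so it is an
  opt-in restriction (`novel_params(homology_matures = ...)`). When
  enabled it can only shrink the accepted set.
* **Deduplication** of overlapping accepted precursors keeps the
  lowest MFE, ties broken by leftmost coordinate; overlap is evaluated
  per chromosome ignoring strand, because a planted hairpin is
  rediscovered from the minus-strand hit of its own star arm.

Acceptance is monotone: tightening any threshold never adds predictions
(tested on the simulated genome).

## Differential expression

TPM = count / library clean-read total × 10⁶, so TPMs sum to 10⁶ per
library by construction. Fold change is log₂(treatment/control) with a
pseudo-value of 0.01 TPM substituted for zeros *in the ratio only*; a
miRNA absent from both libraries therefore has log₂ fold change exactly
0 and can never be called. Up/down calls use the 2-fold threshold
(|log₂fc| ≥ 1).

The exact count statistic `ac_pmf()` is
p(y|x) = (N₂/N₁)ʸ (x+y)! / (x! y! (1+N₂/N₁)^(x+y+1)), evaluated in log
space via `lgamma` so counts up to 10⁷ are stable. For the two-sided
p-value the package had a genuinely open choice, because no function of
the conditional distribution p(·|x) can be exactly invariant under
swapping the libraries (p(y|x; N₁,N₂) = (N₂/N₁)·p(x|y; N₂,N₁)), yet
swap-invariance is the property a user of a symmetric two-library design
should get. The default `ac_test(..., tail = "conditional")` therefore
conditions on the total t = x + y — under the null x ~ Binomial(t,
N₁/(N₁+N₂)) — and sums the probabilities of all outcomes no more likely
than the observed one. This is the classic exact two-Poisson test,
asymptotically equivalent to the count statistic above, exactly
swap-symmetric, and calibrated (type-I fraction at p < 0.05 is 0.044–
0.048 in the 2,000-row null simulations the tests run). The
minimum-likelihood tail over p(·|x) remains available as
`tail = "ac_minlik"`. No multiple-testing correction is applied by
default (selection is fold-change based); `de_table(adjust = TRUE)` adds
a Benjamini–Hochberg column.

## Target prediction

Scoring follows the established plant target-scoring scheme: mismatch 1,
G:U wobble 0.5, gap 2, all doubled within the seed (miRNA positions
2–13); the published procedure names the tool and thresholds but not the
weights, so the weights are explicit parameters. Sites must score
expectation ≤ 3.0. Scanning is ungapped over all windows of the miRNA's
length; single-gap alignments (at most 1 gap, tried at every position)
are available through `score_site()` for ±1 nt windows. Overlapping
candidate sites collapse to the best-scoring one per (miRNA, transcript).
Ambiguous bases score as mismatches.

Mode classification: a true mismatch or gap (wobbles count as paired) at
miRNA positions 9–11 calls translational inhibition, else cleavage.

Accessibility (UPE) is the energy to open the site: the transcript
window spanning the site plus 17 nt upstream and 13 nt downstream is
folded with and without the site constrained single-stranded, and UPE is
the free-energy difference (≥ 0 by construction). Sites with UPE ≥ 25
kcal/mol are discarded when the engine is present; without the engine
the filter is skipped with a warning and UPE is reported missing.

## qPCR quantification

Technical replicates are averaged within each biological replicate
before any subtraction (the aggregation order is not fixed by the ΔΔCt
method; averaging first is the numerically tamer choice). Then ΔCt =
Ct(assay) − Ct(reference) per (condition, replicate), ΔΔCt pairs
replicates across conditions by index, and fold change = 2^−ΔΔCt with
mean ± SD over biological replicates (3 × 2 by default). Amplification
efficiency is fixed at 100 %, the ΔΔCt model's assumption. Noiseless
simulated Ct tables invert exactly; with Gaussian Ct noise of 0.2
cycles the recovered log₂ folds are unbiased (the tests average a few
hundred simulated tables).

## The synthetic-data generator

The generator emulates the study conditions: two libraries (control vs
treatment) of tens of thousands of 50 nt reads — within the 10⁴–10⁶
range such experiments occupy, and small enough that the full test suite
runs in minutes — dominated by 21 nt inserts, using the published 5′/3′
adapter sequences, ~2 % planted contaminants per cleaning class, and a
100 kb genome at GC 0.5 carrying non-overlapping loci with ≥ 400 nt
spacing: hairpin miRNA loci (a fraction on the minus strand), known-miRNA
loci, rRNA/tRNA/snoRNA/snRNA loci, genes contributing exon and intron
fragments, and non-hairpin decoy tags.

Hairpins are constructed *by design*, not rejection-sampled: the mature,
a perfectly complementary star, a short loop, and 15 extra stem pairs on
each side (so that MFEI stays well above threshold even after the
20 nt genomic flanks are included at evaluation time). Each construct is
fold-verified against the full criteria before planting; construction
errors after bounded retries are diagnosed with the failing criteria.
Expressed-tag sequences are screened so they cannot collide with the
cleaning rules (no adapter seeds, no polyA signatures, no 5′-adapter
prefixes); this makes the cleaning partition property exact. For the
same reason the default substitution error rate is 0 — a substitution
can create an adapter seed inside an insert and legitimately change its
fate, making "per-rule removals equal planted counts" ill-defined —
while uniform substitution noise remains available via `error_rate`.
Library counts are independent Poisson draws per locus with
treatment rates scaled by the planted fold change, so realized fold
changes are unbiased; read qualities are fixed at Phred 40 with a
distinct low-quality profile for that contaminant class (the source
procedure defines neither). All randomness flows from one integer seed;
identical configurations give byte-identical FASTQ output.

What passing tests show — and don't. Recovery of planted truth
demonstrates the pipeline's internal consistency: exact cleaning
partition, perfect-match annotation, criteria-compliant hairpin
acceptance, decoy rejection, DE recovery at planted effect sizes, and
exact ΔΔCt inversion. It does not demonstrate performance on real data:
real libraries have sequencing errors, adapter variants, expression
dispersion beyond Poisson, repetitive genomes where exact-match mapping
and the 20-copy limit bite, imperfect hairpins, and miRBase/genome
version effects. Headline counts from any particular study (total reads,
numbers of known/novel miRNAs, numbers of DE calls and targets) depend
on those inputs and are out of scope.

## Problem sizes and numerical notes

The test suite uses a 4-hairpin/4,000-read shared experiment for module
tests and a 20-hairpin + 20-decoy, 20,000-read experiment for end-to-end
recovery; the type-I simulation uses 2,000 null rows at expected count
100; pmf normalization is checked to 10⁻⁹ over x ∈ {0,1,5,20,100} and
depth ratios {0.5, 1, 2}. Tail sums are truncated at the 10⁻¹⁶ quantiles
of the bounding distribution with the excluded mass added where it
belongs. Degenerate inputs are defined, not special-cased silently:
empty insert lists give all-zero histograms, a mature that is entirely
unpaired yields zero-pair metrics (criteria then fail with enumerated
reasons), GC = 0 makes MFEI undefined and the candidate is rejected, and
a zero library total is an error.
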