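---
title: "Localizing a complex transgene insertion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing a complex transgene insertion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A transgenic mouse line carries a ~7 kb expression construct whose
integration produced a recessive-acting glaucoma phenotype with incomplete
penetrance. Whole-genome paired-end sequencing of a homozygous animal,
mapped against a composite reference (the genome plus the cloning vector as
an extra contig), shows a single but complex integration locus: two
insertion sub-sites -- a short 517 b vector fragment (*Ins1*) about 100 kb
upstream of a *Tfap2d*-like gene, and a multi-copy head-to-tail concatemer
of the full vector (*Ins2*) about 250 kb downstream of the gene cluster --
accompanied by three genomic deletions, the largest of which (100 kb)
removes a non-expressed non-coding gene. Copy number at that deleted gene
then serves as a genotyping assay (2 copies = wild type, 1 = heterozygote,
0 = homozygote), and breeding-colony count tables tie the phenotype to
transgene homozygosity through chi-square goodness-of-fit tests.

`tgloc` implements that entire inference chain as reusable, tested code,
together with a synthetic-data module that reproduces the architecture at
desk scale so every stage can be exercised and validated against known
truth.

## The synthetic architecture

`build_wt_reference()` draws a uniformly random contig and places three
gene analogs with the real inter-feature distances multiplied by a `scale`
parameter (default 0.05, so 250 kb becomes 12.5 kb and the whole layout
fits a 500 kb contig while preserving the topology: the sub-sites stay far
apart relative to any clustering window, and every deletion remains
detectable at the default depth-window size). `apply_architecture()`
excises the deletions, inserts the Ins1 fragment and the Ins2 concatemer,
and emits a truth set with every junction, the deletion intervals, the
copy number and a wild-type/transgenic liftover map.

Quantities the source material does not pin down are explicit parameters,
not claims:

* the concatemer copy number (only "multiple copies" is known) defaults to
  5 per haplotype and is configurable (`ins2_copies`, with a per-copy
  orientation pattern);
* the two smaller deletions default to 20 kb unscaled (1 kb at the default
  scale) each, placed near the two sub-sites;
* which construct region the 517 b Ins1 fragment derives from is unknown;
  the fragment interval is a parameter of `vector_construct()`.

### Junction microhomology

If the first inserted bases happen to equal the genome bases that follow
the insertion point, the junction position is ambiguous by the length of
that shared run. An ungapped aligner always extends the genome match as
far as it will go, so the package adopts the *maximal genome extension* as
the canonical junction coordinate (rightmost representation for a
genome-to-vector junction, leftmost for vector-to-genome) and records the
same convention in the truth set. Split-read calls and truth then agree
exactly instead of drifting apart by the microhomology length.

### Read simulation

`simulate_reads()` draws fragments of Normal(550, 60) length (truncated
below at the 150 b read length) and emits FR mate pairs with Phred+33
qualities; per-base substitution errors occur at `error_rate` (default
0.002, a deliberately conservative figure for a modern short-read
library). Fragments are sampled from the two haplotype molecules in
proportion to their lengths -- with equal-length haplotypes this is the
familiar one-half each, and it keeps per-base coverage uniform across
haplotypes when an insertion lengthens one of them (a property the
copy-number linearity checks depend on). Read names carry
`name:hap:contig:start:end:strand` truth tags; the callers never parse
them -- they exist for tests and truth comparison only.

What the generator deliberately does **not** emulate: indel and
PCR-duplicate errors, GC bias, quality-score decay along the read,
chimeric library artifacts, and real mm10 sequence context (repeats,
segmental duplications). Passing tests therefore demonstrate the
correctness of the inference logic under a clean substitution-only error
model, not robustness to every artifact of real libraries; on real data
the uniquely-mapped filter and the support thresholds carry more weight.

## The mapper

A minimal seed-and-extend mapper stands in for a production aligner.
`build_index()` hashes every forward-strand k-mer (k = 21 by default,
valid range 11-31); `align_read()` samples seeds every 10 bases (always
including the final offset, so junction overhangs near the read end can
still seed), collects candidate diagonals from both strands, and scores
each diagonal with a best-local-segment scan (match +1, mismatch -4).
That scoring crosses an isolated sequencing error (recovered within five
matches) but stops quickly in foreign sequence, which is exactly what
makes reads overhanging a junction come back end-clipped with the clip
boundary at the junction. A placement is `unique` when no competing
placement over the same part of the read scores within 2 units of it;
multi-mapping reads are flagged and excluded from insertion evidence and
depth. Up to three non-overlapping segments are reported per read, which
is how the vector-side half of a split read surfaces. There is no gapped
alignment -- consistent with the substitution-only simulator and a
documented limitation for external SAM input (gapped CIGARs are
rejected).

Pair classification applies, in precedence order: chimeric genome/vector
pair, split-junction read (clip of at least 20 b re-aligning uniquely to
the other contig class), genome-concordant (opposite strands, implied
insert within mean plus or minus four standard deviations),
vector-internal, discordant-genome, unmapped. The "uniquely mapped to
both the genome and the vector" idea is thus operationalized as two
evidence classes -- whole-mate (chimeric) and within-read (split) -- and
both feed the caller with their class recorded.

## The insertion caller

Evidence items are the junction-facing outer coordinate of the genome
mate of each chimeric pair (an interval bound: a left-flank mate bounds
the breakpoint from below, a right-flank mate from above) and the clip
boundary of each split read (base-precise). Single-linkage clustering
with a 1100 b window (twice the mean fragment length, the localization
uncertainty of a chimeric pair) groups evidence into candidate sites;
clusters with at least `min_support = 3` items become calls. With split
reads the breakpoint is the modal clip boundary (ties resolved to the
smallest coordinate); otherwise the call reports the interval between the
innermost bounds of the two flanks. Concatemer-internal vector-vector
junctions are deliberately not reported as genomic calls.

Transgene copy number is the depth ratio `2 * mean vector depth / mean
genome depth`, the genome mean taken over windows not masked by called
deletions or insertion flanks (plus or minus one mean fragment length
around each call). A heterozygote carrying an n-copy concatemer is
expected near n, a homozygote near 2n, with the 517 b fragment adding
about 0.07 per carrier haplotype.

## Depth, deletions, and the locus genotype

`compute_depth()` counts uniquely-aligned bases per 200 b window (the
final partial window uses its true width, so window depths exactly
conserve the total aligned base count) and normalizes by the median over
unmasked windows. Deletion calling scans for runs of at least 3 windows
of depth loss. Numerical choices worth knowing:

* a single run state (normalized depth below 0.7, the upper edge of the
  heterozygous band) detects runs, with zygosity assigned from the run
  mean (below 0.2 homozygous, otherwise heterozygous): individual 200 b
  windows of a heterozygous deletion fluctuate between the homozygous and
  heterozygous ranges, and splitting runs on window state would fragment
  them;
* single-window gaps still visibly depressed (below 0.85) are bridged,
  and bridging windows do not count toward the run-length requirement;
* a run must also sit significantly below the diploid level:
  `(1 - mean) * sqrt(n_windows) / sigma >= 5`, with sigma the robust
  (MAD) window-level noise -- without this, short stretches of marginally
  low windows occasionally pass as heterozygous losses;
* calls touching the first or last 700 b of the contig are dropped:
  fragments cannot extend past the contig ends, so coverage ramps over
  about one fragment length there and mimics loss (a synthetic-contig
  artifact; real chromosome-scale references place no calls there);
* boundaries are refined by a joint two-changepoint least-squares fit
  (background / loss / background) on per-base coverage over the run plus
  four windows of flank -- fitting both cuts jointly keeps the true
  coverage steps in control even when noisy windows dragged the
  window-level run edges around -- and finally snapped to the modal
  soft-clip coordinate nearby (two or more supporting reads), since reads
  crossing a deletion junction are clipped exactly at the boundary.

At 30x coverage this recovers 1 kb heterozygous deletions with reciprocal
overlap above 0.9 (usually above 0.99); without the clip snapping the
pure depth signal for that case sits close to its information limit.

The locus genotype is the categorical readout `round(2 * mean normalized
depth over the locus)` clamped to [0, 2] and mapped 2/1/0 to
wild-type-like / heterozygote-like / homozygote-like. Rounding rather
than a likelihood model is intentional: the laboratory assay this mirrors
is a categorical copy-number call, and the three states are separated by
half-unit margins at the depths involved. The genotyping background masks
insertion flanks and other deletions but never the assayed locus itself
(a fully masked locus is an error, not a silent 0).

## Segregation statistics

`chisq_gof()` computes the uncorrected Pearson statistic with expected
counts `total * proportion` and the upper-tail chi-square probability
(`pchisq(..., lower.tail = FALSE)`, the regularized upper incomplete
gamma function). No Yates continuity correction is applied: the
uncorrected statistic reproduces all four published two-decimal p-values
(0.28, 0.01, 0.77, 0.04) from the colony count tables, the corrected one
does not. Two canned hypotheses cover the study design for a het-by-het
cross: Mendelian transmission of the transgene (negative versus pooled
positive, 1:3) and glaucoma-marks-homozygotes (1:2:1). The penetrance
estimator is the plug-in ratio of the observed glaucoma fraction to the
expected 25% homozygote fraction, clamped to [0, 1] with a flag; the
Wilson score interval attached to it is an auxiliary output with no
published counterpart. Published tables print one count short per row;
the TSV loader reconstructs exactly one missing count per row from the
printed total and says so.

```{r}
library(tgloc)
tabs <- read_transmission_tsv(system.file("extdata",
  "transmission_tables.tsv", package = "tgloc"))
segregation_report(tabs[[1]])$homozygote_glaucoma
```

## Problem sizes and verification

The test suite and the acceptance script run everything at desk scale,
chosen so the full suite completes in minutes on one core while keeping
every recovery property measurable:

* insertion recovery: 20 homozygous simulations on the default 500 kb
  contig at 30x, substitution rate 0.002, plus wild-type runs that must
  produce zero calls;
* deletion recovery: homozygous and heterozygous runs on the 500 kb
  contig, at least 90% reciprocal overlap with correct zygosity;
* locus genotyping: 30 simulations per genotype on a compact 150 kb
  contig that carries the same scaled architecture at the same 30x depth;
* copy-number linearity: error-free runs at 1, 2, 5 and 10 concatemer
  copies, slopes 2 (homozygote) and 1 (heterozygote) with R-squared above
  0.99;
* mapper validation: agreement with an exhaustive all-positions Hamming
  scan (via `Biostrings::neditStartingAt`) on a 10 kb reference at 1%
  read error, at least 99% of reads;
* statistical calibration: chi-square tail probabilities against the
  df = 1 and df = 2 closed forms to 1e-12, and the empirical type-I error
  of the homozygote test on 10,000 simulated true-hypothesis colonies of
  400 animals, required to sit in 0.05 plus or minus 0.01.

Every stochastic step takes a seed and derives all draws from it;
identical configuration and seed produce byte-identical FASTQ, SAM and
call files.

## Known limitations

* Substitution-only error model and ungapped alignment: indel-rich or
  long-read data are out of scope, and external SAM with gapped CIGARs is
  rejected rather than approximated.
* The concatemer's internal structure (copy orientations, internal
  rearrangements) is not resolved beyond the copy-count estimate.
* The depth model has no GC-bias or mappability correction; on real data
  the normalization median should be computed per GC stratum before the
  2/1/0 readout is trusted.
* The breeding model covers a single het-by-het F2 cross with a
  recessive, incompletely penetrant phenotype; no pedigrees, no linkage.
* The real study's locus copy-number figures come from a qPCR assay; this
  package reproduces the 2/1/0 decision logic from sequencing depth, not
  the assay chemistry.
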