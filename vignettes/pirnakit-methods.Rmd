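---
title: "Methods: quantifying piRNA stability, truncation and amplification from small RNA alignments"
author: "pirnakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying piRNA stability, truncation and amplification from small RNA alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnakit)
```

## The biological question

PIWI-interacting RNAs (piRNAs) are 23–32 nt germ-line small RNAs. Their
3'-terminal ribose carries a 2'-O-methyl mark deposited by the HEN1/HENMT1
methyltransferase; without it, piRNAs are exposed to 3' exonucleolytic
trimming and to uridylation/adenylation, destabilising the population. A
small RNA sequencing comparison of wild-type and methylation-deficient
mutant germ cells shows this as a syndrome of related signals:

* the read-length profile shifts from a single mode near 30 nt (MIWI-bound
  piRNAs) towards a second, shorter mode near 26 nt;
* the fraction of reads carrying a non-templated 3' A or U rises;
* shortened reads share 5' ends with full-length reads but lose bases at
  the 3' end — truncation is 3'-sided;
* genome-binned expression shows a deficit of long and an excess of short
  piRNA species at the same loci;
* the ping-pong amplification signature (opposite-strand read pairs whose
  5' ends overlap by exactly 10 nt) weakens as substrate piRNAs are lost.

`pirnakit` implements each of these measurements as a reusable, tested
stage over standard alignment inputs (SAM/BAM + FASTA + BED/GFF3), and
pairs them with a synthetic-data generator whose ground truth makes every
estimator testable by parameter recovery.

## Conventions and ingestion

Internally every sample is a `GRanges` (1-based, closed intervals — the
native Bioconductor convention; SAM positions import without conversion,
and all interval logic below is expressed in it). Read-space fields are
stored 5'→3' of the sequenced RNA: for minus-strand alignments `seq` is the
reverse complement of the SAM `SEQ`, and `ref_bases` holds the reference
bases over the aligned span complemented into the same orientation, with
`"."` at soft-clipped or inserted positions. The 5' end of an alignment is
its leftmost position on `+` and its rightmost on `-`; because piRNA decay
proceeds from the 3' end, this 5' key is stable across truncation and
serves as a family proxy throughout.

Reference bases are rebuilt from the MD tag when present, else from the
FASTA; a record with neither is a hard error naming the read. Multi-mapped
reads are counted once per retained alignment (no fractional weighting),
with the retained universe bounded by the reported hit count
(`max_hits = 3` by default, matching the mapper-side cap of the study
design this package follows). The mapping-quality floor defaults to 0 and
is exposed as configuration, since a specific cutoff is a property of the
mapper, not of the method.

## piRNA calling and hierarchical annotation

A read is a piRNA if its length lies in 23–32 nt (configurable). Primary
piRNAs carry U at read position 1, secondary piRNAs A at position 10;
positions are read-space, so the biases are evaluated on the RNA rather
than the reference strand. A read may carry both marks; both flags are
kept, and the exclusive typing needed for 1°/2° ratio reports resolves
primary-first by default (the precedence is a parameter because no
convention exists).

Annotation is exclusive and hierarchical: the categories are tried in the
order piRNA cluster > repeat > coding exon > non-coding exon > intron, a
read takes the first category it overlaps by ≥ 1 bp, and reads overlapping
nothing are intergenic. Cluster reads (candidate piRNAs) are re-annotated
against the remaining tracks for a secondary category, and candidate
piRNAs over coding exons are subtyped 5'UTR/CDS/3'UTR by sub-feature
overlap (largest overlap wins; ties resolve 5'UTR, CDS, 3'UTR). Introns
are computed as gene body minus exons rather than requiring explicit
intron features. Antisense status comes from the feature that decided the
category; among equal-priority features the largest overlap decides and
ties resolve to sense, the conservative call.

## 3' end modifications

For each piRNA read the 3'-terminal base is compared with its reference
base in read orientation. Uridylation is counted when the read ends in U
(T in DNA space) over a reference base that is not T — only then is the
modification determinable — and adenylation symmetrically with A. The
percentage over these informative reads is the primary estimate (it is the
unbiased estimator of the per-read tailing probability); a percentage over
all piRNA reads is also emitted for comparability, since either
denominator is defensible. Reads whose terminal base is soft-clipped are
excluded and tallied by default (`require_aligned_3prime`); with the flag
off they are retained but their clipped terminus remains uninformative for
the base test. Replicate summaries are grouped by condition, and the
between-genotype comparison is a two-sided Welch test per modification on
the replicate percentages.

## Binned expression and denesting

Alignments are tallied per (chromosome, bin, alignment length) with bin
index `floor(start / bin_size)`; the default bin size is 10 Mbp and the
length stratification 20–35 nt. Lengths outside the range are tallied
separately, never silently dropped, so the matrix total plus the
out-of-range count always reconciles with the input. Two pool sums
summarise each bin: long (28–32 nt, MIWI-sized) and short (23–27 nt,
MILI-sized). Per-bp normalisation divides by the true width of the final
partial bin (flagged in the output rather than assumed full). Distinct 5'
ends per bin — keyed by (chromosome, strand, 5' position), strand-aware
because 5' ends are strand-defined — estimate the number of expressed
piRNA families.

Denesting makes that estimate robust to truncation stacks: after removing
duplicate intervals, any interval fully encompassed by a distinct interval
is discarded, so only "canonical" full-length alignments contribute 5'
ends. The implementation is a single sweep over intervals sorted by
(start asc, end desc) with a running maximum end — O(n log n), verified in
the tests against an O(n²) containment scan. Differential matrices are
elementwise (B − A) under an identical binning specification (a mismatch
is an error, never a silent rebin); unique-5'-end counts are kept per
sample rather than differenced, since their difference is not meaningful.

## Truncation (overlap-end) profiling

Long alignments (default 28–32 nt, nominally wild type) and short
alignments (default 23–27 nt, nominally mutant; both pools may come from
one sample) are compared after the long pool is reduced to one instance
per (chromosome, strand, start, length) and optionally denested. Each
short alignment is assigned, by default, to the single longest long
alignment on its chromosome and strand that completely contains it and is
longer (ties: smallest start, then input order — deterministic across
runs); a flag records instead a pair for every containing long alignment,
retained because multiplicity matters when the long pool itself contains
truncated forms, and containment itself suppresses both the multiplicative
over-counting and spurious "negative truncation" that plain overlap
assignment produces. With containment off, ≥ 1 bp overlap qualifies and
positive (lengthening) deltas may occur.

Signed end changes use the convention shortening < 0 < lengthening: on the
plus strand `delta5 = start(L) − start(S)` and `delta3 = end(S) − end(L)`,
with the two interval ends swapping roles on the minus strand. The 3'-vs-5'
comparison is a two-sided Welch two-sample t-test on |delta3| versus
|delta5| with Welch–Satterthwaite degrees of freedom and a 95% confidence
interval for the mean difference; the genotype comparison applies the same
machinery per end (B − A) plus per-length-change proportion differences
for plotting. The Welch routine is implemented directly so the degenerate
inputs have defined behaviour — zero variance in both groups with equal
means gives t = 0, p = 1; with unequal means the limit t = ±Inf, p = 0 —
and it is validated against `stats::t.test` to 1e-9 relative tolerance.
The confidence interval is reported as a difference of means in bases; a
ratio reading of such intervals is conceivable but is not the default
because the standard two-sample t report is the difference.

## Ping-pong signature

For a plus-strand read P and minus-strand read M on one chromosome the
5'-to-5' span is `o = end(M) − start(P) + 1`; a pair is counted once when
`1 ≤ o ≤ o_max` and the overlap region lies inside both reads. The
signature statistic is `z = (count[10] − mean(background)) / sd(background)`
with the background the other overlap lengths in a window (default 1–20)
and the sample (n−1) SD. Window and SD convention are configuration
because published analyses delegate this computation to external scripts
with unstated defaults; a flat background is a reported error state rather
than an infinite score. An option down-weights pairs by
`1/(n_hits_P · n_hits_M)` for multi-mapped reads (off by default — pairs
are unique read pairs).

Stringent ping-pong pairs additionally require both members 23–32 nt, the
exact 10-nt overlap, the primary 1U and the secondary 10A (the conjunctive
reading of the criteria; a flag gives the literal "or"), and the primary
sense — the secondary antisense — to a repeat or protein-coding exon.
Either member of an opposite-strand pair may take the primary role; a pair
is accepted if some assignment satisfies everything. Reported are the
pairs, the fraction of piRNAs participating in at least one pair, and the
primary/secondary splits over repeats and coding genes.

## The synthetic-data generator

The generator emulates the statistical structure of the study libraries at
desk scale, with every modelled feature recorded as ground truth.

A toy genome (default: 2 chromosomes × 1 Mbp of uniform random sequence)
carries mutually disjoint clusters, repeats and gene models (coding genes
with exon/CDS/UTR sub-features and implied introns). piRNA source loci
(default 400) are laid on it with category weights emulating the real
composition — 80% in clusters, ~0.5% repeats, ~4% each exon class, the
rest intronic/intergenic — a 1U probability of 0.8 at the source, and a
configurable antisense fraction (0.3) on stranded features. Loci on the
same chromosome and strand are kept ≥ 40 bp apart: distinct piRNA families
occupy distinct positions, so containment relations hold only within a
family. The locus layout has its own seed, independent of the read-sampling
seed, because samples of both genotypes come from the same genome and must
share source loci — this is what makes cross-genotype truncation profiling
meaningful. Per-locus abundances are log-normal (σ = 1; σ = 0 gives a flat
library whose pair-free 5'-overlap background is near-uniform, the regime
in which the Z score is calibrated).

Each read draws a pre-truncation length from a mixture of discretised
normal modes — wild type {30 nt, weight 1}, mutant {30 nt, 0.55; 26 nt,
0.45}, both with spread 1 nt, reproducing the unimodal and bimodal
profiles — then optional extra 5'/3' truncation from configurable
distributions, and with configured probabilities one non-templated 3' A or
U (wild type 2%/2%; mutant 10%/5%). The mutant tail rates are the regime
under which recovery is verified; the wild-type rates are a low baseline
chosen to be clearly below them. A tail extends the alignment by one base
whose reference position carries the genomic base, so it is detected as a
terminal mismatch exactly when that base differs — which is why the
informative-denominator estimator, not the raw mismatch fraction, recovers
the configured rate. Tails are single-base because the assay inspects one
terminal base; multi-base tails would be invisible to it anyway.

A configured fraction of reads (wild type 0.10, mutant 0.05 — the mutant
keeps roughly half its amplification) is emitted as opposite-strand pairs
from dedicated pair loci whose 5' ends sit exactly 9 bp apart on opposite
strands, the 10-nt overlap geometry. When the primary locus starts with U,
the overlap arithmetic automatically places an A at read position 10 of
the secondary — the generator does not force 10A separately, mirroring how
ping-pong produces the bias in vivo. Pair loci sit sense-primary on
repeats by default so planted pairs satisfy the stringent criteria.

What the generator does **not** model: sequencing errors and quality
strings, PCR duplicates, multi-mapping structure, multi-base tails, and
genome repeat structure (the toy genome is uniform random sequence). Tests
passing on it therefore demonstrate the correctness of the estimators
under the stated generative model, not robustness to real-library
artefacts such as error-induced terminal mismatches, which would inflate
tailing estimates by roughly the per-base error rate.

## Numerical and design choices

* Coordinates: 1-based closed `GRanges` internally; all published-style
  conventions (floor binning, half-open overlap arithmetic) are expressed
  equivalently in it and covered by worked examples in the tests.
* Problem sizes: simulation-backed tests use libraries of 1,200–10,000
  reads on 50 kb–400 kb toy genomes with 150–1,500 loci; these sizes give
  the estimators enough events (e.g. ≥ 3 binomial SEs of separation for
  tailing; 2,000 truncation pairs) while keeping the full suite fast.
  The acceptance script uses the same scales.
* Ties and determinism: every tie-break (longest-partner assignment,
  antisense feature choice, exclusive 1°/2° typing) is fixed and
  documented; the whole pipeline is byte-reproducible for a fixed
  configuration and seed.
* Degenerate inputs: empty pools, flat overlap backgrounds, zero-variance
  Welch inputs, reads with unaligned termini, and unstranded features in
  antisense logic all have explicit, tested behaviour (errors or defined
  values, never NaN or ±Inf by accident).
* The S1-style "sequence-based criteria" beyond length and 1U/10A are not
  modelled anywhere: only the criteria actually defined (length window,
  1U, 10A) are implemented, and nothing further is guessed.

## Known limitations

Fractional multi-mapper weighting is not implemented (each retained
alignment counts once). The binning stage reports descriptive differences
only — no per-bin significance testing, mirroring its descriptive role.
The heuristic for unaligned 3' termini keeps the read but cannot test the
clipped base against a reference; resolving clipped bases against adjacent
genomic sequence would require the FASTA at analysis time and is left out.
Circular/overview visualisations are out of scope: every figure-level
quantity is emitted as a table.
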