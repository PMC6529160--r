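---
title: "Methods: coverage-based gene comparison, pan-genome classification and genetic anchoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-based gene comparison, pan-genome classification and genetic anchoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pananchor)
```

pananchor implements the computational core of a two-accession plant genome
comparison: given a de novo assembly of one accession (called **R**, the
mapping reference) and short-read data of a second accession (**Q**) and of a
larger accession panel, it calls per-gene duplications and presence/absence
variants from read depth, classifies genes as core/dispensable/TE across the
panel, flags TE genes by annotation overlap, compares gene order between two
annotations through reciprocal best hits (RBHs), anchors assembly contigs
into pseudochromosomes with an F2 genetic map, and computes two
genome-distribution statistics (structural-variant clustering around
centromeres; homotetramer enrichment in sequence homologous to reference
assembly gaps). A synthetic-data module generates every input with known
truth, so the whole pipeline is exercised offline and every recovery claim in
the test suite is a measurement against planted truth.

## Relative coverage and duplication calling

For one accession mapped against assembly R, the per-gene statistic is
median-based at every step:

1. per-gene median depth over all positions of the gene span (introns
   included; zero-depth positions included),
2. divided by the accession average, computed as the genome-wide per-position
   median depth,
3. divided by the median over genes of the step-2 values (taken over genes
   with non-zero value), so the median relative coverage is exactly 1.

Step 2 removes the accession's sequencing depth; step 3 absorbs residual
accession-specific mapability differences (e.g. sequence divergence from the
reference). Both are scale-free, so calls are exactly invariant under any
positive rescaling of a depth track — the test suite asserts identity, not
approximate equality.

With $v_R$ and $v_Q$ the relative coverages of a gene, the call is
*duplicated in Q* when $v_R < 0.5\,v_Q$, *duplicated in R* when
$v_R > 1.5\,v_Q$, *balanced* otherwise; both inequalities are strict, so a
gene exactly at a cutoff stays balanced. A gene with $v_Q = 0$ and $v_R > 0$
is called duplicated in R: a deletion in Q and extra copies in R are
indistinguishable from coverage ratios alone, which is why the synthetic
recovery experiments plant deletions only when they are not being scored.
Both-zero genes are *uncallable*. TE-flagged genes are removed from the
duplicated sets afterwards, mirroring the usual practice of excluding
putative TE genes from gene-space comparisons.

### Why planted amplifications default to three copies

A tandem duplication with one extra copy gives an expected coverage ratio of
exactly $1/2$ — precisely on the strict 50% boundary — and is therefore
detected at chance level no matter how deep the sequencing. This is a real
limitation of the hard-cutoff rule, not of the implementation. The
synthetic generator therefore plants amplifications with `dup_copies = 3`
(expected ratio $1/3$, safely inside the called region), and the vignette
records the boundary behaviour so users interpreting two-copy events know
the call is uninformative there.

### Why the default mapability bias is 0.05

The per-gene mapability bias is lognormal with median 1 and log-sd
`bias_spread`, drawn once per accession. A balanced gene's log coverage
ratio then has sd $\sqrt{2}\,\texttt{bias\_spread}$. At `bias_spread = 0.1`
the probability of crossing the $\log 1.5$ cutoff is about 0.2% per gene —
roughly two false duplication calls per 1,000 genes, which would dominate the
30 planted true events. At 0.05 (a few percent per-gene bias, a realistic
magnitude between accessions of one species) the crossing probability is
~1e-8 and calling is limited by Poisson noise on the gene median, which is
negligible at 30x over kilobase genes.

## Pan-genome classification

From a genes x accessions relative-coverage matrix, accessions with average
depth strictly below 10x are excluded first (an accession at exactly 10x is
retained). A gene is **dispensable** when its relative coverage is below 0.1
in more than 100 accessions (both strict); remaining genes are **TE** when
TE-flagged, else **core** — dispensable takes precedence over TE. The
absolute count 100 matches a panel of roughly a thousand accessions; for
small synthetic panels `min_fraction` converts it to a panel fraction. The
classes always partition the gene universe, and raising `min_accessions` can
only shrink the dispensable set (asserted as a property test).

## TE annotation and TE-gene flagging

TE library hits against the assembly are kept when their bitscore reaches at
least 90% (inclusive) of the family's top self-mapping score; overlaps are
then resolved greedily by descending bitscore (ties: longer alignment, then
lexicographic TE id), discarding any hit that overlaps an accepted placement
by one or more bases. The greedy keep-best order is the standard reading of
"overlapping hits removed"; accepted placements are checked pairwise
non-overlapping. A gene is flagged as a putative TE gene when the union of
placements covers strictly more than 80% of its span; an exon-restricted
mode is available since TEs frequently sit in introns.

## RBH synteny and SV blocks

Best hits per direction maximize bitscore (ties: lower evalue, then
lexicographically smaller subject; co-optimal bitscores are recorded on the
pair as `tied`). A pair (a, b) is reciprocal iff each is the other's best
hit. Positions are compared as genome-wide gene ranks with chromosomes
concatenated in a fixed order — ranks, not base pairs, because the reference
comparison is a sorted-gene scatter.

A pair is a synteny outlier when any of three conditions holds:

- its `rank_b` deviates from the median `rank_b` of up to 5 flanking pairs
  per side by more than 20 ranks;
- its `chrom_b` differs from the flanking majority chromosome;
- it is excluded from the longest strictly increasing subsequence (LIS) of
  `rank_b` over pairs sorted by `rank_a`.

The first two rules catch genes moved far from their syntenic position. They
cannot, however, flag members of a *short inversion*: an inversion member's
flanking pairs are mostly fellow inversion members, so its rank deviates
from the flanking median by nearly nothing (at most the block length at the
edges, ~0 in the interior). The LIS rule supplies the missing signal: every
local order reversal is excluded from the monotone backbone. One member of
an inverted block can always be kept in a monotone chain, so a 10-gene
inversion yields 9 flagged members and block boundaries within one gene of
truth — the detection granularity is inherently one gene at block edges.

Maximal runs of at least 3 consecutive outliers whose `rank_b` values are
monotone become SV blocks: decreasing `rank_b` with increasing `rank_a` is
an inversion, otherwise a translocation.

## F2 recombination fractions and anchoring

The estimator is maximum likelihood under the F2 intercross model: the joint
genotype of a marker pair is a 9-class multinomial whose probabilities are
products of two independent gamete transmissions with recombination fraction
$r$; the double heterozygote mixes parental phase (probability
$\propto (1-r)^2$) and recombinant phase ($\propto r^2$). EM iterates the
expected recombinant-gamete count,
$r' = \big(\sum_c n_c k_c + n_{HH}\,2r^2/((1-r)^2+r^2)\big)/(2n)$, with
$k_c$ the fixed recombinant-gamete count of class $c$. Missing calls are
excluded pairwise, never imputed; monomorphic markers return $r = 0$ with a
degenerate flag.

Because the likelihood maps to itself under $r \to 1-r$ combined with an
allele relabeling, it can carry one mode on each side of 0.5. EM is started
in both basins (0.25 and 0.75) and the better mode is folded to
$[0, 0.5]$ as $\min(r, 1-r)$. Folding — rather than clamping the iteration —
makes the estimate exactly invariant under an allele swap at either marker,
which matters when marker phasing is arbitrary; on coupling-phase data the
folded estimate coincides with the $[0, 0.5]$-restricted MLE with
overwhelming probability. Convergence is $|\Delta r| < 10^{-6}$ or 200
iterations; a grid oracle at $10^{-3}$ resolution confirms agreement on
every tested table.

Contigs are grouped by single linkage on the minimum inter-contig $\hat r$,
joined strictly below `r_max = 0.25` (union-find, so the boundary is exact).
Within a group, the order minimizes the sum of adjacent minimum $\hat r$ —
exhaustively for up to 8 contigs (the realistic case is 3–7 contigs per
chromosome), greedy nearest-neighbour beyond. The two mirror-image orders
are tie-broken deterministically (lexicographically smaller first contig
id); biological north–south polarity is applied only via the optional
`reference_polarity` input, since orientation relative to an external
reference is not derivable from the cross itself. Contig orientation comes
from the genetic coordinate implied by flanking contigs: for each marker,
mean $\hat r$ to markers of earlier contigs minus mean $\hat r$ to markers
of later contigs increases along the group; the sign of its covariance with
physical position fixes the orientation. Contigs with fewer than two markers
are `unknown` and treated as forward when sequence is built. Contigs are
concatenated with N spacers (default 100 bp, a conventional unknown-gap
length; the AGP records them as U components with map evidence).

The recombination-rate contrast between regions uses the standard two-sample
proportion test (Pearson chi-square on the 2x2 table with Yates continuity
correction); the test suite checks it against an independently coded
closed-form oracle.

## Genome-distribution statistics

Structural variants of at least 1 kbp are binned into fixed 1 Mbp windows by
start position; each window's count is paired with the distance of its
midpoint to the centromere midpoint, and association is measured by Spearman
rank correlation (average ranks for ties, t-approximation p). Windowing by
start position keeps counts conserved — each variant is counted exactly
once.

Assembly gaps are maximal N runs of at least 10 bases. For each reference
gap, the best hit of each 30 kbp flank against the target assembly is taken;
the gap is spanned when both hits land on one target sequence, same strand,
in consistent order, and the enclosed span is at most 200 kbp (the
configurable `max_span` operationalizes "spanned with confidence"; larger
spans are more plausibly rearranged than homologous). Homotetramer counting
is overlapping by default — a run of length $L \ge 4$ contributes $L-3$ —
with a run-based alternative (`mode = "runs"`); N runs never count, and the
frequency is per kbp of total sequence length. Enrichment of gap homologs
over length-matched, N-free, seeded-random control sequences is tested with
the Mann–Whitney U test (exact enumeration when the pooled size is at most
12 without ties, otherwise normal approximation with tie and continuity
corrections).

## What the synthetic data does and does not emulate

The generators reproduce the *statistical structure* each stage consumes:
Poisson depth with per-gene multiplicative mapability bias; an accession
panel with planted absence sets and a low-coverage fraction; Haldane
(no-interference) crossovers simulated gamete-wise so the true
recombinant-gamete count is recorded alongside the per-plant convention;
hit tables consistent with planted orthology, including reversed order
within an inverted block and extra lower-scoring hits for amplified genes.

They do not emulate read-level artefacts (sequencing error, GC bias,
mapping ambiguity between real paralogs), crossover interference, population
structure in the accession panel, or assembly errors. Passing the recovery
tests therefore demonstrates that the *decision rules* behave as specified
under their own model assumptions — not that the thresholds are optimal for
any particular real data set, where the hard cutoffs were originally
validated against experimentally confirmed gene differences.

Default scales keep everything desk-sized: the two-genotype simulation uses
1,000 genes on a 2 Mbp chromosome at 30x depth; calibration experiments use
500–1,000 F2 plants and 200 replicates; enrichment power uses 10 vs 10
sequences of 20 kbp over 50 seeds. All generators are byte-deterministic
under a fixed seed, and the pipeline driver derives every stage seed from
one root seed.

## Numerical and degenerate-input choices

- Strictness of every threshold follows its verbal definition ("below",
  "more than", "at least"): 0.9 of the TE top score is inclusive, 0.8 TE
  overlap, 0.5/1.5 coverage ratios, 0.1 panel coverage, 100 accessions and
  10x inclusion are strict.
- Zero-coverage genes: both accessions zero is uncallable; one-sided zero is
  an extreme ratio, called accordingly.
- Interval conventions: 0-based half-open internally, 1-based inclusive in
  every file format; BLAST minus-strand hits keep `sstart > send` on disk
  and are normalized on use.
- Ties are always broken deterministically (documented per function), so
  identical inputs give byte-identical outputs.
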