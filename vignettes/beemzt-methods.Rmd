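---
title: "Models and methods behind beemzt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind beemzt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`beemzt` analyses single-embryo RNA-seq data across the honeybee
maternal-to-zygotic transition: haploid male and diploid female embryos
sampled at 24, 48 and 72 h after egg laying, with zygotic genome activation
proceeding in waves in females, maternal transcripts decaying in both sexes,
and thousands of intronic lncRNAs activated alongside the coding program.
This vignette explains the statistical models, the rules, the tunable
parameters and the design decisions, and what the synthetic validation does
and does not demonstrate.

## Coordinates and containers

All genomic coordinates inside the package are 0-based half-open
`[start, end)`; 1-based closed coordinates appear only at the GFF/SAM/GRanges
boundary, where the conversion is done once. Annotation is an exon-level
tibble (one row per exon, introns always derived, never stored); alignments
are one row per read with a list-column of aligned blocks; every analysis
step takes and returns a tibble.

## Counting and normalisation

A uniquely aligned read (mapper hit count 1 when an `NH` tag is present,
otherwise mapping quality at least 20) increments a gene when at least 50% of
its aligned bases fall in the gene's exonic union; among qualifying genes the
largest overlap wins and exact ties are dropped. The 50% majority rule is a
design choice — assignment conventions differ between counting tools and none
is canonical; the threshold is exposed as `min_overlap`.

RPKM is `count / (exonic_kb × library_millions)`; TPM rescales
length-normalised rates so each sample sums to 10^6. Between-sample
normalisation uses median-of-ratios size factors: each sample's factor is the
median, over genes with all-positive counts, of the ratio of its count to the
gene's geometric mean across samples. A gene is *detected* in a sample when
its RPKM strictly exceeds 0.1.

## The negative-binomial exact test

Counts are modelled as negative binomial. Per-gene dispersions are estimated
by method of moments on normalised counts, `max(0, (v − q) / q²)` with `q`
the normalised mean and `v` the pooled within-group variance, then shrunk
with weight 0.5 toward a fitted `a₀ + a₁/q` trend. The shrinkage guards the
moment estimator against its instability at 3–6 replicates; weight 0.5 splits
the difference between the per-gene estimate and the trend and is not tuned.
With fewer than two replicates per group a configurable fallback dispersion
(default 0.1) is used.

The test conditions on a gene's total count K across both groups: group sums
are treated as NB with means proportional to the summed size factors and size
`n/α`, and the two-sided p-value sums, over all splits `(a, K − a)`, the
probabilities not exceeding that of the observed split (relative tolerance
1 + 10⁻⁷, the convention used by exact tests in base R). As α → 0 this
reduces exactly to the conditional binomial test, which the test suite
verifies to 10⁻⁶. Calibration is measured empirically: the suite simulates
2,000 null genes at dispersion 0.1 with six replicates per group and requires
the rejection rate at α = 0.05 to lie inside its 95% binomial interval.

DEG calling supports the two published criteria as modes: `rawp`
(p < 0.01 and fold change strictly > 2 or < 0.5) and `fdr` (BH-adjusted
p < 0.05 and |log2FC| > 1), with `fdr` the default. Fold changes use
normalised group means with pseudocount 1, which keeps log-fold-changes
finite at zero counts at the cost of shrinking them toward 0 for
low-expressed genes.

## Activation waves

Genes are assigned from the three pairwise within-sex comparisons
(48 vs 24, 72 vs 48, 72 vs 24 h), with precedence
wave1 > wave2 > wave3 > maternal degradation:

| label | rule |
|---|---|
| wave1 | up(48v24) and down(72v48) — activated, then re-silenced |
| wave2 | up(48v24) and not down(72v48) — activation lasting to 72 h |
| wave3 | not up(48v24) and up(72v48) — late activation |
| maternal degradation | down(48v24), or neither activation and down(72v24) |
| none | otherwise |

The precedence makes the assignment a partition: every DEG-bearing gene
receives exactly one label.

## lncRNA discovery

Assembly replaces a full transcript assembler with coverage contigs
(per-base depth ≥ 3, contigs separated by ≤ 10 nt joined) chained by splice
junctions supported by ≥ 2 qualifying reads; the scientific content of the
analysis lies downstream, in the filtering and classification, not in
assembly heuristics. Candidates with sense exonic overlap with annotation are
discarded; unknown-strand candidates overlapping any annotated exon are also
discarded since their orientation cannot exclude sense overlap.

The coding potential score is a logistic regression on four features of each
candidate sequence — log10 longest-ORF length over six frames, ORF coverage,
the Fickett TESTCODE statistic (standard published lookup tables), and the
mean in-frame hexamer log-ratio of the longest ORF. Training pairs are the
annotated coding mRNAs against first-order-Markov (dinucleotide-preserving)
shuffles of the same sequences, built with a fixed seed so the model is
reproducible; the hexamer table comes from the same pairs. Candidates with
CPS ≥ 0.5 are treated as coding. Filtering retains candidates longer than
200 nt whose CPS is below the cutoff, with single-exon candidates
additionally required to reach the active single-exon threshold — 1,000 nt
for a conservative set or 500 nt to keep more single-exon lncRNAs; the
500-nt run is by construction a superset of the 1,000-nt run.

Locus classification applies the precedence sense exonic overlap >
intronic (fully within one derived intron, either strand, host gene
recorded) > antisense (opposite-strand gene overlap, only possible when the
candidate strand is known) > intergenic. A candidate spanning the introns of
two genes is assigned to the larger overlap and flagged ambiguous. A lncRNA
is female specific when detected in at least two female samples and no male
sample (symmetrically for males); requiring two samples protects against
single-replicate noise and is configurable.

## Poly(A) tails and polyadenylation sites

A tail is the maximal terminal segment of a read end whose A (or, at the 5'
end, T) fraction is at least 0.9, terminating at the read end in at least 3
consecutive target bases and starting on a target base; it is accepted when
strictly longer than 10 nt. A 5' poly(T) run is interpreted as the
reverse-complemented tail of a minus-strand transcript. Reads contribute to
PAS analysis only when their aligned portion is at least 20 nt. The
pA-finder-style length measurement on raw reads takes the maximal substring
beginning and ending with a run of ≥ 5 consecutive A whose internal non-A
fraction is at most 0.1 (the region-flank reading of "at both sides").

Internal priming: a tail whose adjacent genomic window is A-rich is
genomically templated rather than a true tail. The filter examines 10 nt
beyond the anchor (toward the tail) and discards the tail when at least 7 of
10 — as a fraction, 0.7 of the available bases when the window is truncated
at a contig edge — match the tail base. The 10/7 values follow common
practice for internal-priming screens and are configurable.

Anchors are clustered per chromosome and tail kind by single linkage with a
20 bp gap; the representative is the modal anchor with ties broken toward
the smallest coordinate, and A-supported clusters are "+"-strand PAS,
T-supported ones "−".

Direction assignment: a transcript's PAS lies just beyond its 3' end, so PAS
evidence near a candidate boundary reveals its strand. The rule table is:
A-cluster beyond the reference-right end → "+"; T-cluster beyond the left
end → "−" (the genuine minus-strand signature); A beyond the left end → "−"
and T beyond the right end → "+" (upstream PAS evidence read as
reversed-orientation transcription). Clusters count when within 200 nt of
the boundary (`max_distance`; the linkage window is not dictated by any
published value) with a 20-nt inward tolerance (`boundary_slack`) because
cleavage microheterogeneity and assembly edge effects place the modal anchor
a few nt inside the assembled boundary. Conflicting evidence resolves by
total support; exact ties stay unknown.

## Splicing

Each alignment gap is a junction; a read supports it only with ≥ 8 aligned nt
on both sides (boundary reads). A junction is *known* only on exact equality
with an annotated intron. Event classification groups junctions by the gene
containing them and applies a rule table: junctions sharing a donor with
different acceptors are A3SS on "+" (A5SS on "−"), mirrored for shared
acceptors; when the two alternative boundaries fall in different annotated
terminal exons the event is ALE/AFE instead. A junction spanning an annotated
exon flanked by the two inclusion junctions is exon skipping — called CE when
the skip junction itself is annotated (an annotation-supported cassette) and
ES when it is novel; the distinction is this package's resolution of two
names for one topology. Mutually exclusive exons require common outer
boundaries, two internal exons, and no junction bridging them. Intron
retention is scored per annotated intron as `mean(b5, b3) / (junction +
mean(b5, b3))` from boundary reads at the two exon–intron borders, with an
event called at ≥ 2 boundary reads on each side and at least one spliced
junction read. Unclassifiable overlapping junction patterns are reported as
"other", the ninth category. Novel junction strands come from GT–AG/CT–AC
motifs when a genome is supplied.

The alternative-polyadenylation usage test is a two-sided Fisher exact test
computed by hypergeometric enumeration (probability ordering, relative
tolerance 1 + 10⁻⁷), with a Haldane +0.5 correction on the odds ratio when a
cell is zero. The suite checks agreement with an independent implementation
to 10⁻¹⁰ over an exhaustive small-table grid plus random tables up to
n = 200.

## Co-expression

Correlations are Pearson, by default on log2(RPKM + 1); p-values come from
the t transform with n − 2 degrees of freedom. A lncRNA–host pair is
positive when r ≥ 0.5 with p < 0.05, negative when r ≤ −0.5 with p < 0.05,
otherwise non-correlated; because it is unstated whether the published
non-correlated class used a p criterion, `use_p = FALSE` switches to
magnitude-only classification. Relation calls are monotonically nested
across the threshold grid {0.3, 0.5, 0.7, 0.9}.

## The synthetic-data generator

`simulation_config()` encodes the emulated study design: 2 queens × 2 sexes
× 3 timepoints × 3 replicates (36 single-embryo samples), 33 coding genes
labelled wave1/2/3 (5 each), maternal degradation (6) and constitutive (12),
25 planted lncRNAs (8 intronic-sense, 6 intronic-antisense, 6 intergenic,
5 multi-exon; 550–1,500 nt so both single-exon thresholds bite), 16 introns
forced above 2,000 nt to host them, 100-nt reads at an expected 6,000
aligned reads per sample, negative-binomial counts at dispersion 0.1,
OFF→ON fold change 8 (comfortably above the ×2 calling threshold), maternal
decay 4× per timepoint in females and 2× in males (males degrade maternal
RNA more slowly), and mean tail lengths of 20/30/40 nt in males at 24/48/72 h
versus a constant 30 nt in females. These sizes are the package's validation
scale: large enough that every rule is exercised with replication, small
enough that the complete demo runs in about a minute. Coding exons carry
genuine open reading frames so the CPS can be trained on the toy annotation;
intron boundaries carry GT–AG motifs; the 10 nt beyond every true cleavage
site is set to a balanced sequence so genuine tails survive the
internal-priming filter, while planted genomic A15 runs with reads ending at
them provide true internal-priming artifacts. Tails are emitted as soft
clips (the package consumes alignments); a raw-FASTQ emitter exists for
sequence-level tail tests. All draws derive from one seed; two runs with the
same config are byte-identical.

What the generator does **not** emulate: positional coverage biases,
fragment-length and PCR-duplication effects, sequencing error beyond uniform
substitution, misalignment (reads are placed at their true loci; the unique
filter is exercised by flagged multi-mappers, not by genuinely ambiguous
placements), incomplete or wrong annotation, and expression heterogeneity
beyond the planted NB dispersion. Perfect recovery on synthetic data
therefore demonstrates that the rules are implemented exactly and the
pipeline is self-consistent — not that real single-embryo libraries would be
recovered at the same rates.

## Numerical choices and degenerate inputs

Pseudocount 1 in fold changes; dispersion floor 10⁻⁸; p-value probability
comparisons at relative tolerance 1 + 10⁻⁷; modal PAS ties toward the
smallest coordinate; empty coverage yields an empty candidate set rather
than an error; an all-zero sample has TPM defined as all-zero with a
warning; constant expression vectors yield missing correlations and the
non-correlated class; internal-priming windows truncated at contig edges are
judged on the available bases; overlapping exons within one transcript are
merged with a warning; introns shorter than twice the flank rule are skipped
in retention scoring.

## Limitations

The NB exact test approximates group sums as negative binomial with summed
size factors (exact only at equal size factors, the usual exact-test
compromise). The assembler recovers contiguous, well-covered transcripts and
is not a general-purpose isoform assembler; candidates inherit coverage
boundaries, so termini are approximate. CPS training on a toy annotation
with a few dozen genes separates ORF-bearing from shuffled sequence easily;
on a real genome the same features and training scheme apply but the
decision boundary is harder. Direction assignment reports only lncRNAs with
nearby PAS evidence; its assigned fraction depends on tail coverage and the
200-nt linkage window, which cannot be pinned to a published value.
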