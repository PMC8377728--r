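# beemzt

Single-embryo RNA-seq analysis of the honeybee maternal-to-zygotic
transition (MZT).

Honeybees are haplodiploid: unfertilised haploid eggs develop into males,
fertilised diploid eggs into females. During early embryogenesis the
maternally deposited transcriptome is degraded while the zygotic genome
activates — in diploid female embryos this zygotic genome activation (ZGA)
proceeds in three waves between 24 and 72 h after egg laying, accompanied by
the activation of thousands of long non-coding RNAs (lncRNAs), most of them
transcribed from long (> 2,000 nt) introns of protein-coding genes. `beemzt`
implements the computational side of that analysis for anyone working with
aligned single-embryo RNA-seq data (SAM/BAM), a genome (FASTA) and a gene
annotation (GFF3/GTF):

* **lncRNA discovery** — coverage-contig + junction-chain assembly of
  candidate transcripts, a coding potential score (CPS: logistic model over
  longest-ORF length, ORF coverage, the Fickett TESTCODE statistic and a
  hexamer usage log-ratio, trained on annotation-derived mRNAs vs
  dinucleotide-shuffled decoys), the 500/1,000-nt single-exon length
  thresholds, and genomic locus classification
  (exonic overlap > intronic > antisense > intergenic);
* **poly(A) analysis** — tail detection on soft-clipped read ends
  (tail length > 10 nt at ≤ 0.1 error), pA-finder-style tail length
  measurement (regions flanked by ≥ 5 consecutive A), internal-priming
  filtering against the genome, single-linkage clustering of tail anchors
  within 20 bp into polyadenylation sites (PAS), and lncRNA transcription
  direction inference from PAS evidence;
* **splicing** — junction extraction with the ≥ 8-nt boundary-read rule,
  known/novel annotation, classification into ES, CE, A5SS, A3SS, MXE, AFE,
  ALE, IR and "other" events, splicing-efficiency statistics, and a Fisher
  exact test for alternative polyadenylation usage;
* **differential expression** — read counting by majority exonic overlap,
  RPKM/TPM, median-of-ratios size factors, a negative-binomial exact test
  (two-sided, conditioning on each gene's total count, method-of-moments
  dispersions shrunk toward a mean-dispersion trend), DEG calling under both
  published criteria (p < 0.01 with fold change > 2 or < 0.5; BH-adjusted
  p < 0.05 with |log2FC| > 1), and assignment of genes to the three
  activation waves or maternal degradation;
* **co-expression** — Pearson correlation with t-transform p-values for
  lncRNA–host relation classification, partner sets and sample similarity;
* **a synthetic-data generator** — a seeded toy genome with ORF-bearing
  coding genes, long introns hosting planted sense/antisense lncRNAs, a
  2 queens × 2 sexes × 3 timepoints × 3 replicates design with planted waves,
  spliced and poly(A)/(T)-tailed reads, internal-priming artifacts, and
  complete truth tables, so every stage can be scored against known ground
  truth.

All functions take and return tibbles (genomic coordinates are 0-based
half-open internally; GFF/SAM conventions are converted at the file
boundary), so results chain naturally with the pipe, and the main result
types have `autoplot()` methods.

## Worked example

Detect a poly(A) tail on a read end, cluster tail anchors into PAS:

```r
library(beemzt)

detect_tail("GGCTAGGCATTCGGATCCGGAAAAAAAAAAAAAA")
#> # A tibble: 1 x 4
#>   tail_kind tail_length mismatches_in_tail side
#>   <chr>           <int>              <int> <chr>
#> 1 A                  14                  0 right

tails <- tibble::tibble(
  read_id = paste0("r", 1:5), sample_id = "emb1", chrom = "chr1",
  tail_kind = "A", tail_length = c(14, 15, 13, 16, 14),
  mismatches_in_tail = 0, anchor_pos = c(5012L, 5010L, 5012L, 5040L, 5011L),
  anchor_side = "right")
cluster_pas(tails, max_gap = 20)
#> # A tibble: 2 x 7
#>   chrom kind  position start   end support inferred_strand
#> 1 chr1  A         5012  5010  5013       4 +
#> 2 chr1  A         5040  5040  5041       1 +
```

The four anchors within 20 bp merge into one PAS whose representative is the
modal anchor (5012, supported by 2 of 4 reads); the distant anchor forms its
own cluster. An alternative-polyadenylation 2×2 test (proximal/distal counts
in two groups):

```r
apa_usage_test(matrix(c(12, 30, 35, 11), 2))
#> # A tibble: 1 x 2
#>   odds_ratio   p_value
#> 1      0.126 0.0000134
```

The one-command demo simulates the full study design, runs every stage and
scores it against the planted truth:

```r
demo <- make_demo(seed = 1)
demo
#> Synthetic single-embryo MZT demo
#>   samples: 36   simulated reads: 215416   lncRNA candidates: 25
#>   wave label accuracy:        1.000
#>   DEG sensitivity / FDR:      1.000 / 0.000
#>   lncRNA recovery:            1.000 (locus class 1.000)
#>   direction accuracy:         1.000 (assigned 1.000)
#>   PAS within +/-10 nt:        1.000
#>   internal-priming removal:   1.000
#>   junction count PCC:         0.999
#>   ASE recovery:               1.000
```

Here all 21 genes planted with wave or maternal-degradation labels are
re-assigned correctly from the three pairwise within-sex DEG comparisons, all
25 planted lncRNAs are re-discovered with the right locus class and strand,
and every PAS representative lands within 10 nt of a planted cleavage site.
`demo$results` holds every intermediate table (counts, DEG calls, candidate
lncRNAs at both thresholds, tails, PAS clusters, junctions, events,
correlations) for further inspection, and
`autoplot(demo$results$degs$F_48v24)` draws the volcano plot.

File-based runs use `pipeline_config()` + `run_pipeline()`, which read
FASTA/GFF3/SAM inputs, write deterministic TSV/BED/GFF3 outputs and a
manifest, and halt dependent stages on failure.

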