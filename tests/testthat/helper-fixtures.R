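# Shared fixtures. The full demo and a lighter simulated dataset are built
# once per test run and reused across files.

.fixture_cache <- new.env(parent = emptyenv())

get_demo <- function() {
  if (is.null(.fixture_cache$demo)) {
    .fixture_cache$demo <- suppressWarnings(make_demo(seed = 1))
  }
  .fixture_cache$demo
}

get_small_sim <- function() {
  if (is.null(.fixture_cache$small)) {
    cfg <- simulation_config(seed = 3, reads_per_sample = 1500,
                             error_rate = 0, tail_mismatch_rate = 0,
                             anchor_jitter_max = 0)
    .fixture_cache$small <- suppressWarnings(simulate_dataset(cfg))
  }
  .fixture_cache$small
}

# hand-built alignment tibble row
make_aln <- function(read_id, chrom, blocks, sample_id = "s1",
                     soft_clip_5 = "", soft_clip_3 = "", strand = "+",
                     seq = NULL) {
  m <- matrix(as.integer(blocks), ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("start", "end")))
  alen <- sum(m[, 2] - m[, 1])
  body <- seq %||% strrep("A", alen)
  tibble::tibble(
    read_id = read_id, sample_id = sample_id, chrom = chrom,
    strand = strand, start = min(m[, 1]), end = max(m[, 2]),
    blocks = list(m), soft_clip_5 = soft_clip_5, soft_clip_3 = soft_clip_3,
    read_sequence = paste0(soft_clip_5, body, soft_clip_3),
    mapq = 50L, n_hits = 1L, is_unique = TRUE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# three-gene exon tibble used by several rule tests
toy_annotation <- function() {
  tibble::tribble(
    ~transcript_id, ~gene_id, ~chrom, ~strand, ~start, ~end, ~exon_rank, ~biotype,
    "t1", "g1", "chr1", "+", 100L, 200L, 1L, "coding",
    "t1", "g1", "chr1", "+", 300L, 400L, 2L, "coding",
    "t1", "g1", "chr1", "+", 500L, 600L, 3L, "coding",
    "t2", "g2", "chr1", "-", 1000L, 1100L, 1L, "coding",
    "t2", "g2", "chr1", "-", 1200L, 1300L, 2L, "coding",
    "t3", "g3", "chr2", "+", 50L, 150L, 1L, "coding"
  )
}

write_mini_sam <- function(lines, path = tempfile(fileext = ".sam")) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              "@SQ\tSN:chr1\tLN:10000",
              "@SQ\tSN:chr2\tLN:10000",
              "@RG\tID:s1\tSM:s1")
  readr::write_lines(c(header, lines), path)
  path
}

sam_line <- function(qname, pos, cigar, seq, flag = 0L, rname = "chr1",
                     mapq = 50L, nh = 1L, rg = "s1") {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNH:i:%d\tRG:Z:%s",
          qname, flag, rname, pos, mapq, cigar, seq, strrep("I", nchar(seq)),
          nh, rg)
}
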