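test_that("GFF3 coordinates convert to 0-based half-open exons", {
  gff <- tempfile(fileext = ".gff3")
  readr::write_lines(c(
    "##gff-version 3",
    "chr1\tsrc\ttranscript\t1\t150\t.\t+\t.\tID=tx1;gene_id=g1;biotype=coding",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tID=tx1.e1;Parent=tx1;gene_id=g1",
    "chr1\tsrc\texon\t101\t150\t.\t+\t.\tID=tx1.e2;Parent=tx1;gene_id=g1"
  ), gff)
  ann <- read_annotation(gff)
  expect_equal(nrow(ann), 2)
  expect_equal(ann$start, c(0L, 100L))
  expect_equal(ann$end, c(100L, 150L))
  expect_equal(unique(ann$gene_id), "g1")
})

test_that("malformed exon coordinates are rejected", {
  gff <- tempfile(fileext = ".gff3")
  readr::write_lines(c(
    "##gff-version 3",
    "chr1\tsrc\texon\t50\t10\t.\t+\t.\tID=e;Parent=tx1;gene_id=g1"
  ), gff)
  expect_error(read_annotation(gff))
})

test_that("introns are the gaps between consecutive exons", {
  ann <- tibble::tibble(
    transcript_id = "t", gene_id = "g", chrom = "chr1", strand = "+",
    start = c(0L, 100L, 200L), end = c(50L, 150L, 300L),
    exon_rank = 1:3, biotype = "coding"
  )
  introns <- derive_introns(ann)
  expect_equal(introns$start, c(50L, 150L))
  expect_equal(introns$end, c(100L, 200L))

  single <- ann[1, ]
  expect_equal(nrow(derive_introns(single)), 0)

  # GFF example: exons 1..50 and 101..150 give one intron [50, 100)
  two <- tibble::tibble(
    transcript_id = "t", gene_id = "g", chrom = "chr1", strand = "+",
    start = c(0L, 100L), end = c(50L, 150L), exon_rank = 1:2,
    biotype = "coding"
  )
  expect_equal(derive_introns(two)[, c("start", "end")],
               tibble::tibble(start = 50L, end = 100L))
})

test_that("annotation writing round-trips identical intervals", {
  ann <- toy_annotation()
  path <- tempfile(fileext = ".gff3")
  write_annotation(ann, path)
  back <- read_annotation(path)
  cols <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end",
            "biotype")
  expect_equal(
    dplyr::arrange(back[cols], transcript_id, start),
    dplyr::arrange(ann[cols], transcript_id, start)
  )
  # writer is deterministic
  path2 <- tempfile(fileext = ".gff3")
  write_annotation(ann, path2)
  expect_identical(readr::read_lines(path), readr::read_lines(path2))
})

test_that("BED round-trip preserves intervals", {
  iv <- tibble::tibble(chrom = c("chr1", "chr2"), start = c(10L, 0L),
                       end = c(20L, 5L), name = c("a", "b"),
                       score = c(1, 2), strand = c("+", "-"))
  path <- tempfile(fileext = ".bed")
  write_bed(iv, path)
  back <- read_bed(path)
  expect_equal(back$start, iv$start)
  expect_equal(back$end, iv$end)
  expect_equal(back$strand, iv$strand)
})

test_that("genome partition sums to genome length (per-base oracle)", {
  sim <- get_small_sim()
  part <- genome_partition(sim$annotation, sim$seqlengths)
  expect_equal(sum(part$bases), sum(sim$seqlengths))

  # per-base oracle on one chromosome
  ch <- names(sim$seqlengths)[1]
  n <- sim$seqlengths[[ch]]
  exonic <- rep(FALSE, n); genic <- rep(FALSE, n)
  ann <- sim$annotation[sim$annotation$chrom == ch, ]
  for (i in seq_len(nrow(ann))) {
    exonic[(ann$start[i] + 1):ann$end[i]] <- TRUE
  }
  for (g in unique(ann$gene_id)) {
    rows <- ann[ann$gene_id == g, ]
    genic[(min(rows$start) + 1):max(rows$end)] <- TRUE
  }
  ann_other <- sim$annotation[sim$annotation$chrom != ch, ]
  part_oracle <- c(exonic = sum(exonic), intronic = sum(genic & !exonic),
                   intergenic = n - sum(genic))
  part_all <- genome_partition(sim$annotation, sim$seqlengths)
  part_ch <- genome_partition(ann, setNames(n, ch))
  expect_equal(setNames(part_ch$bases, part_ch$class), part_oracle)
})

test_that("long-intron counting matches a direct scan", {
  sim <- get_small_sim()
  res <- count_long_introns(sim$annotation, min_length = 2000)
  introns <- derive_introns(sim$annotation) |>
    dplyr::distinct(chrom, start, end, strand)
  expect_equal(res$n_total, nrow(introns))
  expect_equal(res$n_long, sum(introns$end - introns$start > 2000))
  expect_gt(res$n_long, 0)  # the toy genome plants > 2,000 nt introns
  expect_equal(res$fraction, res$n_long / res$n_total)
})
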