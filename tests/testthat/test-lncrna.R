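# Candidate assembly, coding-potential filter and locus classification.

make_depth_reads <- function(chrom, start, end, depth, read_len = 100,
                             sample_id = "s1") {
  # tile reads so that every base of [start, end) has exactly `depth` coverage
  rows <- list()
  k <- 0
  for (d in seq_len(depth)) {
    pos <- seq(start, end - 1, by = read_len)
    for (p in pos) {
      k <- k + 1
      rows[[k]] <- make_aln(sprintf("cov%04d", k), chrom,
                            c(p, min(p + read_len, end)),
                            sample_id = sample_id)
    }
  }
  dplyr::bind_rows(rows)
}

test_that("coverage contigs become single-exon candidates above min_depth", {
  ann <- toy_annotation()
  # g1 intron [200, 300) is too small; use a region far from any exon
  aln5 <- make_depth_reads("chr1", 3000, 4200, depth = 5)
  cands <- assemble_candidates(aln5, ann)
  expect_equal(nrow(cands), 1)
  expect_equal(cands$n_exons, 1)
  expect_gte(cands$length, 1150)
  expect_lte(cands$length, 1200)

  aln2 <- make_depth_reads("chr1", 3000, 4200, depth = 2)
  expect_equal(nrow(assemble_candidates(aln2, ann)), 0)
})

test_that("junction-linked contigs become multi-exon candidates", {
  ann <- toy_annotation()
  body <- dplyr::bind_rows(
    make_depth_reads("chr1", 3000, 3500, depth = 5),
    make_depth_reads("chr1", 4000, 4500, depth = 5)
  )
  jreads <- dplyr::bind_rows(lapply(1:3, function(i) {
    make_aln(paste0("j", i), "chr1", c(3450, 3500, 4000, 4050))
  }))
  cands <- assemble_candidates(dplyr::bind_rows(body, jreads), ann)
  expect_equal(nrow(cands), 1)
  expect_equal(cands$n_exons, 2)
  ex <- cands$exons[[1]]
  expect_equal(unname(ex[1, "end"]), 3500)
  expect_equal(unname(ex[2, "start"]), 4000)

  # below min_junction the contigs stay separate
  cands2 <- assemble_candidates(dplyr::bind_rows(body, jreads[1, ]), ann)
  expect_equal(nrow(cands2), 2)
})

test_that("candidates overlapping annotated exons are discarded", {
  ann <- toy_annotation()
  over <- make_depth_reads("chr1", 150, 1350, depth = 5)
  cands <- assemble_candidates(over, ann)
  expect_equal(nrow(cands), 0)
  demo <- get_demo()
  kept <- demo$results$lncrnas_500
  ex_gr <- GenomicRanges::GRanges(
    demo$sim$annotation$chrom,
    IRanges::IRanges(demo$sim$annotation$start + 1,
                     demo$sim$annotation$end))
  for (i in seq_len(nrow(kept))) {
    cand_gr <- GenomicRanges::GRanges(
      kept$chrom[i], IRanges::IRanges(kept$start[i] + 1, kept$end[i]))
    hits <- GenomicRanges::findOverlaps(cand_gr, ex_gr)
    same <- as.character(GenomicRanges::strand(ex_gr))[
      S4Vectors::subjectHits(hits)] == kept$strand[i]
    expect_false(any(same), label = "no sense exonic overlap in retained set")
  }
})

test_that("the CPS separates coding mRNAs from shuffled decoys", {
  demo <- get_demo()
  sim <- demo$sim
  model <- demo$results$cps_model
  coding <- sim$annotation[sim$annotation$biotype == "coding", ]
  seqs <- beemzt:::transcript_sequences(sim$genome, coding)
  scores <- coding_potential_score(seqs, model)
  expect_gt(mean(scores >= 0.5), 0.9)

  set.seed(9)
  decoys <- vapply(seqs[1:10], beemzt:::dinucleotide_shuffle, character(1))
  dscores <- coding_potential_score(unname(decoys), model)
  expect_gt(mean(dscores < 0.5), 0.9)

  expect_error(coding_potential_score(strrep("X", 300), model), "non-ACGTN")
  td <- tidy(model)
  expect_true(all(c("(Intercept)", "fickett", "hexamer") %in% td$term))
  expect_gte(glance(model)$accuracy, 0.9)
})

test_that("length filtering implements the two single-exon thresholds", {
  cands <- tibble::tibble(
    candidate_id = c("a", "b", "c", "d"),
    chrom = "chr1", strand = "unknown",
    start = 0L, end = 1L,                        # placeholder span
    n_exons = c(1L, 2L, 1L, 1L),
    length = c(700L, 350L, 1200L, 700L),
    exons = list(cbind(start = 0L, end = 1L)),
    cps = c(0.1, 0.1, 0.1, 0.9)
  )
  at1000 <- filter_lncrnas(cands, 1000)
  at500 <- filter_lncrnas(cands, 500)
  expect_setequal(at1000$candidate_id, c("b", "c"))   # multi-exon exempt
  expect_setequal(at500$candidate_id, c("a", "b", "c"))
  expect_true(all(at1000$candidate_id %in% at500$candidate_id))
  expect_false("d" %in% at500$candidate_id)           # high CPS always out
  expect_warning(filter_lncrnas(cands, 750), "differs from")

  short <- cands[2, ]; short$length <- 180L; short$n_exons <- 1L
  expect_equal(nrow(filter_lncrnas(short, 500)), 0)   # 200-nt rule
})

test_that("locus classification follows the stated precedence", {
  ann <- toy_annotation()
  cand <- function(id, chrom, start, end, strand = "unknown") {
    tibble::tibble(candidate_id = id, chrom = chrom, strand = strand,
                   start = as.integer(start), end = as.integer(end),
                   n_exons = 1L, length = end - start,
                   exons = list(cbind(start = as.integer(start),
                                      end = as.integer(end))))
  }
  res <- classify_locus(dplyr::bind_rows(
    cand("intronic", "chr1", 220, 280),            # inside g1 intron 1
    cand("anti", "chr1", 120, 180, strand = "-"),  # over g1 exon, minus
    cand("nothing", "chr2", 5000, 5600),
    cand("anti_intron", "chr1", 1120, 1180, strand = "+")  # g2 intron, + vs -
  ), ann)
  got <- setNames(res$locus_class, res$candidate_id)
  expect_equal(unname(got["intronic"]), "intronic")
  # minus-strand candidate over a plus-strand exon: not a sense overlap
  expect_equal(unname(got["anti"]), "antisense")
  expect_equal(unname(got["anti_intron"]), "intronic") # intronic either strand
  expect_equal(unname(got["nothing"]), "intergenic")
  host <- setNames(res$host_gene, res$candidate_id)
  expect_equal(unname(host["intronic"]), "g1")
  expect_equal(unname(host["anti_intron"]), "g2")

  # antisense: minus-strand candidate over a plus-strand gene, not within
  # an intron and not touching an exon
  ann2 <- ann[ann$transcript_id == "t1", ]
  res2 <- classify_locus(cand("anti2", "chr1", 250, 450, strand = "-"), ann2)
  expect_equal(res2$locus_class, "antisense")
  # unknown strand cannot be antisense; overlapping an exon without strand
  # information is conservatively called exonic overlap
  res3 <- classify_locus(cand("unk", "chr1", 250, 450), ann2)
  expect_equal(res3$locus_class, "exonic_overlap")
  res4 <- classify_locus(cand("unk2", "chr1", 420, 480), ann2)
  expect_equal(res4$locus_class, "intronic")
})

test_that("sex specificity needs enough supporting samples", {
  samples <- tibble::tibble(
    sample_id = c("f1", "f2", "f3", "m1", "m2", "m3"),
    sex = c("F", "F", "F", "M", "M", "M")
  )
  det <- tidyr::expand_grid(gene_id = c("fem", "weak", "both", "silent"),
                            sample_id = samples$sample_id) |>
    dplyr::mutate(detected = dplyr::case_when(
      gene_id == "fem" & grepl("f", sample_id) ~ TRUE,
      gene_id == "weak" & sample_id == "f1" ~ TRUE,
      gene_id == "both" ~ TRUE,
      .default = FALSE
    ))
  ss <- sex_specificity(det, samples, min_samples = 2)
  got <- setNames(ss$sex_specificity, ss$gene_id)
  expect_equal(unname(got["fem"]), "female_specific")
  expect_equal(unname(got["weak"]), "shared")   # one sample is not enough
  expect_equal(unname(got["both"]), "shared")
  s <- attr(ss, "summary")
  expect_equal(s$n_detected, 3)                 # silent gene excluded
  expect_equal(s$female_specific_fraction, 1 / 3)
  expect_error(sex_specificity(det, dplyr::select(samples, sample_id)),
               "sex metadata")
})
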