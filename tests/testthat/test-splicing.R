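test_that("junction extraction enforces the 8-nt flank rule", {
  aln <- dplyr::bind_rows(
    make_aln("good1", "chr1", c(100, 150, 200, 250)),
    make_aln("good2", "chr1", c(100, 150, 200, 250)),
    make_aln("short_flank", "chr1", c(143, 150, 200, 250))  # 7 nt left flank
  )
  jx <- extract_junctions(aln)
  expect_equal(nrow(jx), 1)
  expect_equal(jx$donor, 150L)
  expect_equal(jx$acceptor, 200L)
  expect_equal(jx$count, 2L)

  # exactly 8 nt qualifies
  jx8 <- extract_junctions(make_aln("f8", "chr1", c(142, 150, 200, 250)))
  expect_equal(jx8$count, 1L)
  expect_equal(nrow(extract_junctions(make_aln("nogap", "chr1", c(0, 80)))), 0)
})

test_that("junctions are known only on exact intron match", {
  ann <- toy_annotation()   # g1 introns [200,300) and [400,500)
  jx <- tibble::tibble(chrom = "chr1",
                       donor = c(200L, 200L, 150L),
                       acceptor = c(300L, 301L, 200L),
                       sample_id = "s1", count = 1L)
  st <- annotate_junctions(jx, ann)$status
  expect_equal(st, c("known", "novel", "novel"))
})

test_that("event classification follows the rule table", {
  ann <- toy_annotation()   # g1: exons [100,200),[300,400),[500,600) on +
  J <- function(donor, acceptor, count = 10L) {
    tibble::tibble(chrom = "chr1", donor = as.integer(donor),
                   acceptor = as.integer(acceptor), sample_id = "s1",
                   count = count)
  }
  # shared donor, different acceptors inside the same exon -> A3SS on +
  ev <- classify_ase(dplyr::bind_rows(J(200, 300), J(200, 340)), ann)
  expect_equal(ev$type, "A3SS")
  # shared acceptor, different donors -> A5SS on +
  ev <- classify_ase(dplyr::bind_rows(J(200, 300), J(160, 300)), ann)
  expect_equal(ev$type, "A5SS")
  # skip junction over annotated exon 2 with both inclusion junctions:
  # novel skip -> ES
  ev <- classify_ase(dplyr::bind_rows(J(200, 500), J(200, 300), J(400, 500)),
                     ann)
  expect_equal(ev$type, "ES")
  expect_equal(ev$inclusion_count, 10L)
  expect_equal(ev$exclusion_count, 10L)
  # single junction, no partner -> no event
  expect_equal(nrow(classify_ase(J(200, 300), ann)), 0)
})

test_that("A5SS and A3SS mirror between strands", {
  plus <- toy_annotation()[1:3, ]
  minus <- plus; minus$strand <- "-"
  shared_donor <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", donor = 200L, acceptor = c(300L, 340L),
                   sample_id = "s1", count = 5L))
  expect_equal(classify_ase(shared_donor, plus)$type, "A3SS")
  expect_equal(classify_ase(shared_donor, minus)$type, "A5SS")
  shared_acceptor <- tibble::tibble(chrom = "chr1", donor = c(200L, 160L),
                                    acceptor = 300L, sample_id = "s1",
                                    count = 5L)
  expect_equal(classify_ase(shared_acceptor, plus)$type, "A5SS")
  expect_equal(classify_ase(shared_acceptor, minus)$type, "A3SS")
})

test_that("intron retention scoring matches the formula", {
  ann <- toy_annotation()[1:2, ]   # g1 intron [200, 300)
  reads <- list()
  for (i in 1:10) {
    reads[[length(reads) + 1]] <- make_aln(paste0("b5_", i), "chr1", c(185, 215))
    reads[[length(reads) + 1]] <- make_aln(paste0("b3_", i), "chr1", c(285, 315))
    reads[[length(reads) + 1]] <- make_aln(paste0("j_", i), "chr1",
                                           c(150, 200, 300, 350))
  }
  ir <- detect_intron_retention(dplyr::bind_rows(reads), ann)
  expect_equal(ir$boundary_5, 10L)
  expect_equal(ir$boundary_3, 10L)
  expect_equal(ir$junction_count, 10L)
  expect_equal(ir$retention_ratio, 0.5)
  expect_true(ir$event)

  # no spanning reads -> no IR
  ir0 <- detect_intron_retention(make_aln("j", "chr1", c(150, 200, 300, 350)),
                                 ann)
  expect_false(ir0$event)
  # spanning reads without any junction -> constitutive coverage, no event
  span_only <- dplyr::bind_rows(lapply(1:5, function(i) {
    make_aln(paste0("s", i), "chr1", c(185, 215))
  }))
  ir1 <- detect_intron_retention(span_only, ann)
  expect_false(ir1$event)
})

test_that("splicing efficiency and ASE detection efficiency", {
  spliced <- dplyr::bind_rows(lapply(1:8, function(i) {
    make_aln(paste0("sp", i), "chr1", c(100, 150, 200, 250))
  }))
  plain <- dplyr::bind_rows(lapply(1:92, function(i) {
    make_aln(paste0("pl", i), "chr1", c(500, 580))
  }))
  eff <- splicing_efficiency(dplyr::bind_rows(spliced, plain))
  expect_equal(eff$efficiency, 0.08)
  expect_equal(splicing_efficiency(plain)$efficiency, 0)
  expect_equal(splicing_efficiency(spliced)$efficiency, 1)
  expect_error(splicing_efficiency(plain[0, ]), "no reads")

  jx <- tibble::tibble(chrom = "chr1", donor = 1:250, acceptor = 1:250 + 50,
                       sample_id = "s1", count = 1L)
  ev <- tibble::tibble(gene_id = paste0("g", 1:5))
  expect_equal(ase_detection_efficiency(ev, jx), 2)
  expect_equal(ase_detection_efficiency(ev[0, ], jx), 0)
  expect_equal(ase_detection_efficiency(ev, jx[1:5, ]), 100)
  expect_true(is.na(ase_detection_efficiency(ev, jx[0, ])))
})

test_that("the APA Fisher test matches its examples", {
  even <- matrix(c(50, 50, 50, 50), 2)
  expect_equal(apa_usage_test(even)$p_value, 1)
  diagonal <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(apa_usage_test(diagonal)$p_value, 1)
  skewed <- matrix(c(90, 50, 10, 50), 2)  # rows proximal/distal
  res <- apa_usage_test(skewed)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$p_value, fisher.test(skewed)$p.value, tolerance = 1e-12)
  expect_gt(res$odds_ratio, 1)
  # Haldane correction on zero cells
  expect_true(is.finite(apa_usage_test(diagonal)$odds_ratio))
  expect_error(apa_usage_test(matrix(0, 2, 2)), "all-zero")
})
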