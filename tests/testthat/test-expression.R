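test_that("reads are assigned to genes by majority exonic overlap", {
  ann <- toy_annotation()
  # g1 exon [100,200); g2 exons [1000,1100) and [1200,1300)
  aln <- dplyr::bind_rows(
    make_aln("inside", "chr1", c(120, 170)),             # fully inside g1
    make_aln("intergenic", "chr1", c(700, 750)),         # no gene
    make_aln("mostly_g1", "chr1", c(160, 210)),          # 40 nt in g1, 10 out
    make_aln("spliced_g2", "chr1", c(1080, 1100, 1200, 1230))
  )
  counts <- count_reads(aln, ann)
  cm <- counts_matrix(counts)
  expect_equal(cm["g1", "s1"], 2)   # inside + mostly_g1 (80% overlap)
  expect_equal(cm["g2", "s1"], 1)
  expect_equal(cm["g3", "s1"], 0)
  expect_equal(attr(counts, "library_sizes")$library_size, 4)
  expect_error(count_reads(aln, ann[0, ]), "empty annotation")
})

test_that("a read below the majority-overlap rule is not counted", {
  ann <- toy_annotation()
  # 20 of 60 aligned bases in g1 -> below the 50% rule
  aln <- make_aln("edge", "chr1", c(180, 240))
  cm <- counts_matrix(count_reads(aln, ann))
  expect_equal(cm["g1", "s1"], 0)
})

test_that("RPKM follows its closed form", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(10, 500, 1e6), 20)
  expect_equal(rpkm(10, 1000, 2e6), 5)   # doubling library halves RPKM
  expect_error(rpkm(1, 0, 1e6))
  expect_error(rpkm(1, 100, 0))
})

test_that("TPM columns sum to one million", {
  expect_equal(tpm(c(5, 0), c(100, 200)), c(1e6, 0))
  expect_equal(tpm(c(7, 7), c(300, 300)), c(5e5, 5e5))
  set.seed(42)
  for (i in 1:10) {
    counts <- rpois(20, 50)
    lens <- sample(200:5000, 20)
    if (sum(counts) == 0) next
    expect_equal(sum(tpm(counts, lens)), 1e6)
  }
  expect_warning(z <- tpm(c(0, 0), c(100, 100)), "all-zero")
  expect_equal(z, c(0, 0))
})

test_that("median-of-ratios size factors match the closed form", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(deseq_size_factors(m)), c(1, 1))

  m2 <- m; m2[, "b"] <- 2 * m2[, "a"]
  sf <- deseq_size_factors(m2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  # genes with any zero are excluded from the pseudo-reference
  m3 <- rbind(m2, g4 = c(0, 1000))
  expect_equal(deseq_size_factors(m3), sf)

  m4 <- matrix(c(0, 1, 1, 0), ncol = 2,
               dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(deseq_size_factors(m4), "all-positive")
})

test_that("detection uses a strict RPKM threshold", {
  expr <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g1", "g2", "g3"),
    sample_id = rep(c("s1", "s2"), each = 3),
    rpkm = c(0.1, 0.11, 0, 5, 0.1, 0.1)
  )
  det <- detect_expressed(expr, threshold = 0.1)
  expect_equal(det$detected, c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))
  rates <- attr(det, "detection_rates")
  per_sample <- rates$rate[rates$sample_id != "union"]
  union_rate <- rates$rate[rates$sample_id == "union"]
  expect_true(all(union_rate >= per_sample))
  expect_equal(union_rate, 2 / 3)
})

test_that("2^-ddCt relative quantification", {
  expect_equal(ddct(20, 20, 20, 20), 1)
  expect_equal(ddct(19, 20, 20, 20), 2)   # ddCt = -1
  expect_equal(ddct(23, 20, 20, 20), 0.125)
  expect_error(ddct(NA, 20, 20, 20))
})

test_that("size-factor normalisation equalises scaled libraries", {
  sim <- get_small_sim()
  demo_counts <- sim$truth_counts |>
    dplyr::rename(gene_id = transcript_id)
  m <- counts_matrix(demo_counts)
  keep <- rowSums(m > 0) == ncol(m)
  m <- m[keep, ]
  m2 <- cbind(m, doubled = 2 * m[, 1])
  sf <- deseq_size_factors(m2)
  expect_equal(unname(sf["doubled"] / sf[1]), 2, tolerance = 1e-9)
})
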