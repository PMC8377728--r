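test_that("toy genome generation is deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 5, reads_per_sample = 300)
  a <- build_toy_genome(cfg)
  b <- build_toy_genome(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth_lncrnas, b$truth_lncrnas)

  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_dataset(cfg, dir = d1)
  s2 <- simulate_dataset(cfg, dir = d2)
  expect_identical(readr::read_lines(file.path(d1, "genome.fa")),
                   readr::read_lines(file.path(d2, "genome.fa")))
  expect_identical(readr::read_lines(file.path(d1, "annotation.gff3")),
                   readr::read_lines(file.path(d2, "annotation.gff3")))
  expect_identical(readr::read_lines(file.path(d1, "reads.sam")),
                   readr::read_lines(file.path(d2, "reads.sam")))
})

test_that("planted intronic lncRNAs lie fully inside one derived intron", {
  sim <- get_small_sim()
  introns <- derive_introns(sim$annotation)
  lnc <- sim$truth_lncrnas
  intr <- lnc[lnc$class %in% c("intronic_sense", "intronic_antisense"), ]
  expect_equal(nrow(intr),
               sum(simulation_config()$lncrna_counts[c("intronic_sense",
                                                       "intronic_antisense")]))
  for (i in seq_len(nrow(intr))) {
    host_introns <- introns[introns$gene_id == intr$host_gene[i] &
                              introns$chrom == intr$chrom[i], ]
    inside <- any(host_introns$start <= intr$start[i] &
                    intr$end[i] <= host_introns$end)
    expect_true(inside, label = paste("lncRNA", intr$transcript_id[i],
                                      "inside a host intron"))
  }
  # antisense plants are on the strand opposite their host
  anti <- lnc[lnc$class == "intronic_antisense", ]
  host_strand <- sim$annotation$strand[match(anti$host_gene,
                                             sim$annotation$gene_id)]
  expect_true(all(anti$strand != host_strand))
})

test_that("expression patterns follow the planted labels", {
  sim <- get_small_sim()
  ab <- sim$abundance |>
    dplyr::left_join(sim$samples, by = "sample_id") |>
    dplyr::left_join(
      dplyr::select(sim$transcripts, transcript_id, label),
      by = "transcript_id")

  mean_ab <- function(lbl, sx, h) {
    mean(ab$abundance[ab$label == lbl & ab$sex == sx & ab$hours == h])
  }

  # wave1 female: activated at 48 h then re-silenced at 72 h
  expect_gt(mean_ab("wave1", "F", 48), 2 * mean_ab("wave1", "F", 24))
  expect_lt(mean_ab("wave1", "F", 72), mean_ab("wave1", "F", 48) / 2)
  # wave2 stays high at 72 h; wave3 activates only late
  expect_gt(mean_ab("wave2", "F", 72), 2 * mean_ab("wave2", "F", 24))
  expect_gt(mean_ab("wave3", "F", 72), 2 * mean_ab("wave3", "F", 48))
  expect_lt(mean_ab("wave3", "F", 48) / mean_ab("wave3", "F", 24), 2)

  # constant genes: identical expected abundance across samples
  const <- ab[ab$label == "constant", ]
  spread <- tapply(const$abundance, const$transcript_id,
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))

  # maternal decline: male decay slower than female (planted rates 4 vs 2)
  md_f <- mean_ab("maternal_degradation", "F", 24) /
    mean_ab("maternal_degradation", "F", 72)
  md_m <- mean_ab("maternal_degradation", "M", 24) /
    mean_ab("maternal_degradation", "M", 72)
  expect_gt(md_f, md_m)
  expect_equal(md_f, 16, tolerance = 1e-9)
  expect_equal(md_m, 4, tolerance = 1e-9)

  # female-specific lncRNAs have zero male abundance, hence zero male reads
  fs <- sim$transcripts$transcript_id[
    sim$transcripts$label == "female_specific_lncRNA"]
  male_samples <- sim$samples$sample_id[sim$samples$sex == "M"]
  male_counts <- sim$truth_counts |>
    dplyr::filter(transcript_id %in% fs, sample_id %in% male_samples)
  expect_true(all(male_counts$count == 0))
})

test_that("planted tails appear as soft clips on the correct side", {
  sim <- get_small_sim()  # error-free config
  aln <- read_alignments(sim$sam_path)
  tails <- sim$truth_tails |> dplyr::filter(!artifact, is_unique)
  idx <- match(tails$read_id, aln$read_id)
  expect_false(anyNA(idx))
  plus <- tails$kind == "A"
  expect_true(all(aln$soft_clip_3[idx[plus]] ==
                    strrep("A", tails$tail_length[plus])))
  expect_true(all(aln$soft_clip_5[idx[!plus]] ==
                    strrep("T", tails$tail_length[!plus])))
  # anchor is the aligned end adjacent to the clip
  expect_equal(aln$end[idx[plus]], tails$anchor_pos[plus])
  expect_equal(aln$start[idx[!plus]], tails$anchor_pos[!plus])
})

test_that("observed junction usage tracks planted usage", {
  sim <- get_small_sim()
  aln <- read_alignments(sim$sam_path)
  obs <- extract_junctions(aln) |>
    dplyr::group_by(chrom, donor, acceptor) |>
    dplyr::summarise(observed = sum(count), .groups = "drop")
  truth <- sim$truth_junctions |>
    dplyr::group_by(chrom, donor, acceptor) |>
    dplyr::summarise(planted = sum(n), .groups = "drop")
  j <- dplyr::inner_join(obs, truth, by = c("chrom", "donor", "acceptor"))
  expect_gt(nrow(j), 20)
  expect_gt(cor(j$observed, j$planted), 0.9)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(intron_length_range = c(100, 800)),
               "too small to host")
  expect_error(simulation_config(wave_counts = c(wave1 = 1, wave2 = 1,
                                                 wave3 = 1,
                                                 maternal_degradation = 1,
                                                 constant = 1)))
  toy <- build_toy_genome(simulation_config(seed = 4, reads_per_sample = 100))
  ab0 <- simulate_expression(toy)
  ab0$abundance <- 0
  expect_error(simulate_reads(toy, ab0), "zero total abundance")
})
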