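test_that("tail acceptance implements the >10 nt / 0.1 error rule", {
  body <- strrep("C", 30)
  # 12 terminal As: accepted, zero mismatches
  t12 <- detect_tail(paste0(body, strrep("A", 12)))
  expect_equal(t12$tail_kind, "A")
  expect_equal(t12$tail_length, 12)
  expect_equal(t12$mismatches_in_tail, 0)
  # 11 As: the smallest accepted length (strictly more than 10)
  expect_equal(detect_tail(paste0(body, strrep("A", 11)))$tail_length, 11)
  # exactly 10 As: rejected
  expect_null(detect_tail(paste0(body, strrep("A", 10))))
  # 5' poly(T) run detected on the left end
  t5 <- detect_tail(paste0(strrep("T", 15), body))
  expect_equal(t5$tail_kind, "T")
  expect_equal(t5$side, "left")
  # 20-nt terminal segment with 3 non-A (error 0.15) is rejected
  seg <- paste0(body, "AAAAA", "C", "AAAAA", "C", "AAAA", "C", "AAA")
  expect_null(detect_tail(seg))
  # one mismatch in 20 (error 0.05) is tolerated
  seg_ok <- paste0(body, strrep("A", 10), "C", strrep("A", 9))
  t_ok <- detect_tail(seg_ok)
  expect_equal(t_ok$tail_length, 20)
  expect_equal(t_ok$mismatches_in_tail, 1)
})

test_that("pA-finder style region measurement", {
  expect_equal(measure_tail_length(strrep("A", 15)), 15)
  expect_equal(measure_tail_length("AAAAACAAAAA"), 11)
  expect_true(is.na(measure_tail_length("AAAA")))
  expect_true(is.na(measure_tail_length(strrep("C", 30))))
  # region must start and end with a >= 5 A run
  expect_equal(measure_tail_length(paste0("CCC", strrep("A", 6), "G",
                                          strrep("A", 7), "CCC")), 14)
  # internal error rate above 0.1 blocks the widest region
  s <- paste0(strrep("A", 5), "CCCC", strrep("A", 5))
  expect_equal(measure_tail_length(s), 5)
})

test_that("internal priming is judged on the genomic window", {
  genome <- c(chr1 = paste0(strrep("G", 100), strrep("A", 10),
                            "ACGTACGTAC", strrep("G", 30), strrep("A", 4)))
  tails <- tibble::tibble(
    read_id = c("r1", "r2", "r3"), sample_id = "s1", chrom = "chr1",
    tail_kind = "A", tail_length = 15, mismatches_in_tail = 0,
    anchor_pos = c(100L, 110L, 150L), anchor_side = "right"
  )
  res <- internal_priming_filter(tails, genome)
  expect_equal(res$keep, c(FALSE, TRUE, FALSE))
  # r1: window = AAAAAAAAAA -> discard; r2: ACGTACGTAC (2 A) -> keep
  # r3: truncated window AAAA -> 4/4 A -> discard

  # T tails look left on the reference
  genome2 <- c(chr1 = paste0(strrep("T", 10), strrep("G", 100)))
  t_tails <- tibble::tibble(
    read_id = c("t1", "t2"), sample_id = "s1", chrom = "chr1",
    tail_kind = "T", tail_length = 15, mismatches_in_tail = 0,
    anchor_pos = c(10L, 60L), anchor_side = "left"
  )
  res2 <- internal_priming_filter(t_tails, genome2)
  expect_equal(res2$keep, c(FALSE, TRUE))
})

test_that("PAS clustering is single-linkage within 20 bp", {
  mk_tails <- function(pos, kind = "A") {
    tibble::tibble(read_id = paste0("r", seq_along(pos)), sample_id = "s1",
                   chrom = "chr1", tail_kind = kind,
                   tail_length = 15, mismatches_in_tail = 0,
                   anchor_pos = as.integer(pos), anchor_side = "right")
  }
  cl <- cluster_pas(mk_tails(c(100, 105, 130)))
  expect_equal(nrow(cl), 2)          # gap 25 > 20 splits
  expect_equal(cl$support, c(2, 1))

  chain <- cluster_pas(mk_tails(c(100, 115, 130)))
  expect_equal(nrow(chain), 1)       # chained 15-bp gaps merge
  expect_equal(chain$support, 3)

  single <- cluster_pas(mk_tails(42))
  expect_equal(single$support, 1)
  expect_equal(single$position, 42)

  # representative is the modal anchor, ties to the smallest coordinate
  modal <- cluster_pas(mk_tails(c(100, 100, 105)))
  expect_equal(modal$position, 100)
  tie <- cluster_pas(mk_tails(c(100, 105)))
  expect_equal(tie$position, 100)

  # order independence
  set.seed(8)
  pos <- sample(1:500, 40, replace = TRUE)
  a <- cluster_pas(mk_tails(pos))
  b <- cluster_pas(mk_tails(sample(pos)))
  expect_equal(a, b)

  # A and T evidence cluster separately, with inferred strands
  mixed <- cluster_pas(dplyr::bind_rows(mk_tails(c(100, 105)),
                                        mk_tails(c(102), kind = "T")))
  expect_equal(nrow(mixed), 2)
  expect_setequal(mixed$inferred_strand, c("+", "-"))
})

test_that("direction assignment follows the PAS evidence table", {
  cand <- tibble::tibble(candidate_id = "c1", chrom = "chr1",
                         start = 1000L, end = 2000L)
  mk_cl <- function(pos, kind, support = 3) {
    tibble::tibble(chrom = "chr1", kind = kind, position = as.integer(pos),
                   start = as.integer(pos), end = as.integer(pos + 1),
                   support = support, inferred_strand = ifelse(kind == "A", "+", "-"))
  }
  expect_equal(assign_direction(cand, mk_cl(2010, "A"))$strand_call, "+")
  expect_equal(assign_direction(cand, mk_cl(990, "T"))$strand_call, "-")
  expect_equal(assign_direction(cand, mk_cl(990, "A"))$strand_call, "-")
  expect_equal(assign_direction(cand, mk_cl(2010, "T"))$strand_call, "+")
  # out of range -> unknown
  expect_equal(assign_direction(cand, mk_cl(2500, "A"))$strand_call, "unknown")
  # conflict resolves by support; exact tie stays unknown
  both <- dplyr::bind_rows(mk_cl(2010, "A", 5), mk_cl(990, "T", 2))
  expect_equal(assign_direction(cand, both)$strand_call, "+")
  tied <- dplyr::bind_rows(mk_cl(2010, "A", 3), mk_cl(990, "T", 3))
  expect_equal(assign_direction(cand, tied)$strand_call, "unknown")
})

test_that("tail-length group means recover the planted trend", {
  samples <- tidyr::expand_grid(sex = c("F", "M"), hours = c(24L, 48L, 72L),
                                replicate = 1:3) |>
    dplyr::mutate(sample_id = sprintf("%s%d_%d", sex, hours, replicate))
  set.seed(13)
  tails <- purrr::pmap_dfr(samples, function(sex, hours, replicate, sample_id) {
    mu <- if (sex == "M") c(`24` = 20, `48` = 30, `72` = 40)[[as.character(hours)]]
    else 30
    tibble::tibble(sample_id = sample_id,
                   tail_length = rnorm(60, mu, 4))
  })
  res <- mean_tail_length_by_group(tails, samples)
  male <- res$anova[res$anova$sex == "M", ]
  female <- res$anova[res$anova$sex == "F", ]
  expect_lt(male$p_value, 0.01)
  expect_gt(female$p_value, 0.05)
  m_means <- res$per_sample |>
    dplyr::filter(sex == "M") |>
    dplyr::group_by(hours) |>
    dplyr::summarise(m = mean(mean_length))
  expect_true(all(diff(m_means$m[order(m_means$hours)]) > 0))
  # single sample: mean equals the sample mean
  one <- mean_tail_length_by_group(tails[tails$sample_id == "F24_1", ],
                                   samples[samples$sample_id == "F24_1", ])
  expect_equal(one$per_sample$mean_length,
               mean(tails$tail_length[tails$sample_id == "F24_1"]))
})

test_that("accepted tails satisfy their invariants post hoc", {
  demo <- get_demo()
  tails <- demo$results$tails
  expect_true(all(tails$tail_length > 10))
  expect_true(all(tails$mismatches_in_tail / tails$tail_length <= 0.1))
  lens <- demo$sim$seqlengths[tails$chrom]
  expect_true(all(tails$anchor_pos >= 0 & tails$anchor_pos <= lens))
})
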