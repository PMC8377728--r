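test_that("PCC values and p-values match the t-transform oracle", {
  expect_equal(pcc(1:10, 1:10)$r, 1)
  expect_equal(pcc(1:10, 10:1)$r, -1)
  const <- pcc(rep(2, 5), 1:5)
  expect_true(is.na(const$r))
  expect_error(pcc(1:4, 1:5), "length mismatch")
  expect_error(pcc(1:2, 1:2), "at least 3")

  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8) + 0.5 * x
    got <- pcc(x, y)
    oracle <- cor.test(x, y)
    expect_equal(got$r, unname(oracle$estimate), tolerance = 1e-12)
    expect_equal(got$p_value, oracle$p.value, tolerance = 1e-10)
  }
})

test_that("host-relation classes follow the r/p rule", {
  x <- 1:10
  pos <- classify_host_relation(x, x + rnorm(10, 0, 0.1))
  expect_equal(pos$relation, "positive")
  neg <- classify_host_relation(x, -x + rnorm(10, 0, 0.1))
  expect_equal(neg$relation, "negative")
  expect_equal(classify_host_relation(rep(1, 5), 1:5)$relation,
               "non_correlated")
  # strong r but n = 4: p above 0.05 blocks the call
  x4 <- c(1, 2, 3, 4); y4 <- c(1.2, 1.8, 3.4, 3.6)
  stopifnot(cor(x4, y4) > 0.9, cor.test(x4, y4)$p.value > 0.01)
  p4 <- cor.test(x4, y4)$p.value
  got <- classify_host_relation(x4, y4, p_threshold = min(0.05, p4 * 0.9))
  expect_equal(got$relation, "non_correlated")
  # with the p criterion off, magnitude alone decides
  got2 <- classify_host_relation(x4, y4, use_p = FALSE)
  expect_equal(got2$relation, "positive")
})

test_that("a planted anti-correlated module is recovered", {
  set.seed(17)
  n <- 40
  driver <- rnorm(n, 10, 3)
  m <- rbind(
    target = driver,
    t(vapply(1:6, function(i) -driver + rnorm(n, 0, 0.3), numeric(n))),
    t(vapply(1:20, function(i) rnorm(n, 10, 3), numeric(n)))
  )
  rownames(m) <- c("target", paste0("anti", 1:6), paste0("rand", 1:20))
  colnames(m) <- paste0("s", 1:n)
  partners <- coexpression_partners("target", m, log2_transform = FALSE)
  expect_true(all(paste0("anti", 1:6) %in% partners$gene_id))
  anti <- partners[partners$gene_id %in% paste0("anti", 1:6), ]
  expect_equal(unique(anti$sign), "negative")
  expect_gt(attr(partners, "summary")$negative_fraction, 0.8)

  # impossible threshold empties the set; relaxing p never shrinks it
  none <- coexpression_partners("target", m, r_threshold = 1,
                                log2_transform = FALSE)
  expect_equal(nrow(none), 0)
  strict <- coexpression_partners("target", m, p_threshold = 1e-6,
                                  log2_transform = FALSE)
  loose <- coexpression_partners("target", m, p_threshold = 0.05,
                                 log2_transform = FALSE)
  expect_true(all(strict$gene_id %in% loose$gene_id))
  expect_error(coexpression_partners("absent", m), "not in matrix")
})

test_that("host-relation grid is monotonically nested across thresholds", {
  demo <- get_demo()
  rel_full <- demo$results$host_relations
  expect_gte(nrow(rel_full), 3)
  pairs <- rel_full[, c("lncrna_id", "host_gene")]
  combined <- dplyr::bind_rows(
    demo$results$lnc_expr[, c("gene_id", "sample_id", "rpkm")],
    demo$results$expr[, c("gene_id", "sample_id", "rpkm")]
  )
  prev <- NULL
  for (thr in c(0.9, 0.7, 0.5, 0.3)) {
    rel <- host_relations(pairs, combined, r_threshold = thr)
    called <- rel$lncrna_id[rel$relation != "non_correlated"]
    if (!is.null(prev)) expect_true(all(prev %in% called))
    prev <- called
  }
})

test_that("sample similarity is symmetric with unit diagonal", {
  set.seed(23)
  m <- matrix(rpois(200, 40), nrow = 20,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  s <- sample_similarity(m)
  expect_equal(s, t(s))
  expect_equal(unname(diag(s)), rep(1, 10))

  dup <- cbind(m, s1bis = m[, "s1"])
  sdup <- sample_similarity(dup)
  expect_equal(sdup["s1", "s1bis"], 1)

  # independent random columns: off-diagonal near zero at large n
  set.seed(24)
  big <- matrix(rnorm(3000 * 4), ncol = 4,
                dimnames = list(NULL, paste0("s", 1:4)))
  sb <- sample_similarity(big, log2_transform = FALSE)
  expect_lt(max(abs(sb[upper.tri(sb)])), 0.1)

  const <- m; const[, 1] <- 5
  sc <- sample_similarity(const, log2_transform = FALSE)
  expect_true(all(is.na(sc[1, ])))
})
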