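# Counting, normalisation and detection. The expression container is a long
# tibble (gene_id, sample_id, count [, rpkm, tpm]) carrying the per-sample
# library sizes as an attribute; `counts_matrix()` widens it when a matrix is
# more convenient.

#' Count uniquely aligned reads per gene
#'
#' A read increments a gene iff at least `min_overlap` (default 50%) of its
#' aligned bases fall within that gene's exonic union; among genes passing the
#' rule the one with the largest overlap wins, and exact ties are dropped.
#' Reads assigned to no gene contribute to the library size when
#' `count_unassigned = TRUE` (default).
#'
#' @param alignments Alignment tibble ([read_alignments()]), unique-filtered.
#' @param annotation Exon tibble ([read_annotation()]).
#' @param min_overlap Minimal overlapping fraction of aligned bases.
#' @param count_unassigned Count gene-less reads toward library size.
#' @return Long tibble `gene_id`, `sample_id`, `count` (complete grid,
#'   zero-filled) with attribute `library_sizes`.
#' @export
count_reads <- function(alignments, annotation, min_overlap = 0.5,
                        count_unassigned = TRUE) {
  if (nrow(annotation) == 0) stop("empty annotation", call. = FALSE)
  samples <- sort(unique(alignments$sample_id))
  genes <- sort(unique(annotation$gene_id))

  # per-gene exonic union
  union_tbl <- annotation |>
    group_by(.data$gene_id) |>
    group_modify_keep(function(df) {
      red <- IRanges::reduce(IRanges::IRanges(df$start + 1L, df$end))
      tibble(chrom = df$chrom[1], start = IRanges::start(red) - 1L,
             end = IRanges::end(red))
    }) |>
    ungroup()
  gene_gr <- GenomicRanges::GRanges(union_tbl$chrom,
                                    IRanges::IRanges(union_tbl$start + 1L,
                                                     union_tbl$end))

  blk <- alignment_blocks(alignments)
  blk_gr <- GenomicRanges::GRanges(blk$chrom,
                                   IRanges::IRanges(blk$start + 1L, blk$end))
  hits <- GenomicRanges::findOverlaps(blk_gr, gene_gr, ignore.strand = TRUE)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(blk_gr)[S4Vectors::queryHits(hits)],
    IRanges::ranges(gene_gr)[S4Vectors::subjectHits(hits)]))

  assigned <- tibble(
    read_idx = blk$read_idx[S4Vectors::queryHits(hits)],
    gene_id = union_tbl$gene_id[S4Vectors::subjectHits(hits)],
    ov = ov
  ) |>
    group_by(.data$read_idx, .data$gene_id) |>
    summarise(ov = sum(.data$ov), .groups = "drop")

  alen <- aligned_length(alignments)
  assigned <- assigned |>
    filter(.data$ov >= min_overlap * alen[.data$read_idx])
  if (nrow(assigned) > 0) {
    assigned <- assigned |>
      group_by(.data$read_idx) |>
      filter(.data$ov == max(.data$ov)) |>
      filter(n() == 1) |>   # exact ties dropped
      ungroup()
  }
  assigned <- mutate(assigned,
                     sample_id = alignments$sample_id[.data$read_idx])

  counts <- assigned |>
    count(.data$gene_id, .data$sample_id, name = "count") |>
    tidyr::complete(gene_id = genes, sample_id = samples,
                    fill = list(count = 0L))

  lib <- if (count_unassigned) {
    tibble(sample_id = alignments$sample_id) |>
      count(.data$sample_id, name = "library_size")
  } else {
    counts |> group_by(.data$sample_id) |>
      summarise(library_size = sum(.data$count), .groups = "drop")
  }
  lib <- tidyr::complete(lib, sample_id = samples,
                         fill = list(library_size = 0L))
  attr(counts, "library_sizes") <- lib
  counts
}

#' Widen a long count tibble into a genes x samples matrix
#'
#' @param counts Long tibble `gene_id`, `sample_id`, and a value column.
#' @param value Column to spread (default `count`).
#' @return Numeric matrix, genes in rows.
#' @export
counts_matrix <- function(counts, value = "count") {
  wide <- tidyr::pivot_wider(
    counts |> select("gene_id", "sample_id", all_of(value)),
    names_from = "sample_id", values_from = all_of(value), values_fill = 0
  )
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$gene_id
  m
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count / (exonic_length/1e3 * library_size/1e6)`.
#'
#' @param count Read counts.
#' @param exonic_length Gene exonic union length in nt (> 0).
#' @param library_size Per-sample mapped reads (> 0).
#' @return Numeric vector of RPKM values.
#' @export
rpkm <- function(count, exonic_length, library_size) {
  if (any(exonic_length <= 0)) stop("exonic_length must be positive", call. = FALSE)
  if (any(library_size <= 0)) stop("library_size must be positive", call. = FALSE)
  count / (exonic_length / 1e3 * library_size / 1e6)
}

#' Transcripts (tags) per million
#'
#' Length-normalised rates rescaled so each sample sums to 1e6 over the
#' counted genes. An all-zero sample is defined as all-zero, with a warning.
#'
#' @param count Read counts (vector, one sample).
#' @param exonic_length Matching exonic lengths (> 0).
#' @return Numeric vector of TPM values summing to 1e6 (or all zero).
#' @export
tpm <- function(count, exonic_length) {
  if (any(exonic_length <= 0)) stop("exonic_length must be positive", call. = FALSE)
  rate <- count / exonic_length
  s <- sum(rate)
  if (s == 0) {
    warning("all-zero sample: TPM defined as all-zero")
    return(rate)
  }
  rate / s * 1e6
}

#' Add RPKM and TPM layers to a long count tibble
#'
#' @param counts Output of [count_reads()].
#' @param annotation Exon tibble (for exonic lengths).
#' @return The counts tibble with `rpkm` and `tpm` columns.
#' @export
add_expression_layers <- function(counts, annotation) {
  lib <- attr(counts, "library_sizes")
  if (is.null(lib)) {
    lib <- counts |> group_by(.data$sample_id) |>
      summarise(library_size = sum(.data$count), .groups = "drop")
  }
  lens <- gene_exonic_lengths(annotation)
  out <- counts |>
    inner_join(lens, by = "gene_id") |>
    left_join(lib, by = "sample_id") |>
    group_by(.data$sample_id) |>
    mutate(rpkm = rpkm(.data$count, .data$exonic_length, .data$library_size),
           tpm = suppressWarnings(tpm(.data$count, .data$exonic_length))) |>
    ungroup() |>
    select(-"exonic_length", -"library_size")
  attr(out, "library_sizes") <- lib
  out
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes with all-positive counts of the
#' ratio of the sample's count to the gene's geometric mean across samples.
#' Dividing counts by these factors puts samples on the scale of the
#' pseudo-reference.
#'
#' @param counts Genes x samples matrix or long count tibble.
#' @return Named numeric vector of size factors.
#' @export
deseq_size_factors <- function(counts) {
  m <- if (is.matrix(counts)) counts else counts_matrix(counts)
  if (ncol(m) < 2) stop("need at least two samples", call. = FALSE)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    stop("no gene with all-positive counts; filter low-coverage genes first",
         call. = FALSE)
  }
  ref <- exp(rowMeans(log(m[pos, , drop = FALSE])))
  apply(m[pos, , drop = FALSE], 2, function(col) median(col / ref))
}

#' Detect expressed genes at an RPKM threshold
#'
#' Strict inequality: a gene is detected in a sample iff RPKM > `threshold`.
#'
#' @param expr Long tibble with `gene_id`, `sample_id`, `rpkm`
#'   ([add_expression_layers()]).
#' @param threshold RPKM cutoff (default 0.1).
#' @return Long tibble `gene_id`, `sample_id`, `detected`, with attribute
#'   `detection_rates` (per-sample fraction detected plus a `union` row:
#'   fraction detected in at least one sample).
#' @export
detect_expressed <- function(expr, threshold = 0.1) {
  det <- expr |>
    mutate(detected = .data$rpkm > threshold) |>
    select("gene_id", "sample_id", "detected")
  per_sample <- det |>
    group_by(.data$sample_id) |>
    summarise(rate = mean(.data$detected), .groups = "drop")
  union_rate <- det |>
    group_by(.data$gene_id) |>
    summarise(any = any(.data$detected), .groups = "drop") |>
    summarise(rate = mean(.data$any)) |>
    pull(.data$rate)
  attr(det, "detection_rates") <- bind_rows(
    per_sample, tibble(sample_id = "union", rate = union_rate))
  det
}

#' Relative quantification by the 2^-ddCt method
#'
#' `ddCt = (Ct_target - Ct_reference) - (Ct_target_cal - Ct_reference_cal)`;
#' returns `2^-ddCt`.
#'
#' @param ct_target,ct_reference Ct values in the sample of interest.
#' @param ct_target_calibrator,ct_reference_calibrator Ct values in the
#'   calibrator sample.
#' @return Relative expression quantity.
#' @export
ddct <- function(ct_target, ct_reference, ct_target_calibrator,
                 ct_reference_calibrator) {
  stopifnot(is.finite(ct_target), is.finite(ct_reference),
            is.finite(ct_target_calibrator), is.finite(ct_reference_calibrator))
  ddct <- (ct_target - ct_reference) -
    (ct_target_calibrator - ct_reference_calibrator)
  2^(-ddct)
}
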