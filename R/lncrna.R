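# lncRNA discovery: coverage-contig + junction-chain assembly of candidate
# transcripts from alignments, coding-potential filtering, the two single-exon
# length thresholds (1,000 nt for longer candidates, 500 nt to keep more), and
# genomic locus classification against the annotation.

#' Assemble candidate transcripts from aligned reads
#'
#' Single-exon candidates are maximal coverage contigs (per-base depth >=
#' `min_depth`, contigs separated by <= `gap_join` nt joined); multi-exon
#' candidates are contig chains linked by splice junctions supported by at
#' least `min_junction` qualifying reads. Candidates overlapping annotated
#' exons in sense orientation (or with unknown strand) are discarded, so no
#' retained candidate has sense exonic overlap with the annotation.
#'
#' @param alignments Unique-filtered alignment tibble.
#' @param annotation Exon tibble of the known annotation.
#' @param genome Optional genome (named character vector) used to infer
#'   junction strand from GT-AG/CT-AC motifs.
#' @param min_depth Minimal per-base read depth of a contig (default 3).
#' @param min_junction Minimal junction read support to link contigs
#'   (default 2).
#' @param gap_join Maximal gap (nt) joined between adjacent contigs
#'   (default 10).
#' @return Candidate tibble: `candidate_id`, `chrom`, `strand`, `start`,
#'   `end`, `n_exons`, `length`, `exons` (list column of matrices).
#' @export
assemble_candidates <- function(alignments, annotation, genome = NULL,
                                min_depth = 3, min_junction = 2,
                                gap_join = 10) {
  if (nrow(alignments) == 0) {
    return(tibble(candidate_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  n_exons = integer(), length = integer(), exons = list()))
  }
  blk <- alignment_blocks(alignments)
  blk_gr <- GenomicRanges::GRanges(blk$chrom,
                                   IRanges::IRanges(blk$start + 1L, blk$end))
  cov <- GenomicRanges::coverage(blk_gr)
  contig_gr <- GenomicRanges::reduce(
    GenomicRanges::GRanges(IRanges::slice(cov, lower = min_depth,
                                          rangesOnly = TRUE)),
    min.gapwidth = gap_join + 1L
  )
  contigs <- granges_to_intervals(contig_gr) |>
    mutate(contig = row_number())
  if (nrow(contigs) == 0) {
    return(tibble(candidate_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  n_exons = integer(), length = integer(), exons = list()))
  }

  # junction-linked chains
  jx <- extract_junctions(alignments) |>
    group_by(.data$chrom, .data$donor, .data$acceptor) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    filter(.data$count >= min_junction)
  if (!is.null(genome)) jx <- infer_junction_strand(jx, genome)
  else jx$strand <- "unknown"

  # a junction links contig i (covering the base before the gap) to contig j
  # (covering the first base after the gap)
  link <- NULL
  if (nrow(jx) > 0) {
    ctg_of <- function(chrom, pos) {
      # contig containing base [pos, pos+1)
      hit <- GenomicRanges::findOverlaps(
        GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L)),
        contig_gr, select = "first"
      )
      as.integer(hit)
    }
    link <- jx |>
      mutate(from = ctg_of(.data$chrom, .data$donor - 1L),
             to = ctg_of(.data$chrom, .data$acceptor)) |>
      filter(!is.na(.data$from), !is.na(.data$to), .data$from != .data$to)
  }

  # union-find over contigs
  parent <- seq_len(nrow(contigs))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (!is.null(link) && nrow(link) > 0) {
    for (r in seq_len(nrow(link))) {
      a <- find(link$from[r]); b <- find(link$to[r])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  comp <- vapply(seq_len(nrow(contigs)), find, integer(1))

  ann_exon_gr <- intervals_to_granges(annotation)

  cands <- purrr::map_dfr(unique(comp), function(cc) {
    rows <- contigs[comp == cc, ]
    rows <- arrange(rows, .data$start)
    chr <- rows$chrom[1]
    strand <- "unknown"
    if (nrow(rows) > 1) {
      # trim member contigs at the junction boundaries that link them
      lk <- link[link$chrom == chr & link$from %in% rows$contig &
                   link$to %in% rows$contig, ]
      ex <- cbind(start = rows$start, end = rows$end)
      for (r in seq_len(nrow(lk))) {
        i <- which(rows$contig == lk$from[r]); j <- which(rows$contig == lk$to[r])
        ex[i, "end"] <- min(ex[i, "end"], lk$donor[r])
        ex[j, "start"] <- max(ex[j, "start"], lk$acceptor[r])
      }
      st <- unique(lk$strand)
      st <- st[st %in% c("+", "-")]
      if (length(st) == 1) strand <- st
      ex <- ex[ex[, "end"] > ex[, "start"], , drop = FALSE]
    } else {
      ex <- cbind(start = rows$start, end = rows$end)
    }
    tibble(chrom = chr, strand = strand,
           start = as.integer(min(ex[, "start"])),
           end = as.integer(max(ex[, "end"])),
           n_exons = nrow(ex),
           length = as.integer(sum(ex[, "end"] - ex[, "start"])),
           exons = list(ex))
  })

  # discard sense exonic overlap (unknown-strand candidates overlapping any
  # annotated exon are discarded too)
  keep <- vapply(seq_len(nrow(cands)), function(r) {
    ex <- cands$exons[[r]]
    gr <- GenomicRanges::GRanges(cands$chrom[r],
                                 IRanges::IRanges(ex[, "start"] + 1L, ex[, "end"]))
    hits <- GenomicRanges::findOverlaps(gr, ann_exon_gr, ignore.strand = TRUE)
    if (length(hits) == 0) return(TRUE)
    if (cands$strand[r] == "unknown") return(FALSE)
    ann_strand <- as.character(GenomicRanges::strand(
      ann_exon_gr[S4Vectors::subjectHits(hits)]))
    !any(ann_strand == cands$strand[r] | ann_strand == "*")
  }, logical(1))
  cands <- cands[keep, , drop = FALSE]
  cands |>
    arrange(.data$chrom, .data$start) |>
    mutate(candidate_id = sprintf("cand%04d", row_number())) |>
    select("candidate_id", "chrom", "strand", "start", "end", "n_exons",
           "length", "exons")
}

#' Filter lncRNA candidates by coding potential and length
#'
#' Retains candidates with CPS below `cps_cutoff`, length above 200 nt, and —
#' for single-exon candidates — length at or above the active single-exon
#' threshold. The two thresholds used in practice are 1,000 nt (longer,
#' higher-confidence single-exon lncRNAs) and 500 nt (keeping more); runs at
#' both are meant to be reported side by side.
#'
#' @param candidates Candidate tibble with a `cps` column (see
#'   [coding_potential_score()]).
#' @param single_exon_threshold 500 or 1000 (other values allowed with a
#'   warning).
#' @param cps_cutoff CPS at or above which a candidate is considered coding
#'   (default 0.5).
#' @return The retained candidates, with `single_exon_threshold` attribute.
#' @export
filter_lncrnas <- function(candidates, single_exon_threshold = 1000,
                           cps_cutoff = 0.5) {
  if (!single_exon_threshold %in% c(500, 1000)) {
    warning("single-exon threshold ", single_exon_threshold,
            " differs from the standard 500/1,000 nt choices")
  }
  stopifnot("cps" %in% names(candidates))
  out <- candidates |>
    filter(.data$cps < cps_cutoff,
           .data$length > 200,
           .data$n_exons > 1 | .data$length >= single_exon_threshold)
  attr(out, "single_exon_threshold") <- single_exon_threshold
  out
}

#' Classify the genomic locus of lncRNA candidates
#'
#' Precedence: exonic_overlap (sense overlap with an annotated exon) >
#' intronic (fully within one derived intron of a gene, either strand; host
#' recorded) > antisense (overlap with a gene on the opposite strand when the
#' candidate strand is known) > intergenic. Unknown-strand candidates cannot
#' be antisense. A candidate spanning introns of two genes is classified by
#' the larger overlap and flagged ambiguous.
#'
#' @param candidates Candidate tibble.
#' @param annotation Exon tibble.
#' @return `candidates` with `locus_class`, `host_gene`, `ambiguous` columns.
#' @export
classify_locus <- function(candidates, annotation) {
  if (nrow(candidates) == 0) {
    return(mutate(candidates, locus_class = character(0),
                  host_gene = character(0), ambiguous = logical(0)))
  }
  ann_exon_gr <- intervals_to_granges(annotation)
  introns <- derive_introns(annotation)
  intron_gr <- if (nrow(introns) > 0) intervals_to_granges(introns) else NULL
  gene_spans <- annotation |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  gene_gr <- intervals_to_granges(gene_spans)

  res <- purrr::map_dfr(seq_len(nrow(candidates)), function(r) {
    cand_gr <- GenomicRanges::GRanges(
      candidates$chrom[r],
      IRanges::IRanges(candidates$start[r] + 1L, candidates$end[r]))
    strand <- candidates$strand[r]

    # sense exonic overlap
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(cand_gr, ann_exon_gr, ignore.strand = TRUE))
    if (length(hits) > 0 && strand != "unknown") {
      es <- as.character(GenomicRanges::strand(ann_exon_gr[S4Vectors::subjectHits(hits)]))
      if (any(es == strand | es == "*")) {
        g <- annotation$gene_id[S4Vectors::subjectHits(hits)[
          (es == strand | es == "*")][1]]
        return(tibble(locus_class = "exonic_overlap", host_gene = g,
                      ambiguous = FALSE))
      }
    } else if (length(hits) > 0 && strand == "unknown") {
      g <- annotation$gene_id[S4Vectors::subjectHits(hits)[1]]
      return(tibble(locus_class = "exonic_overlap", host_gene = g,
                    ambiguous = FALSE))
    }

    # intronic: fully within one derived intron (either strand)
    if (!is.null(intron_gr)) {
      within <- suppressWarnings(
        GenomicRanges::findOverlaps(cand_gr, intron_gr, type = "within",
                                    ignore.strand = TRUE))
      if (length(within) > 0) {
        hosts <- unique(introns$gene_id[S4Vectors::subjectHits(within)])
        return(tibble(locus_class = "intronic", host_gene = hosts[1],
                      ambiguous = length(hosts) > 1))
      }
      # partial intron overlap of two genes: larger overlap wins, flagged
      part <- suppressWarnings(
        GenomicRanges::findOverlaps(cand_gr, intron_gr, ignore.strand = TRUE))
      if (length(part) > 0) {
        ov <- IRanges::width(IRanges::pintersect(
          IRanges::ranges(cand_gr)[rep(1L, length(part))],
          IRanges::ranges(intron_gr)[S4Vectors::subjectHits(part)]))
        by_gene <- tibble(gene = introns$gene_id[S4Vectors::subjectHits(part)],
                          ov = ov) |>
          group_by(.data$gene) |>
          summarise(ov = sum(.data$ov), .groups = "drop") |>
          arrange(dplyr::desc(.data$ov))
        if (nrow(by_gene) > 1 ||
            by_gene$ov[1] < candidates$end[r] - candidates$start[r]) {
          # spans intron boundaries or multiple genes: fall through unless
          # mostly intronic in a single gene
          if (nrow(by_gene) > 1) {
            return(tibble(locus_class = "intronic", host_gene = by_gene$gene[1],
                          ambiguous = TRUE))
          }
        }
      }
    }

    # antisense
    if (strand != "unknown") {
      gh <- suppressWarnings(
        GenomicRanges::findOverlaps(cand_gr, gene_gr, ignore.strand = TRUE))
      if (length(gh) > 0) {
        gs <- gene_spans$strand[S4Vectors::subjectHits(gh)]
        anti <- which(gs %in% c("+", "-") & gs != strand)
        if (length(anti) > 0) {
          return(tibble(locus_class = "antisense",
                        host_gene = gene_spans$gene_id[S4Vectors::subjectHits(gh)[anti[1]]],
                        ambiguous = FALSE))
        }
      }
    }
    tibble(locus_class = "intergenic", host_gene = NA_character_,
           ambiguous = FALSE)
  })
  bind_cols(candidates, res)
}

#' Sex specificity of lncRNAs from the detection matrix
#'
#' A lncRNA is female specific iff detected (RPKM above the detection
#' threshold) in at least `min_samples` female samples and in no male sample;
#' symmetrically for male specific; otherwise shared. lncRNAs detected
#' nowhere are excluded from the summary fractions.
#'
#' @param detection Long tibble `gene_id`, `sample_id`, `detected`
#'   ([detect_expressed()]) restricted to the lncRNAs of interest.
#' @param samples Sample sheet with `sample_id` and `sex` (`F`/`M`).
#' @param min_samples Minimal supporting samples (default 2).
#' @return Tibble `gene_id`, `n_female`, `n_male`, `sex_specificity`, with a
#'   `summary` attribute reporting the female-specific fraction among
#'   detected lncRNAs.
#' @export
sex_specificity <- function(detection, samples, min_samples = 2) {
  if (!"sex" %in% names(samples)) stop("sample sheet lacks sex metadata", call. = FALSE)
  d <- detection |>
    inner_join(select(samples, "sample_id", "sex"), by = "sample_id") |>
    group_by(.data$gene_id) |>
    summarise(n_female = sum(.data$detected & .data$sex == "F"),
              n_male = sum(.data$detected & .data$sex == "M"),
              .groups = "drop") |>
    mutate(sex_specificity = dplyr::case_when(
      .data$n_female >= min_samples & .data$n_male == 0 ~ "female_specific",
      .data$n_male >= min_samples & .data$n_female == 0 ~ "male_specific",
      .default = "shared"
    ))
  detected <- d |> filter(.data$n_female + .data$n_male > 0)
  attr(d, "summary") <- tibble(
    n_detected = nrow(detected),
    female_specific_fraction = ifelse(nrow(detected) == 0, NA_real_,
                                      mean(detected$sex_specificity == "female_specific"))
  )
  d
}

# candidate tibble -> exon tibble usable by count_reads()/write_annotation()
candidates_to_annotation <- function(candidates) {
  purrr::map_dfr(seq_len(nrow(candidates)), function(r) {
    ex <- candidates$exons[[r]]
    tibble(
      transcript_id = candidates$candidate_id[r],
      gene_id = candidates$candidate_id[r],
      chrom = candidates$chrom[r],
      strand = candidates$strand[r],
      start = as.integer(ex[, "start"]), end = as.integer(ex[, "end"]),
      exon_rank = seq_len(nrow(ex)),
      biotype = "lncRNA"
    )
  })
}

#' Extract candidate sequences from the genome
#'
#' Spliced sequence of each candidate (reverse-complemented for known minus
#' strand; unknown-strand candidates are returned in reference orientation —
#' the CPS scans both strands, so orientation does not matter there).
#'
#' @param candidates Candidate tibble.
#' @param genome Named character vector or DNAStringSet.
#' @return Character vector named by candidate id.
#' @export
candidate_sequences <- function(candidates, genome) {
  genome <- as_genome(genome)
  out <- vapply(seq_len(nrow(candidates)), function(r) {
    ex <- candidates$exons[[r]]
    s <- paste(substring(genome[[candidates$chrom[r]]],
                         ex[, "start"] + 1L, ex[, "end"]), collapse = "")
    if (candidates$strand[r] == "-") revcomp(s) else s
  }, character(1))
  setNames(out, candidates$candidate_id)
}
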