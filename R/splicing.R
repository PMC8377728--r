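# Splice junction extraction, known/novel annotation, alternative-splicing
# event classification (ES, CE, A5SS, A3SS, MXE, AFE, ALE, IR, other),
# splicing-efficiency statistics and the Fisher exact test used for
# alternative polyadenylation usage.

#' Extract splice junctions from gapped alignments
#'
#' Every alignment gap yields a junction (donor = intron start, acceptor =
#' intron end, 0-based half-open). A read supports a junction iff at least
#' `min_flank` aligned nt flank the gap on both sides. Counts are aggregated
#' per sample.
#'
#' @param alignments Alignment tibble.
#' @param min_flank Minimal aligned nt on each side of the gap (default 8).
#' @return Junction tibble: `chrom`, `donor`, `acceptor`, `sample_id`,
#'   `count`.
#' @export
extract_junctions <- function(alignments, min_flank = 8) {
  blk <- alignment_blocks(alignments)
  same_read <- c(FALSE, blk$read_idx[-1] == blk$read_idx[-nrow(blk)])
  w <- blk$end - blk$start
  gap_ok <- same_read &
    c(FALSE, w[-length(w)] >= min_flank) & w >= min_flank
  if (!any(gap_ok)) {
    return(tibble(chrom = character(), donor = integer(),
                  acceptor = integer(), sample_id = character(),
                  count = integer()))
  }
  idx <- which(gap_ok)
  rows <- tibble(chrom = blk$chrom[idx],
                 donor = as.integer(blk$end[idx - 1L]),
                 acceptor = as.integer(blk$start[idx]),
                 sample_id = blk$sample_id[idx])
  if (nrow(rows) == 0) {
    return(tibble(chrom = character(), donor = integer(),
                  acceptor = integer(), sample_id = character(),
                  count = integer()))
  }
  rows |>
    count(.data$chrom, .data$donor, .data$acceptor, .data$sample_id,
          name = "count") |>
    arrange(.data$chrom, .data$donor, .data$acceptor, .data$sample_id)
}

#' Annotate junctions as known or novel
#'
#' A junction is known iff its (donor, acceptor) pair exactly equals an
#' annotated intron's boundaries; any shift makes it novel.
#'
#' @param junctions Junction tibble ([extract_junctions()]).
#' @param annotation Exon tibble.
#' @return `junctions` with a `status` column (`known`/`novel`).
#' @export
annotate_junctions <- function(junctions, annotation) {
  known <- derive_introns(annotation) |>
    distinct(.data$chrom, donor = .data$start, acceptor = .data$end) |>
    mutate(status = "known")
  junctions |>
    left_join(known, by = c("chrom", "donor", "acceptor")) |>
    mutate(status = dplyr::coalesce(.data$status, "novel"))
}

# GT-AG / CT-AC strand inference for junctions
infer_junction_strand <- function(junctions, genome) {
  genome <- as_genome(genome)
  strand <- vapply(seq_len(nrow(junctions)), function(i) {
    ch <- junctions$chrom[i]
    d <- junctions$donor[i]; a <- junctions$acceptor[i]
    if (a - d < 4 || d < 0 || a > nchar(genome[[ch]])) return("unknown")
    left <- genome_sub(genome, ch, d, d + 2L)
    right <- genome_sub(genome, ch, a - 2L, a)
    if (left == "GT" && right == "AG") "+"
    else if (left == "CT" && right == "AC") "-"
    else "unknown"
  }, character(1))
  mutate(junctions, strand = strand)
}

#' Classify alternative-splicing events from junctions
#'
#' Junctions are grouped by the gene whose span contains them, then matched
#' against a rule table (coordinates 0-based half-open; types mirror between
#' strands):
#' \itemize{
#'   \item two junctions sharing a donor with different acceptors:
#'     A3SS on `+` (A5SS on `-`), or ALE/AFE when the two acceptors fall in
#'     different annotated terminal exons;
#'   \item sharing an acceptor with different donors: A5SS on `+`
#'     (A3SS on `-`), or AFE/ALE for distinct terminal exons;
#'   \item a junction spanning an annotated exon flanked by junctions into
#'     that exon: CE when the skip junction matches an annotated intron,
#'     ES when it is novel;
#'   \item two non-overlapping exons sharing upstream donor and downstream
#'     acceptor with no junction between them: MXE;
#'   \item unclassifiable multi-junction patterns: other.
#' }
#' Junction groups spanning two genes are flagged and skipped. Intron
#' retention is detected separately ([detect_intron_retention()]).
#'
#' @param junctions Junction tibble, ideally from [annotate_junctions()]
#'   (a `status` column is added if missing).
#' @param annotation Exon tibble.
#' @return Event tibble: `gene_id`, `type`, `chrom`, `coord_1`, `coord_2`,
#'   `inclusion_count`, `exclusion_count`.
#' @export
classify_ase <- function(junctions, annotation) {
  if (!"status" %in% names(junctions)) {
    junctions <- annotate_junctions(junctions, annotation)
  }
  jx <- junctions |>
    group_by(.data$chrom, .data$donor, .data$acceptor, .data$status) |>
    summarise(count = sum(.data$count), .groups = "drop")

  gene_spans <- annotation |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  gene_gr <- intervals_to_granges(gene_spans)
  j_gr <- GenomicRanges::GRanges(jx$chrom, IRanges::IRanges(jx$donor + 1L, jx$acceptor))
  hits <- GenomicRanges::findOverlaps(j_gr, gene_gr, type = "within",
                                      ignore.strand = TRUE)
  hit_tbl <- tibble(j = S4Vectors::queryHits(hits),
                    g = S4Vectors::subjectHits(hits)) |>
    group_by(.data$j) |>
    summarise(n_genes = n(), g = first(.data$g), .groups = "drop")
  multi_gene <- hit_tbl$j[hit_tbl$n_genes > 1]
  if (length(multi_gene) > 0) {
    warning(length(multi_gene), " junction(s) spanning multiple genes skipped")
  }
  hit_tbl <- hit_tbl |> filter(.data$n_genes == 1)
  jx <- jx[hit_tbl$j, ]
  jx$gene_id <- gene_spans$gene_id[hit_tbl$g]
  jx$gene_strand <- gene_spans$strand[hit_tbl$g]

  events <- list()
  add_event <- function(gene, type, chrom, c1, c2, inc, exc) {
    events[[length(events) + 1]] <<- tibble(
      gene_id = gene, type = type, chrom = chrom,
      coord_1 = as.integer(c1), coord_2 = as.integer(c2),
      inclusion_count = as.integer(inc), exclusion_count = as.integer(exc))
  }

  for (g in unique(jx$gene_id)) {
    jg <- jx[jx$gene_id == g, ]
    gstrand <- jg$gene_strand[1]
    exons <- annotation |> filter(.data$gene_id == g)
    pick_edge <- function(df, leftmost) {
      df |> group_by(.data$transcript_id) |>
        filter(.data$start == (if (leftmost) min(.data$start) else max(.data$start))) |>
        ungroup()
    }
    tx_first <- pick_edge(exons, leftmost = gstrand != "-")
    tx_last <- pick_edge(exons, leftmost = gstrand == "-")
    exon_of <- function(pos) {
      # index into exons of a distinct exon containing pos
      w <- which(exons$start <= pos & pos <= exons$end)
      if (length(w) == 0) NA_integer_ else w[1]
    }
    classified <- rep(FALSE, nrow(jg))

    # skipped / cassette exons: skip junction spans an annotated exon with
    # both inclusion junctions present
    for (i in seq_len(nrow(jg))) {
      span <- exons |> filter(.data$start >= jg$donor[i], .data$end <= jg$acceptor[i])
      if (nrow(span) == 0) next
      for (e in seq_len(nrow(span))) {
        left_j <- which(jg$donor == jg$donor[i] & jg$acceptor == span$start[e])
        right_j <- which(jg$donor == span$end[e] & jg$acceptor == jg$acceptor[i])
        if (length(left_j) > 0 && length(right_j) > 0) {
          type <- if (jg$status[i] == "known") "CE" else "ES"
          add_event(g, type, jg$chrom[i], span$start[e], span$end[e],
                    min(jg$count[left_j[1]], jg$count[right_j[1]]),
                    jg$count[i])
          classified[c(i, left_j[1], right_j[1])] <- TRUE
        }
      }
    }

    # MXE: common donor u and acceptor v via two mutually exclusive exons
    donors <- unique(jg$donor); acceptors <- unique(jg$acceptor)
    for (u in donors) {
      for (v in acceptors[acceptors > u]) {
        into <- which(jg$donor == u)
        outof <- which(jg$acceptor == v)
        exA <- NULL
        for (i1 in into) for (i2 in outof) {
          # exon bounded by acceptor of the in-junction and donor of the out
          if (jg$acceptor[i1] < jg$donor[i2]) {
            exA <- rbind(exA, c(jg$acceptor[i1], jg$donor[i2], i1, i2))
          }
        }
        if (is.null(exA) || nrow(exA) < 2) next
        for (a in seq_len(nrow(exA) - 1)) for (b in (a + 1):nrow(exA)) {
          e1 <- exA[a, ]; e2 <- exA[b, ]
          disjoint <- e1[2] <= e2[1] || e2[2] <= e1[1]
          bridge <- any(jg$donor == min(e1[2], e2[2]) &
                          jg$acceptor == max(e1[1], e2[1]))
          if (disjoint && !bridge) {
            add_event(g, "MXE", jg$chrom[1], min(e1[1], e2[1]),
                      max(e1[2], e2[2]),
                      jg$count[e1[3]] + jg$count[e1[4]],
                      jg$count[e2[3]] + jg$count[e2[4]])
            classified[c(e1[3], e1[4], e2[3], e2[4])] <- TRUE
          }
        }
      }
    }

    # shared donor, different acceptors
    for (d in unique(jg$donor)) {
      idx <- which(jg$donor == d)
      if (length(idx) < 2) next
      if (any(classified[idx])) next
      idx <- idx[order(jg$acceptor[idx])]
      for (k in seq_len(length(idx) - 1)) {
        i1 <- idx[k]; i2 <- idx[k + 1]
        e1 <- exon_of(jg$acceptor[i1]); e2 <- exon_of(jg$acceptor[i2])
        terminal <- !is.na(e1) && !is.na(e2) && e1 != e2 &&
          ((gstrand == "+" &&
              all(c(paste(exons$start[e1], exons$end[e1]),
                    paste(exons$start[e2], exons$end[e2])) %in%
                    paste(tx_last$start, tx_last$end))) ||
             (gstrand == "-" &&
                all(c(paste(exons$start[e1], exons$end[e1]),
                      paste(exons$start[e2], exons$end[e2])) %in%
                      paste(tx_first$start, tx_first$end))))
        type <- if (terminal) {
          if (gstrand == "-") "AFE" else "ALE"
        } else if (gstrand == "-") "A5SS" else "A3SS"
        add_event(g, type, jg$chrom[i1], jg$acceptor[i1], jg$acceptor[i2],
                  jg$count[i1], jg$count[i2])
        classified[c(i1, i2)] <- TRUE
      }
    }

    # shared acceptor, different donors
    for (acc in unique(jg$acceptor)) {
      idx <- which(jg$acceptor == acc)
      if (length(idx) < 2) next
      if (any(classified[idx])) next
      idx <- idx[order(jg$donor[idx])]
      for (k in seq_len(length(idx) - 1)) {
        i1 <- idx[k]; i2 <- idx[k + 1]
        e1 <- exon_of(jg$donor[i1]); e2 <- exon_of(jg$donor[i2])
        terminal <- !is.na(e1) && !is.na(e2) && e1 != e2 &&
          ((gstrand == "+" &&
              all(c(paste(exons$start[e1], exons$end[e1]),
                    paste(exons$start[e2], exons$end[e2])) %in%
                    paste(tx_first$start, tx_first$end))) ||
             (gstrand == "-" &&
                all(c(paste(exons$start[e1], exons$end[e1]),
                      paste(exons$start[e2], exons$end[e2])) %in%
                      paste(tx_last$start, tx_last$end))))
        type <- if (terminal) {
          if (gstrand == "-") "ALE" else "AFE"
        } else if (gstrand == "-") "A3SS" else "A5SS"
        add_event(g, type, jg$chrom[i1], jg$donor[i1], jg$donor[i2],
                  jg$count[i1], jg$count[i2])
        classified[c(i1, i2)] <- TRUE
      }
    }

    # remaining overlapping-junction patterns: other
    if (nrow(jg) > 1) {
      un <- which(!classified)
      for (a in un) {
        partners <- which(jg$donor < jg$acceptor[a] & jg$acceptor > jg$acceptor[a] &
                            jg$donor > jg$donor[a])
        partners <- setdiff(partners, a)
        if (length(partners) > 0) {
          b <- partners[1]
          add_event(g, "other", jg$chrom[a], jg$donor[a], jg$acceptor[b],
                    jg$count[a], jg$count[b])
          classified[c(a, b)] <- TRUE
        }
      }
    }
  }

  if (length(events) == 0) {
    return(tibble(gene_id = character(), type = character(), chrom = character(),
                  coord_1 = integer(), coord_2 = integer(),
                  inclusion_count = integer(), exclusion_count = integer()))
  }
  bind_rows(events) |>
    distinct(.data$gene_id, .data$type, .data$coord_1, .data$coord_2,
             .keep_all = TRUE) |>
    arrange(.data$gene_id, .data$coord_1)
}

#' Detect intron retention events
#'
#' For each annotated intron, boundary reads are reads spanning an
#' exon-intron border with at least `min_flank` aligned nt on each side.
#' The retention score is `mean(b5, b3) / (junction + mean(b5, b3))` where
#' `b5`/`b3` are boundary-read counts at the two borders and `junction` the
#' spliced junction count. An IR event is called when both boundaries have at
#' least `min_boundary` reads and the junction is also observed.
#'
#' @param alignments Alignment tibble.
#' @param annotation Exon tibble.
#' @param min_flank Flank rule (default 8).
#' @param min_boundary Minimal boundary reads on each side (default 2).
#' @return Tibble `gene_id`, `chrom`, `intron_start`, `intron_end`,
#'   `boundary_5`, `boundary_3`, `junction_count`, `retention_ratio`,
#'   `event` (logical: IR event called).
#' @export
detect_intron_retention <- function(alignments, annotation, min_flank = 8,
                                    min_boundary = 2) {
  introns <- derive_introns(annotation) |>
    distinct(.data$gene_id, .data$chrom, .data$start, .data$end)
  short <- introns$end - introns$start < 2 * min_flank
  if (any(short)) {
    warning(sum(short), " intron(s) shorter than ", 2 * min_flank, " nt skipped")
    introns <- introns[!short, ]
  }
  if (nrow(introns) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  intron_start = integer(), intron_end = integer(),
                  boundary_5 = integer(), boundary_3 = integer(),
                  junction_count = integer(), retention_ratio = numeric(),
                  event = logical()))
  }
  blk <- alignment_blocks(alignments)
  blk_gr <- GenomicRanges::GRanges(blk$chrom,
                                   IRanges::IRanges(blk$start + 1L, blk$end))
  count_spanning <- function(pos_tbl) {
    # reads with a block covering [pos - min_flank, pos + min_flank)
    q <- GenomicRanges::GRanges(pos_tbl$chrom,
                                IRanges::IRanges(pos_tbl$pos - min_flank + 1L,
                                                 pos_tbl$pos + min_flank))
    hits <- GenomicRanges::findOverlaps(q, blk_gr, type = "within")
    tibble(i = S4Vectors::queryHits(hits),
           read = blk$read_idx[S4Vectors::subjectHits(hits)]) |>
      distinct() |>
      count(.data$i, name = "n") |>
      (\(d) { out <- integer(nrow(pos_tbl)); out[d$i] <- d$n; out })()
  }
  b5 <- count_spanning(tibble(chrom = introns$chrom, pos = introns$start))
  b3 <- count_spanning(tibble(chrom = introns$chrom, pos = introns$end))
  jx <- extract_junctions(alignments, min_flank = min_flank) |>
    group_by(.data$chrom, .data$donor, .data$acceptor) |>
    summarise(count = sum(.data$count), .groups = "drop")
  introns <- introns |>
    left_join(jx, by = c("chrom", "start" = "donor", "end" = "acceptor")) |>
    mutate(count = dplyr::coalesce(.data$count, 0L))
  bmean <- (b5 + b3) / 2
  tibble(
    gene_id = introns$gene_id, chrom = introns$chrom,
    intron_start = introns$start, intron_end = introns$end,
    boundary_5 = b5, boundary_3 = b3,
    junction_count = introns$count,
    retention_ratio = ifelse(bmean + introns$count > 0,
                             bmean / (introns$count + bmean), 0),
    event = b5 >= min_boundary & b3 >= min_boundary & introns$count > 0
  )
}

#' Splicing efficiency: fraction of spliced reads
#'
#' Share of uniquely mapped reads carrying at least one qualifying junction.
#'
#' @param alignments Unique-filtered alignment tibble.
#' @param min_flank Junction flank rule (default 8).
#' @return Tibble `sample_id`, `spliced`, `total`, `efficiency`.
#' @export
splicing_efficiency <- function(alignments, min_flank = 8) {
  if (nrow(alignments) == 0) stop("no reads", call. = FALSE)
  has_junction <- vapply(alignments$blocks, function(m) {
    if (nrow(m) < 2) return(FALSE)
    w <- m[, "end"] - m[, "start"]
    any(w[-nrow(m)] >= min_flank & w[-1] >= min_flank)
  }, logical(1))
  tibble(sample_id = alignments$sample_id, spliced = has_junction) |>
    group_by(.data$sample_id) |>
    summarise(spliced = sum(.data$spliced), total = n(), .groups = "drop") |>
    mutate(efficiency = .data$spliced / .data$total)
}

#' Alternative-splicing detection efficiency
#'
#' Detected events per 100 splice junctions: `100 * n_events / n_junctions`.
#'
#' @param events Event tibble ([classify_ase()]).
#' @param junctions Junction tibble aggregated over samples.
#' @return Single numeric, or `NA` when there are no junctions.
#' @export
ase_detection_efficiency <- function(events, junctions) {
  n_j <- junctions |> distinct(.data$chrom, .data$donor, .data$acceptor) |> nrow()
  if (n_j == 0) return(NA_real_)
  100 * nrow(events) / n_j
}

#' Fisher exact test for alternative polyadenylation usage
#'
#' Two-sided Fisher exact test on a 2x2 table (proximal/distal isoform counts
#' in two groups) by hypergeometric enumeration: the p-value sums the
#' probabilities of all tables with the observed margins whose probability
#' does not exceed the observed one. The odds ratio uses the Haldane
#' correction (+0.5) when any cell is zero.
#'
#' @param table_2x2 2x2 matrix of non-negative integer counts: rows
#'   proximal/distal, columns the two groups.
#' @return Tibble `odds_ratio`, `p_value`.
#' @export
apa_usage_test <- function(table_2x2) {
  stopifnot(is.matrix(table_2x2), all(dim(table_2x2) == c(2, 2)),
            all(table_2x2 >= 0), all(table_2x2 == round(table_2x2)))
  if (sum(table_2x2) == 0) stop("all-zero table", call. = FALSE)
  x <- table_2x2[1, 1]
  m <- sum(table_2x2[1, ])   # proximal total
  n <- sum(table_2x2[2, ])   # distal total
  k <- sum(table_2x2[, 1])   # group-A total
  support <- max(0, k - n):min(k, m)
  p_all <- dhyper(support, m, n, k)
  p_obs <- dhyper(x, m, n, k)
  p <- min(1, sum(p_all[p_all <= p_obs * (1 + 1e-7)]))
  t2 <- table_2x2
  if (any(t2 == 0)) t2 <- t2 + 0.5
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  tibble(odds_ratio = or, p_value = p)
}
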