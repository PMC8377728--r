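# Gene annotation handling. The in-memory representation of an annotation is
# an exon-level tibble ("one row per exon"), the tidy analogue of a transcript
# model: columns transcript_id, gene_id, chrom, strand, start, end (0-based
# half-open), exon_rank, biotype. Introns are derived, never stored.

#' Read a GFF3/GTF gene annotation into an exon tibble
#'
#' Parses a GFF3 or GTF file (via `rtracklayer`) and returns the transcript
#' models as one row per exon. Input 1-based closed coordinates are converted
#' to the package-internal 0-based half-open convention. Exons lacking a
#' transcript or gene identifier are dropped with a warning; overlapping exons
#' within one transcript are merged with a warning.
#'
#' @param path Path to a GFF3 (`.gff`, `.gff3`) or GTF (`.gtf`) file.
#' @return A tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `exon_rank`, `biotype`. Biotype is taken from a
#'   `biotype`/`gene_biotype`/`transcript_biotype` attribute when present,
#'   else `"other"`.
#' @export
read_annotation <- function(path) {
  fmt <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  gr <- tryCatch(
    rtracklayer::import(path, format = fmt),
    error = function(e) stop("failed to parse annotation '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  md <- S4Vectors::mcols(gr)
  is_exon <- !is.na(md$type) & tolower(as.character(md$type)) == "exon"
  if (!any(is_exon)) stop("annotation contains no exon features", call. = FALSE)
  ex <- gr[is_exon]
  md <- S4Vectors::mcols(ex)

  get_attr <- function(nms) {
    for (nm in nms) {
      if (nm %in% names(md)) {
        v <- md[[nm]]
        if (methods::is(v, "CharacterList") || is.list(v)) {
          v <- vapply(v, function(x) if (length(x)) as.character(x[[1]]) else NA_character_,
                      character(1))
        }
        return(as.character(v))
      }
    }
    rep(NA_character_, length(ex))
  }

  transcript_id <- get_attr(c("transcript_id", "Parent"))
  gene_id <- get_attr(c("gene_id", "gene"))
  biotype <- get_attr(c("biotype", "gene_biotype", "transcript_biotype"))
  biotype[is.na(biotype)] <- "other"
  biotype[!biotype %in% c("coding", "lncRNA")] <-
    ifelse(grepl("protein|coding|mRNA", biotype[!biotype %in% c("coding", "lncRNA")],
                 ignore.case = TRUE), "coding",
           ifelse(grepl("lnc", biotype[!biotype %in% c("coding", "lncRNA")],
                        ignore.case = TRUE), "lncRNA", "other"))

  orphan <- is.na(transcript_id)
  if (any(orphan)) {
    warning(sum(orphan), " exon feature(s) without a transcript/Parent id were skipped")
    ex <- ex[!orphan]
    transcript_id <- transcript_id[!orphan]
    gene_id <- gene_id[!orphan]
    biotype <- biotype[!orphan]
  }
  gene_id[is.na(gene_id)] <- transcript_id[is.na(gene_id)]

  tbl <- tibble(
    transcript_id = transcript_id,
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = norm_strand(as.character(GenomicRanges::strand(ex))),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    biotype = biotype
  )
  assert_intervals(tbl, "exon")
  normalize_annotation(tbl)
}

# sort exons, merge within-transcript overlaps (warning), add exon_rank
normalize_annotation <- function(tbl) {
  tbl <- arrange(tbl, .data$chrom, .data$transcript_id, .data$start, .data$end)
  merged_any <- FALSE
  out <- tbl |>
    group_by(.data$transcript_id) |>
    group_modify_keep(function(df) {
      if (nrow(df) > 1 && any(df$start[-1] < cummax(df$end)[-nrow(df)])) {
        merged_any <<- TRUE
        gr <- IRanges::reduce(IRanges::IRanges(df$start + 1L, df$end))
        df <- df[rep(1L, length(gr)), ]
        df$start <- IRanges::start(gr) - 1L
        df$end <- IRanges::end(gr)
      }
      df$exon_rank <- seq_len(nrow(df))
      df
    }) |>
    ungroup()
  if (merged_any) warning("overlapping exons within a transcript were merged")
  arrange(out, .data$chrom, .data$start, .data$transcript_id)
}

# dplyr::group_modify drops grouping columns from .x; keep them
group_modify_keep <- function(.data, .f) {
  dplyr::group_modify(.data, function(.x, .y) {
    res <- .f(dplyr::bind_cols(.y[rep(1, nrow(.x)), , drop = FALSE], .x))
    res[setdiff(names(res), names(.y))]
  })
}

#' Write an exon tibble to GFF3
#'
#' Deterministic writer (sorted by chrom, start, transcript): emits
#' transcript and exon features with `ID`/`Parent` attributes and a `biotype`
#' attribute on transcripts. Coordinates are converted back to 1-based closed.
#'
#' @param annotation Exon tibble as returned by [read_annotation()].
#' @param path Output `.gff3` path.
#' @return `annotation`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  ann <- arrange(annotation, .data$chrom, .data$start, .data$transcript_id,
                 .data$exon_rank)
  tx <- ann |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = first(.data$gene_id), chrom = first(.data$chrom),
      strand = first(.data$strand), start = min(.data$start),
      end = max(.data$end), biotype = first(.data$biotype), .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$start, .data$transcript_id)
  fmt_strand <- function(s) ifelse(s %in% c("+", "-"), s, ".")
  tx_lines <- sprintf(
    "%s\tbeemzt\ttranscript\t%d\t%d\t.\t%s\t.\tID=%s;gene_id=%s;biotype=%s",
    tx$chrom, tx$start + 1L, tx$end, fmt_strand(tx$strand),
    tx$transcript_id, tx$gene_id, tx$biotype
  )
  ex_lines <- sprintf(
    "%s\tbeemzt\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s;gene_id=%s;biotype=%s",
    ann$chrom, ann$start + 1L, ann$end, fmt_strand(ann$strand),
    ann$transcript_id, ann$exon_rank, ann$transcript_id, ann$gene_id, ann$biotype
  )
  # interleave so exons follow their transcript, keeping global sort stable
  ord <- order(match(ann$transcript_id, tx$transcript_id))
  lines <- c("##gff-version 3",
             unlist(purrr::map(seq_len(nrow(tx)), function(i) {
               c(tx_lines[i], ex_lines[ord][ann$transcript_id[ord] == tx$transcript_id[i]])
             })))
  readr::write_lines(lines, path)
  invisible(annotation)
}

#' Derive introns from transcript models
#'
#' Introns are the gaps between consecutive exons of one transcript:
#' a transcript with n exons yields n - 1 introns; single-exon transcripts
#' yield none.
#'
#' @param annotation Exon tibble ([read_annotation()]), or the exons of a
#'   single transcript.
#' @return Tibble with `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `intron_rank` (0-based half-open intervals).
#' @export
derive_introns <- function(annotation) {
  annotation |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand) |>
    dplyr::reframe(
      istart = if (dplyr::n() > 1) .data$end[-dplyr::n()] else integer(0),
      iend = if (dplyr::n() > 1) .data$start[-1] else integer(0)
    ) |>
    rename(start = "istart", end = "iend") |>
    group_by(.data$transcript_id) |>
    mutate(intron_rank = row_number()) |>
    ungroup() |>
    arrange(.data$chrom, .data$start)
}

#' Count annotated introns longer than a threshold
#'
#' Counts distinct gene-level introns (duplicate intervals shared between
#' isoforms counted once) whose length exceeds `min_length`, and the fraction
#' they represent of all distinct introns. Long introns are where most
#' embryonically expressed honeybee lncRNAs reside.
#'
#' @param annotation Exon tibble.
#' @param min_length Intron length cutoff in nt (default 2000).
#' @return A one-row tibble: `n_long`, `n_total`, `fraction`.
#' @export
count_long_introns <- function(annotation, min_length = 2000) {
  introns <- derive_introns(annotation) |>
    distinct(.data$chrom, .data$start, .data$end, .data$strand)
  tibble(
    n_long = sum(introns$end - introns$start > min_length),
    n_total = nrow(introns),
    fraction = ifelse(nrow(introns) == 0, NA_real_,
                      sum(introns$end - introns$start > min_length) / nrow(introns))
  )
}

#' Partition a genome into exonic / intronic / intergenic bases
#'
#' Computes the per-base partition induced by an annotation: bases covered by
#' any exon are exonic; bases inside a gene span but not exonic are intronic;
#' the remainder is intergenic. The three widths sum to the genome length.
#'
#' @param annotation Exon tibble.
#' @param seqlengths Named integer vector of chromosome lengths.
#' @return Tibble with `class` and `bases` (and `fraction`).
#' @export
genome_partition <- function(annotation, seqlengths) {
  exon_gr <- GenomicRanges::reduce(intervals_to_granges(
    mutate(annotation, strand = "unknown")))
  gene_spans <- annotation |>
    group_by(.data$gene_id, .data$chrom) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  gene_gr <- GenomicRanges::reduce(intervals_to_granges(
    mutate(gene_spans, strand = "unknown")))
  exonic <- sum(GenomicRanges::width(exon_gr))
  genic <- sum(GenomicRanges::width(gene_gr))
  total <- sum(seqlengths)
  intronic <- genic - exonic
  tibble(
    class = c("exonic", "intronic", "intergenic"),
    bases = c(exonic, intronic, total - genic)
  ) |>
    mutate(fraction = .data$bases / total)
}

#' Exonic union length per gene
#'
#' Length of the union of all exons of a gene, the denominator used for RPKM.
#'
#' @param annotation Exon tibble.
#' @return Tibble `gene_id`, `exonic_length`.
#' @export
gene_exonic_lengths <- function(annotation) {
  annotation |>
    group_by(.data$gene_id) |>
    group_modify_keep(function(df) {
      red <- IRanges::reduce(IRanges::IRanges(df$start + 1L, df$end))
      tibble(gene_id = df$gene_id[1], exonic_length = sum(IRanges::width(red)))
    }) |>
    ungroup() |>
    select(gene_id = 1, exonic_length = 2)
}
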