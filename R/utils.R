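# Internal helpers shared across modules. All genomic coordinates inside the
# package are 0-based half-open [start, end); conversion to/from the 1-based
# closed convention happens only at GFF/GRanges/SAM boundaries.

# tibble of 0-based half-open intervals -> GRanges (1-based closed)
intervals_to_granges <- function(tbl) {
  strand <- if ("strand" %in% names(tbl)) {
    ifelse(tbl$strand %in% c("+", "-"), tbl$strand, "*")
  } else "*"
  GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end),
    strand = strand
  )
}

granges_to_intervals <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ifelse(s == "*", "unknown", s)
  )
}

# validate a strand value vector
norm_strand <- function(x) {
  x <- as.character(x)
  x[!x %in% c("+", "-")] <- "unknown"
  x
}

assert_intervals <- function(tbl, what = "interval") {
  bad <- which(!(tbl$start >= 0 & tbl$start < tbl$end))
  if (length(bad) > 0) {
    stop(sprintf("%s with start >= end or negative start (first offender: row %d, [%s, %s))",
                 what, bad[1], tbl$start[bad[1]], tbl$end[bad[1]]), call. = FALSE)
  }
  invisible(tbl)
}

# deterministic writer: BED6, 0-based half-open (native BED convention)
#' Write intervals to a BED6 file
#'
#' Writes a deterministic (chrom, start sorted) BED6 file from a tibble of
#' 0-based half-open intervals. `name`, `score` and `strand` columns are used
#' when present.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand` columns.
#' @param path Output file path.
#' @return The input, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  assert_intervals(intervals, "BED interval")
  out <- tibble(
    chrom = intervals$chrom,
    start = intervals$start,
    end = intervals$end,
    name = if ("name" %in% names(intervals)) intervals$name else ".",
    score = if ("score" %in% names(intervals)) intervals$score else 0,
    strand = if ("strand" %in% names(intervals)) {
      ifelse(intervals$strand %in% c("+", "-"), intervals$strand, ".")
    } else "."
  )
  out <- arrange(out, .data$chrom, .data$start, .data$end)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(intervals)
}

#' Read a BED6 file into an interval tibble
#'
#' @param path BED file path.
#' @return Tibble with `chrom`, `start`, `end`, `name`, `score`, `strand`
#'   (0-based half-open; BED is already half-open so no shift is applied).
#' @export
read_bed <- function(path) {
  cols <- readr::cols(
    X1 = readr::col_character(), X2 = readr::col_integer(),
    X3 = readr::col_integer(), X4 = readr::col_character(),
    X5 = readr::col_double(), X6 = readr::col_character()
  )
  x <- readr::read_tsv(path, col_names = FALSE, col_types = cols, progress = FALSE)
  tibble(
    chrom = x$X1, start = x$X2, end = x$X3,
    name = x$X4, score = x$X5, strand = norm_strand(x$X6)
  )
}

# seeded RNG scope: runs code with a local seed without disturbing the
# caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# substring of a genome (named character vector of chrom sequences),
# 0-based half-open
genome_sub <- function(genome, chrom, start, end) {
  substr(genome[[chrom]], start + 1L, end)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}
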