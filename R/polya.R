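# Poly(A)/poly(T) tail analysis: tail detection on soft-clipped read ends,
# pA-finder-style tail length measurement on raw read sequence, internal
# priming filtering against the genome, single-linkage clustering of tail-read
# anchors into polyadenylation sites (PAS), and lncRNA transcription-direction
# inference from PAS evidence.

# maximal terminal segment of `s` (from the given side) whose target-base
# fraction is >= 1 - error_rate and which terminates in >= 3 consecutive
# target bases; returns c(length, mismatches) or NULL
terminal_tail_segment <- function(s, base, side, error_rate = 0.1) {
  n <- nchar(s)
  if (n == 0) return(NULL)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  # scan from the read terminus inward: for a right-side tail the terminus is
  # the last character, for a left-side tail the first
  if (side == "right") v <- rev(v)
  is_b <- v == base
  if (!(length(v) >= 3 && all(is_b[1:3]))) return(NULL)
  cum <- cumsum(is_b)
  lens <- seq_along(v)
  ok <- cum / lens >= 1 - error_rate
  if (!any(ok)) return(NULL)
  L <- max(lens[ok])
  while (L > 0 && !is_b[L]) L <- L - 1L  # the tail starts on a target base
  if (L == 0) return(NULL)
  c(length = L, mismatches = L - cum[L])
}

#' Detect a poly(A)/poly(T) tail on a read
#'
#' Scans the read (or soft-clip) ends: the right end for a poly(A) tail and
#' the left end for a poly(T) run (the reverse-complemented tail of a
#' minus-strand transcript). The tail is the maximal terminal segment whose
#' A (resp. T) fraction is at least `1 - error_rate` and which ends in at
#' least 3 consecutive A/T. A tail is accepted iff its length is strictly
#' greater than `min_tail`.
#'
#' @param sequence Read or soft-clip sequence.
#' @param min_tail Tail length must exceed this (default 10).
#' @param error_rate Allowed mismatch fraction inside the tail (default 0.1).
#' @return One-row tibble `tail_kind` (`A`/`T`), `tail_length`,
#'   `mismatches_in_tail`, `side` — or `NULL` when no tail qualifies. When
#'   both ends qualify the longer tail wins.
#' @export
detect_tail <- function(sequence, min_tail = 10, error_rate = 0.1) {
  right <- terminal_tail_segment(sequence, "A", "right", error_rate)
  left <- terminal_tail_segment(sequence, "T", "left", error_rate)
  cand <- list()
  if (!is.null(right) && right[["length"]] > min_tail) {
    cand$A <- tibble(tail_kind = "A", tail_length = right[["length"]],
                     mismatches_in_tail = right[["mismatches"]], side = "right")
  }
  if (!is.null(left) && left[["length"]] > min_tail) {
    cand$T <- tibble(tail_kind = "T", tail_length = left[["length"]],
                     mismatches_in_tail = left[["mismatches"]], side = "left")
  }
  if (length(cand) == 0) return(NULL)
  out <- bind_rows(cand)
  out[which.max(out$tail_length), ]
}

#' Detect tails on all alignments
#'
#' Applies [detect_tail()] to the soft-clipped ends of each alignment: the 3'
#' (right) clip is scanned for poly(A) and the 5' (left) clip for poly(T).
#' The anchor is the genomic coordinate of the aligned end adjacent to the
#' clip. Tails on reads whose aligned portion is shorter than
#' `min_aligned` nt are dropped (too little anchor sequence for PAS use).
#'
#' @param alignments Alignment tibble.
#' @param min_tail,error_rate Tail acceptance rule (see [detect_tail()]).
#' @param min_aligned Minimal aligned (non-tail) length (default 20).
#' @return Tail tibble: `read_id`, `sample_id`, `chrom`, `tail_kind`,
#'   `tail_length`, `mismatches_in_tail`, `anchor_pos`, `anchor_side`.
#' @export
detect_tails <- function(alignments, min_tail = 10, error_rate = 0.1,
                         min_aligned = 20) {
  alen <- aligned_length(alignments)
  empty <- tibble(read_id = character(), sample_id = character(),
                  chrom = character(), tail_kind = character(),
                  tail_length = integer(), mismatches_in_tail = integer(),
                  anchor_pos = integer(), anchor_side = character())

  scan_side <- function(clips, base, side) {
    cand <- which(alen >= min_aligned & nchar(clips) > min_tail)
    if (length(cand) == 0) return(empty)
    segs <- lapply(cand, function(i) {
      terminal_tail_segment(clips[i], base, side, error_rate)
    })
    ok <- vapply(segs, function(s) !is.null(s) && s[["length"]] > min_tail,
                 logical(1))
    cand <- cand[ok]; segs <- segs[ok]
    if (length(cand) == 0) return(empty)
    tibble(
      read_id = alignments$read_id[cand],
      sample_id = alignments$sample_id[cand],
      chrom = alignments$chrom[cand],
      tail_kind = base,
      tail_length = vapply(segs, `[[`, numeric(1), "length"),
      mismatches_in_tail = vapply(segs, `[[`, numeric(1), "mismatches"),
      anchor_pos = if (side == "right") alignments$end[cand] else
        alignments$start[cand],
      anchor_side = side
    )
  }
  a_tails <- scan_side(alignments$soft_clip_3, "A", "right")
  t_tails <- scan_side(alignments$soft_clip_5, "T", "left")
  # a read contributes at most one tail; A (3') evidence wins if both
  t_tails <- t_tails |> filter(!.data$read_id %in% a_tails$read_id)
  bind_rows(a_tails, t_tails)
}

#' Measure poly(A) region length on a raw read sequence
#'
#' A candidate region is the maximal substring that begins and ends with a
#' run of at least 5 consecutive A and whose internal non-A fraction is at
#' most `error_rate`. Returns the region length, or `NA` when no region
#' exists.
#'
#' @param sequence Raw read sequence.
#' @param min_run Flanking A-run length (default 5).
#' @param error_rate Maximal non-A fraction inside the region (default 0.1).
#' @return Integer region length or `NA_integer_`.
#' @export
measure_tail_length <- function(sequence, min_run = 5, error_rate = 0.1) {
  v <- strsplit(sequence, "", fixed = TRUE)[[1]]
  r <- rle(v == "A")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_run)
  if (length(runs) == 0) return(NA_integer_)
  cumA <- cumsum(v == "A")
  best <- NA_integer_
  for (i in runs) {
    for (j in rev(runs[runs >= i])) {
      a <- starts[i]; b <- ends[j]
      len <- b - a + 1L
      nA <- cumA[b] - if (a > 1) cumA[a - 1] else 0L
      if ((len - nA) / len <= error_rate) {
        if (is.na(best) || len > best) best <- len
        break  # widest region for this start already found
      }
    }
  }
  best
}

#' Filter internal-priming artifacts
#'
#' A tail whose adjacent genomic sequence is A-rich is genomically templated
#' (internal priming), not a true tail. For an A-tail the `window` nt of
#' genome beyond the right anchor are examined (T and the window to the left
#' for T-tails); the tail is discarded when the fraction of matching bases in
#' the available window is at least `min_a / window` (default 7/10). Windows
#' truncated at a contig edge are judged on the available bases.
#'
#' @param tails Tail tibble ([detect_tails()]).
#' @param genome Named character vector or DNAStringSet.
#' @param window Window size in nt (default 10).
#' @param min_a Matching bases in a full window that trigger discarding
#'   (default 7).
#' @return `tails` with a logical `keep` column.
#' @export
internal_priming_filter <- function(tails, genome, window = 10, min_a = 7) {
  genome <- as_genome(genome)
  frac_cut <- min_a / window
  keep <- vapply(seq_len(nrow(tails)), function(i) {
    chrom <- tails$chrom[i]
    clen <- nchar(genome[[chrom]])
    if (tails$tail_kind[i] == "A") {
      s <- tails$anchor_pos[i]; e <- min(s + window, clen)
      base <- "A"
    } else {
      e <- tails$anchor_pos[i]; s <- max(0L, e - window)
      base <- "T"
    }
    if (e <= s) return(TRUE)  # no genomic window available
    w <- strsplit(genome_sub(genome, chrom, s, e), "", fixed = TRUE)[[1]]
    mean(w == base) < frac_cut
  }, logical(1))
  mutate(tails, keep = keep)
}

#' Cluster tail-read anchors into polyadenylation sites
#'
#' Single-linkage clustering of anchor positions along each chromosome,
#' separately per tail kind: anchors within `max_gap` bp of a cluster member
#' join the cluster (chains merge). The representative position is the modal
#' anchor (ties broken toward the smallest coordinate); the inferred strand is
#' `+` for A-supported and `-` for T-supported clusters.
#'
#' @param tails Filtered tail tibble (rows with `keep == FALSE` are dropped
#'   if the column is present).
#' @param max_gap Single-linkage distance (default 20 bp).
#' @return PAS tibble: `chrom`, `kind`, `position` (representative), `start`,
#'   `end` (span), `support`, `inferred_strand`, sorted by position.
#' @export
cluster_pas <- function(tails, max_gap = 20) {
  if ("keep" %in% names(tails)) tails <- filter(tails, .data$keep)
  if (nrow(tails) == 0) {
    return(tibble(chrom = character(), kind = character(), position = integer(),
                  start = integer(), end = integer(), support = integer(),
                  inferred_strand = character()))
  }
  srt <- tails[order(tails$chrom, tails$tail_kind, tails$anchor_pos), ]
  pos <- srt$anchor_pos
  new_cluster <- c(TRUE, srt$chrom[-1] != srt$chrom[-nrow(srt)] |
                     srt$tail_kind[-1] != srt$tail_kind[-nrow(srt)] |
                     diff(pos) > max_gap)
  cl <- cumsum(new_cluster)
  first <- which(new_cluster)
  last <- c(first[-1] - 1L, length(cl))
  # modal anchor per cluster, ties toward the smallest coordinate: within a
  # cluster positions are sorted, so the first run of maximal length wins
  rep_pos <- vapply(seq_along(first), function(k) {
    p <- pos[first[k]:last[k]]
    r <- rle(p)
    r$values[which.max(r$lengths)]
  }, numeric(1))
  tibble(
    chrom = srt$chrom[first],
    kind = srt$tail_kind[first],
    position = as.integer(rep_pos),
    start = pos[first],
    end = pos[last] + 1L,
    support = last - first + 1L,
    inferred_strand = ifelse(srt$tail_kind[first] == "A", "+", "-")
  ) |>
    arrange(.data$chrom, .data$position)
}

#' Infer lncRNA transcription direction from PAS evidence
#'
#' A transcript's polyadenylation site sits just beyond its 3' end, so PAS
#' evidence near a candidate boundary reveals its strand. Rule table (each
#' within `max_distance` nt of the boundary): an A-supported cluster beyond
#' the reference-right end supports `+`; a T-supported cluster beyond the
#' reference-left end supports `-` (the 5' poly(T) run of a minus-strand
#' transcript); an A-supported cluster beyond the left end supports `-` and a
#' T-supported cluster beyond the right end supports `+` (poly(T) evidence
#' reverses the call). Conflicting evidence resolves to the side with larger
#' total support; exact ties stay `unknown`.
#'
#' @param candidates Candidate tibble (`chrom`, `start`, `end`).
#' @param clusters PAS tibble ([cluster_pas()]).
#' @param max_distance Maximal distance from the candidate boundary
#'   (default 200 nt).
#' @param boundary_slack Tolerance (nt) for cluster representatives falling
#'   just inside the candidate boundary — cleavage microheterogeneity and
#'   assembly edge effects place the modal anchor a few nt inward
#'   (default 20).
#' @return `candidates` with `strand_call` and `direction_support` columns,
#'   plus an `assigned_fraction` attribute.
#' @export
assign_direction <- function(candidates, clusters, max_distance = 200,
                             boundary_slack = 20) {
  call_one <- function(chrom, s, e) {
    cl <- clusters[clusters$chrom == chrom, ]
    if (nrow(cl) == 0) return(list("unknown", 0L))
    right <- cl$position >= e - boundary_slack & cl$position - e <= max_distance
    left <- cl$position <= s + boundary_slack & s - cl$position <= max_distance
    # rule table: A beyond the right end and T beyond the right end -> "+";
    # T beyond the left end and A beyond the left end -> "-"
    plus <- sum(cl$support[right & cl$kind == "A"]) +
      sum(cl$support[right & cl$kind == "T"])
    minus <- sum(cl$support[left & cl$kind == "T"]) +
      sum(cl$support[left & cl$kind == "A"])
    if (plus == 0 && minus == 0) return(list("unknown", 0L))
    if (plus == minus) return(list("unknown", as.integer(plus + minus)))
    list(if (plus > minus) "+" else "-", as.integer(plus + minus))
  }
  calls <- purrr::pmap(list(candidates$chrom, candidates$start, candidates$end),
                       call_one)
  out <- candidates |>
    mutate(strand_call = purrr::map_chr(calls, 1),
           direction_support = purrr::map_int(calls, 2))
  attr(out, "assigned_fraction") <- mean(out$strand_call != "unknown")
  out
}

#' Per-sample and per-group mean tail lengths with a trend test
#'
#' Summarises tail lengths per sample, then tests for a time trend within
#' each sex by one-way ANOVA on the per-sample means across timepoints.
#'
#' @param tails Tail tibble with `sample_id`, `tail_length`.
#' @param samples Sample sheet (`sample_id`, `sex`, `hours`).
#' @return List: `per_sample` (mean/median/n per sample), `anova` (per sex:
#'   F statistic and p-value across timepoints).
#' @export
mean_tail_length_by_group <- function(tails, samples) {
  if (nrow(tails) == 0) stop("no tails", call. = FALSE)
  per_sample <- tails |>
    group_by(.data$sample_id) |>
    summarise(mean_length = mean(.data$tail_length),
              median_length = median(.data$tail_length),
              n = n(), .groups = "drop") |>
    inner_join(samples, by = "sample_id")
  missing <- setdiff(samples$sample_id, per_sample$sample_id)
  if (length(missing) > 0) {
    warning("samples without tails excluded: ", paste(missing, collapse = ", "))
  }
  anova_tbl <- per_sample |>
    group_by(.data$sex) |>
    group_modify_keep(function(df) {
      if (length(unique(df$hours)) < 2 || nrow(df) < 3) {
        return(tibble(sex = df$sex[1], f_statistic = NA_real_, p_value = NA_real_))
      }
      a <- anova(aov(mean_length ~ factor(hours), data = df))
      tibble(sex = df$sex[1], f_statistic = a$`F value`[1],
             p_value = a$`Pr(>F)`[1])
    }) |>
    ungroup()
  list(per_sample = per_sample, anova = anova_tbl)
}
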