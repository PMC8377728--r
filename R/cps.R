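# Coding potential score (CPS). A logistic classifier over four sequence
# features -- longest-ORF length, ORF coverage, Fickett TESTCODE statistic and
# a hexamer usage log-ratio -- trained on annotation-derived coding mRNAs
# versus dinucleotide-shuffled decoys. High CPS marks coding sequences;
# candidates with CPS >= cutoff (default 0.5) are removed from the lncRNA set.

BASES <- c("A", "C", "G", "T")

# Fickett (1982) TESTCODE lookup tables (position and composition parameters)
.fickett <- list(
  pos_prob = list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
  ),
  pos_weight = c(A = 0.26, C = 0.18, G = 0.31, T = 0.33),
  pos_para = c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0),
  content_prob = list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
  ),
  content_weight = c(A = 0.11, C = 0.12, G = 0.15, T = 0.14),
  content_para = c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0)
)

#' Fickett TESTCODE statistic
#'
#' Position-asymmetry and composition statistic separating coding from
#' non-coding sequence, computed with the standard published lookup tables.
#' Higher values indicate coding-like periodicity.
#'
#' @param seq A single DNA string (ACGT; other letters are ignored).
#' @return The TESTCODE score (roughly 0.2-1.3).
#' @export
fickett_testcode <- function(seq) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  keep <- v %in% BASES
  v <- v[keep]
  if (length(v) < 6) return(0)
  phase <- (seq_along(v) - 1L) %% 3L
  score <- 0
  for (b in BASES) {
    cnt <- vapply(0:2, function(p) sum(v == b & phase == p), numeric(1))
    pos_val <- max(cnt) / (min(cnt) + 1)
    idx <- which(pos_val >= .fickett$pos_para)[1]
    score <- score + .fickett$pos_prob[[b]][idx] * .fickett$pos_weight[[b]]
    comp <- sum(v == b) / length(v)
    idx <- which(comp >= .fickett$content_para)[1]
    score <- score + .fickett$content_prob[[b]][idx] * .fickett$content_weight[[b]]
  }
  score
}

# longest ORF over six frames; returns list(length, orf_seq)
longest_orf <- function(seq) {
  best_len <- 0L; best_seq <- ""
  for (s in c(seq, revcomp(seq))) {
    n <- nchar(s)
    for (f in 0:2) {
      ncod <- (n - f) %/% 3L
      if (ncod < 2) next
      codons <- substring(s, f + 1L + 3L * (0:(ncod - 1L)),
                          f + 3L + 3L * (0:(ncod - 1L)))
      is_start <- codons == "ATG"
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      if (!any(is_start)) next
      stop_idx <- which(is_stop)
      starts <- which(is_start)
      # next stop at or after each start; ORF runs to sequence end if none
      nxt <- stop_idx[findInterval(starts - 1L, stop_idx) + 1L]
      ends <- ifelse(is.na(nxt), ncod, nxt)
      lens <- (ends - starts + 1L) * 3L
      # keep the first (5'-most) longest ORF
      i <- which.max(lens)
      if (lens[i] > best_len) {
        best_len <- as.integer(lens[i])
        best_seq <- paste(codons[starts[i]:ends[i]], collapse = "")
      }
    }
  }
  list(length = best_len, orf = best_seq)
}

# in-frame hexamer table of a sequence (codon-phase hexamers, step 3)
inframe_hexamers <- function(seq) {
  n <- nchar(seq)
  if (n < 6) return(character(0))
  starts <- seq(1L, n - 5L, by = 3L)
  substring(seq, starts, starts + 5L)
}

# first-order Markov resample preserving dinucleotide composition
dinucleotide_shuffle <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  v <- v[v %in% BASES]
  n <- length(v)
  if (n < 10) return(paste(v, collapse = ""))
  trans <- table(factor(v[-n], BASES), factor(v[-1], BASES)) + 0.1
  out <- character(n)
  out[1] <- v[1]
  for (i in 2:n) {
    out[i] <- sample(BASES, 1, prob = trans[out[i - 1], ])
  }
  paste(out, collapse = "")
}

cps_features <- function(seqs, hex_table) {
  purrr::map_dfr(seqs, function(s) {
    orf <- longest_orf(s)
    hx <- inframe_hexamers(orf$orf)
    hs <- hex_table[hx]
    tibble(
      orf_length = log10(orf$length + 1),
      orf_coverage = orf$length / nchar(s),
      fickett = fickett_testcode(s),
      hexamer = if (length(hs) && any(!is.na(hs))) mean(hs, na.rm = TRUE) else 0
    )
  })
}

#' Train the coding potential score model
#'
#' Extracts the spliced mRNA sequences of annotated coding transcripts from
#' the genome, builds dinucleotide-shuffled decoys of the same lengths, fits a
#' hexamer usage log-ratio table (coding ORFs versus decoys) and a logistic
#' regression on the four CPS features. Training is seeded for
#' reproducibility.
#'
#' @param genome Named character vector of chromosome sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param annotation Exon tibble; transcripts with `biotype == "coding"` are
#'   the positive class.
#' @param seed Integer seed for decoy generation.
#' @return List of class `mzt_cps_model`: `glm` coefficients, hexamer table,
#'   and training summary.
#' @export
train_cps <- function(genome, annotation, seed = 1) {
  genome <- as_genome(genome)
  coding <- annotation |> filter(.data$biotype == "coding")
  if (nrow(coding) == 0) stop("annotation has no coding transcripts", call. = FALSE)
  pos_seqs <- transcript_sequences(genome, coding)
  pos_seqs <- pos_seqs[nchar(pos_seqs) >= 200]
  if (length(pos_seqs) < 5) stop("too few coding transcripts to train on", call. = FALSE)

  with_seed(seed, {
    neg_seqs <- vapply(pos_seqs, dinucleotide_shuffle, character(1),
                       USE.NAMES = FALSE)

    pos_hex <- unlist(purrr::map(pos_seqs, ~ inframe_hexamers(longest_orf(.x)$orf)))
    neg_hex <- unlist(purrr::map(neg_seqs, inframe_hexamers))
    all_hex <- sort(unique(c(pos_hex, neg_hex)))
    fp <- table(factor(pos_hex, all_hex)) + 1
    fn <- table(factor(neg_hex, all_hex)) + 1
    hex_table <- setNames(as.numeric(log((fp / sum(fp)) / (fn / sum(fn)))),
                          all_hex)

    feats <- bind_rows(cps_features(pos_seqs, hex_table),
                       cps_features(neg_seqs, hex_table))
    y <- c(rep(1L, length(pos_seqs)), rep(0L, length(neg_seqs)))
    fit <- suppressWarnings(glm(y ~ ., data = cbind(feats, y = y),
                                family = binomial()))
    pred <- predict(fit, type = "response")
    structure(list(
      coefficients = coef(fit),
      hexamer_table = hex_table,
      training = tibble(n_coding = length(pos_seqs),
                        n_decoy = length(neg_seqs),
                        accuracy = mean((pred > 0.5) == (y == 1))),
      seed = seed
    ), class = "mzt_cps_model")
  })
}

#' Coding potential score
#'
#' Logistic score between 0 and 1; sequences scoring at or above the cutoff are
#' treated as coding and filtered out of the lncRNA candidate set.
#'
#' @param sequences Character vector of DNA sequences (>= 200 nt, ACGTN).
#' @param model `mzt_cps_model` from [train_cps()].
#' @return Numeric vector of scores between 0 and 1.
#' @export
coding_potential_score <- function(sequences, model) {
  stopifnot(inherits(model, "mzt_cps_model"))
  frac_bad <- 1 - vapply(sequences, function(s) {
    v <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    mean(v %in% c(BASES, "N"))
  }, numeric(1))
  if (any(frac_bad > 0.1)) {
    stop("sequence with more than 10% non-ACGTN characters", call. = FALSE)
  }
  feats <- cps_features(toupper(sequences), model$hexamer_table)
  eta <- model$coefficients[1] +
    as.matrix(feats) %*% model$coefficients[c("orf_length", "orf_coverage",
                                              "fickett", "hexamer")]
  as.numeric(1 / (1 + exp(-eta)))
}

#' @export
tidy.mzt_cps_model <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @export
glance.mzt_cps_model <- function(x, ...) {
  x$training
}

# ---- sequence helpers --------------------------------------------------------

as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else if (is.character(genome)) {
    genome
  } else {
    stop("genome must be a named character vector or DNAStringSet", call. = FALSE)
  }
}

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of chromosome sequences.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as_genome(x)
}

# spliced transcript sequence (5'->3', i.e. reverse-complemented for minus
# strand) for every transcript in an exon tibble
transcript_sequences <- function(genome, annotation) {
  genome <- as_genome(genome)
  ann <- arrange(annotation, .data$transcript_id, .data$start)
  parts <- split(ann, ann$transcript_id)
  out <- vapply(parts, function(df) {
    s <- paste(substring(genome[[df$chrom[1]]], df$start + 1L, df$end),
               collapse = "")
    if (df$strand[1] == "-") revcomp(s) else s
  }, character(1))
  out
}
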