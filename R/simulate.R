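# Synthetic-data generator. Emulates the study design this package targets:
# single honeybee embryos of both sexes sampled at 24/48/72 h after egg
# laying from two queens, three zygotic activation waves plus maternal
# degradation, long (> 2,000 nt) introns hosting single- and multi-exon
# lncRNAs on both strands, spliced reads, and reads carrying non-genomic
# poly(A)/poly(T) tails including internal-priming artifacts. Every draw is
# fixed by the config seed; complete truth tables accompany the output.

#' Simulation configuration
#'
#' Builds the configuration object for the synthetic dataset. Defaults encode
#' the emulated study design: a 2 queens x 2 sexes x {24,48,72} h x 3
#' replicates single-embryo design (36 samples), coding genes assigned to
#' three female activation waves plus maternal degradation and constitutive
#' expression, planted lncRNAs of four locus classes, negative-binomial counts
#' (dispersion 0.1), 100-nt reads, male poly(A) tails lengthening over
#' development while female tails stay constant.
#'
#' @param seed Integer seed fixing every downstream draw.
#' @param n_genes Number of coding genes (default 33).
#' @param n_chroms Number of chromosomes (default 3).
#' @param exon_count_range,exon_length_range,intron_length_range Gene
#'   structure draws; `intron_length_range` must allow introns long enough to
#'   host planted lncRNAs.
#' @param n_long_introns Introns forced above 2,000 nt (hosts for intronic
#'   lncRNAs; default 16).
#' @param lncrna_counts Named vector: planted lncRNAs per class
#'   (`intronic_sense`, `intronic_antisense`, `intergenic`, `multi_exon`).
#' @param lncrna_length_range Planted single-exon lncRNA length range;
#'   straddles the 500/1,000-nt filter thresholds by default.
#' @param wave_counts Named vector of coding-gene label counts
#'   (`wave1`, `wave2`, `wave3`, `maternal_degradation`, `constant`).
#' @param off_on_fold Fold change between OFF and ON states of planted waves
#'   (default 8, comfortably above the x2 calling threshold).
#' @param md_decay Per-timepoint decay factor of maternal transcripts,
#'   named `female`/`male`; males decay slower.
#' @param base_abundance_range Per-transcript baseline abundance draw.
#' @param dispersion Negative-binomial dispersion of simulated counts.
#' @param read_length Read length in nt.
#' @param reads_per_sample Expected aligned reads per sample.
#' @param error_rate Uniform substitution rate on aligned read bases.
#' @param tail_read_fraction Fraction of a transcript's reads anchored at the
#'   3' end and carrying a non-genomic tail.
#' @param tail_length_mean Matrix (rows `female`,`male`; columns `24`,`48`,
#'   `72`) of mean tail lengths.
#' @param tail_length_sd Tail length standard deviation.
#' @param tail_mismatch_rate Per-base mismatch rate inside simulated tails.
#' @param anchor_jitter_max Maximal inward jitter (nt) of tail-read cleavage
#'   positions around the true polyadenylation site.
#' @param n_internal_priming_sites Genomic A15 runs planted inside expressed
#'   exons; reads ending there mimic internal priming.
#' @param artifact_reads_per_site Expected artifact reads per site per sample.
#' @param multi_map_fraction Fraction of reads flagged as multi-mapping.
#' @param queens,replicates Design dimensions.
#' @return A list of class `mzt_sim_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_genes = 33,
                              n_chroms = 3,
                              exon_count_range = c(2, 5),
                              exon_length_range = c(150, 500),
                              intron_length_range = c(300, 2600),
                              n_long_introns = 16,
                              lncrna_counts = c(intronic_sense = 8,
                                                intronic_antisense = 6,
                                                intergenic = 6,
                                                multi_exon = 5),
                              lncrna_length_range = c(550, 1500),
                              wave_counts = c(wave1 = 5, wave2 = 5, wave3 = 5,
                                              maternal_degradation = 6,
                                              constant = 12),
                              off_on_fold = 8,
                              md_decay = c(female = 4, male = 2),
                              base_abundance_range = c(40, 120),
                              dispersion = 0.1,
                              read_length = 100,
                              reads_per_sample = 6000,
                              error_rate = 0.002,
                              tail_read_fraction = 0.12,
                              tail_length_mean = rbind(female = c(30, 30, 30),
                                                       male = c(20, 30, 40)),
                              tail_length_sd = 4,
                              tail_mismatch_rate = 0.02,
                              anchor_jitter_max = 2,
                              n_internal_priming_sites = 8,
                              artifact_reads_per_site = 1.2,
                              multi_map_fraction = 0.01,
                              queens = c("P1", "P2"),
                              replicates = 3) {
  cfg <- as.list(environment())
  stopifnot(
    seed == as.integer(seed),
    n_genes > 0, n_chroms > 0,
    all(lncrna_counts >= 0), all(wave_counts >= 0),
    sum(wave_counts) == n_genes,
    off_on_fold >= 4,
    dispersion > 0, read_length > 40, reads_per_sample > 0,
    error_rate >= 0, error_rate < 0.05,
    tail_read_fraction >= 0, tail_read_fraction <= 1
  )
  n_intronic <- lncrna_counts[["intronic_sense"]] + lncrna_counts[["intronic_antisense"]]
  if (intron_length_range[2] < max(lncrna_length_range) + 40 ||
      n_long_introns < n_intronic) {
    stop("intron_length_range/n_long_introns too small to host the requested ",
         "intronic lncRNAs", call. = FALSE)
  }
  colnames(cfg$tail_length_mean) <- c("24", "48", "72")
  structure(cfg, class = "mzt_sim_config")
}

#' Sample sheet implied by a simulation config
#'
#' @param config `mzt_sim_config`.
#' @return Tibble `sample_id`, `queen`, `sex` (`F`/`M`), `hours`
#'   (24/48/72), `replicate`.
#' @export
sim_samples <- function(config) {
  tidyr::expand_grid(
    queen = config$queens, sex = c("F", "M"),
    hours = c(24L, 48L, 72L), replicate = seq_len(config$replicates)
  ) |>
    mutate(sample_id = sprintf("%s_%s%d_%d", .data$queen, .data$sex,
                               .data$hours, .data$replicate)) |>
    select("sample_id", "queen", "sex", "hours", "replicate")
}

# ---- genome construction ----------------------------------------------------

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(0.27, 0.23, 0.23, 0.27)), collapse = "")
}

# mRNA-like sequence of length n with an ORF spanning ~3/4 of it
orf_sequence <- function(n) {
  utr5 <- max(10L, round(n * 0.1))
  orf_len <- ((n - utr5 - 30L) %/% 3L) * 3L
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(matrix(sample(c("A", "C", "G", "T"), (orf_len / 3 - 2) * 3,
                                replace = TRUE), nrow = 3), 2, paste, collapse = "")
  codons[codons %in% stops] <- "AAG"
  orf <- paste0("ATG", paste(codons, collapse = ""), "TAA")
  tail_len <- n - utr5 - nchar(orf)
  paste0(random_dna(utr5), orf, random_dna(tail_len))
}

#' Build a toy genome, annotation, and planted lncRNA truth
#'
#' Deterministically (given the config seed) lays out coding genes and
#' lncRNA loci on `n_chroms` chromosomes. Coding exons carry genuine open
#' reading frames (so the coding-potential filter can be trained on them);
#' planted intronic lncRNAs lie fully inside one long intron of a coding
#' gene, antisense plants on the strand opposite their host. Alternative
#' isoforms (exon skipping, cassette exon, alternative 5'/3' splice sites,
#' intron retention) are planted on constitutively expressed genes. A15 runs
#' are written into expressed exons as internal-priming decoys, and the 10 nt
#' beyond every true polyadenylation site is set to a balanced sequence so
#' genuine tails survive the internal-priming filter.
#'
#' @param config `mzt_sim_config` from [simulation_config()].
#' @return List of class `mzt_toy_genome`: `genome` (named character vector),
#'   `seqlengths`, `annotation` (exon tibble of annotated coding isoforms),
#'   `transcripts` (all simulated transcripts incl. unannotated isoforms and
#'   lncRNAs, with exon list-column and truth labels), `truth_lncrnas`,
#'   `truth_ase`, `artifact_sites`, `config`.
#' @export
build_toy_genome <- function(config) {
  with_seed(config$seed, build_toy_genome_impl(config))
}

build_toy_genome_impl <- function(cfg) {
  n_wave <- cfg$wave_counts
  gene_labels <- sample(rep(names(n_wave), n_wave))
  # ASE isoforms are planted on constitutive genes so every sample has reads
  ase_types <- c("ES", "ES", "CE", "CE", "A5SS", "A5SS", "A3SS", "A3SS", "IR", "IR")
  const_idx <- which(gene_labels == "constant")
  ase_genes <- const_idx[seq_len(min(length(ase_types), length(const_idx)))]
  ase_types <- ase_types[seq_along(ase_genes)]

  # gene structures
  genes <- purrr::map(seq_len(cfg$n_genes), function(i) {
    n_ex <- sample(cfg$exon_count_range[1]:cfg$exon_count_range[2], 1)
    if (i %in% ase_genes) n_ex <- max(n_ex, 3L)
    list(
      gene_id = sprintf("gene%02d", i),
      label = gene_labels[i],
      strand = sample(c("+", "-"), 1),
      exon_len = sample(cfg$exon_length_range[1]:cfg$exon_length_range[2],
                        n_ex, replace = TRUE),
      intron_len = if (n_ex > 1) {
        sample(cfg$intron_length_range[1]:min(1800L, cfg$intron_length_range[2]),
               n_ex - 1, replace = TRUE)
      } else integer(0)
    )
  })
  # artifact-bearing genes must be constitutive and on the plus strand
  art_genes <- setdiff(const_idx, integer(0))
  for (i in head(art_genes, 4)) genes[[i]]$strand <- "+"

  # force long introns (> 2,000 nt) to host intronic lncRNAs
  slots <- purrr::map_dfr(seq_along(genes), function(i) {
    k <- length(genes[[i]]$intron_len)
    if (k == 0) return(tibble(gene = integer(0), intron = integer(0)))
    tibble(gene = i, intron = seq_len(k))
  })
  long_pick <- slots[sample(nrow(slots), min(cfg$n_long_introns, nrow(slots))), ]
  long_min <- max(2100L, max(cfg$lncrna_length_range) + 60L)
  for (r in seq_len(nrow(long_pick))) {
    g <- long_pick$gene[r]; k <- long_pick$intron[r]
    genes[[g]]$intron_len[k] <- sample(long_min:max(long_min + 500L,
                                                    cfg$intron_length_range[2]), 1)
  }

  # lncRNA loci
  lc <- cfg$lncrna_counts
  lnc_classes <- c(rep("intronic_sense", lc[["intronic_sense"]]),
                   rep("intronic_antisense", lc[["intronic_antisense"]]),
                   rep("intergenic", lc[["intergenic"]]),
                   rep("multi_exon", lc[["multi_exon"]]))
  lnc_labels_pool <- function(k, pool) pool[((seq_len(k) - 1) %% length(pool)) + 1]
  lnc_labels <- c(
    lnc_labels_pool(lc[["intronic_sense"]],
                    c("female_specific_lncRNA", "female_specific_lncRNA", "constant")),
    lnc_labels_pool(lc[["intronic_antisense"]],
                    c("female_specific_lncRNA", "female_specific_lncRNA", "constant")),
    lnc_labels_pool(lc[["intergenic"]],
                    c("female_specific_lncRNA", "constant", "male_late")),
    lnc_labels_pool(lc[["multi_exon"]],
                    c("female_specific_lncRNA", "female_specific_lncRNA", "constant"))
  )

  # chromosome layout: genes and standalone lncRNA loci left to right
  n_standalone <- lc[["intergenic"]] + lc[["multi_exon"]]
  locus_kind <- sample(c(rep("gene", cfg$n_genes), rep("lnc", n_standalone)))
  gene_queue <- sample(seq_len(cfg$n_genes))
  lnc_queue <- sample(which(lnc_classes %in% c("intergenic", "multi_exon")))

  chrom_of <- rep(seq_len(cfg$n_chroms), length.out = length(locus_kind))
  chrom_of <- sort(chrom_of)

  tx <- list(); ann_rows <- list(); cursor <- integer(cfg$n_chroms)
  gq <- 1L; lq <- 1L
  gap <- function() sample(800:2000, 1)
  gene_meta <- vector("list", cfg$n_genes)

  for (li in seq_along(locus_kind)) {
    ch <- chrom_of[li]
    chrom <- sprintf("chr%d", ch)
    pos <- cursor[ch] + gap()
    if (locus_kind[li] == "gene") {
      gi <- gene_queue[gq]; gq <- gq + 1L
      g <- genes[[gi]]
      n_ex <- length(g$exon_len)
      starts <- integer(n_ex); ends <- integer(n_ex)
      p <- pos
      for (k in seq_len(n_ex)) {
        starts[k] <- p; ends[k] <- p + g$exon_len[k]
        p <- ends[k] + if (k < n_ex) g$intron_len[k] else 0L
      }
      gene_meta[[gi]] <- list(chrom = chrom, starts = starts, ends = ends,
                              strand = g$strand, label = g$label,
                              gene_id = g$gene_id)
      cursor[ch] <- ends[n_ex]
    } else {
      i <- lnc_queue[lq]; lq <- lq + 1L
      cls <- lnc_classes[i]
      strand <- sample(c("+", "-"), 1)
      if (cls == "intergenic") {
        len <- sample(cfg$lncrna_length_range[1]:cfg$lncrna_length_range[2], 1)
        exons <- cbind(start = pos, end = pos + len)
        cursor[ch] <- pos + len
      } else { # multi_exon, placed intergenically
        n_ex <- sample(2:3, 1)
        el <- sample(250:500, n_ex, replace = TRUE)
        il <- sample(300:800, n_ex - 1, replace = TRUE)
        starts <- integer(n_ex); ends <- integer(n_ex); p <- pos
        for (k in seq_len(n_ex)) {
          starts[k] <- p; ends[k] <- p + el[k]
          p <- ends[k] + if (k < n_ex) il[k] else 0L
        }
        exons <- cbind(start = starts, end = ends)
        cursor[ch] <- ends[n_ex]
      }
      tx[[length(tx) + 1]] <- tibble(
        transcript_id = sprintf("lnc%02d", i), gene_id = sprintf("lnc%02d", i),
        biotype = "lncRNA", label = lnc_labels[i], chrom = chrom,
        strand = strand, exons = list(exons), lnc_class = cls,
        host_gene = NA_character_, annotated = FALSE
      )
    }
  }
  seqlengths <- setNames(cursor + 1500L, sprintf("chr%d", seq_len(cfg$n_chroms)))

  # intronic lncRNAs: one per distinct long intron
  intr_idx <- which(lnc_classes %in% c("intronic_sense", "intronic_antisense"))
  host_rows <- long_pick[sample(nrow(long_pick), length(intr_idx)), ]
  for (j in seq_along(intr_idx)) {
    i <- intr_idx[j]
    g <- host_rows$gene[j]; k <- host_rows$intron[j]
    gm <- gene_meta[[g]]
    istart <- gm$ends[k]; iend <- gm$starts[k + 1]
    len <- sample(cfg$lncrna_length_range[1]:cfg$lncrna_length_range[2], 1)
    margin <- iend - istart - len
    off <- sample(20:max(20, margin - 20), 1)
    s <- istart + off
    strand <- if (lnc_classes[i] == "intronic_sense") gm$strand else
      setdiff(c("+", "-"), gm$strand)
    tx[[length(tx) + 1]] <- tibble(
      transcript_id = sprintf("lnc%02d", i), gene_id = sprintf("lnc%02d", i),
      biotype = "lncRNA", label = lnc_labels[i], chrom = gm$chrom,
      strand = strand, exons = list(cbind(start = s, end = s + len)),
      lnc_class = lnc_classes[i], host_gene = gm$gene_id, annotated = FALSE
    )
  }

  # coding transcripts (isoform A everywhere; isoform B on ASE genes)
  for (gi in seq_len(cfg$n_genes)) {
    gm <- gene_meta[[gi]]
    exons <- cbind(start = gm$starts, end = gm$ends)
    tx[[length(tx) + 1]] <- tibble(
      transcript_id = paste0(gm$gene_id, ".A"), gene_id = gm$gene_id,
      biotype = "coding", label = gm$label, chrom = gm$chrom,
      strand = gm$strand, exons = list(exons), lnc_class = NA_character_,
      host_gene = NA_character_, annotated = TRUE
    )
  }
  truth_ase <- tibble(gene_id = character(), type = character(),
                      chrom = character(), coord = integer())
  for (j in seq_along(ase_genes)) {
    gi <- ase_genes[j]; ty <- ase_types[j]
    gm <- gene_meta[[gi]]
    exons <- cbind(start = gm$starts, end = gm$ends)
    n_ex <- nrow(exons)
    annotatedB <- FALSE
    if (ty %in% c("ES", "CE")) {
      exB <- exons[-2, , drop = FALSE]          # skip exon 2
      annotatedB <- ty == "CE"                   # CE: skipping is annotated
      coord <- exons[2, 1]
    } else if (ty == "A5SS") {
      exB <- exons
      shift <- 40L
      if (gm$strand == "+") exB[1, 2] <- exB[1, 2] - shift  # alt donor
      else exB[n_ex, 1] <- exB[n_ex, 1] + shift
      coord <- if (gm$strand == "+") exB[1, 2] else exB[n_ex, 1]
    } else if (ty == "A3SS") {
      exB <- exons
      shift <- 40L
      if (gm$strand == "+") exB[2, 1] <- exB[2, 1] + shift  # alt acceptor
      else exB[n_ex - 1, 2] <- exB[n_ex - 1, 2] - shift
      coord <- if (gm$strand == "+") exB[2, 1] else exB[n_ex - 1, 2]
    } else { # IR: retain intron 2 (or intron 1 for 2-intron genes)
      ki <- min(2L, n_ex - 1L)
      exB <- exons
      exB[ki, 2] <- exB[ki + 1, 2]               # merge across the intron
      exB <- exB[-(ki + 1), , drop = FALSE]
      coord <- exons[ki, 2]
    }
    tx[[length(tx) + 1]] <- tibble(
      transcript_id = paste0(gm$gene_id, ".B"), gene_id = gm$gene_id,
      biotype = "coding", label = gm$label, chrom = gm$chrom,
      strand = gm$strand, exons = list(exB), lnc_class = NA_character_,
      host_gene = NA_character_, annotated = annotatedB
    )
    truth_ase <- bind_rows(truth_ase, tibble(
      gene_id = gm$gene_id, type = ty, chrom = gm$chrom, coord = coord))
  }
  transcripts <- bind_rows(tx)

  # genome sequence
  genome <- setNames(purrr::map_chr(seqlengths, random_dna), names(seqlengths))

  # write ORF-bearing mRNA sequence into annotated coding isoform A exons
  put <- function(chrom, start, s) {
    substr(genome[[chrom]], start + 1L, start + nchar(s)) <<- s
    invisible(NULL)
  }
  for (gi in seq_len(cfg$n_genes)) {
    gm <- gene_meta[[gi]]
    tx_len <- sum(gm$ends - gm$starts)
    mrna <- orf_sequence(tx_len)
    if (gm$strand == "-") mrna <- revcomp(mrna)
    # mrna is laid down in genomic (forward) orientation across the exons
    off <- 0L
    for (k in seq_along(gm$starts)) {
      w <- gm$ends[k] - gm$starts[k]
      put(gm$chrom, gm$starts[k], substr(mrna, off + 1L, off + w))
      off <- off + w
    }
  }

  # canonical splice motifs (GT..AG on +, CT..AC on -) at every intron of an
  # annotated or lncRNA transcript, so junction strand is inferable
  for (r in seq_len(nrow(transcripts))) {
    ex <- transcripts$exons[[r]]
    if (nrow(ex) < 2) next
    chrom <- transcripts$chrom[r]
    for (k in seq_len(nrow(ex) - 1)) {
      istart <- ex[k, 2]; iend <- ex[k + 1, 1]
      if (iend - istart < 8) next
      if (transcripts$strand[r] == "+") {
        put(chrom, istart, "GT"); put(chrom, iend - 2L, "AG")
      } else {
        put(chrom, istart, "CT"); put(chrom, iend - 2L, "AC")
      }
    }
  }

  # balanced sequence beyond every transcript 3' end so true tails pass the
  # internal-priming filter
  flank <- "GCTAGCTAGC"
  for (r in seq_len(nrow(transcripts))) {
    ex <- transcripts$exons[[r]]
    chrom <- transcripts$chrom[r]
    if (transcripts$strand[r] == "+") {
      p <- max(ex[, 2])
      if (p + 10 <= seqlengths[[chrom]]) put(chrom, p, flank)
    } else {
      p <- min(ex[, 1]) - 10L
      if (p >= 0) put(chrom, p, flank)
    }
  }

  # internal-priming decoys: A15 runs inside plus-strand constitutive exons
  art_hosts <- transcripts |>
    filter(.data$biotype == "coding", .data$label == "constant",
           .data$strand == "+", grepl("\\.A$", .data$transcript_id))
  artifact_sites <- tibble(transcript_id = character(), chrom = character(),
                           genomic_pos = integer(), tx_pos = integer())
  n_sites <- cfg$n_internal_priming_sites
  if (nrow(art_hosts) > 0 && n_sites > 0) {
    hosts <- art_hosts[rep(seq_len(nrow(art_hosts)), length.out = n_sites), ]
    for (r in seq_len(nrow(hosts))) {
      ex <- hosts$exons[[r]]
      widths <- ex[, 2] - ex[, 1]
      cum <- c(0L, cumsum(widths))
      L <- sum(widths)
      # stay >= read_length into the transcript and >= 20 nt inside one exon
      ok_ex <- which(widths >= 60 & cum[-length(cum)] + 40 >= 0)
      k <- ok_ex[length(ok_ex)]  # late exon, deterministic
      tx_pos <- min(cum[k] + (widths[k] %/% 2L), L - 20L)
      tx_pos <- max(tx_pos, cfg$read_length)
      if (tx_pos > L - 16L) next
      gpos <- ex[k, 1] + (tx_pos - cum[k])
      put(hosts$chrom[r], gpos, strrep("A", 15))
      artifact_sites <- bind_rows(artifact_sites, tibble(
        transcript_id = hosts$transcript_id[r], chrom = hosts$chrom[r],
        genomic_pos = as.integer(unname(gpos)), tx_pos = as.integer(tx_pos)))
    }
    artifact_sites <- distinct(artifact_sites,
                               .data$transcript_id, .data$genomic_pos,
                               .keep_all = TRUE)
  }

  annotation <- transcripts |>
    filter(.data$annotated) |>
    transcripts_to_annotation()

  truth_lncrnas <- transcripts |>
    filter(.data$biotype == "lncRNA") |>
    mutate(start = purrr::map_int(.data$exons, ~ as.integer(min(.x[, 1]))),
           end = purrr::map_int(.data$exons, ~ as.integer(max(.x[, 2]))),
           n_exons = purrr::map_int(.data$exons, nrow),
           length = purrr::map_int(.data$exons, ~ as.integer(sum(.x[, 2] - .x[, 1])))) |>
    select("transcript_id", "chrom", "strand", "start", "end", "n_exons",
           "length", class = "lnc_class", "host_gene", "label")

  structure(list(
    genome = genome, seqlengths = seqlengths, annotation = annotation,
    transcripts = transcripts, truth_lncrnas = truth_lncrnas,
    truth_ase = truth_ase, artifact_sites = artifact_sites, config = cfg
  ), class = "mzt_toy_genome")
}

# transcripts tibble (exon list-column) -> exon tibble
transcripts_to_annotation <- function(transcripts) {
  purrr::map_dfr(seq_len(nrow(transcripts)), function(r) {
    ex <- transcripts$exons[[r]]
    tibble(
      transcript_id = transcripts$transcript_id[r],
      gene_id = transcripts$gene_id[r],
      chrom = transcripts$chrom[r],
      strand = transcripts$strand[r],
      start = as.integer(ex[, 1]), end = as.integer(ex[, 2]),
      exon_rank = seq_len(nrow(ex)),
      biotype = transcripts$biotype[r]
    )
  }) |>
    arrange(.data$chrom, .data$start, .data$transcript_id)
}

# ---- expression design ------------------------------------------------------

# multiplier of the baseline abundance for one label/sex/timepoint
pattern_multiplier <- function(label, sex, time_idx, fold, md_decay) {
  f <- fold
  female <- sex == "F"
  switch(label,
    wave1 = if (female) c(1, f, 1)[time_idx] else 1,
    wave2 = if (female) c(1, f, f)[time_idx] else 1,
    wave3 = if (female) c(1, 1, f)[time_idx] else 1,
    maternal_degradation = {
      d <- if (female) md_decay[["female"]] else md_decay[["male"]]
      f / d^(time_idx - 1)
    },
    constant = 3,
    female_specific_lncRNA = if (female) c(1, f, f)[time_idx] else 0,
    male_late = if (!female) c(1, 1, f)[time_idx] else 0,
    stop("unknown expression label: ", label, call. = FALSE)
  )
}

#' Simulate true expected abundances for the sex-by-time design
#'
#' Assigns each transcript a baseline abundance and modulates it by its
#' planted label: wave 1 genes are low at 24 h, high at 48 h and re-silenced
#' at 72 h in females only; wave 2 stays high through 72 h; wave 3 activates
#' only between 48 and 72 h; maternal transcripts start high and decay, more
#' slowly in males; female-specific lncRNAs have zero male abundance.
#'
#' @param toy `mzt_toy_genome` from [build_toy_genome()] (or any tibble with
#'   `transcript_id` and `label` via the `transcripts` element).
#' @param config Optional `mzt_sim_config`; defaults to `toy$config`.
#' @return Long tibble `transcript_id`, `sample_id`, `abundance` (expected
#'   relative abundance, arbitrary units).
#' @export
simulate_expression <- function(toy, config = toy$config) {
  with_seed(config$seed + 1L, {
    samples <- sim_samples(config)
    txs <- toy$transcripts
    base <- runif(nrow(txs), config$base_abundance_range[1],
                  config$base_abundance_range[2])
    # isoform split within a gene: A gets 60%, B 40%
    iso_b <- grepl("\\.B$", txs$transcript_id)
    base[iso_b] <- base[iso_b] * 0.4
    base[grepl("\\.A$", txs$transcript_id) &
           txs$gene_id %in% txs$gene_id[iso_b]] <-
      base[grepl("\\.A$", txs$transcript_id) &
             txs$gene_id %in% txs$gene_id[iso_b]] * 0.6
    time_idx <- match(samples$hours, c(24L, 48L, 72L))
    out <- tidyr::expand_grid(t = seq_len(nrow(txs)), s = seq_len(nrow(samples)))
    out$abundance <- purrr::map2_dbl(out$t, out$s, function(t, s) {
      base[t] * pattern_multiplier(txs$label[t], samples$sex[s], time_idx[s],
                                   config$off_on_fold, config$md_decay)
    })
    tibble(
      transcript_id = txs$transcript_id[out$t],
      sample_id = samples$sample_id[out$s],
      abundance = out$abundance
    )
  })
}

# ---- read simulation --------------------------------------------------------

# map transcript-coordinate reads [a, b) onto genomic blocks given the exon
# chain (genomic order); returns a long tibble with read index
tx_reads_to_blocks <- function(a, b, exons) {
  widths <- exons[, 2] - exons[, 1]
  cum <- c(0L, cumsum(widths))
  k1 <- findInterval(a, cum, rightmost.closed = FALSE)
  k2 <- findInterval(b - 1L, cum, rightmost.closed = FALSE)
  cnt <- k2 - k1 + 1L
  rd <- rep(seq_along(a), cnt)
  ke <- sequence(cnt) - 1L + rep(k1, cnt)
  s <- pmax(exons[ke, 1], exons[ke, 1] + (a[rd] - cum[ke]))
  e <- pmin(exons[ke, 2], exons[ke, 1] + (b[rd] - cum[ke]))
  list(read = rd, start = as.integer(s), end = as.integer(e))
}

# per-group paste of string pieces, cheap for mostly-single groups;
# `grp` must be sorted, pieces ordered within group
paste_by_group <- function(pieces, grp, n_groups) {
  out <- character(n_groups)
  nb <- tabulate(grp, n_groups)
  single <- nb[grp] == 1L
  out[grp[single]] <- pieces[single]
  if (any(!single)) {
    multi <- vapply(split(pieces[!single], grp[!single]), paste,
                    character(1), collapse = "")
    out[as.integer(names(multi))] <- multi
  }
  out
}

mutate_bases <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  n_mut <- rbinom(length(seqs), nchar(seqs), rate)
  hit <- which(n_mut > 0)
  for (i in hit) {
    pos <- sample.int(nchar(seqs[i]), n_mut[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
  }
  seqs
}

#' Simulate aligned reads with poly(A)/(T) tails and truth tables
#'
#' Draws per-transcript, per-sample counts negative-binomially around the
#' expected abundances, places reads uniformly along transcripts (spliced
#' reads follow the exon chain), anchors a configured fraction of reads at
#' the 3' end with a non-genomic poly(A) tail (written as a soft clip; on
#' minus-strand transcripts the tail appears as a 5' poly(T) run in reference
#' orientation), and adds internal-priming artifact reads whose "tails" are
#' genomically templated A-runs. Writes a sorted SAM file with per-sample
#' read groups.
#'
#' @param toy `mzt_toy_genome`.
#' @param abundance Output of [simulate_expression()].
#' @param sam_path Output SAM path (default `tempfile`).
#' @param fastq_path Optional FASTQ path for raw-read emission (tail scanner
#'   tests); default `NULL` skips it.
#' @param config Optional override of `toy$config`.
#' @return List of class `mzt_sim_reads`: `sam_path`, `samples`,
#'   `truth_counts` (realised reads per transcript per sample),
#'   `truth_tails`, `truth_pas`, `truth_junctions`.
#' @export
simulate_reads <- function(toy, abundance, sam_path = tempfile(fileext = ".sam"),
                           fastq_path = NULL, config = toy$config) {
  with_seed(config$seed + 2L,
            simulate_reads_impl(toy, abundance, sam_path, fastq_path, config))
}

simulate_reads_impl <- function(toy, abundance, sam_path, fastq_path, cfg) {
  samples <- sim_samples(toy$config)
  txs <- toy$transcripts
  rl <- cfg$read_length
  if (all(abundance$abundance == 0)) stop("zero total abundance", call. = FALSE)

  ab <- abundance |>
    group_by(.data$sample_id) |>
    mutate(mu = .data$abundance / sum(.data$abundance) * cfg$reads_per_sample) |>
    ungroup()
  ab$count <- ifelse(ab$mu > 0,
                     rnbinom(nrow(ab), mu = ab$mu, size = 1 / cfg$dispersion), 0L)
  truth_counts <- ab |> select("transcript_id", "sample_id", "count")

  tx_len <- vapply(txs$exons, function(m) sum(m[, 2] - m[, 1]), numeric(1))
  tx_idx <- setNames(seq_len(nrow(txs)), txs$transcript_id)

  # per-sample mean tail length (sex x timepoint)
  sex_name <- ifelse(samples$sex == "F", "female", "male")
  tmean_by_sample <- setNames(
    cfg$tail_length_mean[cbind(sex_name, as.character(samples$hours))],
    samples$sample_id)

  gen <- ab |> filter(.data$count > 0)
  n <- sum(gen$count)
  ri <- rep(seq_len(nrow(gen)), gen$count)
  t_of <- unname(tx_idx[gen$transcript_id[ri]])
  sid <- gen$sample_id[ri]
  L <- tx_len[t_of]
  strand <- txs$strand[t_of]
  chromv <- txs$chrom[t_of]

  is_tail <- runif(n) < cfg$tail_read_fraction & L >= rl
  tail_len <- integer(n)
  tail_len[is_tail] <- pmin(55L, pmax(12L, as.integer(round(
    rnorm(sum(is_tail), tmean_by_sample[sid[is_tail]], cfg$tail_length_sd)))))
  glen <- pmin(L, rl) - tail_len
  jit <- integer(n)
  jit[is_tail] <- sample(0:cfg$anchor_jitter_max, sum(is_tail), replace = TRUE)

  a <- integer(n); b <- integer(n)
  uni <- !is_tail
  a[uni] <- as.integer(floor(runif(sum(uni)) * pmax(1, L[uni] - rl + 1)))
  b[uni] <- a[uni] + glen[uni]
  tp <- is_tail & strand == "+"
  b[tp] <- as.integer(L[tp] - jit[tp]); a[tp] <- b[tp] - glen[tp]
  tm <- is_tail & strand == "-"
  a[tm] <- jit[tm]; b[tm] <- a[tm] + glen[tm]

  # genomic blocks, grouped per transcript then re-indexed to global reads
  blk_read <- integer(0); blk_start <- integer(0); blk_end <- integer(0)
  acc <- vector("list", length(unique(t_of)))
  ui <- 0L
  for (u in unique(t_of)) {
    idx <- which(t_of == u)
    bl <- tx_reads_to_blocks(a[idx], b[idx], txs$exons[[u]])
    ui <- ui + 1L
    acc[[ui]] <- list(read = idx[bl$read], start = bl$start, end = bl$end)
  }
  blk_read <- unlist(lapply(acc, `[[`, "read"), use.names = FALSE)
  blk_start <- unlist(lapply(acc, `[[`, "start"), use.names = FALSE)
  blk_end <- unlist(lapply(acc, `[[`, "end"), use.names = FALSE)
  ord <- order(blk_read, blk_start)
  blk_read <- blk_read[ord]; blk_start <- blk_start[ord]; blk_end <- blk_end[ord]
  first_blk <- !duplicated(blk_read)
  last_blk <- rev(!duplicated(rev(blk_read)))

  read_pos <- integer(n); read_pos[blk_read[first_blk]] <- blk_start[first_blk]
  read_end <- integer(n); read_end[blk_read[last_blk]] <- blk_end[last_blk]

  # sequences per block, pasted per read
  blk_chrom <- chromv[blk_read]
  blk_seq <- character(length(blk_read))
  for (ch in names(toy$genome)) {
    sel <- blk_chrom == ch
    if (any(sel)) {
      blk_seq[sel] <- substring(toy$genome[[ch]], blk_start[sel] + 1L,
                                blk_end[sel])
    }
  }
  seqs <- paste_by_group(blk_seq, blk_read, n)
  seqs <- mutate_bases(seqs, cfg$error_rate)

  # tails: poly(A) 3' clip on plus-strand transcripts, poly(T) 5' clip on
  # minus-strand transcripts (reference orientation)
  tails <- character(n)
  tails[tp] <- mutate_bases(strrep("A", tail_len[tp]), cfg$tail_mismatch_rate)
  tails[tm] <- mutate_bases(strrep("T", tail_len[tm]), cfg$tail_mismatch_rate)
  clip5 <- ifelse(tm, tails, "")
  clip3 <- ifelse(tp, tails, "")

  # CIGAR
  gapN <- ifelse(first_blk, "",
                 paste0(blk_start - c(0L, blk_end[-length(blk_end)]), "N"))
  piece <- paste0(gapN, blk_end - blk_start, "M")
  cigars <- paste_by_group(piece, blk_read, n)
  cigars <- paste0(ifelse(nchar(clip5) > 0, paste0(nchar(clip5), "S"), ""),
                   cigars,
                   ifelse(nchar(clip3) > 0, paste0(nchar(clip3), "S"), ""))

  multi <- runif(n) < cfg$multi_map_fraction
  full_seq <- paste0(clip5, seqs, clip3)
  read_ids <- sprintf("%s:%s:%07d", sid, txs$transcript_id[t_of], seq_len(n))

  sam <- tibble(
    qname = read_ids, flag = ifelse(strand == "-", 16L, 0L),
    rname = chromv, pos = read_pos + 1L,
    mapq = ifelse(multi, 0L, 50L), cigar = cigars,
    seq = full_seq, rg = sid, nh = ifelse(multi, 2L, 1L)
  )

  truth_tails <- tibble(
    read_id = read_ids[is_tail], sample_id = sid[is_tail],
    transcript_id = txs$transcript_id[t_of[is_tail]],
    chrom = chromv[is_tail],
    kind = ifelse(strand[is_tail] == "+", "A", "T"),
    tail_length = tail_len[is_tail],
    anchor_pos = unname(ifelse(strand[is_tail] == "+", read_end[is_tail],
                               read_pos[is_tail])),
    artifact = FALSE, is_unique = !multi[is_tail]
  )

  # truth junctions: every read crossing an exon-exon boundary
  gap_rows <- which(!first_blk)
  truth_junctions <- tibble(
    chrom = blk_chrom[gap_rows],
    donor = blk_end[gap_rows - 1L],
    acceptor = blk_start[gap_rows],
    sample_id = sid[blk_read[gap_rows]],
    transcript_id = txs$transcript_id[t_of[blk_read[gap_rows]]]
  ) |>
    count(.data$chrom, .data$donor, .data$acceptor, .data$sample_id,
          .data$transcript_id)

  fq <- list(tibble(id = read_ids, seq = full_seq))

  # internal-priming artifact reads: non-genomic-looking A clips whose
  # "tails" are genomically templated A-runs just beyond the anchor
  art <- toy$artifact_sites
  art_sam <- NULL; art_tails <- NULL
  if (nrow(art) > 0) {
    expressed <- truth_counts |> filter(.data$count > 0)
    grid <- inner_join(art, expressed, by = "transcript_id")
    grid$k <- stats::rpois(nrow(grid), cfg$artifact_reads_per_site)
    grid <- grid[grid$k > 0, ]
    if (nrow(grid) > 0) {
      m <- sum(grid$k)
      gi <- rep(seq_len(nrow(grid)), grid$k)
      t_a <- tx_idx[grid$transcript_id[gi]]
      glen_a <- rl - 15L
      rows <- vector("list", nrow(grid))
      for (r in seq_len(nrow(grid))) {
        u <- tx_idx[[grid$transcript_id[r]]]
        bl <- tx_reads_to_blocks(rep(grid$tx_pos[r] - glen_a, grid$k[r]),
                                 rep(grid$tx_pos[r], grid$k[r]),
                                 txs$exons[[u]])
        rows[[r]] <- list(g = rep(r, length(bl$read)), read = bl$read,
                          start = bl$start, end = bl$end)
      }
      ar_g <- unlist(lapply(rows, `[[`, "g"))
      ar_read_local <- unlist(lapply(rows, `[[`, "read"))
      ar_start <- unlist(lapply(rows, `[[`, "start"))
      ar_end <- unlist(lapply(rows, `[[`, "end"))
      # global artifact read index
      offs <- c(0L, cumsum(grid$k))
      ar_read <- offs[ar_g] + ar_read_local
      aord <- order(ar_read, ar_start)
      ar_read <- ar_read[aord]; ar_start <- ar_start[aord]
      ar_end <- ar_end[aord]; ar_g <- ar_g[aord]
      a_first <- !duplicated(ar_read)
      ar_chrom <- grid$chrom[gi]
      ar_seq <- character(length(ar_read))
      for (ch in names(toy$genome)) {
        sel <- grid$chrom[ar_g] == ch
        if (any(sel)) {
          ar_seq[sel] <- substring(toy$genome[[ch]], ar_start[sel] + 1L,
                                   ar_end[sel])
        }
      }
      aseqs <- paste_by_group(ar_seq, ar_read, m)
      agap <- ifelse(a_first, "",
                     paste0(ar_start - c(0L, ar_end[-length(ar_end)]), "N"))
      acig <- paste_by_group(paste0(agap, ar_end - ar_start, "M"), ar_read, m)
      apos <- integer(m); apos[ar_read[a_first]] <- ar_start[a_first]
      aids <- sprintf("%s:IP:%07d", grid$sample_id[gi], seq_len(m))
      art_sam <- tibble(
        qname = aids, flag = 0L, rname = ar_chrom, pos = apos + 1L,
        mapq = 50L, cigar = paste0(acig, "15S"),
        seq = paste0(aseqs, strrep("A", 15)), rg = grid$sample_id[gi], nh = 1L
      )
      art_tails <- tibble(
        read_id = aids, sample_id = grid$sample_id[gi],
        transcript_id = grid$transcript_id[gi], chrom = ar_chrom,
        kind = "A", tail_length = 15L, anchor_pos = grid$genomic_pos[gi],
        artifact = TRUE, is_unique = TRUE
      )
      fq[[2]] <- tibble(id = aids, seq = art_sam$seq)
    }
  }

  sam <- bind_rows(sam, art_sam) |>
    arrange(.data$rname, .data$pos, .data$qname)
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(toy$seqlengths),
            unname(toy$seqlengths)),
    sprintf("@RG\tID:%s\tSM:%s", samples$sample_id, samples$sample_id)
  )
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNH:i:%d\tRG:Z:%s",
                  sam$qname, sam$flag, sam$rname, sam$pos, sam$mapq, sam$cigar,
                  sam$seq, strrep("I", nchar(sam$seq)), sam$nh, sam$rg)
  readr::write_lines(c(header, body), sam_path)
  if (!is.null(fastq_path)) {
    fqt <- bind_rows(fq)
    readr::write_lines(as.vector(rbind(paste0("@", fqt$id), fqt$seq, "+",
                                       strrep("I", nchar(fqt$seq)))), fastq_path)
  }

  truth_tails <- bind_rows(truth_tails, art_tails)
  truth_pas <- txs |>
    filter(.data$transcript_id %in% truth_tails$transcript_id[!truth_tails$artifact]) |>
    mutate(position = purrr::map2_int(.data$exons, .data$strand, function(ex, st) {
      if (st == "+") as.integer(max(ex[, 2])) else as.integer(min(ex[, 1]))
    })) |>
    select("transcript_id", "chrom", "strand", "position")

  structure(list(
    sam_path = sam_path, fastq_path = fastq_path, samples = samples,
    truth_counts = truth_counts,
    truth_tails = truth_tails,
    truth_pas = truth_pas,
    truth_junctions = truth_junctions
  ), class = "mzt_sim_reads")
}

#' Generate the full synthetic dataset
#'
#' Convenience wrapper: [build_toy_genome()] + [simulate_expression()] +
#' [simulate_reads()], optionally writing `genome.fa`, `annotation.gff3`,
#' `reads.sam` and `truth/*.tsv` under `dir`.
#'
#' @param config `mzt_sim_config` (default `simulation_config()`).
#' @param dir Optional output directory.
#' @param fastq Also emit raw reads as FASTQ (default FALSE).
#' @return List of class `mzt_sim` combining the toy genome, abundances and
#'   read-level truth.
#' @export
simulate_dataset <- function(config = simulation_config(), dir = NULL,
                             fastq = FALSE) {
  toy <- build_toy_genome(config)
  abundance <- simulate_expression(toy)
  sam_path <- if (is.null(dir)) tempfile(fileext = ".sam") else
    file.path(dir, "reads.sam")
  fq_path <- if (fastq) {
    if (is.null(dir)) tempfile(fileext = ".fastq") else file.path(dir, "reads.fastq")
  } else NULL
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reads <- simulate_reads(toy, abundance, sam_path = sam_path,
                          fastq_path = fq_path)
  if (!is.null(dir)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(toy$genome),
                                file.path(dir, "genome.fa"))
    write_annotation(toy$annotation, file.path(dir, "annotation.gff3"))
    tdir <- file.path(dir, "truth")
    dir.create(tdir, showWarnings = FALSE)
    readr::write_tsv(toy$truth_lncrnas, file.path(tdir, "lncrnas.tsv"), progress = FALSE)
    readr::write_tsv(abundance, file.path(tdir, "abundance.tsv"), progress = FALSE)
    readr::write_tsv(reads$truth_counts, file.path(tdir, "counts.tsv"), progress = FALSE)
    readr::write_tsv(reads$truth_tails, file.path(tdir, "tails.tsv"), progress = FALSE)
    readr::write_tsv(reads$truth_pas, file.path(tdir, "pas.tsv"), progress = FALSE)
    readr::write_tsv(reads$truth_junctions, file.path(tdir, "junctions.tsv"), progress = FALSE)
    readr::write_tsv(toy$truth_ase, file.path(tdir, "ase.tsv"), progress = FALSE)
  }
  structure(c(toy, list(abundance = abundance), unclass(reads)),
            class = "mzt_sim")
}
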