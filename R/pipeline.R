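# Orchestration: a configuration-driven pipeline over the file-based inputs
# (genome FASTA, annotation GFF3, SAM/BAM alignments, sample sheet) and a
# one-command synthetic end-to-end demo with a truth-recovery report.

#' Build a pipeline configuration
#'
#' @param genome,annotation,alignments,sample_sheet Input paths (FASTA, GFF3,
#'   SAM/BAM, TSV with `sample_id`, `sex`, `hours`, `queen`, `replicate`).
#' @param out_dir Output directory.
#' @param params Named list overriding stage parameters. Defaults follow the
#'   package-wide conventions: detection RPKM > 0.1, tails > 10 nt at 0.1
#'   error, 20-bp PAS clustering, 8-nt junction flanks, DEG modes
#'   rawp (p < 0.01, fold change over 2) / fdr (BH < 0.05, |log2FC| > 1,
#'   default), CPS cutoff 0.5, single-exon thresholds 500/1,000 nt.
#' @param stages Stages to run, a subset of
#'   `c("expression", "lncrna", "polya", "splicing", "coexpression")`.
#' @return List of class `mzt_pipeline_config`.
#' @export
pipeline_config <- function(genome, annotation, alignments, sample_sheet,
                            out_dir, params = list(),
                            stages = c("expression", "lncrna", "polya",
                                       "splicing", "coexpression")) {
  defaults <- list(
    detection_threshold = 0.1, min_tail = 10, tail_error_rate = 0.1,
    pas_max_gap = 20, min_flank = 8, deg_mode = "fdr",
    cps_cutoff = 0.5, single_exon_threshold = 500, min_depth = 3,
    min_junction = 2, max_direction_distance = 200, mapq_floor = 20,
    r_threshold = 0.5, p_threshold = 0.05, seed = 1
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  defaults[names(params)] <- params
  stages <- match.arg(stages, c("expression", "lncrna", "polya", "splicing",
                                "coexpression"), several.ok = TRUE)
  structure(list(genome = genome, annotation = annotation,
                 alignments = alignments, sample_sheet = sample_sheet,
                 out_dir = out_dir, params = defaults, stages = stages),
            class = "mzt_pipeline_config")
}

#' Run the analysis pipeline
#'
#' Validates the configuration, loads the shared inputs once, then runs the
#' requested stages in dependency order (counting and normalisation before
#' differential expression and waves; assembly before coding-potential
#' filtering and locus classification; tail detection before internal-priming
#' filtering, PAS clustering and direction assignment; junction extraction
#' before event classification; correlations last). Outputs are deterministic
#' TSV/BED/GFF3 files; a `manifest.dcf` records package version, parameters
#' and input checksums. A failed stage halts its dependents but already
#' written outputs are preserved.
#'
#' @param config `mzt_pipeline_config`.
#' @return Invisible list with the in-memory stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mzt_pipeline_config"))
  for (p in c("genome", "annotation", "alignments", "sample_sheet")) {
    if (!file.exists(config[[p]])) {
      stop("config error: ", p, " path does not exist: ", config[[p]],
           call. = FALSE)
    }
  }
  pr <- config$params
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  genome <- read_genome(config$genome)
  annotation <- read_annotation(config$annotation)
  samples <- readr::read_tsv(config$sample_sheet, show_col_types = FALSE,
                             progress = FALSE)
  alignments <- read_alignments(config$alignments, unique_only = TRUE,
                                mapq_floor = pr$mapq_floor)
  if (all(is.na(alignments$sample_id)) && nrow(samples) == 1) {
    alignments$sample_id <- samples$sample_id[1]
  }

  out <- list(); failed <- character()
  run_stage <- function(name, deps, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    if (any(deps %in% failed)) {
      message("stage ", name, " skipped (failed dependency)")
      failed <<- c(failed, name)
      return(invisible(NULL))
    }
    res <- tryCatch(fn(), error = function(e) {
      message("stage ", name, " failed: ", conditionMessage(e))
      failed <<- c(failed, name)
      NULL
    })
    if (!is.null(res)) out[[name]] <<- res
    invisible(NULL)
  }

  path <- function(f) file.path(config$out_dir, f)

  run_stage("expression", character(), function() {
    counts <- count_reads(alignments, annotation)
    expr <- add_expression_layers(counts, annotation)
    readr::write_tsv(expr, path("counts.tsv"), progress = FALSE)
    det <- detect_expressed(expr, pr$detection_threshold)
    degs <- list(); waves <- NULL
    for (sx in intersect(c("F", "M"), samples$sex)) {
      grp <- function(h) samples$sample_id[samples$sex == sx & samples$hours == h]
      if (any(vapply(c(24, 48, 72), function(h) length(grp(h)) == 0, logical(1)))) next
      cm <- counts_matrix(counts)
      sf <- deseq_size_factors(cm)
      cmp <- list(c(24, 48), c(48, 72), c(24, 72))
      for (cp in cmp) {
        nm <- sprintf("%s_%dv%d", sx, cp[2], cp[1])
        degs[[nm]] <- call_degs(
          nb_exact_test(cm, grp(cp[1]), grp(cp[2]), size_factors = sf),
          mode = pr$deg_mode)
        readr::write_tsv(degs[[nm]], path(sprintf("deg_%s.tsv", nm)),
                         progress = FALSE)
      }
      if (sx == "F") {
        waves <- assign_waves(degs[["F_48v24"]], degs[["F_72v48"]],
                              degs[["F_72v24"]])
        readr::write_tsv(waves, path("waves.tsv"), progress = FALSE)
      }
    }
    list(counts = counts, expr = expr, detection = det, degs = degs,
         waves = waves)
  })

  run_stage("lncrna", "expression", function() {
    model <- train_cps(genome, annotation, seed = pr$seed)
    cands <- assemble_candidates(alignments, annotation, genome,
                                 min_depth = pr$min_depth,
                                 min_junction = pr$min_junction)
    if (nrow(cands) > 0) {
      cands$cps <- coding_potential_score(candidate_sequences(cands, genome),
                                          model)
    } else cands$cps <- numeric(0)
    kept <- filter_lncrnas(cands, pr$single_exon_threshold, pr$cps_cutoff)
    kept <- classify_locus(kept, annotation)
    summary_tbl <- kept |> count(.data$locus_class, name = "n")
    readr::write_tsv(summary_tbl, path("lncrna_summary.tsv"), progress = FALSE)
    write_annotation(candidates_to_annotation(kept), path("lncrna_candidates.gff3"))
    list(model = model, candidates = cands, lncrnas = kept)
  })

  run_stage("polya", character(), function() {
    tails <- detect_tails(alignments, min_tail = pr$min_tail,
                          error_rate = pr$tail_error_rate)
    tails <- internal_priming_filter(tails, genome)
    readr::write_tsv(tails, path("tails.tsv"), progress = FALSE)
    clusters <- cluster_pas(tails, max_gap = pr$pas_max_gap)
    write_bed(clusters |>
                mutate(name = paste0("PAS_", .data$kind, "_", .data$position),
                       score = .data$support, strand = .data$inferred_strand,
                       start = .data$position, end = .data$position + 1L),
              path("pas_clusters.bed"))
    list(tails = tails, clusters = clusters)
  })

  run_stage("splicing", character(), function() {
    junctions <- extract_junctions(alignments, min_flank = pr$min_flank) |>
      annotate_junctions(annotation)
    readr::write_tsv(junctions, path("junctions.tsv"), progress = FALSE)
    events <- classify_ase(junctions, annotation)
    ir <- detect_intron_retention(alignments, annotation,
                                  min_flank = pr$min_flank)
    readr::write_tsv(events, path("ase_events.tsv"), progress = FALSE)
    stats <- splicing_efficiency(alignments, min_flank = pr$min_flank)
    readr::write_tsv(stats, path("splicing_stats.tsv"), progress = FALSE)
    list(junctions = junctions, events = events, intron_retention = ir,
         stats = stats)
  })

  run_stage("coexpression", "expression", function() {
    expr <- out$expression$expr
    pcc_m <- sample_similarity(expr)
    readr::write_tsv(as_tibble(pcc_m, rownames = "sample_id"),
                     path("sample_pcc.tsv"), progress = FALSE)
    list(sample_pcc = pcc_m)
  })

  # direction assignment needs both lncrna and polya results
  if (all(c("lncrna", "polya") %in% names(out))) {
    dirs <- assign_direction(out$lncrna$lncrnas, out$polya$clusters,
                             max_distance = pr$max_direction_distance)
    readr::write_tsv(dirs |> select(-"exons"), path("directions.tsv"),
                     progress = FALSE)
    out$lncrna$lncrnas <- dirs
  }

  manifest <- c(
    package = "beemzt",
    version = as.character(utils::packageVersion("beemzt")),
    genome_md5 = unname(tools::md5sum(config$genome)),
    annotation_md5 = unname(tools::md5sum(config$annotation)),
    alignments_md5 = unname(tools::md5sum(config$alignments)),
    stages = paste(config$stages, collapse = ","),
    vapply(pr, function(x) paste(x, collapse = ","), character(1))
  )
  write.dcf(as.data.frame(t(manifest)), path("manifest.dcf"))
  out$manifest <- manifest

  if (length(failed) > 0) {
    stop("pipeline stage(s) failed: ", paste(unique(failed), collapse = ", "),
         call. = FALSE)
  }
  invisible(out)
}

#' Synthetic end-to-end demo with truth recovery report
#'
#' Generates the default synthetic dataset for `seed`, runs every analysis
#' stage on it, and compares calls against the planted truth: activation-wave
#' label recovery, DEG sensitivity/false discovery, lncRNA recovery and locus
#' classes, transcription-direction accuracy, PAS positional accuracy,
#' internal-priming removal, junction count concordance and splicing event
#' recovery.
#'
#' @param seed Integer seed.
#' @param config Optional `mzt_sim_config` (default `simulation_config(seed)`).
#' @return List of class `mzt_demo` with elements `sim`, `results` (stage
#'   outputs) and `metrics` (one-row tibble of recovery metrics).
#' @export
make_demo <- function(seed = 1, config = simulation_config(seed = seed)) {
  sim <- simulate_dataset(config)
  aln <- read_alignments(sim$sam_path, unique_only = TRUE)
  samples <- sim$samples
  annotation <- sim$annotation
  genome <- sim$genome

  ## expression / waves -------------------------------------------------------
  counts <- count_reads(aln, annotation)
  expr <- add_expression_layers(counts, annotation)
  cm <- counts_matrix(counts)
  sf <- deseq_size_factors(cm)
  fgrp <- function(h) samples$sample_id[samples$sex == "F" & samples$hours == h]
  deg_48v24 <- call_degs(nb_exact_test(cm, fgrp(24), fgrp(48), size_factors = sf))
  deg_72v48 <- call_degs(nb_exact_test(cm, fgrp(48), fgrp(72), size_factors = sf))
  deg_72v24 <- call_degs(nb_exact_test(cm, fgrp(24), fgrp(72), size_factors = sf))
  waves <- assign_waves(deg_48v24, deg_72v48, deg_72v24)

  truth_gene <- sim$transcripts |>
    filter(.data$biotype == "coding") |>
    distinct(.data$gene_id, .data$label)
  wave_truth <- truth_gene |>
    mutate(label = ifelse(.data$label %in% c("wave1", "wave2", "wave3",
                                             "maternal_degradation"),
                          .data$label, "none"))
  wave_cmp <- inner_join(wave_truth, waves, by = "gene_id",
                         suffix = c("_truth", "_called"))
  planted <- wave_cmp |> filter(.data$label_truth != "none")
  wave_accuracy <- mean(planted$label_truth == planted$label_called)

  deg_truth_up <- wave_truth$gene_id[wave_truth$label %in% c("wave1", "wave2")]
  deg_truth_down <- wave_truth$gene_id[wave_truth$label == "maternal_degradation"]
  called_up <- deg_48v24$gene_id[deg_48v24$class == "up"]
  called_down <- deg_48v24$gene_id[deg_48v24$class == "down"]
  deg_sensitivity <- (sum(deg_truth_up %in% called_up) +
                        sum(deg_truth_down %in% called_down)) /
    (length(deg_truth_up) + length(deg_truth_down))
  false_calls <- sum(!called_up %in% deg_truth_up) +
    sum(!called_down %in% deg_truth_down)
  deg_fdr <- ifelse(length(called_up) + length(called_down) == 0, 0,
                    false_calls / (length(called_up) + length(called_down)))

  ## lncRNA discovery ---------------------------------------------------------
  model <- train_cps(genome, annotation, seed = config$seed)
  cands <- assemble_candidates(aln, annotation, genome)
  cands$cps <- coding_potential_score(candidate_sequences(cands, genome), model)
  lnc_1000 <- filter_lncrnas(cands, 1000)
  lnc_500 <- classify_locus(filter_lncrnas(cands, 500), annotation)

  truth_lnc <- sim$truth_lncrnas
  match_truth <- purrr::map_int(seq_len(nrow(truth_lnc)), function(i) {
    same <- lnc_500$chrom == truth_lnc$chrom[i]
    ov <- pmin(lnc_500$end, truth_lnc$end[i]) - pmax(lnc_500$start, truth_lnc$start[i])
    hit <- which(same & ov >= 0.5 * (truth_lnc$end[i] - truth_lnc$start[i]))
    if (length(hit) == 0) NA_integer_ else hit[1]
  })
  lnc_sensitivity <- mean(!is.na(match_truth))
  truth_class_expected <- dplyr::recode(truth_lnc$class,
                                        intronic_sense = "intronic",
                                        intronic_antisense = "intronic",
                                        intergenic = "intergenic",
                                        multi_exon = "intergenic")
  matched <- which(!is.na(match_truth))
  class_ok <- lnc_500$locus_class[match_truth[matched]] ==
    truth_class_expected[matched]
  amb <- lnc_500$ambiguous[match_truth[matched]]
  locus_accuracy <- mean(class_ok[!amb])

  ## polyadenylation ----------------------------------------------------------
  tails <- detect_tails(aln)
  tails <- internal_priming_filter(tails, genome)
  clusters <- cluster_pas(filter(tails, .data$keep))
  dirs <- assign_direction(lnc_500, clusters)

  truth_tails <- sim$truth_tails
  art <- truth_tails |> filter(.data$artifact, .data$is_unique)
  art_obs <- tails |> filter(.data$read_id %in% art$read_id)
  ip_specificity <- ifelse(nrow(art_obs) == 0, NA_real_, mean(!art_obs$keep))

  pas_truth <- sim$truth_pas
  strong <- clusters |> filter(.data$support >= 3)
  pas_hit <- purrr::map_lgl(seq_len(nrow(strong)), function(i) {
    same <- pas_truth$chrom == strong$chrom[i]
    any(same & abs(pas_truth$position - strong$position[i]) <= 10)
  })
  pas_within_10 <- mean(pas_hit)

  dir_cmp <- dirs[match_truth[matched], , drop = FALSE]
  dir_cmp$truth_strand <- truth_lnc$strand[matched]
  assigned <- dir_cmp |> filter(.data$strand_call != "unknown")
  direction_accuracy <- ifelse(nrow(assigned) == 0, NA_real_,
                               mean(assigned$strand_call == assigned$truth_strand))

  ## splicing -----------------------------------------------------------------
  junctions <- extract_junctions(aln) |> annotate_junctions(annotation)
  events <- classify_ase(junctions, annotation)
  ir <- detect_intron_retention(aln, annotation)
  obs_j <- junctions |>
    group_by(.data$chrom, .data$donor, .data$acceptor) |>
    summarise(observed = sum(.data$count), .groups = "drop")
  true_j <- sim$truth_junctions |>
    group_by(.data$chrom, .data$donor, .data$acceptor) |>
    summarise(planted = sum(.data$n), .groups = "drop")
  jcmp <- full_join(obs_j, true_j, by = c("chrom", "donor", "acceptor")) |>
    mutate(observed = dplyr::coalesce(.data$observed, 0L),
           planted = dplyr::coalesce(.data$planted, 0L))
  junction_pcc <- cor(jcmp$observed, jcmp$planted)

  ase_truth <- sim$truth_ase
  ase_recovered <- purrr::map_lgl(seq_len(nrow(ase_truth)), function(i) {
    ty <- ase_truth$type[i]
    if (ty == "IR") {
      any(ir$event[ir$gene_id == ase_truth$gene_id[i]])
    } else {
      any(events$type == ty & events$gene_id == ase_truth$gene_id[i])
    }
  })
  ase_recovery <- mean(ase_recovered)

  spl_eff <- splicing_efficiency(aln)

  ## lncRNA expression / sex specificity / host correlation -------------------
  lnc_ann <- candidates_to_annotation(lnc_500)
  lnc_counts <- count_reads(aln, lnc_ann)
  attr(lnc_counts, "library_sizes") <- attr(counts, "library_sizes")
  lnc_expr <- add_expression_layers(lnc_counts, lnc_ann)
  lnc_det <- detect_expressed(lnc_expr)
  sexspec <- sex_specificity(lnc_det, samples)

  host_pairs <- lnc_500 |>
    filter(.data$locus_class == "intronic", !is.na(.data$host_gene)) |>
    select(lncrna_id = "candidate_id", "host_gene")
  combined <- bind_rows(
    lnc_expr |> select("gene_id", "sample_id", "rpkm"),
    expr |> select("gene_id", "sample_id", "rpkm")
  )
  hosts <- if (nrow(host_pairs) > 0) {
    host_relations(host_pairs, combined)
  } else NULL

  ## truth-based sex specificity accuracy
  lnc_500_matchback <- tibble(
    truth_id = truth_lnc$transcript_id[matched],
    candidate_id = lnc_500$candidate_id[match_truth[matched]],
    truth_label = truth_lnc$label[matched]
  )
  ss_cmp <- lnc_500_matchback |>
    inner_join(sexspec, by = c(candidate_id = "gene_id")) |>
    mutate(expected = ifelse(.data$truth_label == "female_specific_lncRNA",
                             "female_specific",
                             ifelse(.data$truth_label == "male_late",
                                    "male_specific", "shared")))
  sexspec_accuracy <- mean(ss_cmp$sex_specificity == ss_cmp$expected)

  metrics <- tibble(
    wave_accuracy = wave_accuracy,
    deg_sensitivity = deg_sensitivity,
    deg_fdr = deg_fdr,
    lncrna_sensitivity = lnc_sensitivity,
    locus_class_accuracy = locus_accuracy,
    n_lncrna_500 = nrow(lnc_500),
    n_lncrna_1000 = nrow(lnc_1000),
    direction_accuracy = direction_accuracy,
    direction_assigned_fraction = attr(dirs, "assigned_fraction"),
    pas_within_10nt = pas_within_10,
    internal_priming_specificity = ip_specificity,
    junction_count_pcc = junction_pcc,
    ase_recovery = ase_recovery,
    mean_splicing_efficiency = mean(spl_eff$efficiency),
    sexspec_accuracy = sexspec_accuracy,
    female_specific_fraction = attr(sexspec, "summary")$female_specific_fraction,
    host_noncorrelated_fraction = if (!is.null(hosts))
      attr(hosts, "summary")$non_correlated_fraction else NA_real_
  )

  structure(list(
    sim = sim,
    results = list(
      counts = counts, expr = expr, size_factors = sf,
      degs = list(F_48v24 = deg_48v24, F_72v48 = deg_72v48,
                  F_72v24 = deg_72v24),
      waves = waves, wave_comparison = wave_cmp,
      cps_model = model, candidates = cands,
      lncrnas_500 = lnc_500, lncrnas_1000 = lnc_1000,
      tails = tails, pas_clusters = clusters, directions = dirs,
      junctions = junctions, events = events, intron_retention = ir,
      splicing_efficiency = spl_eff, sex_specificity = sexspec,
      lnc_expr = lnc_expr, host_relations = hosts
    ),
    metrics = metrics
  ), class = "mzt_demo")
}

#' @export
print.mzt_demo <- function(x, ...) {
  cat("Synthetic single-embryo MZT demo\n")
  cat(sprintf("  samples: %d   simulated reads: %d   lncRNA candidates: %d\n",
              nrow(x$sim$samples), sum(x$sim$truth_counts$count),
              nrow(x$results$lncrnas_500)))
  m <- x$metrics
  cat(sprintf("  wave label accuracy:        %.3f\n", m$wave_accuracy))
  cat(sprintf("  DEG sensitivity / FDR:      %.3f / %.3f\n",
              m$deg_sensitivity, m$deg_fdr))
  cat(sprintf("  lncRNA recovery:            %.3f (locus class %.3f)\n",
              m$lncrna_sensitivity, m$locus_class_accuracy))
  cat(sprintf("  direction accuracy:         %.3f (assigned %.3f)\n",
              m$direction_accuracy, m$direction_assigned_fraction))
  cat(sprintf("  PAS within +/-10 nt:        %.3f\n", m$pas_within_10nt))
  cat(sprintf("  internal-priming removal:   %.3f\n",
              m$internal_priming_specificity))
  cat(sprintf("  junction count PCC:         %.3f\n", m$junction_count_pcc))
  cat(sprintf("  ASE recovery:               %.3f\n", m$ase_recovery))
  invisible(x)
}
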