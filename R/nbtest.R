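# Negative-binomial exact differential expression and activation-wave
# assignment. The test conditions on each gene's total count across both
# groups and sums the probabilities of all splits at most as likely as the
# observed one (two-sided by probability ordering); group sums are treated as
# negative binomial with the gene's (shrunken) dispersion. As the dispersion
# approaches zero this reduces to the conditional binomial exact test.

# method-of-moments dispersions with shrinkage toward a 1/mean trend
estimate_dispersions <- function(norm_a, norm_b, shrink_weight = 0.5) {
  q <- (rowSums(norm_a) + rowSums(norm_b)) / (ncol(norm_a) + ncol(norm_b))
  va <- apply(norm_a, 1, var)
  vb <- apply(norm_b, 1, var)
  wa <- ncol(norm_a) - 1; wb <- ncol(norm_b) - 1
  v <- (va * wa + vb * wb) / (wa + wb)
  raw <- pmax(1e-8, (v - q) / q^2)
  ok <- is.finite(raw) & q > 0
  trend <- rep(median(raw[ok]), length(raw))
  if (sum(ok) >= 10) {
    fit <- stats::lm(raw[ok] ~ I(1 / q[ok]))
    a0 <- max(coef(fit)[1], 1e-8); a1 <- max(coef(fit)[2], 0)
    trend <- a0 + a1 / pmax(q, 1e-8)
  }
  disp <- shrink_weight * trend + (1 - shrink_weight) * raw
  disp[!ok] <- trend[!ok]
  pmax(disp, 1e-8)
}

# exact two-sided NB test for one gene
nb_exact_p <- function(k_a, k_b, s_a, s_b, n_a, n_b, disp) {
  K <- k_a + k_b
  if (K == 0) return(1)
  q0 <- K / (s_a + s_b)
  a <- 0:K
  lp <- dnbinom(a, mu = q0 * s_a, size = n_a / disp, log = TRUE) +
    dnbinom(K - a, mu = q0 * s_b, size = n_b / disp, log = TRUE)
  lp_obs <- lp[k_a + 1]
  denom <- sum(exp(lp - max(lp)))
  num <- sum(exp(lp - max(lp))[lp <= lp_obs + 1e-7])
  min(1, num / denom)
}

#' Negative-binomial exact test between two sample groups
#'
#' Per-gene dispersions are estimated by method of moments on normalised
#' counts and shrunk (weight 0.5) toward a fitted mean-dispersion trend; with
#' fewer than two replicates in either group the configured
#' `fallback_dispersion` is used. The two-sided p-value conditions on the
#' gene's total count; the log2 fold change (group B over group A) uses
#' normalised group means with pseudocount 1.
#'
#' @param counts Genes x samples count matrix, or long count tibble
#'   ([count_reads()]).
#' @param group_a,group_b Character vectors of sample (column) names.
#' @param size_factors Optional named size factors; computed by
#'   [deseq_size_factors()] from the involved samples when `NULL`.
#' @param dispersion Optional fixed dispersion (scalar or per-gene vector)
#'   overriding estimation.
#' @param fallback_dispersion Dispersion used when replication is
#'   insufficient (default 0.1).
#' @return Tibble `gene_id`, `base_mean`, `mean_a`, `mean_b`, `log2_fc`,
#'   `p_value`, `dispersion`.
#' @export
nb_exact_test <- function(counts, group_a, group_b, size_factors = NULL,
                          dispersion = NULL, fallback_dispersion = 0.1) {
  m <- if (is.matrix(counts)) counts else counts_matrix(counts)
  if (any(m < 0)) stop("negative counts", call. = FALSE)
  stopifnot(all(group_a %in% colnames(m)), all(group_b %in% colnames(m)))
  if (is.null(size_factors)) {
    size_factors <- tryCatch(
      deseq_size_factors(m[, c(group_a, group_b), drop = FALSE]),
      error = function(e) setNames(rep(1, length(c(group_a, group_b))),
                                   c(group_a, group_b))
    )
  }
  sf_a <- size_factors[group_a]; sf_b <- size_factors[group_b]
  raw_a <- m[, group_a, drop = FALSE]; raw_b <- m[, group_b, drop = FALSE]
  norm_a <- sweep(raw_a, 2, sf_a, "/")
  norm_b <- sweep(raw_b, 2, sf_b, "/")

  if (is.null(dispersion)) {
    disp <- if (length(group_a) >= 2 && length(group_b) >= 2) {
      estimate_dispersions(norm_a, norm_b)
    } else rep(fallback_dispersion, nrow(m))
  } else {
    disp <- rep_len(dispersion, nrow(m))
  }

  k_a <- rowSums(raw_a); k_b <- rowSums(raw_b)
  s_a <- sum(sf_a); s_b <- sum(sf_b)
  p <- vapply(seq_len(nrow(m)), function(i) {
    nb_exact_p(k_a[i], k_b[i], s_a, s_b, length(group_a), length(group_b),
               disp[i])
  }, numeric(1))

  mean_a <- unname(rowMeans(norm_a)); mean_b <- unname(rowMeans(norm_b))
  tibble(
    gene_id = rownames(m),
    base_mean = (mean_a + mean_b) / 2,
    mean_a = mean_a, mean_b = mean_b,
    log2_fc = log2((mean_b + 1) / (mean_a + 1)),
    p_value = unname(p),
    dispersion = unname(disp)
  )
}

#' Call differentially expressed genes
#'
#' Two selectable criteria: `"rawp"` calls up when the fold change exceeds 2
#' (strictly) with p < 0.01 and down when it is below 0.5 with p < 0.01;
#' `"fdr"` (default) calls up/down at BH-adjusted p < 0.05 and |log2 fold
#' change| > 1.
#'
#' @param test_results Tibble from [nb_exact_test()].
#' @param mode `"fdr"` or `"rawp"`.
#' @param p_cutoff,fc_cutoff Optional overrides of the mode's thresholds.
#' @return The input with `padj` and `class` (`up`/`down`/`ns`) columns;
#'   class `mzt_deg`.
#' @export
call_degs <- function(test_results, mode = c("fdr", "rawp"),
                      p_cutoff = NULL, fc_cutoff = NULL) {
  mode <- match.arg(mode)
  res <- test_results |> mutate(padj = p.adjust(.data$p_value, "BH"))
  fc <- 2^res$log2_fc
  if (mode == "rawp") {
    p_cut <- p_cutoff %||% 0.01
    f_cut <- fc_cutoff %||% 2
    up <- fc > f_cut & res$p_value < p_cut
    down <- fc < 1 / f_cut & res$p_value < p_cut
  } else {
    p_cut <- p_cutoff %||% 0.05
    l_cut <- log2(fc_cutoff %||% 2)
    up <- res$padj < p_cut & res$log2_fc > l_cut
    down <- res$padj < p_cut & res$log2_fc < -l_cut
  }
  res$class <- ifelse(up, "up", ifelse(down, "down", "ns"))
  class(res) <- c("mzt_deg", class(res))
  attr(res, "mode") <- mode
  res
}

#' Assign zygotic activation waves from pairwise DEG calls
#'
#' Decision table over the three within-sex pairwise comparisons (48 vs 24 h,
#' 72 vs 48 h, 72 vs 24 h), with precedence wave1 > wave2 > wave3 >
#' maternal degradation:
#' \itemize{
#'   \item wave1: up(48v24) and down(72v48) — activated then re-silenced;
#'   \item wave2: up(48v24) and not down(72v48) — activation lasting to 72 h;
#'   \item wave3: not up(48v24) and up(72v48) — late activation;
#'   \item maternal_degradation: down(48v24), or neither up(48v24) nor
#'     up(72v48) but down(72v24);
#'   \item none otherwise.
#' }
#'
#' @param deg_48v24,deg_72v48,deg_72v24 `mzt_deg` tibbles for the three
#'   comparisons (B = later timepoint, so `up` means increasing with time).
#' @return Tibble `gene_id`, `label`; class `mzt_waves`.
#' @export
assign_waves <- function(deg_48v24, deg_72v48, deg_72v24) {
  for (d in list(deg_48v24, deg_72v48, deg_72v24)) {
    if (!all(c("gene_id", "class") %in% names(d))) {
      stop("each comparison must be a DEG call tibble with gene_id and class",
           call. = FALSE)
    }
  }
  j <- deg_48v24 |> select("gene_id", c1 = "class") |>
    inner_join(select(deg_72v48, "gene_id", c2 = "class"), by = "gene_id") |>
    inner_join(select(deg_72v24, "gene_id", c3 = "class"), by = "gene_id")
  if (nrow(j) == 0) stop("no shared genes across the three comparisons", call. = FALSE)
  up1 <- j$c1 == "up"; down1 <- j$c1 == "down"
  up2 <- j$c2 == "up"; down2 <- j$c2 == "down"
  down3 <- j$c3 == "down"
  label <- dplyr::case_when(
    up1 & down2 ~ "wave1",
    up1 & !down2 ~ "wave2",
    !up1 & up2 ~ "wave3",
    down1 | (!up1 & down3) ~ "maternal_degradation",
    .default = "none"
  )
  out <- tibble(gene_id = j$gene_id, label = label)
  class(out) <- c("mzt_waves", class(out))
  out
}
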