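# Pearson-correlation machinery: lncRNA-host relation classification,
# co-expression partner sets and sample-similarity matrices. Expression
# vectors default to log2(x + 1) space.

#' Pearson correlation with t-distribution p-value
#'
#' Standard PCC; the p-value comes from the t transform
#' `t = r * sqrt((n-2) / (1-r^2))` with n - 2 degrees of freedom. A constant
#' vector yields a missing correlation (relation non-correlated downstream).
#'
#' @param x,y Numeric vectors of equal length (>= 3), finite values.
#' @return One-row tibble `r`, `p_value`, `n`.
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired samples", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(r = NA_real_, p_value = NA_real_, n = length(x)))
  }
  r <- cor(x, y)
  n <- length(x)
  if (abs(r) >= 1) return(tibble(r = r, p_value = 0, n = n))
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  tibble(r = r, p_value = 2 * pt(abs(t_stat), n - 2, lower.tail = FALSE), n = n)
}

#' Classify the expression relation of a lncRNA and its host gene
#'
#' positive iff the correlation is at least `r_threshold` with p below
#' `p_threshold`; negative iff it is at most `-r_threshold` with p below
#' `p_threshold`; otherwise non-correlated.
#' With `use_p = FALSE` only the correlation magnitude is used.
#'
#' @param lnc_expr,host_expr Expression vectors over identical samples.
#' @param r_threshold PCC magnitude threshold (default 0.5).
#' @param p_threshold p-value threshold (default 0.05).
#' @param use_p Apply the p criterion (default TRUE).
#' @return One-row tibble `r`, `p_value`, `n`, `relation`.
#' @export
classify_host_relation <- function(lnc_expr, host_expr, r_threshold = 0.5,
                                   p_threshold = 0.05, use_p = TRUE) {
  res <- pcc(lnc_expr, host_expr)
  sig <- if (use_p) !is.na(res$p_value) && res$p_value < p_threshold else TRUE
  relation <- if (is.na(res$r)) "non_correlated"
  else if (res$r >= r_threshold && sig) "positive"
  else if (res$r <= -r_threshold && sig) "negative"
  else "non_correlated"
  mutate(res, relation = relation)
}

#' Classify all lncRNA-host pairs
#'
#' @param pairs Tibble with `lncrna_id`, `host_gene`.
#' @param expr Long expression tibble (`gene_id`, `sample_id`, value column).
#' @param value Expression column (default `rpkm`).
#' @param log2_transform Correlate in log2(x + 1) space (default TRUE).
#' @param r_threshold,p_threshold,use_p See [classify_host_relation()].
#' @return `pairs` with `r`, `p_value`, `n`, `relation`; attribute `summary`
#'   reports the non-correlated fraction.
#' @export
host_relations <- function(pairs, expr, value = "rpkm", log2_transform = TRUE,
                           r_threshold = 0.5, p_threshold = 0.05,
                           use_p = TRUE) {
  m <- counts_matrix(expr, value = value)
  if (log2_transform) m <- log2(m + 1)
  res <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- pairs$lncrna_id[i]; b <- pairs$host_gene[i]
    if (!a %in% rownames(m) || !b %in% rownames(m)) {
      return(tibble(r = NA_real_, p_value = NA_real_, n = ncol(m),
                    relation = "non_correlated"))
    }
    classify_host_relation(m[a, ], m[b, ], r_threshold, p_threshold, use_p)
  })
  out <- bind_cols(pairs, res)
  attr(out, "summary") <- tibble(
    n_pairs = nrow(out),
    non_correlated_fraction = mean(out$relation == "non_correlated")
  )
  out
}

#' Co-expression partners of a target feature
#'
#' All features whose expression passes `|r| > r_threshold` and
#' `p < p_threshold` against the target, labelled by correlation sign.
#'
#' @param target Feature (row) identifier.
#' @param expr Long expression tibble or genes x samples matrix.
#' @param value Expression column when `expr` is long (default `rpkm`).
#' @param r_threshold,p_threshold Partner thresholds (defaults 0.5, 0.05).
#' @param log2_transform Correlate in log2(x + 1) space (default TRUE).
#' @return Tibble `gene_id`, `r`, `p_value`, `sign`; attribute `summary` has
#'   the negative-partner fraction.
#' @export
coexpression_partners <- function(target, expr, value = "rpkm",
                                  r_threshold = 0.5, p_threshold = 0.05,
                                  log2_transform = TRUE) {
  m <- if (is.matrix(expr)) expr else counts_matrix(expr, value = value)
  if (!target %in% rownames(m)) stop("target not in matrix: ", target, call. = FALSE)
  if (log2_transform) m <- log2(m + 1)
  tv <- m[target, ]
  if (sd(tv) == 0) stop("target has constant expression", call. = FALSE)
  others <- setdiff(rownames(m), target)
  res <- purrr::map_dfr(others, function(g) {
    p <- pcc(tv, m[g, ])
    tibble(gene_id = g, r = p$r, p_value = p$p_value)
  }) |>
    filter(!is.na(.data$r), abs(.data$r) > r_threshold,
           .data$p_value < p_threshold) |>
    mutate(sign = ifelse(.data$r > 0, "positive", "negative"))
  attr(res, "summary") <- tibble(
    n_partners = nrow(res),
    negative_fraction = ifelse(nrow(res) == 0, NA_real_,
                               mean(res$sign == "negative"))
  )
  res
}

#' Sample-by-sample Pearson correlation matrix
#'
#' Symmetric with unit diagonal; samples with zero variance yield missing
#' rows/columns.
#'
#' @param expr Long expression tibble or genes x samples matrix.
#' @param value Expression column when long (default `rpkm`).
#' @param log2_transform Correlate in log2(x + 1) space (default TRUE).
#' @return samples x samples numeric matrix.
#' @export
sample_similarity <- function(expr, value = "rpkm", log2_transform = TRUE) {
  m <- if (is.matrix(expr)) expr else counts_matrix(expr, value = value)
  if (ncol(m) < 2) stop("need at least two samples", call. = FALSE)
  if (log2_transform) m <- log2(m + 1)
  v <- apply(m, 2, sd)
  out <- suppressWarnings(cor(m))
  out[v == 0, ] <- NA_real_
  out[, v == 0] <- NA_real_
  diag(out) <- ifelse(v == 0, NA_real_, 1)
  out
}
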