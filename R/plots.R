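# ggplot2 views of the main result types.

#' @export
glance.mzt_deg <- function(x, ...) {
  tibble(n = nrow(x), n_up = sum(x$class == "up"),
         n_down = sum(x$class == "down"),
         mode = attr(x, "mode") %||% NA_character_)
}

#' Volcano plot of a DEG result
#'
#' @param object `mzt_deg` tibble from [call_degs()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.mzt_deg <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$log2_fc,
                               y = -log10(pmax(.data$p_value, 1e-300)),
                               colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Wave composition plot
#'
#' @param object `mzt_waves` tibble from [assign_waves()].
#' @param ... Ignored.
#' @return A ggplot bar chart of activation-wave label counts.
#' @export
autoplot.mzt_waves <- function(object, ...) {
  lv <- c("wave1", "wave2", "wave3", "maternal_degradation", "none")
  dat <- object |> count(label = factor(.data$label, levels = lv))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$label, y = .data$n)) +
    ggplot2::geom_col(fill = "#6c5ce7") +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Poly(A) tail length by sex and timepoint
#'
#' @param tails Tail tibble with `sample_id`, `tail_length`.
#' @param samples Sample sheet with `sample_id`, `sex`, `hours`.
#' @return A ggplot boxplot of per-sample mean tail lengths.
#' @export
plot_tail_lengths <- function(tails, samples) {
  dat <- mean_tail_length_by_group(tails, samples)$per_sample
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$hours),
                                    y = .data$mean_length,
                                    fill = .data$sex)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = "hours after egg laying", y = "mean poly(A) length (nt)",
                  fill = "sex") +
    ggplot2::theme_minimal()
}

#' Sample-similarity heatmap
#'
#' @param similarity Matrix from [sample_similarity()].
#' @return A ggplot tile heatmap.
#' @export
plot_sample_similarity <- function(similarity) {
  dat <- as_tibble(similarity, rownames = "sample_a") |>
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b", values_to = "r")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                                    fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "PCC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}
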