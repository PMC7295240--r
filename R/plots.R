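#' Plot seed k-mer abundances
#'
#' Rank-abundance plot of the most abundant k-mers of a dataset; the heavy
#' head of this curve is dominated by D-gene substrings and is where seeds
#' are drawn from.
#'
#' @param kmers A k-mer table from [count_kmers()].
#' @param top_n Number of top k-mers to show (default 300).
#' @return A ggplot object.
#' @export
plot_seed_abundance <- function(kmers, top_n = 300) {
  df <- kmers |>
    arrange(desc(.data$count), .data$kmer) |>
    slice_head(n = top_n) |>
    mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$count)) +
    ggplot2::geom_point(size = 0.8, colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "k-mer rank", y = "abundance",
                  title = sprintf("Top %d k-mer abundances", nrow(df))) +
    ggplot2::theme_minimal()
}

#' Plot mean relative positions of extensions
#'
#' Dot plot of mean relative positions, coloured by segment class when
#' available; V-, D- and J-derived extensions separate into left, central
#' and right clusters.
#'
#' @param extensions A tibble with `mean_rp` (and optionally
#'   `segment_class`) columns.
#' @return A ggplot object.
#' @export
plot_relative_positions <- function(extensions) {
  df <- as_tibble(extensions)
  aes <- if ("segment_class" %in% names(df)) {
    ggplot2::aes(x = .data$mean_rp, y = 0, colour = .data$segment_class)
  } else {
    ggplot2::aes(x = .data$mean_rp, y = 0)
  }
  p <- ggplot2::ggplot(df, aes) +
    ggplot2::geom_jitter(height = 0.2, width = 0) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "mean relative position", y = NULL,
                  colour = "segment") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  p
}

#' @export
autoplot.usage_profile <- function(object, ...) {
  df <- object$gene_usage |>
    mutate(gene = factor(.data$gene, levels = .data$gene))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$usage)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::labs(x = NULL, y = "usage (fraction of traceable CDR3s)",
                  title = sprintf("%.1f%% of %d CDR3s traceable",
                                  100 * object$traceable_fraction,
                                  object$n_cdr3s)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.d_mining <- function(object, ...) {
  stages <- c("seeds", "extensions", "after_unidirectional", "unique",
              "central_cluster", "post_merge")
  df <- object$funnel |>
    tidyr::pivot_longer(dplyr::all_of(stages),
                        names_to = "stage", values_to = "n") |>
    mutate(stage = factor(.data$stage, levels = stages))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n,
                                   group = .data$dataset,
                                   colour = .data$dataset)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "count", title = "Inference funnel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
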