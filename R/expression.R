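#' Tissue-expressed gene calls
#'
#' A gene is called expressed in a tissue when its expression is at least
#' `rpkm_min` in strictly more than `sample_frac` of that tissue's samples
#' (the "RPKM >= 1 in > 80% samples" rule; exactly 80% does not qualify).
#'
#' @param expr Long expression tibble (`gene_id, sample, value`) from
#'   [read_expression_matrix()].
#' @param sample_map Tibble `sample, tissue`.
#' @param tissue Tissue to call; a tissue with zero mapped samples is an
#'   error.
#' @param rpkm_min Expression threshold (default 1, RPKM scale).
#' @param sample_frac Strict sample-fraction threshold (default 0.8).
#' @return Tibble `tissue, gene_id` of expressed genes (a subset of the
#'   matrix genes), sorted by gene id.
#' @export
tissue_expressed_genes <- function(expr, sample_map, tissue, rpkm_min = 1,
                                   sample_frac = 0.8) {
  samples <- sample_map$sample[sample_map$tissue == tissue]
  if (length(samples) == 0) {
    abort(paste0("tissue '", tissue, "' has no samples in the map"))
  }
  expr |>
    filter(.data$sample %in% samples) |>
    group_by(.data$gene_id) |>
    summarise(frac = mean(.data$value >= rpkm_min), .groups = "drop") |>
    filter(.data$frac > sample_frac) |>
    mutate(tissue = !!tissue) |>
    select("tissue", "gene_id") |>
    arrange(.data$gene_id)
}

#' Tissue-specificity z-scores of gene expression
#'
#' For each gene i, computes the per-tissue mean expression E(i,t), the
#' grand mean <E(i)> and the standard deviation delta_E(i) of those
#' per-tissue means across all considered tissues (sample SD, n - 1), and
#' the specificity score
#'
#'   z_E(i,t) = (E(i,t) - <E(i)>) / delta_E(i).
#'
#' A larger z means higher expression in that tissue relative to the others.
#' The grand mean and SD are taken across per-tissue means, not pooled
#' samples, so tissues with more samples do not dominate. When delta_E(i)
#' is 0 (identical means everywhere) all z are set to 0. For a gene whose
#' per-tissue z's exist, they sum to 0 by construction.
#'
#' @inheritParams tissue_expressed_genes
#' @param log_transform If `TRUE`, apply log2(x + 1) to expression values
#'   before averaging (off by default).
#' @return An `expression_summary` tibble: `gene_id, tissue, mean_expr,
#'   grand_mean, sd_expr, z`, one row per gene x tissue. Fewer than 2
#'   tissues is an error.
#' @export
tissue_specificity_z <- function(expr, sample_map, log_transform = FALSE) {
  tissues <- unique(sample_map$tissue)
  if (length(tissues) < 2) {
    abort("tissue-specificity z needs at least 2 tissues")
  }
  df <- expr |>
    inner_join(sample_map, by = "sample")
  if (log_transform) df$value <- log2(df$value + 1)
  per_tissue <- df |>
    group_by(.data$gene_id, .data$tissue) |>
    summarise(mean_expr = mean(.data$value), .groups = "drop")
  out <- per_tissue |>
    group_by(.data$gene_id) |>
    mutate(grand_mean = mean(.data$mean_expr),
           sd_expr = sd(.data$mean_expr),
           z = ifelse(.data$sd_expr > 0,
                      (.data$mean_expr - .data$grand_mean) / .data$sd_expr,
                      0)) |>
    ungroup() |>
    arrange(.data$gene_id, .data$tissue)
  class(out) <- c("expression_summary", class(out))
  out
}

#' @export
autoplot.expression_summary <- function(object, genes = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(genes)) df <- filter(df, .data$gene_id %in% genes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue, y = .data$z,
                                   group = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = NULL, y = expression(z[E](i, t)),
                  title = "Tissue-specificity z-scores") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Tissue with the maximum z per gene
#'
#' Convenience accessor used to colour circuit genes and to check planted
#' tissue-specific genes: the tissue where each gene attains its maximum
#' specificity z (ties broken by tissue name for determinism).
#'
#' @param summary An `expression_summary` from [tissue_specificity_z()].
#' @return Tibble `gene_id, tissue, z` with one row per gene.
#' @export
max_z_tissue <- function(summary) {
  as_tibble(summary) |>
    arrange(.data$gene_id, dplyr::desc(.data$z), .data$tissue) |>
    distinct(.data$gene_id, .keep_all = TRUE) |>
    select("gene_id", "tissue", "z")
}
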