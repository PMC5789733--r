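#' Map SNPs onto regulatory elements with the promoter-flank rule
#'
#' A SNP hits a promoter if it lies in the promoter span, in the 400-bp
#' region upstream of the promoter's 5' end, or in the 50-bp region
#' downstream of its 3' end (both windows inclusive of the outer boundary
#' base and strand-aware; unstranded promoters are oriented as + strand). A
#' SNP hits an enhancer only if it lies inside the enhancer span — enhancers
#' carry no flank.
#'
#' @param snps Tibble with `snp_id, chrom, pos` (1-based).
#' @param promoters,enhancers Interval tibbles (e.g. [read_bed_track()]);
#'   either may be empty or `NULL`.
#' @param up_bp,down_bp Promoter flank widths in bp (defaults 400 and 50).
#' @return Tibble `snp_id, element_id, element_kind, hit_rule` with
#'   `hit_rule` in {promoter_body, promoter_flank, enhancer_body}; one row
#'   per (SNP, element) pair, body taking precedence over flank. SNPs
#'   hitting nothing are absent.
#' @export
map_snps_to_elements <- function(snps, promoters = NULL, enhancers = NULL,
                                 up_bp = 400L, down_bp = 50L) {
  snps <- distinct(as_tibble(snps), .data$snp_id, .data$chrom, .data$pos)
  regions <- list()
  if (!is.null(promoters) && nrow(promoters) > 0) {
    pr <- validate_intervals(promoters)
    plus <- pr$strand != "-"   # unstranded treated as + strand
    up_start <- ifelse(plus, pr$start - up_bp, pr$end)
    up_end <- ifelse(plus, pr$start, pr$end + up_bp)
    dn_start <- ifelse(plus, pr$end, pr$start - down_bp)
    dn_end <- ifelse(plus, pr$end + down_bp, pr$start)
    body <- mutate(pr, hit_rule = "promoter_body")
    flank <- bind_rows(
      mutate(pr, start = as.integer(pmax(up_start, 0L)),
             end = as.integer(up_end)),
      mutate(pr, start = as.integer(pmax(dn_start, 0L)),
             end = as.integer(dn_end))) |>
      filter(.data$start < .data$end) |>
      mutate(hit_rule = "promoter_flank")
    regions <- c(regions, list(body, flank))
  }
  if (!is.null(enhancers) && nrow(enhancers) > 0) {
    regions <- c(regions, list(
      mutate(validate_intervals(enhancers), hit_rule = "enhancer_body")))
  }
  empty <- tibble(snp_id = character(), element_id = character(),
                  element_kind = character(), hit_rule = character())
  if (length(regions) == 0 || nrow(snps) == 0) return(empty)
  all_regions <- bind_rows(regions)
  idx <- interval_index(select(all_regions, "chrom", "start", "end", "strand",
                               "feature_id", "feature_kind", "hit_rule"))
  hits <- query_points(idx, snps)
  if (nrow(hits) == 0) return(empty)
  hits |>
    mutate(element_id = .data$feature_id,
           element_kind = .data$feature_kind) |>
    select("snp_id", "element_id", "element_kind", "hit_rule") |>
    # body beats flank when a SNP lands in both views of one promoter
    arrange(.data$snp_id, .data$element_id, .data$hit_rule) |>
    distinct(.data$snp_id, .data$element_id, .keep_all = TRUE) |>
    arrange(.data$snp_id, .data$element_id)
}

#' Reconstruct the SNP-perturbed regulatory circuit for one tissue
#'
#' For every element hit by a disease-associated SNP, every TF -> element ->
#' target edge through that element in the requested tissue's network is
#' emitted as a perturbed interaction: `promoter_perturbed` when the SNP
#' affects TF-promoter binding, `enhancer_perturbed` for TF-enhancer
#' binding. Each edge lists all witnessing SNP ids. Construction is
#' deterministic and order-invariant in both SNP and edge input order.
#'
#' @param hits Element hits from [map_snps_to_elements()], already restricted
#'   to the disease's significant SNPs.
#' @param network_edges Network tibble from [read_network()].
#' @param tissue Tissue whose network to use; an absent tissue is an error
#'   listing the available ones.
#' @param trait Label stored on the circuit (the disease/trait analysed).
#' @return A `perturbed_circuit`: edges tibble (`tf, element_id,
#'   element_kind, target, tissue, perturbation_kind, witness_snps`) plus the
#'   sorted union of TFs and targets in `genes`.
#' @export
build_perturbed_circuit <- function(hits, network_edges, tissue,
                                    trait = NA_character_) {
  tissues <- unique(network_edges$tissue)
  if (!tissue %in% tissues) {
    abort(paste0("tissue '", tissue, "' absent from network; available: ",
                 paste(sort(tissues), collapse = ", ")))
  }
  net <- filter(network_edges, .data$tissue == !!tissue)
  edges <- net |>
    inner_join(select(hits, "snp_id", "element_id", "element_kind"),
               by = c("element_id", "element_kind"),
               relationship = "many-to-many") |>
    group_by(.data$tf, .data$element_id, .data$element_kind, .data$target,
             .data$tissue) |>
    summarise(witness_snps = collapse_support(.data$snp_id),
              .groups = "drop") |>
    mutate(perturbation_kind = paste0(.data$element_kind, "_perturbed")) |>
    select("tf", "element_id", "element_kind", "target", "tissue",
           "perturbation_kind", "witness_snps") |>
    arrange(.data$tf, .data$element_id, .data$target)
  genes <- sort(unique(c(edges$tf, edges$target)))
  structure(list(trait = trait, tissue = tissue, edges = edges,
                 genes = genes),
            class = "perturbed_circuit")
}

#' @export
print.perturbed_circuit <- function(x, ...) {
  cat("<perturbed_circuit> trait = ", x$trait, ", tissue = ", x$tissue,
      "\n  ", nrow(x$edges), " perturbed edges over ", length(x$genes),
      " genes\n", sep = "")
  invisible(x)
}

#' @export
tidy.perturbed_circuit <- function(x, ...) {
  x$edges
}

#' @export
glance.perturbed_circuit <- function(x, ...) {
  tibble(trait = x$trait, tissue = x$tissue, n_edges = nrow(x$edges),
         n_promoter_perturbed = sum(x$edges$perturbation_kind ==
                                      "promoter_perturbed"),
         n_enhancer_perturbed = sum(x$edges$perturbation_kind ==
                                      "enhancer_perturbed"),
         n_genes = length(x$genes),
         n_witness_snps = length(unique(unlist(
           strsplit(x$edges$witness_snps, ";", fixed = TRUE)))))
}

#' @export
autoplot.perturbed_circuit <- function(object, ...) {
  counts <- object$edges |>
    group_by(.data$perturbation_kind) |>
    summarise(n = n(), .groups = "drop")
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$perturbation_kind,
                                       y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "perturbed edges",
                  title = sprintf("%s circuit in %s", object$trait,
                                  object$tissue)) +
    ggplot2::theme_minimal()
}

#' Nearest-gene set for a list of SNPs
#'
#' Baseline gene module: the nearest gene of each SNP (gene-body distance;
#' ties resolved by smaller distance then lexicographic gene id), as a
#' deduplicated set. SNPs on chromosomes without genes are skipped and
#' reported via the `"skipped"` attribute.
#'
#' @param snps Tibble with `snp_id, chrom, pos`.
#' @param gene_index [interval_index()] containing `gene` features.
#' @return Sorted character vector of gene ids.
#' @export
nearest_gene_set <- function(snps, gene_index) {
  snps <- distinct(as_tibble(snps), .data$snp_id, .data$chrom, .data$pos)
  nf <- nearest_features(gene_index, snps, kind = "gene")
  skipped <- nf$snp_id[is.na(nf$feature_id)]
  out <- sort(unique(nf$feature_id[!is.na(nf$feature_id)]))
  attr(out, "skipped") <- skipped
  out
}

#' Disease-gene enrichment of a gene module
#'
#' Fisher's exact test of the overlap between a gene module (e.g. perturbed
#' circuit genes, or the nearest-gene baseline) and a disease gene set
#' within a gene universe: the 2x2 table is (module-and-disease, module
#' only, disease only, neither).
#'
#' @param module_genes,disease_genes Character vectors, subsets of
#'   `universe`.
#' @param universe Character vector of all genes under consideration.
#' @return One-row tibble `a, b, c, d, fold_change, p_value`.
#' @export
disease_gene_enrichment <- function(module_genes, disease_genes, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty gene universe")
  module_genes <- unique(module_genes)
  disease_genes <- unique(disease_genes)
  if (!all(module_genes %in% universe)) {
    abort("module_genes must be a subset of the universe")
  }
  if (!all(disease_genes %in% universe)) {
    abort("disease_genes must be a subset of the universe")
  }
  a <- length(intersect(module_genes, disease_genes))
  b <- length(setdiff(module_genes, disease_genes))
  c <- length(setdiff(disease_genes, module_genes))
  d <- length(universe) - a - b - c
  fold <- if (a + b == 0 || c + d == 0 || c == 0) NA_real_ else
    (a / (a + b)) / (c / (c + d))
  p <- if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) 1 else
    fisher_exact_2x2(a, b, c, d)
  tibble(a = a, b = b, c = c, d = d, fold_change = fold, p_value = p)
}

#' Flag candidate novel associations by FDR
#'
#' Benjamini-Hochberg q-values over the catalog's raw P values; records with
#' q below `fdr_q` (strict) are flagged `candidate_novel`, mirroring the
#' FDR < 0.1 novel-association screen applied to PheWAS catalogs.
#'
#' @param records Tibble with a `p` column.
#' @param fdr_q FDR threshold (default 0.1).
#' @return `records` with `q_value` and logical `candidate_novel` columns.
#' @export
threshold_novel_associations <- function(records, fdr_q = 0.1) {
  records <- as_tibble(records)
  if (!"p" %in% names(records)) abort("records need a `p` column")
  records$q_value <- p.adjust(records$p, method = "BH")
  records$candidate_novel <- records$q_value < fdr_q
  records
}
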