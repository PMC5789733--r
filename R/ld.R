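#' Find proxy SNPs in strong linkage disequilibrium
#'
#' For each index SNP, returns the SNPs in strong LD (r2 >= `r2_min`,
#' inclusive) within a `window_bp` flanking region on each side (distance <=
#' `window_bp`, inclusive), emulating a SNAP-style proxy search. Only direct
#' proxies are returned — no proxy-of-proxy chaining. Distances come from
#' the LD table's `distance_bp` column; rows with missing distance fall back
#' to coordinates in `positions` when supplied, else are excluded from the
#' window filter's reach (treated as failing it).
#'
#' @param snp_ids Character vector of index SNP ids (SNPs absent from the LD
#'   table simply get no proxies).
#' @param ld Symmetrized LD tibble from [read_ld_table()].
#' @param r2_min Inclusive r2 threshold (default 0.8).
#' @param window_bp Inclusive distance window in bp (default 500000, i.e. a
#'   500-kb flank on each side).
#' @param positions Optional tibble `snp_id, chrom, pos` used to compute
#'   missing distances.
#' @return Tibble `index_snp_id, proxy_snp_id, r2, distance_bp`, sorted by
#'   index SNP, then descending r2, then proxy id.
#' @export
find_proxies <- function(snp_ids, ld, r2_min = 0.8, window_bp = 500000L,
                         positions = NULL) {
  stopifnot(r2_min >= 0, r2_min <= 1, window_bp >= 0)
  cand <- ld |>
    filter(.data$snp_a %in% snp_ids) |>
    rename(index_snp_id = "snp_a", proxy_snp_id = "snp_b")
  if (!is.null(positions) && any(is.na(cand$distance_bp))) {
    pos <- distinct(as_tibble(positions), .data$snp_id, .keep_all = TRUE)
    cand <- cand |>
      left_join(select(pos, index_snp_id = "snp_id", chrom_a = "chrom",
                       pos_a = "pos"), by = "index_snp_id") |>
      left_join(select(pos, proxy_snp_id = "snp_id", chrom_b = "chrom",
                       pos_b = "pos"), by = "proxy_snp_id") |>
      mutate(distance_bp = ifelse(
        is.na(.data$distance_bp) & !is.na(.data$pos_a) & !is.na(.data$pos_b) &
          .data$chrom_a == .data$chrom_b,
        abs(.data$pos_a - .data$pos_b), .data$distance_bp)) |>
      select(-dplyr::any_of(c("chrom_a", "pos_a", "chrom_b", "pos_b")))
  }
  cand |>
    filter(.data$r2 >= r2_min, !is.na(.data$distance_bp),
           .data$distance_bp <= window_bp) |>
    arrange(.data$index_snp_id, dplyr::desc(.data$r2), .data$proxy_snp_id) |>
    select("index_snp_id", "proxy_snp_id", "r2", "distance_bp")
}

#' Propagate functional annotations through LD proxies
#'
#' A reported SNP is considered annotated with a category if it, or at least
#' one of its proxies, carries that category — the "LD extension" step. Each
#' extended flag is the logical OR of the base flag and all proxy flags;
#' base-true flags stay true (monotone), and extending an already-extended
#' table with the same proxy set is a no-op (idempotent).
#'
#' @param base Annotation tibble for the reported SNPs
#'   ([annotate_catalog()] or [annotate_regulatory()]).
#' @param proxy_annotations Annotation tibble covering the proxy SNPs (same
#'   flag columns); proxies absent from it contribute nothing.
#' @param proxies Proxy map from [find_proxies()].
#' @return `base` with `extended_motif, extended_promoter_enhancer,
#'   extended_eqtl`, `extended_n_regulatory_categories` and per-flag
#'   `proxies_motif, proxies_promoter_enhancer, proxies_eqtl` columns listing
#'   the contributing proxy SNP ids (semicolon-joined).
#' @export
extend_annotations <- function(base, proxy_annotations, proxies) {
  base <- as_tibble(base)
  flags <- c("motif", "promoter_enhancer", "eqtl")
  pa <- as_tibble(proxy_annotations) |>
    select(proxy_snp_id = "snp_id", dplyr::all_of(flags)) |>
    distinct(.data$proxy_snp_id, .keep_all = TRUE)
  contrib <- proxies |>
    select("index_snp_id", "proxy_snp_id") |>
    inner_join(pa, by = "proxy_snp_id")
  out <- base
  for (f in flags) {
    sup <- contrib |>
      filter(.data[[f]]) |>
      group_by(.data$index_snp_id) |>
      summarise(sup = collapse_support(.data$proxy_snp_id), .groups = "drop")
    out <- out |>
      left_join(sup, by = c(snp_id = "index_snp_id")) |>
      mutate("extended_{f}" := .data[[f]] | !is.na(.data$sup),
             "proxies_{f}" := ifelse(is.na(.data$sup), "", .data$sup)) |>
      select(-"sup")
  }
  mutate(out, extended_n_regulatory_categories =
           as.integer(.data$extended_motif) +
           as.integer(.data$extended_promoter_enhancer) +
           as.integer(.data$extended_eqtl))
}

#' Summary view of extended annotations
#'
#' Rebinds the `extended_` flag block onto the plain flag names so
#' [summarize_annotations()] can be applied to post-LD coverage.
#'
#' @param extended Tibble from [extend_annotations()].
#' @return Tibble with `motif, promoter_enhancer, eqtl` taken from the
#'   extended flags (other columns carried through).
#' @export
extended_as_flags <- function(extended) {
  extended |>
    mutate(motif = .data$extended_motif,
           promoter_enhancer = .data$extended_promoter_enhancer,
           eqtl = .data$extended_eqtl,
           n_regulatory_categories = .data$extended_n_regulatory_categories)
}
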