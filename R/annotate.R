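#' Classify SNPs by genic context
#'
#' A deliberately minimal exon/intron/intergenic classifier: exonic if the
#' position falls inside any exon, else intronic if inside any gene body,
#' else intergenic. Only the exonic-versus-noncoding split feeds downstream
#' logic, so finer subcategories (UTR, splice) are out of scope.
#'
#' @param snps Tibble with `snp_id, chrom, pos` (1-based).
#' @param gene_index,exon_index [interval_index()]es over the gene model;
#'   either may be `NULL` (an empty model classifies everything intergenic).
#' @return `snps` with a `genic_context` column added.
#' @export
classify_genic_context <- function(snps, gene_index = NULL, exon_index = NULL) {
  snps <- as_tibble(snps)
  in_exon <- if (is.null(exon_index)) rep(FALSE, nrow(snps)) else
    points_overlap(exon_index, snps, kind = "exon")
  in_gene <- if (is.null(gene_index)) rep(FALSE, nrow(snps)) else
    points_overlap(gene_index, snps, kind = "gene")
  snps$genic_context <- dplyr::case_when(
    in_exon ~ "exonic",
    in_gene ~ "intronic",
    TRUE ~ "intergenic")
  snps
}

#' Flag coding variants near protein functional sites
#'
#' A variant is flagged `ligand_site` if it lies at a ligand-binding residue
#' or within its two-residue flanking region
#' (|variant residue - site residue| <= 2 on the same protein), and
#' `phospho_site` if within seven residues of a phosphorylation site.
#' Variants on proteins absent from the site table get both flags `FALSE`.
#'
#' @param variants Tibble from [read_coding_variants()].
#' @param sites Tibble from [read_protein_sites()].
#' @param ligand_flank,phospho_flank Flank widths in residues.
#' @return `variants` with logical `ligand_site` and `phospho_site` columns.
#' @export
annotate_protein_sites <- function(variants, sites,
                                   ligand_flank = 2L, phospho_flank = 7L) {
  variants <- as_tibble(variants)
  flag_for <- function(kind, flank) {
    s <- filter(sites, .data$site_kind == kind) |>
      select("protein_id", site_residue = "residue_index")
    if (nrow(s) == 0 || nrow(variants) == 0) return(rep(FALSE, nrow(variants)))
    hits <- variants |>
      mutate(.row = row_number()) |>
      inner_join(s, by = "protein_id", relationship = "many-to-many") |>
      filter(abs(.data$residue_index - .data$site_residue) <= flank)
    out <- rep(FALSE, nrow(variants))
    out[unique(hits$.row)] <- TRUE
    out
  }
  variants$ligand_site <- flag_for("ligand_binding", ligand_flank)
  variants$phospho_site <- flag_for("phosphorylation", phospho_flank)
  variants
}

collapse_support <- function(x) {
  paste(sort(unique(x)), collapse = ";")
}

#' Annotate SNPs with regulatory evidence
#'
#' Assigns the three regulatory categories: `motif` (the position overlaps at
#' least one TF motif occurrence), `promoter_enhancer` (overlaps a promoter
#' or enhancer detected in at least one cell line), and `eqtl` (the SNP is
#' significantly cis-associated with at least one gene's expression at
#' FDR <= `eqtl_fdr` in at least one tissue; the threshold is inclusive).
#' Supporting features (TF names, element ids, gene@tissue pairs) are
#' deduplicated, sorted and recorded per flag.
#'
#' @param snps Tibble with `snp_id, chrom, pos`; duplicated `snp_id`s (e.g.
#'   one row per trait) are annotated once and the result joined back.
#' @param motif_index,element_index [interval_index()]es over motif and
#'   promoter+enhancer tracks (either may be `NULL`).
#' @param eqtl Tibble from [read_eqtl_table()], or `NULL`.
#' @param eqtl_fdr Inclusive FDR threshold for a qualifying eQTL.
#' @return One row per distinct `snp_id` with logical flags, support strings
#'   and `n_regulatory_categories` (0-3). SNPs with missing coordinates get
#'   all overlap flags `FALSE` and are listed in the `"skipped"` attribute.
#' @export
annotate_regulatory <- function(snps, motif_index = NULL, element_index = NULL,
                                eqtl = NULL, eqtl_fdr = 0.05) {
  snps <- as_tibble(snps) |>
    distinct(.data$snp_id, .data$chrom, .data$pos) |>
    distinct(.data$snp_id, .keep_all = TRUE)
  skipped <- snps$snp_id[is.na(snps$chrom) | is.na(snps$pos)]
  placed <- filter(snps, !.data$snp_id %in% skipped)

  overlap_support <- function(index, kind, support_col) {
    empty <- tibble(snp_id = character(), support = character())
    names(empty)[2] <- support_col
    if (is.null(index) || nrow(placed) == 0) return(empty)
    hits <- query_points(index, placed, kind = kind)
    if (nrow(hits) == 0) return(empty)
    support_val <- if (identical(kind, "motif") && "tf" %in% names(hits))
      hits$tf else hits$feature_id
    hits |>
      mutate(.support = support_val) |>
      group_by(.data$snp_id) |>
      summarise("{support_col}" := collapse_support(.data$.support),
                .groups = "drop")
  }

  motif_sup <- overlap_support(motif_index, "motif", "support_motif")
  pe_sup <- overlap_support(element_index, c("promoter", "enhancer"),
                            "support_promoter_enhancer")
  eqtl_sup <- if (is.null(eqtl)) {
    tibble(snp_id = character(), support_eqtl = character())
  } else {
    eqtl |>
      filter(.data$fdr <= eqtl_fdr, .data$snp_id %in% snps$snp_id) |>
      group_by(.data$snp_id) |>
      summarise(support_eqtl = collapse_support(
        paste0(.data$gene_id, "@", .data$tissue)), .groups = "drop")
  }

  out <- snps |>
    left_join(motif_sup, by = "snp_id") |>
    left_join(pe_sup, by = "snp_id") |>
    left_join(eqtl_sup, by = "snp_id") |>
    mutate(
      motif = !is.na(.data$support_motif),
      promoter_enhancer = !is.na(.data$support_promoter_enhancer),
      eqtl = !is.na(.data$support_eqtl),
      across(dplyr::starts_with("support_"), ~ifelse(is.na(.x), "", .x)),
      n_regulatory_categories = as.integer(.data$motif) +
        as.integer(.data$promoter_enhancer) + as.integer(.data$eqtl)) |>
    arrange(.data$snp_id)
  attr(out, "skipped") <- skipped
  out
}

#' Annotate a full SNP catalog
#'
#' Convenience driver combining [classify_genic_context()],
#' [annotate_regulatory()] and (when coding-variant and protein-site tables
#' are supplied) [annotate_protein_sites()]. Regulatory flags are computed
#' for every SNP, coding or not; summaries choose the denominator.
#'
#' @inheritParams annotate_regulatory
#' @param gene_index,exon_index Gene-model indices (may be `NULL`).
#' @param coding_variants,protein_sites Optional tibbles (see
#'   [read_coding_variants()], [read_protein_sites()]).
#' @return One row per distinct SNP: `snp_id, chrom, pos, genic_context`,
#'   the five flags, support strings, `n_regulatory_categories`.
#' @export
annotate_catalog <- function(snps, gene_index = NULL, exon_index = NULL,
                             motif_index = NULL, element_index = NULL,
                             eqtl = NULL, coding_variants = NULL,
                             protein_sites = NULL, eqtl_fdr = 0.05) {
  ann <- annotate_regulatory(snps, motif_index, element_index, eqtl,
                             eqtl_fdr = eqtl_fdr)
  skipped <- attr(ann, "skipped")
  ann <- classify_genic_context(ann, gene_index, exon_index)
  ann$ligand_site <- FALSE
  ann$phospho_site <- FALSE
  if (!is.null(coding_variants) && !is.null(protein_sites) &&
      nrow(coding_variants) > 0) {
    prot <- annotate_protein_sites(coding_variants, protein_sites) |>
      group_by(.data$snp_id) |>
      summarise(ligand_site = any(.data$ligand_site),
                phospho_site = any(.data$phospho_site), .groups = "drop")
    ann <- ann |>
      select(-"ligand_site", -"phospho_site") |>
      left_join(prot, by = "snp_id") |>
      mutate(ligand_site = !is.na(.data$ligand_site) & .data$ligand_site,
             phospho_site = !is.na(.data$phospho_site) & .data$phospho_site)
  }
  out <- ann |>
    select("snp_id", "chrom", "pos", "genic_context", "ligand_site",
           "phospho_site", "motif", "promoter_enhancer", "eqtl",
           "n_regulatory_categories", "support_motif",
           "support_promoter_enhancer", "support_eqtl") |>
    arrange(.data$snp_id)
  attr(out, "skipped") <- skipped
  out
}

#' Summarize functional-category coverage of a catalog
#'
#' Counts and proportions of SNPs per regulatory category and for the
#' at-least-one / more-than-one / all-three tiers, with the denominator
#' either all SNPs or noncoding (non-exonic) SNPs only. Flags are taken from
#' columns `motif, promoter_enhancer, eqtl` — pass an extended annotation
#' table (with those columns renamed from the `extended_` block) to
#' summarise post-LD coverage.
#'
#' @param annotations Annotation tibble ([annotate_catalog()]).
#' @param denominator_mode `"all"` or `"noncoding"`. `"noncoding"` drops
#'   exonic SNPs from both numerator and denominator and requires a
#'   `genic_context` column.
#' @return A one-row tibble: `denominator_mode, denominator, n_motif,
#'   n_promoter_enhancer, n_eqtl, at_least_1, more_than_1, all_3` plus
#'   matching `prop_*` columns (0 when the denominator is 0).
#' @export
summarize_annotations <- function(annotations,
                                  denominator_mode = c("all", "noncoding")) {
  denominator_mode <- match.arg(denominator_mode)
  df <- as_tibble(annotations)
  if (denominator_mode == "noncoding") {
    if (!"genic_context" %in% names(df)) {
      abort("denominator_mode = 'noncoding' needs a genic_context column")
    }
    df <- filter(df, .data$genic_context != "exonic")
  }
  n_cat <- as.integer(df$motif) + as.integer(df$promoter_enhancer) +
    as.integer(df$eqtl)
  denom <- nrow(df)
  counts <- tibble(
    denominator_mode = denominator_mode,
    denominator = denom,
    n_motif = sum(df$motif),
    n_promoter_enhancer = sum(df$promoter_enhancer),
    n_eqtl = sum(df$eqtl),
    at_least_1 = sum(n_cat >= 1L),
    more_than_1 = sum(n_cat > 1L),
    all_3 = sum(n_cat == 3L))
  props <- counts |>
    mutate(across(c("n_motif", "n_promoter_enhancer", "n_eqtl",
                    "at_least_1", "more_than_1", "all_3"),
                  ~if (denom > 0) .x / denom else 0,
                  .names = "prop_{sub('^n_', '', .col)}"))
  props
}
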