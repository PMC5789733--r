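#' Pipeline configuration
#'
#' Collects the input file paths and every analysis threshold. Defaults are
#' the study's stated values: eQTL FDR <= 0.05, LD r2 >= 0.8 within a 500-kb
#' flank, promoter flanks of 400 bp upstream / 50 bp downstream, tissue
#' expression at RPKM >= 1 in > 80% of samples, novel-association screen at
#' FDR < 0.1, and circuit inclusion for SNP-trait associations with
#' P < 0.05.
#'
#' @param input_dir Directory holding the canonical input files (the layout
#'   written by [simulate_inputs()]); individual paths can be overridden via
#'   `files`.
#' @param eqtl_fdr,r2_min,ld_window,promoter_up,promoter_down,rpkm_min,
#'   sample_frac,novel_fdr,circuit_p Analysis thresholds (see above).
#' @param n_bins Strata for [power_stratified_enrichment()].
#' @param denominator_mode `"all"` or `"noncoding"` for the headline
#'   summary; both are always written.
#' @param circuits Tibble `trait, tissue` of circuits to build; `NULL`
#'   builds one circuit per (trait, tissue) pair that has qualifying SNP
#'   element hits... by default the pair named in the simulation truth is
#'   supplied by the caller.
#' @param files Named list overriding default file names inside `input_dir`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir,
                            eqtl_fdr = 0.05, r2_min = 0.8,
                            ld_window = 500000L,
                            promoter_up = 400L, promoter_down = 50L,
                            rpkm_min = 1, sample_frac = 0.8,
                            novel_fdr = 0.1, circuit_p = 0.05,
                            n_bins = 10L,
                            denominator_mode = "all",
                            circuits = NULL,
                            files = list()) {
  defaults <- list(
    genes = "genes.bed", exons = "exons.bed", promoters = "promoters.bed",
    enhancers = "enhancers.bed", motifs = "motifs.bed",
    catalog = "catalog.tsv", background = "background.tsv",
    proxies = "proxies.tsv", eqtl = "eqtl.tsv", ld = "ld.tsv",
    network = "network.tsv", expression = "expression.tsv",
    samples = "samples.tsv", gene_disease = "gene_disease.tsv")
  files <- modifyList(defaults, files)
  paths <- purrr::map(files, ~file.path(input_dir, .x))
  stopifnot(eqtl_fdr >= 0, eqtl_fdr <= 1, r2_min >= 0, r2_min <= 1,
            ld_window >= 0, promoter_up >= 0, promoter_down >= 0,
            sample_frac >= 0, sample_frac < 1, novel_fdr > 0, novel_fdr <= 1,
            circuit_p > 0, circuit_p <= 1, n_bins >= 2)
  structure(list(paths = paths, eqtl_fdr = eqtl_fdr, r2_min = r2_min,
                 ld_window = ld_window, promoter_up = promoter_up,
                 promoter_down = promoter_down, rpkm_min = rpkm_min,
                 sample_frac = sample_frac, novel_fdr = novel_fdr,
                 circuit_p = circuit_p, n_bins = n_bins,
                 denominator_mode = denominator_mode, circuits = circuits),
            class = "pipeline_config")
}

#' Run the full annotation-to-circuits pipeline
#'
#' One-shot orchestration over plain-file handoffs: reads every input,
#' annotates the catalog, background and proxy SNPs, applies LD extension,
#' computes category enrichment against the background and the
#' power-stratified coverage trend, flags candidate novel associations,
#' builds the requested perturbed circuits, scores tissue expression, and
#' compares circuit-module versus nearest-gene disease enrichment. All
#' outputs are deterministic: rerunning on identical inputs reproduces every
#' file byte-for-byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the main in-memory results (`annotations`,
#'   `extended`, `enrichment`, `stratification`, `circuits`,
#'   `expression_summary`, `comparison`, `summary`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- config$paths
  op <- function(f) file.path(out_dir, f)

  genes <- read_bed_track(pth$genes, "gene")
  exons <- read_bed_track(pth$exons, "exon")
  promoters <- read_bed_track(pth$promoters, "promoter")
  enhancers <- read_bed_track(pth$enhancers, "enhancer")
  motifs <- read_bed_track(pth$motifs, "motif")
  catalog <- read_snp_catalog(pth$catalog, "phewas")
  background <- read_snp_catalog(pth$background, "background")
  proxies_tbl <- if (file.exists(pth$proxies))
    read_snp_catalog(pth$proxies, "background") else NULL
  eqtl <- read_eqtl_table(pth$eqtl)
  ld <- if (file.exists(pth$ld)) read_ld_table(pth$ld) else NULL
  network <- read_network(pth$network)
  exprs <- read_expression_matrix(pth$expression, pth$samples)
  gene_disease <- read_gene_disease_table(pth$gene_disease)

  gene_idx <- interval_index(genes)
  exon_idx <- interval_index(exons)
  motif_idx <- interval_index(motifs)
  element_idx <- interval_index(bind_rows(promoters, enhancers))

  ann_cat <- annotate_catalog(catalog, gene_idx, exon_idx, motif_idx,
                              element_idx, eqtl, eqtl_fdr = config$eqtl_fdr)
  ann_bg <- annotate_catalog(background, gene_idx, exon_idx, motif_idx,
                             element_idx, eqtl, eqtl_fdr = config$eqtl_fdr)
  write_annotated_catalog(ann_cat, op("annotated_catalog.tsv"))
  write_annotated_catalog(ann_bg, op("annotated_background.tsv"))

  # LD extension
  if (!is.null(ld) && !is.null(proxies_tbl) && nrow(ld) > 0) {
    ann_px <- annotate_catalog(proxies_tbl, gene_idx, exon_idx, motif_idx,
                               element_idx, eqtl, eqtl_fdr = config$eqtl_fdr)
    positions <- bind_rows(
      select(catalog, "snp_id", "chrom", "pos"),
      select(proxies_tbl, "snp_id", "chrom", "pos"))
    prox <- find_proxies(unique(catalog$snp_id), ld, r2_min = config$r2_min,
                         window_bp = config$ld_window, positions = positions)
    extended <- extend_annotations(ann_cat, ann_px, prox)
  } else {
    extended <- extend_annotations(
      ann_cat, ann_cat[0, ],
      tibble(index_snp_id = character(), proxy_snp_id = character(),
             r2 = double(), distance_bp = integer()))
  }
  ext_out <- extended |>
    select("snp_id", dplyr::starts_with("extended_"),
           dplyr::starts_with("proxies_")) |>
    arrange(.data$snp_id)
  write_tsv_stable(ext_out, op("extended_catalog.tsv"))

  summaries <- bind_rows(
    mutate(summarize_annotations(ann_cat, "all"), stage = "base"),
    mutate(summarize_annotations(ann_cat, "noncoding"), stage = "base"),
    mutate(summarize_annotations(extended_as_flags(extended), "all"),
           stage = "ld_extended"),
    mutate(summarize_annotations(extended_as_flags(extended), "noncoding"),
           stage = "ld_extended")) |>
    select("stage", dplyr::everything())
  write_tsv_stable(summaries, op("annotation_summary.tsv"))

  enr <- category_enrichment(
    ann_cat, ann_bg,
    categories = c("motif", "promoter_enhancer", "eqtl", "at_least_1",
                   "more_than_1", "all_3"))
  write_enrichment_report(enr, op("enrichment.tsv"))

  strat_input <- catalog |>
    distinct(.data$snp_id, .keep_all = TRUE) |>
    inner_join(select(ann_cat, "snp_id", "motif", "promoter_enhancer",
                      "eqtl"), by = "snp_id")
  strat <- power_stratified_enrichment(strat_input, n_bins = config$n_bins)
  write_tsv_stable(tidy(strat), op("stratification.tsv"))

  novel <- threshold_novel_associations(catalog, fdr_q = config$novel_fdr) |>
    arrange(.data$snp_id, .data$trait) |>
    select("snp_id", "trait", "p", "q_value", "candidate_novel")
  write_tsv_stable(novel, op("novel_associations.tsv"))

  # circuits per requested (trait, tissue)
  circuit_specs <- config$circuits
  if (is.null(circuit_specs)) {
    circuit_specs <- tibble(trait = character(), tissue = character())
  }
  circuits <- purrr::pmap(circuit_specs, function(trait, tissue) {
    sig <- filter(catalog, .data$trait == !!trait, .data$p < config$circuit_p)
    hits <- map_snps_to_elements(sig, promoters, enhancers,
                                 up_bp = config$promoter_up,
                                 down_bp = config$promoter_down)
    circ <- build_perturbed_circuit(hits, network, tissue, trait)
    write_circuit_edges(circ, op(paste0("circuit_", trait, "_", tissue,
                                        ".tsv")))
    circ
  })

  expr_summary <- tissue_specificity_z(exprs$expr, exprs$sample_map)
  write_tsv_stable(as_tibble(expr_summary), op("expression_summary.tsv"))
  expressed <- purrr::map(sort(unique(exprs$sample_map$tissue)),
                          ~tissue_expressed_genes(
                            exprs$expr, exprs$sample_map, .x,
                            rpkm_min = config$rpkm_min,
                            sample_frac = config$sample_frac)) |>
    bind_rows()
  write_tsv_stable(expressed, op("tissue_expressed.tsv"))

  # circuit-module vs nearest-gene disease enrichment
  universe <- sort(unique(genes$feature_id))
  comparison <- purrr::map2(circuits, seq_along(circuits), function(circ, i) {
    dz <- gene_disease$gene_id[gene_disease$disease == circ$trait]
    dz <- intersect(dz, universe)
    sig <- filter(catalog, .data$trait == circ$trait,
                  .data$p < config$circuit_p)
    near <- nearest_gene_set(sig, gene_idx)
    bind_rows(
      mutate(disease_gene_enrichment(intersect(circ$genes, universe), dz,
                                     universe),
             module = "circuit"),
      mutate(disease_gene_enrichment(near, dz, universe),
             module = "nearest_gene")) |>
      mutate(trait = circ$trait, tissue = circ$tissue) |>
      select("trait", "tissue", "module", dplyr::everything())
  }) |> bind_rows()
  if (nrow(comparison) > 0) {
    write_tsv_stable(comparison, op("module_comparison.tsv"))
  }

  summary <- list(
    n_catalog_snps = nrow(ann_cat),
    n_background_snvs = nrow(ann_bg),
    base_at_least_1 = summaries$prop_at_least_1[summaries$stage == "base" &
                                                  summaries$denominator_mode == "all"],
    extended_at_least_1 = summaries$prop_at_least_1[
      summaries$stage == "ld_extended" & summaries$denominator_mode == "all"],
    fold_change = setNames(as.list(signif(enr$fold_change, 6)), enr$category),
    stratification = list(pearson_r = signif(strat$pearson_r, 6),
                          pearson_p = signif(strat$pearson_p, 6)),
    n_candidate_novel = sum(novel$candidate_novel),
    circuits = purrr::map(circuits, ~as.list(glance(.x))))
  jsonlite::write_json(summary, op("summary.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(annotations = ann_cat, background_annotations = ann_bg,
                 extended = extended, summaries = summaries,
                 enrichment = enr, stratification = strat, novel = novel,
                 circuits = circuits, expression_summary = expr_summary,
                 tissue_expressed = expressed, comparison = comparison,
                 summary = summary))
}
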