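#' File formats
#'
#' Every tabular input uses one TSV dialect: tab-separated, UTF-8, leading
#' '#'-prefixed comment lines, a header row naming the columns below. Genomic
#' tracks use BED (0-based half-open, no header). Readers validate strictly
#' and reject malformed rows with the offending file line; they never coerce
#' silently. Writers emit deterministic column order, a fixed row sort and
#' numbers at 6 significant digits, so identical inputs give byte-identical
#' files.
#'
#' @name file-formats
NULL

count_leading_comments <- function(path) {
  head_lines <- readLines(path, n = 1000L, warn = FALSE)
  n <- 0L
  for (l in head_lines) {
    if (startsWith(l, "#")) n <- n + 1L else break
  }
  n
}

# data-row index -> file line number (header + leading comments)
file_line <- function(path, row, header = TRUE) {
  row + count_leading_comments(path) + if (header) 1L else 0L
}

read_tsv_strict <- function(path, col_types, required,
                            call = rlang::caller_env()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path), call = call)
  df <- suppressWarnings(
    readr::read_tsv(path, comment = "#", col_types = col_types,
                    progress = FALSE, na = c("", "NA")))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(paste0("malformed value in ", path, " at line ", probs$row[1] + 1L,
                 ": expected ", probs$expected[1], ", got '",
                 probs$actual[1], "'"), call = call)
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(path, " lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")), call = call)
  }
  as_tibble(df)
}

check_range <- function(df, path, col, lo, hi, lo_open = FALSE,
                        call = rlang::caller_env()) {
  v <- df[[col]]
  bad <- which(is.na(v) | v > hi | if (lo_open) v <= lo else v < lo)
  if (length(bad) > 0) {
    abort(paste0(path, " line ", file_line(path, bad[1]), ": ", col, " = ",
                 v[bad[1]], " outside ", if (lo_open) "(" else "[", lo, ",",
                 hi, "]"), call = call)
  }
  invisible(df)
}

check_nonempty <- function(df, path, col, call = rlang::caller_env()) {
  bad <- which(is.na(df[[col]]) | df[[col]] == "")
  if (length(bad) > 0) {
    abort(paste0(path, " line ", file_line(path, bad[1]), ": empty ", col),
          call = call)
  }
  invisible(df)
}

#' Read a SNP-trait association catalog
#'
#' Expects a TSV with header `snp_id, chrom, pos, trait, p` and optional
#' `n_cases`, emulating PheWAS/GWAS Catalog exports. Duplicate
#' `(snp_id, trait)` rows are collapsed keeping the smallest P value. P values
#' must lie in (0, 1]: a literal 0 is rejected because downstream work is on
#' the -log10 scale, so callers must floor their zeros explicitly.
#'
#' @param path TSV path.
#' @param source Catalog provenance: `"phewas"`, `"gwas"` or `"background"`.
#' @return A tibble with columns `snp_id, chrom, pos, trait, p, n_cases,
#'   source`, one row per (snp_id, trait) pair.
#' @export
read_snp_catalog <- function(path, source = c("phewas", "gwas", "background")) {
  source <- match.arg(source)
  df <- read_tsv_strict(
    path,
    col_types = readr::cols(
      snp_id = readr::col_character(), chrom = readr::col_character(),
      pos = readr::col_double(), trait = readr::col_character(),
      p = readr::col_double(), .default = readr::col_double()),
    required = c("snp_id", "chrom", "pos", "trait", "p"))
  check_nonempty(df, path, "snp_id")
  check_range(df, path, "p", 0, 1, lo_open = TRUE)
  check_range(df, path, "pos", 1, Inf)
  if (!"n_cases" %in% names(df)) df$n_cases <- NA_integer_
  df$pos <- as.integer(df$pos)
  df$n_cases <- as.integer(df$n_cases)
  df |>
    select("snp_id", "chrom", "pos", "trait", "p", "n_cases") |>
    arrange(.data$snp_id, .data$trait, .data$p) |>
    distinct(.data$snp_id, .data$trait, .keep_all = TRUE) |>
    mutate(source = source)
}

#' Read a BED track as genomic intervals
#'
#' Accepts BED3+ (`chrom, start, end[, name, score, strand]`). Intervals are
#' kept in the native 0-based half-open convention. Missing strand (or ".")
#' becomes unstranded. For motif tracks the `name` column carries the TF name
#' and is duplicated into a `tf` column.
#'
#' @param path BED path.
#' @param feature_kind One of `"gene", "exon", "promoter", "enhancer",
#'   "motif"`.
#' @return A tibble of intervals (see [interval_index()]).
#' @export
read_bed_track <- function(path, feature_kind) {
  feature_kind <- match.arg(feature_kind, VALID_KINDS)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (nrow(df) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), feature_id = character(),
                  feature_kind = character()))
  }
  if (ncol(df) < 3) abort(paste0(path, ": BED needs at least 3 columns"))
  start <- suppressWarnings(as.integer(df$X2))
  end <- suppressWarnings(as.integer(df$X3))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad) > 0) {
    abort(paste0(path, " line ", file_line(path, bad[1], header = FALSE),
                 ": invalid BED interval (need 0 <= start < end)"))
  }
  name <- if (ncol(df) >= 4) df$X4 else paste0(feature_kind, "_", seq_len(nrow(df)))
  strand <- if (ncol(df) >= 6) df$X6 else "."
  strand[is.na(strand) | strand == "."] <- "*"
  out <- tibble(chrom = df$X1, start = start, end = end, strand = strand,
                feature_id = name, feature_kind = feature_kind)
  if (feature_kind == "motif") out$tf <- name
  validate_intervals(out)
}

#' Write genomic intervals as BED
#'
#' Inverse of [read_bed_track()]: emits BED6 (`score` fixed at "."), rows
#' sorted by chromosome, start, end, feature_id, so output is byte-stable.
#' `write_bed_track(read_bed_track(x))` reproduces canonical input.
#'
#' @param intervals Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_track <- function(intervals, path) {
  intervals <- validate_intervals(intervals)
  intervals <- arrange(intervals, .data$chrom, .data$start, .data$end,
                       .data$feature_id)
  lines <- paste(intervals$chrom, intervals$start, intervals$end,
                 intervals$feature_id, ".",
                 ifelse(intervals$strand == "*", ".", intervals$strand),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a cis-eQTL table
#'
#' TSV with header `snp_id, gene_id, tissue, fdr`, emulating a GTEx
#' significant-pair export. The FDR <= 0.05 significance filter is applied
#' downstream (in [annotate_regulatory()]), not at read time.
#'
#' @param path TSV path.
#' @return Tibble with those four columns, `fdr` validated to [0, 1].
#' @export
read_eqtl_table <- function(path) {
  df <- read_tsv_strict(
    path,
    col_types = readr::cols(
      snp_id = readr::col_character(), gene_id = readr::col_character(),
      tissue = readr::col_character(), fdr = readr::col_double()),
    required = c("snp_id", "gene_id", "tissue", "fdr"))
  check_range(df, path, "fdr", 0, 1)
  select(df, "snp_id", "gene_id", "tissue", "fdr")
}

#' Read a pairwise LD table
#'
#' TSV with header `snp_a, snp_b, r2, distance_bp`, emulating SNAP proxy
#' output. The table is symmetrized on read: proxies of `b` include `a`
#' whenever `(a, b)` was listed. Self-pairs are dropped.
#'
#' @param path TSV path.
#' @return Symmetric tibble of pairs with `r2` in [0, 1] and non-negative
#'   distances.
#' @export
read_ld_table <- function(path) {
  df <- read_tsv_strict(
    path,
    col_types = readr::cols(
      snp_a = readr::col_character(), snp_b = readr::col_character(),
      r2 = readr::col_double(), distance_bp = readr::col_double()),
    required = c("snp_a", "snp_b", "r2", "distance_bp"))
  check_range(df, path, "r2", 0, 1)
  check_range(df, path, "distance_bp", 0, Inf)
  df$distance_bp <- as.integer(df$distance_bp)
  df <- select(df, "snp_a", "snp_b", "r2", "distance_bp")
  sym <- bind_rows(df, rename(df, snp_a = "snp_b", snp_b = "snp_a"))
  sym |>
    filter(.data$snp_a != .data$snp_b) |>
    arrange(.data$snp_a, .data$snp_b, dplyr::desc(.data$r2)) |>
    distinct(.data$snp_a, .data$snp_b, .keep_all = TRUE)
}

#' Read a protein functional-site table
#'
#' TSV with header `protein_id, residue_index, site_kind`; `site_kind` is
#' `ligand_binding` or `phosphorylation` (BioLiP / PhosphoSitePlus-style
#' extracts).
#'
#' @param path TSV path.
#' @return Tibble of sites with 1-based residue indices.
#' @export
read_protein_sites <- function(path) {
  df <- read_tsv_strict(
    path,
    col_types = readr::cols(
      protein_id = readr::col_character(),
      residue_index = readr::col_double(),
      site_kind = readr::col_character()),
    required = c("protein_id", "residue_index", "site_kind"))
  check_range(df, path, "residue_index", 1, Inf)
  bad <- which(!df$site_kind %in% c("ligand_binding", "phosphorylation"))
  if (length(bad) > 0) {
    abort(paste0(path, " line ", file_line(path, bad[1]),
                 ": unknown site_kind '", df$site_kind[bad[1]], "'"))
  }
  df$residue_index <- as.integer(df$residue_index)
  select(df, "protein_id", "residue_index", "site_kind")
}

#' Read a coding-variant table
#'
#' TSV with header `snp_id, protein_id, residue_index, aa_change` mapping
#' exonic SNPs to protein residues (e.g. "I359L").
#'
#' @param path TSV path.
#' @return Tibble of coding variants.
#' @export
read_coding_variants <- function(path) {
  df <- read_tsv_strict(
    path,
    col_types = readr::cols(
      snp_id = readr::col_character(), protein_id = readr::col_character(),
      residue_index = readr::col_double(), aa_change = readr::col_character()),
    required = c("snp_id", "protein_id", "residue_index", "aa_change"))
  check_range(df, path, "residue_index", 1, Inf)
  df$residue_index <- as.integer(df$residue_index)
  select(df, "snp_id", "protein_id", "residue_index", "aa_change")
}

#' Read a tissue-specific regulatory network edge list
#'
#' TSV with header `tf, element_id, element_kind, target, tissue` emulating
#' a regulatorycircuits.org-style TF -> promoter/enhancer -> target-gene
#' network.
#'
#' @param path TSV path.
#' @return Tibble of edges, `element_kind` in {promoter, enhancer}.
#' @export
read_network <- function(path) {
  df <- read_tsv_strict(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    required = c("tf", "element_id", "element_kind", "target", "tissue"))
  bad <- which(!df$element_kind %in% c("promoter", "enhancer"))
  if (length(bad) > 0) {
    abort(paste0(path, " line ", file_line(path, bad[1]),
                 ": unknown element_kind '", df$element_kind[bad[1]], "'"))
  }
  df |>
    select("tf", "element_id", "element_kind", "target", "tissue") |>
    distinct()
}

#' Read a genes-by-samples expression matrix with its sample->tissue map
#'
#' The matrix TSV has a `gene_id` column followed by one column per sample
#' (RPKM-scale, non-negative); the map TSV has header `sample, tissue`.
#' Every matrix sample must appear in the map.
#'
#' @param matrix_path,map_path TSV paths.
#' @return List with `expr` (long tibble `gene_id, sample, value`) and
#'   `sample_map` (tibble `sample, tissue`).
#' @export
read_expression_matrix <- function(matrix_path, map_path) {
  mat <- read_tsv_strict(matrix_path,
                         col_types = readr::cols(
                           gene_id = readr::col_character(),
                           .default = readr::col_double()),
                         required = "gene_id")
  smap <- read_tsv_strict(map_path,
                          col_types = readr::cols(.default = readr::col_character()),
                          required = c("sample", "tissue"))
  samples <- setdiff(names(mat), "gene_id")
  if (length(samples) == 0) abort(paste0(matrix_path, ": no sample columns"))
  missing_samples <- setdiff(samples, smap$sample)
  if (length(missing_samples) > 0) {
    abort(paste0(matrix_path, ": sample(s) absent from tissue map: ",
                 paste(head(missing_samples, 5), collapse = ", ")))
  }
  long <- tidyr::pivot_longer(mat, -"gene_id", names_to = "sample",
                              values_to = "value")
  if (any(is.na(long$value) | long$value < 0)) {
    bad <- long[which(is.na(long$value) | long$value < 0)[1], ]
    abort(paste0(matrix_path, ": negative or missing expression for gene ",
                 bad$gene_id, ", sample ", bad$sample))
  }
  list(expr = long, sample_map = select(smap, "sample", "tissue"))
}

#' Read a gene-disease association table
#'
#' TSV with header `gene_id, disease` (DisGeNET-style extract).
#'
#' @param path TSV path.
#' @return Tibble of distinct gene-disease pairs.
#' @export
read_gene_disease_table <- function(path) {
  df <- read_tsv_strict(path,
                        col_types = readr::cols(.default = readr::col_character()),
                        required = c("gene_id", "disease"))
  check_nonempty(df, path, "gene_id")
  df |> select("gene_id", "disease") |> distinct()
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    formatC(v, digits = 6, format = "g")
  }, character(1))
  out
}

#' Write a tibble as a deterministic TSV
#'
#' Numeric columns are printed at 6 significant digits; rows must already be
#' in their canonical sort order. Two runs over identical input produce
#' byte-identical files.
#'
#' @param df Tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_stable <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- fmt_num(out[[col]])
    else if (is.logical(out[[col]])) out[[col]] <- ifelse(out[[col]], "TRUE", "FALSE")
    else out[[col]] <- as.character(out[[col]])
  }
  lines <- c(paste(names(out), collapse = "\t"),
             if (nrow(out) > 0) do.call(paste, c(unname(as.list(out)), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Write / re-read an annotated SNP catalog
#'
#' One row per SNP: genic context, the five functional flags and their
#' semicolon-joined supporting features. Rows are sorted by `snp_id`.
#'
#' @param annotations Tibble from [annotate_catalog()].
#' @param path Output path.
#' @return `path` invisibly; `read_annotated_catalog()` returns the tibble.
#' @export
write_annotated_catalog <- function(annotations, path) {
  cols <- c("snp_id", "genic_context", "ligand_site", "phospho_site",
            "motif", "promoter_enhancer", "eqtl", "n_regulatory_categories",
            "support_motif", "support_promoter_enhancer", "support_eqtl")
  df <- annotations |>
    select(dplyr::any_of(cols)) |>
    arrange(.data$snp_id)
  write_tsv_stable(df, path)
}

#' @rdname write_annotated_catalog
#' @export
read_annotated_catalog <- function(path) {
  df <- read_tsv_strict(
    path,
    col_types = readr::cols(
      snp_id = readr::col_character(),
      genic_context = readr::col_character(),
      ligand_site = readr::col_logical(), phospho_site = readr::col_logical(),
      motif = readr::col_logical(), promoter_enhancer = readr::col_logical(),
      eqtl = readr::col_logical(),
      n_regulatory_categories = readr::col_integer(),
      .default = readr::col_character()),
    required = c("snp_id", "motif", "promoter_enhancer", "eqtl"))
  for (col in intersect(c("support_motif", "support_promoter_enhancer",
                          "support_eqtl"), names(df))) {
    df[[col]][is.na(df[[col]])] <- ""
  }
  df
}

#' Write an enrichment report as TSV and JSON
#'
#' @param results Tibble from [category_enrichment()].
#' @param path Output TSV path; a sibling `.json` file is written alongside.
#' @return `path`, invisibly.
#' @export
write_enrichment_report <- function(results, path) {
  df <- results |>
    select(dplyr::any_of(c("category", "a", "b", "c", "d", "fold_change",
                           "p_value", "log10_p"))) |>
    arrange(match(.data$category, unique(.data$category)))
  write_tsv_stable(df, path)
  json_path <- paste0(sub("\\.tsv$", "", path), ".json")
  payload <- purrr::transpose(as.list(df) |> purrr::map(as.list))
  jsonlite::write_json(
    purrr::map(payload, function(r) purrr::map(r, ~signif_or_na(.x))),
    json_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

signif_or_na <- function(x) {
  if (is.numeric(x) && !is.na(x)) signif(x, 6) else x
}

#' Write perturbed-circuit edges
#'
#' Columns `tf, element_id, element_kind, target, tissue, perturbation_kind,
#' witness_snps` (semicolon-joined), sorted by tf, element, target.
#'
#' @param circuit A `perturbed_circuit` object or its `edges` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_circuit_edges <- function(circuit, path) {
  edges <- if (inherits(circuit, "perturbed_circuit")) circuit$edges else circuit
  edges <- edges |>
    select("tf", "element_id", "element_kind", "target", "tissue",
           "perturbation_kind", "witness_snps") |>
    arrange(.data$tf, .data$element_id, .data$target)
  write_tsv_stable(edges, path)
}
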