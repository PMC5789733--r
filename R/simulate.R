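#' Simulation configuration with planted ground truth
#'
#' Builds the configuration for the synthetic-data generator that emulates
#' every input the pipeline consumes: a gene model with promoters adjacent to
#' gene 5' ends, enhancer/motif tracks, SNP-trait catalogs placed into
#' functional elements with planted per-category probabilities, an LD table
#' with planted functional proxies, tissue-specific TF-element-target
#' networks with planted perturbed edges, a log-normal expression matrix
#' with planted tissue-specific genes, and a disease-gene table biased
#' toward circuit targets.
#'
#' Category placement follows `prob_background` for the background SNV set
#' and `prob_background * fold` for the catalog, so `fold` is the planted
#' enrichment fold-change per category. The defaults plant the catalog
#' proportions 12.6% (motif), 34.8% (promoter/enhancer) and 38.8% (eQTL)
#' with folds 1.32, 1.42 and 14.6 over background.
#'
#' @param seed Master seed; each generator stage derives its own stream so
#'   changing one stage's parameters does not perturb the others' draws.
#' @param ... Overrides for any default field (see the function body for the
#'   full list; nested lists such as `ld`, `network`, `expression`,
#'   `perturb`, `disease` are replaced member-wise).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    n_chroms = 1L,
    chrom_length = 1e7,
    n_genes = 200L,
    exons_per_gene = 3L,
    gene_length = c(2000L, 8000L),
    promoter_length = 1000L,
    n_enhancers = 150L,
    enhancer_length = c(500L, 2000L),
    n_motifs = 300L,
    motif_length = c(8L, 20L),
    motif_in_element_frac = 0.5,
    n_network_promoters = 40L,
    n_network_enhancers = 40L,
    n_catalog_snps = 5000L,
    n_background_snvs = 50000L,
    prob_background = c(motif = 0.126 / 1.32, promoter_enhancer = 0.348 / 1.42,
                        eqtl = 0.388 / 14.6),
    fold = c(motif = 1.32, promoter_enhancer = 1.42, eqtl = 14.6),
    power_slope = 0,
    p_log10_range = c(1.301, 8),
    n_traits = 20L,
    ld = list(tagging_prob = 0.5, r2_range = c(0.8, 1),
              max_distance = 500000L, n_distractors = 500L),
    network = list(n_tfs = 30L, tfs_per_element = 2L,
                   element_frac_per_tissue = 0.8),
    tissues = paste0("tissue_", 1:4),
    samples_per_tissue = 50L,
    expression = list(log_mean = 1, log_sd = 1, tissue_sd = 0.3,
                      noise_sd = 0.5, n_specific_genes = 10L,
                      specific_effect_sd = 4),
    perturb = list(n_edges = 5L, trait = "trait_1", tissue = "tissue_1",
                   enhancer_frac = 0.7),
    disease = list(n_genes = 30L, excess = 8)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]] <- modifyList(cfg[[nm]], dots[[nm]])
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  probs <- cfg$prob_background * cfg$fold[names(cfg$prob_background)]
  if (any(probs > 1 | cfg$prob_background < 0)) {
    abort("planted catalog probability (prob_background * fold) exceeds 1")
  }
  cfg$prob_catalog <- probs
  structure(cfg, class = "sim_config")
}

# independent RNG stream per generator stage
stage_seed <- function(seed, stage) {
  offset <- match(stage, c("tracks", "network", "catalogs", "ld",
                           "expression", "disease"))
  as.integer((abs(seed) * 131L + offset * 7919L) %% .Machine$integer.max)
}

runif_int <- function(n, lo, hi) as.integer(floor(runif(n, lo, hi + 1)))

#' Generate the synthetic gene model and regulatory tracks
#'
#' Lays genes (with exons and a stranded promoter adjacent to each gene's 5'
#' end), enhancers and motif occurrences along the genome without overlap
#' between units; a configured fraction of motifs is nested inside
#' (non-network) enhancers so that multi-category SNP placement is possible.
#' A subset of promoters and enhancers is reserved for the regulatory
#' networks and excluded from the general SNP placement pools, so only
#' deliberately planted SNPs can perturb circuit edges.
#'
#' @param cfg A [sim_config()].
#' @return List of interval tibbles (`genes, exons, promoters, enhancers,
#'   motifs`), the placement `pools` (disjoint GRanges: motif-only,
#'   element-only, motif-and-element, neither), and the reserved network
#'   element ids.
#' @export
sim_genome_tracks <- function(cfg) {
  set.seed(stage_seed(cfg$seed, "tracks"))
  chroms <- paste0("chr", seq_len(cfg$n_chroms))

  n_nested <- round(cfg$n_motifs * cfg$motif_in_element_frac)
  n_free_motifs <- cfg$n_motifs - n_nested

  gene_len <- runif_int(cfg$n_genes, cfg$gene_length[1], cfg$gene_length[2])
  enh_len <- runif_int(cfg$n_enhancers, cfg$enhancer_length[1],
                       cfg$enhancer_length[2])
  motif_len <- runif_int(cfg$n_motifs, cfg$motif_length[1], cfg$motif_length[2])

  units <- bind_rows(
    tibble(kind = "gene", id = seq_len(cfg$n_genes),
           len = gene_len + cfg$promoter_length),
    tibble(kind = "enhancer", id = seq_len(cfg$n_enhancers), len = enh_len),
    tibble(kind = "motif", id = seq_len(n_free_motifs),
           len = motif_len[seq_len(n_free_motifs)]))
  units <- units[sample(nrow(units)), ]
  units$chrom <- sample(chroms, nrow(units), replace = TRUE)

  genes <- exons <- promoters <- enhancers <- motifs <- list()
  for (ch in chroms) {
    u <- units[units$chrom == ch, , drop = FALSE]
    slack <- cfg$chrom_length - sum(u$len)
    if (slack < nrow(u) + 1) {
      abort("infeasible packing: elements exceed genome size")
    }
    g <- runif(nrow(u) + 1)
    gaps <- floor(slack * g / sum(g))
    cursor <- 0L
    for (i in seq_len(nrow(u))) {
      cursor <- cursor + gaps[i]
      s <- as.integer(cursor)
      e <- as.integer(cursor + u$len[i])
      if (u$kind[i] == "gene") {
        gid <- paste0("gene_", u$id[i])
        strand <- sample(c("+", "-"), 1)
        if (strand == "+") {
          ps <- s; pe <- s + cfg$promoter_length
          gs <- pe; ge <- e
        } else {
          gs <- s; ge <- e - cfg$promoter_length
          ps <- ge; pe <- e
        }
        glen <- ge - gs
        promoters[[length(promoters) + 1]] <- tibble(
          chrom = ch, start = ps, end = pe, strand = strand,
          feature_id = paste0("prom_", u$id[i]), feature_kind = "promoter",
          gene_id = gid)
        genes[[length(genes) + 1]] <- tibble(
          chrom = ch, start = gs, end = ge, strand = strand,
          feature_id = gid, feature_kind = "gene")
        k <- cfg$exons_per_gene
        elen <- max(50L, as.integer(floor(0.08 * glen)))
        estart <- gs + as.integer(floor((seq_len(k) - 1) * glen / k))
        exons[[length(exons) + 1]] <- tibble(
          chrom = ch, start = estart,
          end = pmin(estart + elen, ge), strand = strand,
          feature_id = paste0(gid, "_exon", seq_len(k)),
          feature_kind = "exon")
      } else if (u$kind[i] == "enhancer") {
        enhancers[[length(enhancers) + 1]] <- tibble(
          chrom = ch, start = s, end = e, strand = "*",
          feature_id = paste0("enh_", u$id[i]), feature_kind = "enhancer")
      } else {
        motifs[[length(motifs) + 1]] <- tibble(
          chrom = ch, start = s, end = e, strand = "*",
          feature_id = paste0("TF_", (u$id[i] %% 25L) + 1L),
          feature_kind = "motif")
      }
      cursor <- cursor + u$len[i]
    }
  }
  genes <- bind_rows(genes); exons <- bind_rows(exons)
  promoters <- bind_rows(promoters); enhancers <- bind_rows(enhancers)
  motifs <- bind_rows(motifs)

  net_prom <- sort(sample(promoters$feature_id,
                          min(cfg$n_network_promoters, nrow(promoters))))
  net_enh <- sort(sample(enhancers$feature_id,
                         min(cfg$n_network_enhancers, nrow(enhancers))))

  # nest the remaining motifs inside non-network enhancers
  host_pool <- filter(enhancers, !.data$feature_id %in% net_enh)
  if (n_nested > 0 && nrow(host_pool) > 0) {
    hosts <- host_pool[sample(nrow(host_pool), n_nested, replace = TRUE), ]
    mlen <- motif_len[n_free_motifs + seq_len(n_nested)]
    mstart <- hosts$start +
      as.integer(floor(runif(n_nested) * pmax(hosts$end - hosts$start - mlen, 1)))
    motifs <- bind_rows(motifs, tibble(
      chrom = hosts$chrom, start = mstart,
      end = pmin(mstart + mlen, hosts$end), strand = "*",
      feature_id = paste0("TF_", (seq_len(n_nested) %% 25L) + 1L),
      feature_kind = "motif"))
  }
  motifs$tf <- motifs$feature_id
  motifs$feature_id <- paste0(motifs$feature_id, "_occ", seq_len(nrow(motifs)))

  to_gr <- function(df) {
    if (nrow(df) == 0) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(df$start + 1L, df$end))
  }
  red <- function(gr) GenomicRanges::reduce(gr, ignore.strand = TRUE)
  genome_gr <- GenomicRanges::GRanges(
    chroms, IRanges::IRanges(1L, as.integer(cfg$chrom_length)))
  # network elements plus their promoter flanks are walled off from every pool
  netp <- filter(promoters, .data$feature_id %in% net_prom)
  netp_flank <- netp |>
    mutate(start = pmax(.data$start - 400L, 0L), end = .data$end + 400L)
  net_gr <- red(c(to_gr(netp_flank),
                  to_gr(filter(enhancers, .data$feature_id %in% net_enh))))
  m_gr <- red(to_gr(motifs))
  p_gr <- red(c(to_gr(filter(promoters, !.data$feature_id %in% net_prom)),
                to_gr(filter(enhancers, !.data$feature_id %in% net_enh))))
  pools <- list(
    motif_only = GenomicRanges::setdiff(m_gr, GenomicRanges::union(p_gr, net_gr)),
    element_only = GenomicRanges::setdiff(p_gr, GenomicRanges::union(m_gr, net_gr)),
    motif_and_element = GenomicRanges::setdiff(
      GenomicRanges::intersect(m_gr, p_gr), net_gr),
    neither = GenomicRanges::setdiff(
      genome_gr, Reduce(GenomicRanges::union, list(m_gr, p_gr, net_gr))))

  list(genes = genes, exons = exons, promoters = promoters,
       enhancers = enhancers, motifs = motifs, pools = pools,
       network_promoters = net_prom, network_enhancers = net_enh,
       chroms = chroms)
}

sample_pool_positions <- function(pool_gr, n) {
  if (n == 0) {
    return(tibble(chrom = character(), pos = integer()))
  }
  if (length(pool_gr) == 0 || sum(as.numeric(IRanges::width(pool_gr))) == 0) {
    abort("planted placement probability exceeds achievable coverage: empty pool")
  }
  w <- as.numeric(IRanges::width(pool_gr))
  cum <- cumsum(w)
  r <- runif(n) * cum[length(cum)]
  idx <- findInterval(r, cum) + 1L
  offset <- floor(r - c(0, cum)[idx])
  tibble(chrom = as.character(GenomicRanges::seqnames(pool_gr))[idx],
         pos = as.integer(GenomicRanges::start(pool_gr)[idx] + offset))
}

#' Generate synthetic tissue networks, perturbations and expression
#'
#' Builds per-tissue TF -> element -> target edge lists over the reserved
#' network elements (a promoter targets its own gene; enhancers target
#' random genes), plants a set of perturbed edges by placing witness catalog
#' SNPs inside their elements — promoter witnesses cycle through the element
#' body and the outermost upstream (400th bp) and downstream (50th bp) flank
#' bases on the promoter's strand — and simulates a log-normal genes x
#' samples expression matrix with planted tissue-specific genes whose
#' per-tissue mean sits `specific_effect_sd` standard deviations above the
#' others.
#'
#' @param cfg A [sim_config()].
#' @param tracks Output of [sim_genome_tracks()].
#' @return List: `network` (edge tibble), `witness_snps` (catalog rows that
#'   perturb circuits), `perturbed_edges` (ground-truth edges), `expr` (long
#'   expression tibble), `sample_map`, `specific_genes` (ground truth).
#' @export
sim_network_expression <- function(cfg, tracks) {
  set.seed(stage_seed(cfg$seed, "network"))
  genes <- tracks$genes$feature_id
  if (length(cfg$tissues) == 0) abort("at least one tissue is required")
  tfs <- sort(sample(genes, min(cfg$network$n_tfs, length(genes))))

  prom <- filter(tracks$promoters, .data$feature_id %in% tracks$network_promoters)
  enh <- filter(tracks$enhancers, .data$feature_id %in% tracks$network_enhancers)
  n_enh_w <- round(cfg$perturb$n_edges * cfg$perturb$enhancer_frac /
                     cfg$network$tfs_per_element)
  elements <- bind_rows(
    tibble(element_id = prom$feature_id, element_kind = "promoter",
           target = prom$gene_id),
    tibble(element_id = enh$feature_id, element_kind = "enhancer",
           target = sample(genes, nrow(enh), replace = TRUE)))
  base_edges <- elements |>
    tidyr::crossing(slot = seq_len(cfg$network$tfs_per_element)) |>
    mutate(tf = sample(tfs, n(), replace = TRUE)) |>
    select("tf", "element_id", "element_kind", "target") |>
    distinct()
  network <- purrr::map(cfg$tissues, function(ts) {
    keep <- runif(nrow(elements)) < cfg$network$element_frac_per_tissue
    kept <- elements$element_id[keep]
    base_edges |>
      filter(.data$element_id %in% kept) |>
      mutate(tissue = ts)
  }) |> bind_rows()

  # plant perturbed edges in the configured tissue
  pt <- cfg$perturb$tissue
  net_t <- filter(network, .data$tissue == pt)
  avail <- unique(net_t$element_id)
  if (cfg$perturb$n_edges > nrow(net_t)) {
    abort("requested perturbed edges exceed edges available in the tissue network")
  }
  enh_avail <- intersect(avail, enh$feature_id)
  prom_avail <- intersect(avail, prom$feature_id)
  chosen <- character()
  covered <- 0L
  pick_order <- c(sample(enh_avail, min(n_enh_w, length(enh_avail))),
                  sample(prom_avail), sample(setdiff(enh_avail, character())))
  pick_order <- unique(pick_order)
  for (el in pick_order) {
    if (covered >= cfg$perturb$n_edges) break
    chosen <- c(chosen, el)
    covered <- covered + sum(net_t$element_id == el)
  }
  perturbed_edges <- net_t |>
    filter(.data$element_id %in% chosen) |>
    arrange(.data$tf, .data$element_id, .data$target)

  # witness SNP per chosen element; promoter witnesses exercise the
  # body / 400-bp-upstream-boundary / 50-bp-downstream-boundary positions
  rule_cycle <- 0L
  wit <- purrr::map(seq_along(chosen), function(i) {
    el <- chosen[i]
    if (el %in% prom$feature_id) {
      pr <- prom[prom$feature_id == el, ]
      rule_cycle <<- rule_cycle + 1L
      rule <- c("body", "up_boundary", "down_boundary")[(rule_cycle - 1L) %% 3L + 1L]
      pos <- if (rule == "body") {
        as.integer(floor((pr$start + pr$end) / 2)) + 1L
      } else if (rule == "up_boundary") {
        if (pr$strand == "+") pr$start - 400L + 1L else pr$end + 400L
      } else {
        if (pr$strand == "+") pr$end + 50L else pr$start - 50L + 1L
      }
      tibble(chrom = pr$chrom, pos = as.integer(pos))
    } else {
      en <- enh[enh$feature_id == el, ]
      tibble(chrom = en$chrom,
             pos = as.integer(floor((en$start + en$end) / 2)) + 1L)
    }
  }) |> bind_rows()
  witness_snps <- if (nrow(wit) > 0) {
    wit |>
      mutate(snp_id = paste0("rs_w", seq_len(nrow(wit))),
             trait = cfg$perturb$trait,
             p = 10^-runif(nrow(wit), 6, 8),
             n_cases = NA_integer_, source = "phewas") |>
      select("snp_id", "chrom", "pos", "trait", "p", "n_cases", "source")
  } else {
    tibble(snp_id = character(), chrom = character(), pos = integer(),
           trait = character(), p = double(), n_cases = integer(),
           source = character())
  }

  # expression matrix
  set.seed(stage_seed(cfg$seed, "expression"))
  ex <- cfg$expression
  n_genes <- length(genes)
  tissues <- cfg$tissues
  mu_g <- rnorm(n_genes, ex$log_mean, ex$log_sd)
  eps <- matrix(rnorm(n_genes * length(tissues), 0, ex$tissue_sd),
                nrow = n_genes)
  spec_genes <- sort(sample(genes, min(ex$n_specific_genes, n_genes)))
  spec_tissue <- tissues[(seq_along(spec_genes) - 1L) %% length(tissues) + 1L]
  for (i in seq_along(spec_genes)) {
    gi <- match(spec_genes[i], genes)
    ti <- match(spec_tissue[i], tissues)
    eps[gi, ti] <- ex$specific_effect_sd * ex$tissue_sd
  }
  sample_map <- tibble(
    tissue = rep(tissues, each = cfg$samples_per_tissue),
    sample = paste0(rep(tissues, each = cfg$samples_per_tissue), "_s",
                    sprintf("%02d", rep(seq_len(cfg$samples_per_tissue),
                                        length(tissues))))) |>
    select("sample", "tissue")
  expr <- tidyr::crossing(gene_id = genes, sample = sample_map$sample) |>
    left_join(sample_map, by = "sample") |>
    mutate(value = exp(mu_g[match(.data$gene_id, genes)] +
                         eps[cbind(match(.data$gene_id, genes),
                                   match(.data$tissue, tissues))] +
                         rnorm(n(), 0, ex$noise_sd))) |>
    select("gene_id", "sample", "value")

  list(network = network, witness_snps = witness_snps,
       perturbed_edges = perturbed_edges, expr = expr,
       sample_map = sample_map,
       specific_genes = tibble(gene_id = spec_genes, tissue = spec_tissue))
}

#' Generate the synthetic SNP catalog, background SNVs and eQTL table
#'
#' Draws each catalog SNP's category memberships (motif, promoter/enhancer,
#' eQTL) independently with the planted catalog probabilities, then places
#' it uniformly in the matching disjoint placement pool; background SNVs use
#' the (lower) background probabilities. eQTL membership is realised as rows
#' in the eQTL table at FDR <= 0.05 (plus super-threshold distractor rows).
#' Catalog P values are drawn log-uniformly over `p_log10_range` and, when
#' `power_slope` is non-zero, each category's placement probability is
#' shifted by `power_slope * (-log10 p - mean)` so annotation coverage
#' trends with association strength.
#'
#' @param cfg A [sim_config()].
#' @param tracks Output of [sim_genome_tracks()].
#' @param witness_snps Witness rows from [sim_network_expression()] to append
#'   to the catalog (counted inside `n_catalog_snps`).
#' @return List: `catalog`, `background`, `proxy` positions placeholder,
#'   `eqtl` table, and `truth` (per-SNP planted flags and realized counts).
#' @export
sim_catalogs <- function(cfg, tracks, witness_snps = NULL) {
  set.seed(stage_seed(cfg$seed, "catalogs"))
  n_wit <- if (is.null(witness_snps)) 0L else nrow(witness_snps)
  n_gen <- cfg$n_catalog_snps - n_wit
  if (n_gen < 0) abort("n_catalog_snps smaller than the witness count")

  draw_set <- function(n, probs, u = NULL, id_prefix, source) {
    if (n == 0) {
      return(list(snps = tibble(snp_id = character(), chrom = character(),
                                pos = integer(), trait = character(),
                                p = double(), n_cases = integer(),
                                source = character()),
                  flags = tibble(snp_id = character(), motif = logical(),
                                 promoter_enhancer = logical(),
                                 eqtl = logical())))
    }
    adj <- function(base) {
      if (is.null(u) || cfg$power_slope == 0) return(rep(base, n))
      pmin(pmax(base + cfg$power_slope * (u - mean(u)), 0), 1)
    }
    m_flag <- runif(n) < adj(probs[["motif"]])
    pe_flag <- runif(n) < adj(probs[["promoter_enhancer"]])
    e_flag <- runif(n) < adj(probs[["eqtl"]])
    pool_of <- dplyr::case_when(
      m_flag & pe_flag ~ "motif_and_element",
      m_flag ~ "motif_only",
      pe_flag ~ "element_only",
      TRUE ~ "neither")
    pos <- tibble(chrom = character(n), pos = integer(n))
    for (pl in unique(pool_of)) {
      sel <- which(pool_of == pl)
      pos[sel, ] <- sample_pool_positions(tracks$pools[[pl]], length(sel))
    }
    snps <- tibble(snp_id = paste0(id_prefix, seq_len(n)),
                   chrom = pos$chrom, pos = pos$pos)
    list(snps = snps,
         flags = tibble(snp_id = snps$snp_id, motif = m_flag,
                        promoter_enhancer = pe_flag, eqtl = e_flag))
  }

  u <- runif(n_gen, cfg$p_log10_range[1], cfg$p_log10_range[2])
  cat_set <- draw_set(n_gen, cfg$prob_catalog, u = u, id_prefix = "rs",
                      source = "phewas")
  catalog <- cat_set$snps |>
    mutate(trait = sample(paste0("trait_", seq_len(cfg$n_traits)), n_gen,
                          replace = TRUE),
           p = 10^-u, n_cases = NA_integer_, source = "phewas")
  if (n_wit > 0) catalog <- bind_rows(catalog, witness_snps)

  bg_set <- draw_set(cfg$n_background_snvs, cfg$prob_background,
                     id_prefix = "kg", source = "background")
  background <- bg_set$snps |>
    mutate(trait = "background",
           p = pmax(runif(cfg$n_background_snvs), 1e-12),
           n_cases = NA_integer_, source = "background")

  # realise eQTL membership as table rows (FDR <= 0.05), plus distractors
  eqtl_members <- c(cat_set$flags$snp_id[cat_set$flags$eqtl],
                    bg_set$flags$snp_id[bg_set$flags$eqtl])
  all_genes <- tracks$genes$feature_id
  eqtl <- tibble(
    snp_id = eqtl_members,
    gene_id = sample(all_genes, length(eqtl_members), replace = TRUE),
    tissue = sample(cfg$tissues, length(eqtl_members), replace = TRUE),
    fdr = runif(length(eqtl_members), 0, 0.05))
  non_members <- setdiff(c(cat_set$flags$snp_id, bg_set$flags$snp_id),
                         eqtl_members)
  n_distr <- min(1000L, length(non_members))
  if (n_distr > 0) {
    distr <- sample(non_members, n_distr)
    eqtl <- bind_rows(eqtl, tibble(
      snp_id = distr,
      gene_id = sample(all_genes, n_distr, replace = TRUE),
      tissue = sample(cfg$tissues, n_distr, replace = TRUE),
      fdr = runif(n_distr, 0.051, 1)))
  }
  eqtl <- arrange(eqtl, .data$snp_id, .data$gene_id, .data$tissue)

  truth_flags <- bind_rows(
    mutate(cat_set$flags, set = "catalog"),
    mutate(bg_set$flags, set = "background"))
  list(catalog = catalog, background = background, eqtl = eqtl,
       truth = list(
         flags = truth_flags,
         planted_fold = cfg$fold,
         prob_catalog = cfg$prob_catalog,
         prob_background = cfg$prob_background,
         realized_catalog = colMeans(cat_set$flags[c("motif",
                                                     "promoter_enhancer",
                                                     "eqtl")]),
         realized_background = colMeans(bg_set$flags[c("motif",
                                                       "promoter_enhancer",
                                                       "eqtl")])))
}

#' Generate the synthetic LD table with planted functional proxies
#'
#' A configured fraction of the catalog SNPs that carry no planted category
#' receives a proxy SNP in strong LD (r2 drawn from `r2_range`, distance <=
#' `max_distance`) placed inside a promoter/enhancer placement pool, so that
#' LD extension should recover the tagging. Distractor pairs that fail the
#' r2 threshold or the distance window (also pointing at functional
#' positions) are added to exercise the filters.
#'
#' @param cfg A [sim_config()].
#' @param catalogs Output of [sim_catalogs()].
#' @param tracks Output of [sim_genome_tracks()].
#' @return List: `ld` (pair tibble), `proxy_snps` (coordinate table for all
#'   proxy SNPs), `taggings` (ground-truth planted index-proxy pairs).
#' @export
sim_ld <- function(cfg, catalogs, tracks) {
  set.seed(stage_seed(cfg$seed, "ld"))
  flags <- filter(catalogs$truth$flags, .data$set == "catalog")
  unannotated <- flags$snp_id[!(flags$motif | flags$promoter_enhancer |
                                  flags$eqtl)]
  tagged <- unannotated[runif(length(unannotated)) < cfg$ld$tagging_prob]
  cat_pos <- distinct(catalogs$catalog, .data$snp_id, .data$chrom, .data$pos)
  pool <- tracks$pools$element_only
  pool_tbl <- tibble(chrom = as.character(GenomicRanges::seqnames(pool)),
                     start = GenomicRanges::start(pool),
                     end = GenomicRanges::end(pool))

  mk_proxy <- function(ids, max_d, lab) {
    rows <- purrr::map(ids, function(id) {
      snp <- cat_pos[cat_pos$snp_id == id, ]
      cand <- pool_tbl |>
        filter(.data$chrom == snp$chrom,
               .data$start <= snp$pos + max_d,
               .data$end >= snp$pos - max_d)
      if (nrow(cand) == 0) return(NULL)
      iv <- cand[sample(nrow(cand), 1), ]
      lo <- max(iv$start, snp$pos - max_d)
      hi <- min(iv$end, snp$pos + max_d)
      tibble(index_snp_id = id, chrom = snp$chrom,
             proxy_pos = runif_int(1, lo, hi),
             distance_bp = NA_integer_)
    })
    bind_rows(rows)
  }
  planted <- mk_proxy(tagged, cfg$ld$max_distance, "tag")
  if (is.null(planted) || nrow(planted) == 0) {
    planted <- tibble(index_snp_id = character(), chrom = character(),
                      proxy_pos = integer(), distance_bp = integer())
  }
  planted <- planted |>
    mutate(proxy_snp_id = paste0("px", seq_len(nrow(planted))),
           r2 = runif(nrow(planted), cfg$ld$r2_range[1], cfg$ld$r2_range[2]),
           distance_bp = abs(.data$proxy_pos -
                               cat_pos$pos[match(.data$index_snp_id,
                                                 cat_pos$snp_id)]))

  # distractors: strong r2 but beyond the window, or close but weak r2
  n_d <- cfg$ld$n_distractors
  weak <- far <- NULL
  if (n_d > 0 && nrow(cat_pos) > 0 && nrow(pool_tbl) > 0) {
    idx <- sample(cat_pos$snp_id, n_d, replace = TRUE)
    half <- floor(n_d / 2)
    weak <- mk_proxy(idx[seq_len(half)], cfg$ld$max_distance, "weak")
    if (!is.null(weak) && nrow(weak) > 0) {
      weak <- weak |>
        mutate(proxy_snp_id = paste0("pxw", seq_len(nrow(weak))),
               r2 = runif(nrow(weak), 0.2, 0.79),
               distance_bp = abs(.data$proxy_pos -
                                   cat_pos$pos[match(.data$index_snp_id,
                                                     cat_pos$snp_id)]))
    }
    far_ids <- idx[(half + 1):n_d]
    far <- mk_proxy(far_ids, cfg$ld$max_distance * 4L, "far")
    if (!is.null(far) && nrow(far) > 0) {
      far <- far |>
        mutate(distance_bp = abs(.data$proxy_pos -
                                   cat_pos$pos[match(.data$index_snp_id,
                                                     cat_pos$snp_id)])) |>
        filter(.data$distance_bp > cfg$ld$max_distance)
      if (nrow(far) > 0) {
        far <- mutate(far, proxy_snp_id = paste0("pxf", seq_len(nrow(far))),
                      r2 = runif(nrow(far), 0.85, 1))
      }
    }
  }
  all_px <- bind_rows(planted, weak, far)
  ld <- if (nrow(all_px) > 0) {
    tibble(snp_a = all_px$index_snp_id, snp_b = all_px$proxy_snp_id,
           r2 = all_px$r2, distance_bp = as.integer(all_px$distance_bp))
  } else {
    tibble(snp_a = character(), snp_b = character(), r2 = double(),
           distance_bp = integer())
  }
  proxy_snps <- if (nrow(all_px) > 0) {
    tibble(snp_id = all_px$proxy_snp_id, chrom = all_px$chrom,
           pos = as.integer(all_px$proxy_pos), trait = "proxy", p = 1,
           n_cases = NA_integer_, source = "background")
  } else {
    tibble(snp_id = character(), chrom = character(), pos = integer(),
           trait = character(), p = double(), n_cases = integer(),
           source = character())
  }
  taggings <- select(planted, "index_snp_id", "proxy_snp_id", "r2",
                     "distance_bp")
  list(ld = ld, proxy_snps = proxy_snps, taggings = taggings)
}

#' Generate the synthetic disease-gene table
#'
#' Samples disease genes from the gene universe with an excess sampling
#' weight on perturbed-circuit genes (TFs and targets of the planted
#' perturbed edges), planting the signal that makes the circuit module more
#' disease-enriched than a nearest-gene baseline. `excess = 0` gives a
#' uniform draw (null).
#'
#' @param cfg A [sim_config()].
#' @param tracks Output of [sim_genome_tracks()].
#' @param netexp Output of [sim_network_expression()].
#' @return List: `gene_disease` tibble and `truth` (disease genes and the
#'   circuit gene set they were biased toward).
#' @export
sim_disease_genes <- function(cfg, tracks, netexp) {
  set.seed(stage_seed(cfg$seed, "disease"))
  universe <- tracks$genes$feature_id
  circuit_genes <- unique(c(netexp$perturbed_edges$tf,
                            netexp$perturbed_edges$target))
  w <- 1 + cfg$disease$excess * (universe %in% circuit_genes)
  n <- min(cfg$disease$n_genes, length(universe))
  picked <- sort(sample(universe, n, prob = w))
  list(gene_disease = tibble(gene_id = picked, disease = cfg$perturb$trait),
       truth = list(disease_genes = picked, circuit_genes = sort(circuit_genes)))
}

#' Generate and write every pipeline input with its ground truth
#'
#' One-shot driver running all generator stages under per-stage seeded
#' streams and writing the full set of input files the pipeline consumes,
#' plus `truth.json` recording the planted ground truth. With a fixed seed
#' the emitted files are byte-identical across runs.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects (`tracks`,
#'   `catalogs`, `ldres`, `netexp`, `disease`), the `truth` list and the
#'   file `paths`.
#' @export
simulate_inputs <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tracks <- sim_genome_tracks(cfg)
  netexp <- sim_network_expression(cfg, tracks)
  catalogs <- sim_catalogs(cfg, tracks, netexp$witness_snps)
  ldres <- sim_ld(cfg, catalogs, tracks)
  disease <- sim_disease_genes(cfg, tracks, netexp)

  p <- function(f) file.path(dir, f)
  write_bed_track(tracks$genes, p("genes.bed"))
  write_bed_track(tracks$exons, p("exons.bed"))
  write_bed_track(select(tracks$promoters, -"gene_id"), p("promoters.bed"))
  write_bed_track(tracks$enhancers, p("enhancers.bed"))
  write_bed_track(mutate(tracks$motifs, feature_id = .data$tf), p("motifs.bed"))

  write_catalog_file <- function(df, path) {
    df |>
      select("snp_id", "chrom", "pos", "trait", "p", "n_cases") |>
      arrange(.data$snp_id, .data$trait) |>
      write_tsv_stable(path)
  }
  write_catalog_file(catalogs$catalog, p("catalog.tsv"))
  write_catalog_file(catalogs$background, p("background.tsv"))
  write_catalog_file(ldres$proxy_snps, p("proxies.tsv"))
  write_tsv_stable(catalogs$eqtl, p("eqtl.tsv"))
  write_tsv_stable(arrange(ldres$ld, .data$snp_a, .data$snp_b), p("ld.tsv"))
  write_tsv_stable(arrange(netexp$network, .data$tissue, .data$tf,
                           .data$element_id, .data$target), p("network.tsv"))
  wide <- netexp$expr |>
    tidyr::pivot_wider(names_from = "sample", values_from = "value") |>
    arrange(.data$gene_id)
  write_tsv_stable(wide, p("expression.tsv"))
  write_tsv_stable(netexp$sample_map, p("samples.tsv"))
  write_tsv_stable(disease$gene_disease, p("gene_disease.tsv"))

  truth <- list(
    planted_fold = as.list(catalogs$truth$planted_fold),
    prob_catalog = as.list(catalogs$truth$prob_catalog),
    prob_background = as.list(catalogs$truth$prob_background),
    realized_catalog = as.list(catalogs$truth$realized_catalog),
    realized_background = as.list(catalogs$truth$realized_background),
    taggings = ldres$taggings,
    perturbed_edges = netexp$perturbed_edges,
    witness_snps = netexp$witness_snps$snp_id,
    specific_genes = netexp$specific_genes,
    disease_genes = disease$truth$disease_genes,
    circuit_genes = disease$truth$circuit_genes,
    perturb_trait = cfg$perturb$trait,
    perturb_tissue = cfg$perturb$tissue)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(list(tracks = tracks, catalogs = catalogs, ldres = ldres,
                 netexp = netexp, disease = disease, truth = truth,
                 paths = list(dir = dir)))
}
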