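test_that("generated tracks are well-formed and inside the genome", {
  cfg <- small_sim_config(seed = 2)
  tracks <- sim_genome_tracks(cfg)
  for (tab in list(tracks$genes, tracks$exons, tracks$promoters,
                   tracks$enhancers, tracks$motifs)) {
    expect_true(all(tab$start >= 0))
    expect_true(all(tab$start < tab$end))
    expect_true(all(tab$end <= cfg$chrom_length))
  }
  # promoters are stranded and adjacent to their gene's 5' end
  pg <- dplyr::inner_join(tracks$promoters, tracks$genes,
                          by = c(gene_id = "feature_id"),
                          suffix = c("_p", "_g"))
  plus <- pg[pg$strand_p == "+", ]
  minus <- pg[pg$strand_p == "-", ]
  expect_true(all(plus$end_p == plus$start_g))
  expect_true(all(minus$start_p == minus$end_g))
  # element ids unique per track
  expect_false(any(duplicated(tracks$promoters$feature_id)))
  expect_false(any(duplicated(tracks$enhancers$feature_id)))
  # infeasible packing errors out
  expect_error(sim_genome_tracks(sim_config(seed = 1, chrom_length = 1e5)),
               "packing")
})

test_that("generator output is byte-identical under a fixed seed", {
  cfg <- small_sim_config(seed = 7, n_catalog_snps = 200L,
                          n_background_snvs = 300L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_inputs(cfg, d1)
  simulate_inputs(cfg, d2)
  files <- list.files(d1)
  expect_gt(length(files), 10)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  simulate_inputs(small_sim_config(seed = 8, n_catalog_snps = 200L,
                                   n_background_snvs = 300L), d3)
  expect_false(identical(readLines(file.path(d1, "catalog.tsv")),
                         readLines(file.path(d3, "catalog.tsv"))))
})

test_that("every emitted file passes its reader", {
  cfg <- small_sim_config(seed = 3, n_catalog_snps = 300L,
                          n_background_snvs = 400L)
  d <- withr::local_tempdir()
  sim <- simulate_inputs(cfg, d)
  expect_no_error({
    genes <- read_bed_track(file.path(d, "genes.bed"), "gene")
    read_bed_track(file.path(d, "exons.bed"), "exon")
    read_bed_track(file.path(d, "promoters.bed"), "promoter")
    read_bed_track(file.path(d, "enhancers.bed"), "enhancer")
    read_bed_track(file.path(d, "motifs.bed"), "motif")
    cat <- read_snp_catalog(file.path(d, "catalog.tsv"), "phewas")
    read_snp_catalog(file.path(d, "background.tsv"), "background")
    read_snp_catalog(file.path(d, "proxies.tsv"), "background")
    read_eqtl_table(file.path(d, "eqtl.tsv"))
    read_ld_table(file.path(d, "ld.tsv"))
    read_network(file.path(d, "network.tsv"))
    read_expression_matrix(file.path(d, "expression.tsv"),
                           file.path(d, "samples.tsv"))
    read_gene_disease_table(file.path(d, "gene_disease.tsv"))
  })
  expect_equal(nrow(read_snp_catalog(file.path(d, "catalog.tsv"), "phewas")),
               cfg$n_catalog_snps)
})

test_that("planted placement probabilities are realized in the catalog", {
  cfg <- sim_config(seed = 5, n_catalog_snps = 5000L,
                    n_background_snvs = 5000L,
                    ld = list(tagging_prob = 0), perturb = list(n_edges = 0L))
  tracks <- sim_genome_tracks(cfg)
  cats <- sim_catalogs(cfg, tracks)
  flags <- dplyr::filter(cats$truth$flags, set == "catalog")
  for (cat_name in c("motif", "promoter_enhancer", "eqtl")) {
    p0 <- cfg$prob_catalog[[cat_name]]
    ci <- qnorm(0.995) * sqrt(p0 * (1 - p0) / nrow(flags))
    expect_lt(abs(mean(flags[[cat_name]]) - p0), ci + 1e-9, label = cat_name)
  }
  # planted flags agree with what annotation recovers
  motif_idx <- interval_index(tracks$motifs)
  element_idx <- interval_index(dplyr::bind_rows(
    dplyr::select(tracks$promoters, -gene_id), tracks$enhancers))
  ann <- annotate_regulatory(cats$catalog, motif_idx, element_idx, cats$eqtl)
  joined <- dplyr::inner_join(ann, flags, by = "snp_id",
                              suffix = c("_obs", "_true"))
  expect_equal(joined$motif_obs, joined$motif_true)
  expect_equal(joined$promoter_enhancer_obs, joined$promoter_enhancer_true)
  expect_equal(joined$eqtl_obs, joined$eqtl_true)
})

test_that("LD generator honours tagging probability at both extremes", {
  cfg1 <- small_sim_config(seed = 4, n_catalog_snps = 300L,
                           n_background_snvs = 200L,
                           ld = list(tagging_prob = 1, n_distractors = 50L))
  tracks <- sim_genome_tracks(cfg1)
  netexp <- sim_network_expression(cfg1, tracks)
  cats <- sim_catalogs(cfg1, tracks, netexp$witness_snps)
  ldres <- sim_ld(cfg1, cats, tracks)
  flags <- dplyr::filter(cats$truth$flags, set == "catalog")
  unann <- flags$snp_id[!(flags$motif | flags$promoter_enhancer | flags$eqtl)]
  expect_setequal(ldres$taggings$index_snp_id, unann)
  expect_true(all(ldres$taggings$r2 >= 0.8))
  expect_true(all(ldres$taggings$distance_bp <= cfg1$ld$max_distance))

  cfg0 <- small_sim_config(seed = 4, n_catalog_snps = 300L,
                           n_background_snvs = 200L,
                           ld = list(tagging_prob = 0, n_distractors = 50L))
  ldres0 <- sim_ld(cfg0, cats, tracks)
  expect_equal(nrow(ldres0$taggings), 0)
})

test_that("generator guards its degenerate configurations", {
  cfg <- small_sim_config(seed = 6)
  tracks <- sim_genome_tracks(cfg)
  cfg_no_tissue <- cfg
  cfg_no_tissue$tissues <- character()
  expect_error(sim_network_expression(cfg_no_tissue, tracks), "tissue")
  cfg_many <- small_sim_config(seed = 6, perturb = list(n_edges = 10000L))
  expect_error(sim_network_expression(cfg_many, tracks), "exceed")
  expect_error(sim_config(seed = 1, prob_background = c(
    motif = 0.5, promoter_enhancer = 0.5, eqtl = 0.5),
    fold = c(motif = 3, promoter_enhancer = 1, eqtl = 1)), "exceeds 1")
})
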