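toy_gene_model <- function() {
  genes <- tibble::tibble(chrom = "chr1", start = 1000L, end = 5000L,
                          feature_id = "geneA", feature_kind = "gene")
  exons <- tibble::tibble(chrom = "chr1", start = c(1000L, 3000L),
                          end = c(1500L, 3500L),
                          feature_id = c("ex1", "ex2"), feature_kind = "exon")
  list(gene = interval_index(genes), exon = interval_index(exons))
}

test_that("genic context distinguishes exonic, intronic, intergenic", {
  m <- toy_gene_model()
  snps <- tibble::tibble(snp_id = c("s1", "s2", "s3", "s4"),
                         chrom = c("chr1", "chr1", "chr1", "chr9"),
                         pos = c(1200L, 2000L, 9000L, 100L))
  out <- classify_genic_context(snps, m$gene, m$exon)
  expect_equal(out$genic_context,
               c("exonic", "intronic", "intergenic", "intergenic"))
  # empty model -> everything intergenic
  out0 <- classify_genic_context(snps, NULL, NULL)
  expect_true(all(out0$genic_context == "intergenic"))
})

test_that("protein-site flags obey the 2- and 7-residue flank rules", {
  sites <- tibble::tibble(
    protein_id = c("P1", "P2"),
    residue_index = c(139L, 576L),
    site_kind = c("ligand_binding", "phosphorylation"))
  vars <- tibble::tibble(
    snp_id = c("v_at2", "v_at3", "v_phos", "v_far", "v_absent"),
    protein_id = c("P1", "P1", "P2", "P2", "P9"),
    residue_index = c(141L, 142L, 576L, 584L, 10L),
    aa_change = "X1Y")
  out <- annotate_protein_sites(vars, sites)
  expect_equal(out$ligand_site, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # |576-576| = 0 and |584-576| = 8 > 7
  expect_equal(out$phospho_site, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  # empty site table -> all false
  none <- annotate_protein_sites(vars, sites[0, ])
  expect_false(any(none$ligand_site) || any(none$phospho_site))
})

test_that("regulatory annotation combines motif, element and eQTL evidence", {
  motifs <- interval_index(tibble::tibble(
    chrom = "chr1", start = 100L, end = 120L, feature_id = "TF_A_occ1",
    feature_kind = "motif", tf = "TF_A"))
  elements <- interval_index(tibble::tibble(
    chrom = "chr1", start = c(90L, 500L), end = c(150L, 600L),
    feature_id = c("enh1", "prom1"),
    feature_kind = c("enhancer", "promoter")))
  eqtl <- tibble::tibble(snp_id = c("s2", "s2", "s3"),
                         gene_id = c("g1", "g1", "g2"),
                         tissue = c("lung", "brain", "lung"),
                         fdr = c(0.05, 0.2, 0.051))
  snps <- tibble::tibble(snp_id = c("s1", "s2", "s3"),
                         chrom = "chr1", pos = c(110L, 550L, 9000L))
  ann <- annotate_regulatory(snps, motifs, elements, eqtl)
  s1 <- ann[ann$snp_id == "s1", ]
  expect_true(s1$motif && s1$promoter_enhancer && !s1$eqtl)
  expect_equal(s1$n_regulatory_categories, 2L)
  expect_equal(s1$support_motif, "TF_A")
  expect_equal(s1$support_promoter_enhancer, "enh1")
  # FDR threshold is inclusive at 0.05; 0.051 does not qualify
  s2 <- ann[ann$snp_id == "s2", ]
  expect_true(s2$eqtl)
  expect_equal(s2$support_eqtl, "g1@lung")
  s3 <- ann[ann$snp_id == "s3", ]
  expect_false(s3$eqtl)
  expect_equal(s3$n_regulatory_categories, 0L)
})

test_that("annotation is independent of SNP and track order", {
  set.seed(11)
  ivs <- random_intervals(300)
  motifs <- ivs[ivs$feature_kind == "motif", ]
  elements <- ivs[ivs$feature_kind %in% c("promoter", "enhancer"), ]
  snps <- tibble::tibble(snp_id = sprintf("s%03d", 1:150),
                         chrom = sample(paste0("chr", 1:3), 150, TRUE),
                         pos = sample.int(1e6, 150))
  a1 <- annotate_regulatory(snps, interval_index(motifs),
                            interval_index(elements), NULL)
  a2 <- annotate_regulatory(snps[sample(nrow(snps)), ],
                            interval_index(motifs[sample(nrow(motifs)), ]),
                            interval_index(elements[sample(nrow(elements)), ]),
                            NULL)
  expect_equal(a1, a2, ignore_attr = TRUE)
})

test_that("summary tiers nest and respect the denominator mode", {
  ann <- tibble::tibble(
    snp_id = c("a", "b", "c"),
    genic_context = c("exonic", "intergenic", "intronic"),
    motif = c(TRUE, FALSE, FALSE),
    promoter_enhancer = c(FALSE, TRUE, FALSE),
    eqtl = c(TRUE, FALSE, FALSE))
  s <- summarize_annotations(ann, "all")
  expect_equal(s$at_least_1, 2)
  expect_equal(s$more_than_1, 1)
  expect_equal(s$all_3, 0)
  expect_equal(s$denominator, 3)
  s_nc <- summarize_annotations(ann, "noncoding")
  expect_equal(s_nc$denominator, 2)
  expect_equal(s_nc$more_than_1, 0)

  # tier nesting holds on random flag tables
  set.seed(3)
  for (i in 1:20) {
    rnd <- tibble::tibble(snp_id = as.character(1:50),
                          motif = runif(50) < 0.3,
                          promoter_enhancer = runif(50) < 0.4,
                          eqtl = runif(50) < 0.2)
    s <- summarize_annotations(rnd, "all")
    expect_true(s$all_3 <= s$more_than_1)
    expect_true(s$more_than_1 <= s$at_least_1)
    expect_true(s$at_least_1 <= s$denominator)
  }
  # all-three everywhere
  all3 <- tibble::tibble(snp_id = "x", motif = TRUE,
                         promoter_enhancer = TRUE, eqtl = TRUE)
  expect_equal(summarize_annotations(all3, "all")$all_3, 1)
  # empty input -> all-zero summary
  expect_equal(summarize_annotations(all3[0, ], "all")$at_least_1, 0)
})
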