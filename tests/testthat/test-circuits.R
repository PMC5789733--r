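test_that("promoter flank windows are strand-aware and boundary-inclusive", {
  prom_plus <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1500L,
                              strand = "+", feature_id = "P1",
                              feature_kind = "promoter")
  hits_at <- function(prom, pos) {
    map_snps_to_elements(
      tibble::tibble(snp_id = "s", chrom = "chr1", pos = pos), prom, NULL)
  }
  # + strand: upstream window is 1-based [601, 1000], downstream (1500, 1550]
  expect_equal(hits_at(prom_plus, 601)$hit_rule, "promoter_flank")
  expect_equal(nrow(hits_at(prom_plus, 600)), 0)
  expect_equal(hits_at(prom_plus, 1550)$hit_rule, "promoter_flank")
  expect_equal(nrow(hits_at(prom_plus, 1551)), 0)
  expect_equal(hits_at(prom_plus, 1200)$hit_rule, "promoter_body")

  # - strand: upstream window sits on the right of the span
  prom_minus <- dplyr::mutate(prom_plus, strand = "-")
  expect_equal(hits_at(prom_minus, 1900)$hit_rule, "promoter_flank")
  expect_equal(nrow(hits_at(prom_minus, 1901)), 0)
  expect_equal(hits_at(prom_minus, 951)$hit_rule, "promoter_flank")
  expect_equal(nrow(hits_at(prom_minus, 950)), 0)

  # unstranded promoters are treated as + strand
  prom_un <- dplyr::mutate(prom_plus, strand = "*")
  expect_equal(hits_at(prom_un, 601)$hit_rule, "promoter_flank")
})

test_that("enhancers have no flank", {
  enh <- tibble::tibble(chrom = "chr1", start = 2000L, end = 2100L,
                        strand = "*", feature_id = "E1",
                        feature_kind = "enhancer")
  inside <- map_snps_to_elements(
    tibble::tibble(snp_id = "s", chrom = "chr1", pos = 2050), NULL, enh)
  expect_equal(inside$hit_rule, "enhancer_body")
  outside <- map_snps_to_elements(
    tibble::tibble(snp_id = "s", chrom = "chr1", pos = 2101), NULL, enh)
  expect_equal(nrow(outside), 0)
})

toy_network <- function() {
  tibble::tribble(
    ~tf, ~element_id, ~element_kind, ~target, ~tissue,
    "TF_A", "E1", "enhancer", "geneG", "lung",
    "TF_A", "P1", "promoter", "geneH", "lung",
    "TF_B", "P1", "promoter", "geneH", "lung",
    "TF_A", "E1", "enhancer", "geneG", "brain")
}

test_that("perturbed circuits collect every edge through hit elements", {
  hits <- tibble::tibble(snp_id = "rs1", element_id = "E1",
                         element_kind = "enhancer", hit_rule = "enhancer_body")
  circ <- build_perturbed_circuit(hits, toy_network(), "lung", "asthma")
  expect_equal(nrow(circ$edges), 1)
  expect_equal(circ$edges$perturbation_kind, "enhancer_perturbed")
  expect_equal(circ$edges$witness_snps, "rs1")
  expect_equal(circ$genes, c("TF_A", "geneG"))

  # promoter bound by two TFs: two promoter-perturbed edges
  hits_p <- tibble::tibble(snp_id = c("rs2", "rs3"), element_id = "P1",
                           element_kind = "promoter",
                           hit_rule = "promoter_body")
  circ_p <- build_perturbed_circuit(hits_p, toy_network(), "lung", "x")
  expect_equal(nrow(circ_p$edges), 2)
  expect_true(all(circ_p$edges$perturbation_kind == "promoter_perturbed"))
  expect_true(all(circ_p$edges$witness_snps == "rs2;rs3"))

  # hit on an element absent from the network: empty circuit
  miss <- tibble::tibble(snp_id = "rs1", element_id = "E9",
                         element_kind = "enhancer", hit_rule = "enhancer_body")
  expect_equal(nrow(build_perturbed_circuit(miss, toy_network(), "lung")$edges), 0)

  # unknown tissue errors and lists what is available
  expect_error(build_perturbed_circuit(hits, toy_network(), "kidney"),
               "brain, lung")

  # order-invariance in both SNP and edge order
  net <- toy_network()
  c1 <- build_perturbed_circuit(hits_p, net, "lung")
  c2 <- build_perturbed_circuit(hits_p[2:1, ], net[sample(nrow(net)), ], "lung")
  expect_equal(c1$edges, c2$edges)
})

test_that("edges are a subset of the network and track their witnesses", {
  hits <- tibble::tibble(
    snp_id = c("rs1", "rs2"), element_id = c("E1", "P1"),
    element_kind = c("enhancer", "promoter"),
    hit_rule = c("enhancer_body", "promoter_body"))
  circ <- build_perturbed_circuit(hits, toy_network(), "lung")
  net_keys <- paste(toy_network()$tf, toy_network()$element_id,
                    toy_network()$target)
  expect_true(all(paste(circ$edges$tf, circ$edges$element_id,
                        circ$edges$target) %in% net_keys))
  # dropping a witness removes exactly the edges it alone witnessed
  circ_wo <- build_perturbed_circuit(hits[hits$snp_id != "rs1", ],
                                     toy_network(), "lung")
  removed <- dplyr::anti_join(circ$edges, circ_wo$edges,
                              by = c("tf", "element_id", "target"))
  expect_true(all(removed$witness_snps == "rs1"))
})

test_that("nearest-gene sets deduplicate and skip geneless chromosomes", {
  genes <- interval_index(tibble::tibble(
    chrom = "chr1", start = c(0L, 10000L), end = c(1000L, 11000L),
    feature_id = c("gA", "gB"), feature_kind = "gene"))
  snps <- tibble::tibble(snp_id = c("s1", "s2", "s3", "s4"),
                         chrom = c("chr1", "chr1", "chr1", "chr2"),
                         pos = c(500L, 600L, 10500L, 5L))
  gs <- nearest_gene_set(snps, genes)
  expect_equal(as.character(gs), c("gA", "gB"))
  expect_equal(attr(gs, "skipped"), "s4")
  expect_length(nearest_gene_set(snps[0, ], genes), 0)
})

test_that("disease-gene enrichment behaves at the extremes", {
  universe <- paste0("g", 1:20)
  # disjoint module and disease set: depleted
  res <- disease_gene_enrichment(paste0("g", 1:5), paste0("g", 6:15), universe)
  expect_lt(res$fold_change, 1)
  # perfect overlap of half the universe: the most extreme arrangement
  half <- paste0("g", 1:10)
  res_perf <- disease_gene_enrichment(half, half, universe)
  p_min <- min(vapply(0:10, function(k) {
    fisher_exact_2x2(k, 10 - k, 10 - k, k)
  }, double(1)))
  expect_equal(res_perf$p_value, p_min)
  expect_error(disease_gene_enrichment("gX", half, universe), "subset")
  expect_error(disease_gene_enrichment(half, half, character()), "universe")
})

test_that("novel-association flagging follows Benjamini-Hochberg", {
  all_null <- tibble::tibble(p = rep(1, 50))
  expect_false(any(threshold_novel_associations(all_null)$candidate_novel))

  set.seed(13)
  rec <- tibble::tibble(p = c(1e-10, runif(999)))
  out <- threshold_novel_associations(rec, fdr_q = 0.1)
  expect_true(out$candidate_novel[1])
  expect_equal(out$q_value, p.adjust(rec$p, "BH"))
  # q is monotone non-decreasing in p
  ord <- order(out$p)
  expect_true(all(diff(out$q_value[ord]) >= 0))
})
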