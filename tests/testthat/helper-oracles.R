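# Independent brute-force oracles used against the package implementations.

# linear scan: all intervals containing 1-based pos, ordered (start, id)
brute_query <- function(intervals, chrom, pos) {
  p0 <- pos - 1
  hit <- intervals$chrom == chrom & intervals$start <= p0 & p0 < intervals$end
  iv <- intervals[hit, , drop = FALSE]
  iv[order(iv$start, iv$feature_id), , drop = FALSE]
}

# linear scan nearest feature of a kind; adjacency = distance 1
brute_nearest <- function(intervals, chrom, pos, kind) {
  iv <- intervals[intervals$feature_kind == kind &
                    intervals$chrom == chrom, , drop = FALSE]
  if (nrow(iv) == 0) return(list(feature_id = NA_character_, distance = NA_integer_))
  p0 <- pos - 1
  d <- ifelse(p0 >= iv$start & p0 < iv$end, 0L,
              pmax(iv$start - p0, p0 - (iv$end - 1L)))
  ord <- order(d, iv$feature_id)
  list(feature_id = iv$feature_id[ord[1]], distance = as.integer(d[ord[1]]))
}

# exhaustive two-sided Fisher P from binomial coefficients (no dhyper)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c; N <- m + n
  supp <- max(0, k - n):min(k, m)
  pr <- choose(m, supp) * choose(n, k - supp) / choose(N, k)
  sum(pr[pr <= pr[supp == a] * (1 + 1e-7)])
}

random_intervals <- function(n, n_chrom = 3, span = 1e6) {
  chrom <- sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE)
  start <- sample.int(span, n, replace = TRUE) - 1L
  width <- sample.int(5000L, n, replace = TRUE)
  tibble::tibble(
    chrom = chrom, start = start, end = start + width,
    strand = sample(c("+", "-", "*"), n, replace = TRUE),
    feature_id = sprintf("f%05d", sample.int(n, n)),
    feature_kind = sample(c("gene", "promoter", "enhancer", "motif"), n,
                          replace = TRUE))
}

# in-memory equivalent of the symmetrization read_ld_table performs
read_ld_sym <- function(ld) {
  dplyr::bind_rows(ld, dplyr::rename(ld, snp_a = snp_b, snp_b = snp_a))
}

# a tiny simulation config sized for unit tests
small_sim_config <- function(seed = 1, ...) {
  args <- list(
    seed = seed, chrom_length = 4e6, n_genes = 80L, n_enhancers = 60L,
    n_motifs = 100L, n_network_promoters = 20L, n_network_enhancers = 20L,
    n_catalog_snps = 500L, n_background_snvs = 1000L,
    samples_per_tissue = 20L,
    ld = list(n_distractors = 100L),
    expression = list(n_specific_genes = 8L))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(args[[nm]]) && is.list(dots[[nm]])) {
      args[[nm]] <- utils::modifyList(args[[nm]], dots[[nm]])
    } else {
      args[[nm]] <- dots[[nm]]
    }
  }
  do.call(sim_config, args)
}
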