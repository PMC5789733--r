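test_that("exact test agrees with closed forms and rejects zero margins", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1.0)
  # only the two extreme tables qualify at these margins
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / choose(20, 10))
  expect_error(fisher_exact_2x2(0, 0, 3, 4), "margins")
  expect_error(fisher_exact_2x2(2, 3, -1, 4), "non-negative")
})

test_that("exact test matches stats::fisher.test and is transpose-invariant", {
  set.seed(19)
  for (i in 1:200) {
    cells <- as.integer(rmultinom(1, sample(8:60, 1), runif(4, 0.05, 1)))
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    p <- fisher_exact_2x2(a, b, c, d)
    ref <- stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value
    expect_equal(p, ref, tolerance = 1e-9)
    expect_equal(p, fisher_exact_2x2(a, c, b, d), tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(a, b, c, d, log10 = TRUE), log10(p),
                 tolerance = 1e-7)
  }
})

test_that("log-scale P stays finite where the linear scale underflows", {
  p_lin <- fisher_exact_2x2(900, 100, 100, 900)
  p_log <- fisher_exact_2x2(900, 100, 100, 900, log10 = TRUE)
  expect_lt(p_log, -100)
  expect_true(is.finite(p_log))
  expect_equal(p_log, log10(p_lin), tolerance = 1e-6)
  # a genuinely underflowing table still yields a usable log10 P
  deep <- fisher_exact_2x2(5000, 5000, 100, 9900, log10 = TRUE)
  expect_true(is.finite(deep) && deep < -320)
})

flag_table <- function(n, frac) {
  tibble::tibble(snp_id = as.character(seq_len(n)),
                 motif = seq_len(n) <= round(n * frac),
                 promoter_enhancer = FALSE, eqtl = FALSE)
}

test_that("category enrichment computes folds against the background", {
  # constructed equal fractions give fold exactly 1
  res <- category_enrichment(flag_table(100, 0.2), flag_table(400, 0.2),
                             categories = "motif")
  expect_equal(res$fold_change, 1.0)
  expect_equal(res$a + res$b, 100)
  expect_equal(res$c + res$d, 400)

  # category absent from the catalog: fold 0, exact P still defined
  res0 <- category_enrichment(flag_table(50, 0), flag_table(100, 0.3),
                              categories = "motif")
  expect_equal(res0$fold_change, 0)
  expect_lt(res0$p_value, 1)

  # background count 0: fold undefined
  res_na <- category_enrichment(flag_table(50, 0.2), flag_table(100, 0),
                                categories = "motif")
  expect_true(is.na(res_na$fold_change))

  # fold > 1 iff catalog fraction exceeds background fraction
  res_gt <- category_enrichment(flag_table(100, 0.4), flag_table(100, 0.1),
                                categories = "motif")
  expect_gt(res_gt$fold_change, 1)
  expect_error(category_enrichment(flag_table(10, 0.5), flag_table(10, 0.5)[0, ]),
               "background")
})

test_that("planted two-arm fold is recovered within binomial error", {
  set.seed(23)
  n_cat <- 2000; n_bg <- 2000
  cat_tab <- tibble::tibble(snp_id = as.character(1:n_cat),
                            motif = FALSE, eqtl = FALSE,
                            promoter_enhancer = runif(n_cat) < 0.3)
  bg_tab <- tibble::tibble(snp_id = as.character(1:n_bg),
                           motif = FALSE, eqtl = FALSE,
                           promoter_enhancer = runif(n_bg) < 0.1)
  res <- category_enrichment(cat_tab, bg_tab, categories = "promoter_enhancer")
  # 99% CI of the log fold around the planted 3.0 (delta method)
  se <- sqrt((1 - 0.3) / (n_cat * 0.3) + (1 - 0.1) / (n_bg * 0.1))
  expect_gt(res$fold_change, 3 * exp(-2.576 * se))
  expect_lt(res$fold_change, 3 * exp(2.576 * se))
  expect_lt(res$p_value, 1e-10)
})

test_that("power stratification detects planted trends and flat nulls", {
  set.seed(31)
  n <- 5000
  u <- runif(n, 1.3, 8)
  # null: constant annotation probability
  null_rec <- tibble::tibble(p = 10^-u, at_least_1 = runif(n) < 0.4)
  ps_null <- power_stratified_enrichment(null_rec, n_bins = 10)
  expect_lt(abs(ps_null$pearson_r), 0.2)

  # planted monotone trend
  prob <- 0.15 + 0.08 * (u - mean(u))
  trend_rec <- tibble::tibble(p = 10^-u, at_least_1 = runif(n) < prob)
  ps <- power_stratified_enrichment(trend_rec, n_bins = 10)
  expect_gt(ps$pearson_r, 0)
  expect_lt(ps$pearson_p, 0.05)
  expect_equal(nrow(tidy(ps)), 10)
  expect_equal(glance(ps)$n_records, n)

  # two bins with a perfect step correlate perfectly
  step <- tibble::tibble(p = c(rep(0.04, 10), rep(1e-6, 10)),
                         at_least_1 = c(rep(FALSE, 10), rep(TRUE, 10)))
  expect_equal(power_stratified_enrichment(step, n_bins = 2)$pearson_r, 1.0)

  expect_error(power_stratified_enrichment(null_rec, n_bins = 1), "n_bins")
  expect_error(power_stratified_enrichment(null_rec[1:20, ], n_bins = 10),
               "fewer bins")
})
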