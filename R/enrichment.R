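#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the two-sided exact P by summing hypergeometric probabilities,
#' at the observed table's fixed margins, of all tables whose probability is
#' less than or equal to that of the observed table (the comparison uses a
#' relative tolerance of 1e-7, matching common practice for this test).
#'
#' @param a,b,c,d Non-negative integer cells: `a` catalog-and-annotated, `b`
#'   catalog-not-annotated, `c` background-and-annotated, `d`
#'   background-not-annotated.
#' @param log10 If `TRUE`, return log10 of the P value, accumulated in log
#'   space so that P values far below double-precision underflow (common for
#'   strong eQTL enrichments at genome scale) are still resolved instead of
#'   collapsing to 0.
#' @return The two-sided P value (or its log10).
#' @examples
#' fisher_exact_2x2(5, 5, 5, 5)    # perfectly balanced: 1
#' fisher_exact_2x2(10, 0, 0, 10)  # only the two extreme tables qualify
#' @export
fisher_exact_2x2 <- function(a, b, c, d, log10 = FALSE) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    abort("cells must be non-negative integers")
  }
  m <- a + b
  n <- c + d
  k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) {
    abort("fisher_exact_2x2 requires all four margins > 0")
  }
  support <- max(0, k - n):min(k, m)
  lprobs <- dhyper(support, m, n, k, log = TRUE)
  l_obs <- dhyper(a, m, n, k, log = TRUE)
  keep <- lprobs <= l_obs + log1p(1e-7)
  if (log10) {
    lp <- lprobs[keep]
    mx <- max(lp)
    lsum <- mx + log(sum(exp(lp - mx)))
    min(lsum, 0) / log(10)
  } else {
    min(sum(exp(lprobs[keep])), 1)
  }
}

category_flags <- function(annotations, category) {
  if (category %in% names(annotations)) {
    as.logical(annotations[[category]])
  } else if (category %in% c("at_least_1", "more_than_1", "all_3")) {
    ncat <- as.integer(annotations$motif) +
      as.integer(annotations$promoter_enhancer) + as.integer(annotations$eqtl)
    switch(category,
           at_least_1 = ncat >= 1L,
           more_than_1 = ncat > 1L,
           all_3 = ncat == 3L)
  } else {
    abort(paste0("unknown category: ", category))
  }
}

#' Enrichment of functional categories against a background variant set
#'
#' For each category, builds the 2x2 table (catalog annotated / not,
#' background annotated / not), computes the fold-change
#' `(a/(a+b)) / (c/(c+d))` and the two-sided exact P via
#' [fisher_exact_2x2()]. The background is used as-is — catalog SNPs are not
#' removed from it. Fold is `NA` when the background count `c` is 0; when a
#' category is absent from both sets the test degenerates and P is 1.
#'
#' @param catalog_annotations,background_annotations Annotation tibbles with
#'   identical category definitions ([annotate_catalog()]).
#' @param categories Categories to test; flag columns or the derived tiers
#'   `at_least_1`, `more_than_1`, `all_3`.
#' @param adjust If `TRUE`, add a Benjamini-Hochberg adjusted P column
#'   across the tested categories (off by default; raw P is the headline
#'   statistic).
#' @return A `snp_enrichment` tibble: `category, a, b, c, d, fold_change,
#'   p_value, log10_p` (and `p_adjusted` when `adjust`), in the order given.
#'   `log10_p` carries the log-scale P, which stays informative when the
#'   linear-scale value underflows to 0.
#' @export
category_enrichment <- function(catalog_annotations, background_annotations,
                                categories = c("motif", "promoter_enhancer",
                                               "eqtl"),
                                adjust = FALSE) {
  if (nrow(background_annotations) == 0) abort("background set is empty")
  if (nrow(catalog_annotations) == 0) abort("catalog set is empty")
  rows <- purrr::map(categories, function(cat) {
    f_cat <- category_flags(catalog_annotations, cat)
    f_bg <- category_flags(background_annotations, cat)
    a <- sum(f_cat); b <- sum(!f_cat)
    c <- sum(f_bg); d <- sum(!f_bg)
    fold <- if (c == 0) NA_real_ else (a / (a + b)) / (c / (c + d))
    degenerate <- a + c == 0 || b + d == 0
    p <- if (degenerate) 1 else fisher_exact_2x2(a, b, c, d)
    lp <- if (degenerate) 0 else fisher_exact_2x2(a, b, c, d, log10 = TRUE)
    tibble(category = cat, a = a, b = b, c = c, d = d,
           fold_change = fold, p_value = p, log10_p = lp)
  })
  out <- bind_rows(rows)
  if (adjust) out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  class(out) <- c("snp_enrichment", class(out))
  out
}

#' @export
autoplot.snp_enrichment <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$category, levels = .data$category),
    y = .data$fold_change)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(label = format.pval(.data$p_value, digits = 2)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "fold enrichment vs background",
                  title = "Functional-category enrichment") +
    ggplot2::theme_minimal()
}

#' Annotation coverage stratified by association strength
#'
#' Bins catalog records by -log10(P) into `n_bins` equal-occupancy
#' (quantile) strata and correlates each bin's annotated fraction with the
#' bin midpoint of -log10(P) (Pearson), testing whether functional coverage
#' rises with the statistical power of the association.
#'
#' @param records Tibble carrying a `p` column and the chosen flag (a
#'   logical column named by `flag`, or one of the derived tiers when the
#'   three category flags are present).
#' @param n_bins Number of strata (>= 2; default 10).
#' @param flag Column/tier defining "annotated" (default `"at_least_1"`).
#' @return A `power_strat` object: bin table plus Pearson r and its
#'   two-sided P. Errors if any bin holds fewer than 5 records (use fewer
#'   bins).
#' @export
power_stratified_enrichment <- function(records, n_bins = 10,
                                        flag = "at_least_1") {
  records <- as_tibble(records)
  if (n_bins < 2) abort("n_bins must be >= 2")
  if (!"p" %in% names(records)) abort("records need a `p` column")
  annotated <- category_flags(records, flag)
  nl <- -log10(records$p)
  df <- tibble(neg_log10_p = nl, annotated = annotated) |>
    arrange(.data$neg_log10_p) |>
    mutate(bin = dplyr::ntile(.data$neg_log10_p, n_bins))
  bins <- df |>
    group_by(.data$bin) |>
    summarise(n = n(),
              p_lo = min(.data$neg_log10_p), p_hi = max(.data$neg_log10_p),
              midpoint = (min(.data$neg_log10_p) + max(.data$neg_log10_p)) / 2,
              fraction = mean(.data$annotated), .groups = "drop")
  if (any(bins$n < 5)) {
    abort(paste0("a stratum holds fewer than 5 records; use fewer bins ",
                 "(requested ", n_bins, ")"))
  }
  r <- cor(bins$midpoint, bins$fraction)
  # the correlation P needs >= 3 strata; with 2 bins only r is defined
  p_r <- if (n_bins >= 3) {
    cor.test(bins$midpoint, bins$fraction, method = "pearson")$p.value
  } else {
    NA_real_
  }
  structure(list(bins = bins, pearson_r = r,
                 pearson_p = p_r, n_bins = n_bins, flag = flag,
                 n_records = nrow(records)),
            class = "power_strat")
}

#' @export
print.power_strat <- function(x, ...) {
  cat("<power_strat> ", x$n_bins, " strata over ", x$n_records,
      " records; flag = ", x$flag, "\n", sep = "")
  cat("  Pearson r = ", signif(x$pearson_r, 4), ", P = ",
      signif(x$pearson_p, 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.power_strat <- function(x, ...) {
  x$bins
}

#' @export
glance.power_strat <- function(x, ...) {
  tibble(pearson_r = x$pearson_r, pearson_p = x$pearson_p,
         n_bins = x$n_bins, n_records = x$n_records, flag = x$flag)
}

#' @export
autoplot.power_strat <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$midpoint, y = .data$fraction)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.4) +
    ggplot2::labs(
      x = expression(-log[10](italic(P)) ~ "bin midpoint"),
      y = "annotated fraction",
      title = sprintf("Annotation vs association strength (r = %.3f, P = %.3g)",
                      object$pearson_r, object$pearson_p)) +
    ggplot2::theme_minimal()
}
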