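# Cell-by-cell statistical contrast of two exchange matrices and the
# correlation / distribution-shift analyses used alongside it.

#' Fisher exact test for one matrix cell against dataset totals
#'
#' Two-sided exact p for the 2x2 table
#' `[[a_xy, a_total - a_xy], [b_xy, b_total - b_xy]]`: does the exchange
#' occupy a different proportion of dataset A than of dataset B? Vectorized
#' over cells.
#'
#' @param a_xy,b_xy Cell counts in datasets A and B.
#' @param a_total,b_total Dataset totals (conditioning margins).
#' @return Numeric vector of two-sided p-values.
#' @export
fisher_cell_test <- function(a_xy, a_total, b_xy, b_total) {
  n <- max(length(a_xy), length(b_xy), length(a_total), length(b_total))
  a_xy <- rep_len(a_xy, n); a_total <- rep_len(a_total, n)
  b_xy <- rep_len(b_xy, n); b_total <- rep_len(b_total, n)
  if (any(c(a_xy, b_xy) < 0) || any(a_xy > a_total) || any(b_xy > b_total) ||
      any(c(a_total, b_total) <= 0)) {
    abort("Counts must satisfy 0 <= x <= total and totals > 0.")
  }
  vapply(seq_len(n), function(i) {
    tab <- matrix(c(a_xy[i], a_total[i] - a_xy[i],
                    b_xy[i], b_total[i] - b_xy[i]), 2, byrow = TRUE)
    fisher.test(tab)$p.value
  }, numeric(1))
}

#' Benjamini-Yekutieli false-discovery-rate adjustment
#'
#' Step-up FDR adjustment valid under arbitrary dependence, with the
#' harmonic correction factor `c(m) = sum_{i=1..m} 1/i`; delegates to
#' [stats::p.adjust()] with `method = "BY"`. Output is order-preserving and
#' element-wise at least as large as the input.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, clipped to `[0, 1]`.
#' @export
bhy_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("`p` must be numeric in [0, 1] with no missing values.")
  }
  p.adjust(p, method = "BY")
}

#' Classify exchange-matrix cells by significant excess
#'
#' For every theoretically reachable cell (plus multi-base cells observed in
#' either matrix), tests the two counts against the dataset totals with
#' [fisher_cell_test()], adjusts with [bhy_adjust()], and assigns a class:
#' `ABSENT_IN_A` when dataset A has no events in a reachable cell,
#' `MORE_IN_A` / `MORE_IN_B` for a significant proportional excess (adjusted
#' p below `alpha`), otherwise `NOT_SIGNIFICANT`. The union of the two
#' directional classes corresponds to the "significantly different" cells of
#' the classic heatmap.
#'
#' @param a,b `exchange_counts` objects (A is conventionally the natural
#'   set, B the disease set).
#' @param alpha Significance level on adjusted p-values (default 0.01).
#' @param conditioning `"total"` (cell vs all other cells in the dataset,
#'   default) or `"row"` (cell vs the rest of its source-amino-acid row).
#' @return A `significance_matrix` tibble: `from`, `to`, `count_a`,
#'   `count_b`, `p`, `p_adj`, `class`, with `alpha` and the dataset labels
#'   as attributes.
#' @export
classify_cells <- function(a, b, alpha = 0.01,
                           conditioning = c("total", "row")) {
  conditioning <- match.arg(conditioning)
  cells <- single_base_exchanges()
  extra <- tidyr::expand_grid(from = aa_codes(), to = aa_codes()) |>
    dplyr::filter(.data$from != .data$to) |>
    dplyr::anti_join(cells, by = c("from", "to"))
  observed_extra <- extra[a$counts[cbind(extra$from, extra$to)] +
                            b$counts[cbind(extra$from, extra$to)] > 0, ]
  cells <- dplyr::bind_rows(cells |> dplyr::mutate(reachable = TRUE),
                            observed_extra |>
                              dplyr::mutate(reachable = FALSE)) |>
    dplyr::arrange(.data$from, .data$to)

  idx <- cbind(cells$from, cells$to)
  ca <- a$counts[idx]; cb <- b$counts[idx]
  if (conditioning == "total") {
    ta <- rep(a$total, nrow(cells)); tb <- rep(b$total, nrow(cells))
  } else {
    ta <- rowSums(a$counts)[cells$from]; tb <- rowSums(b$counts)[cells$from]
    ok <- ta > 0 & tb > 0
    if (!all(ok)) {
      cells <- cells[ok, ]; idx <- idx[ok, , drop = FALSE]
      ca <- ca[ok]; cb <- cb[ok]; ta <- ta[ok]; tb <- tb[ok]
    }
  }
  p <- fisher_cell_test(ca, ta, cb, tb)
  p_adj <- bhy_adjust(p)
  prop_a <- ca / ta; prop_b <- cb / tb
  class <- dplyr::case_when(
    ca == 0 & cells$reachable ~ "ABSENT_IN_A",
    p_adj < alpha & prop_a > prop_b ~ "MORE_IN_A",
    p_adj < alpha & prop_b > prop_a ~ "MORE_IN_B",
    .default = "NOT_SIGNIFICANT")
  out <- tibble(from = cells$from, to = cells$to, count_a = ca,
                count_b = cb, p = p, p_adj = p_adj, class = class)
  attr(out, "alpha") <- alpha
  attr(out, "labels") <- c(a = a$label, b = b$label)
  attr(out, "conditioning") <- conditioning
  class(out) <- c("significance_matrix", class(out))
  out
}

r_strength <- function(r) {
  dplyr::case_when(abs(r) > 0.7 ~ "strong",
                   abs(r) > 0.4 ~ "moderate",
                   .default = "weak")
}

#' Correlation with outlier exclusion and strength labelling
#'
#' Pearson or Spearman correlation, with named observations optionally
#' excluded first (the classic use: dropping Arg and Leu as extreme
#' outliers). Coefficients are labelled `strong` (|r| > 0.7), `moderate`
#' (0.4 < |r| <= 0.7) or `weak` (everything else; the band \[0.3, 0.4\] is
#' mapped to weak).
#'
#' @param x,y Numeric vectors of equal length; names of `x` (or of `y` if
#'   `x` has none) identify observations for `exclude`.
#' @param method `"pearson"` or `"spearman"`.
#' @param exclude Character vector of observation names to drop.
#' @return One-row tibble: `r`, `n`, `strength`, `method`, `excluded`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      exclude = NULL) {
  method <- match.arg(method)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  nm <- names(x) %||% names(y)
  if (!is.null(exclude)) {
    if (is.null(nm)) abort("`exclude` given but observations are unnamed.")
    keep <- !(nm %in% exclude)
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 3) abort("Need at least 3 observations after exclusions.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Degenerate (constant) vector; correlation undefined.")
  }
  r <- cor(x, y, method = method)
  tibble(r = r, n = length(x), strength = r_strength(r), method = method,
         excluded = paste(exclude %||% character(), collapse = ","))
}

#' Two-sample distribution shift test
#'
#' Compares the location/shape of two samples (for example conservation
#' scores at variant sites versus disease sites) with a two-sided
#' Mann-Whitney test (default) or Kolmogorov-Smirnov test, reporting both
#' sample means alongside the p-value.
#'
#' @param sample_a,sample_b Nonempty numeric vectors.
#' @param test `"wilcoxon"` or `"ks"`.
#' @return One-row tibble: `p_value`, `mean_a`, `mean_b`, `n_a`, `n_b`,
#'   `test`.
#' @export
distribution_shift_test <- function(sample_a, sample_b,
                                    test = c("wilcoxon", "ks")) {
  test <- match.arg(test)
  if (!length(sample_a) || !length(sample_b)) {
    abort("Both samples must be nonempty.")
  }
  p <- if (test == "wilcoxon") {
    wilcox.test(sample_a, sample_b, exact = FALSE)$p.value
  } else {
    suppressWarnings(ks.test(sample_a, sample_b)$p.value)
  }
  tibble(p_value = p, mean_a = mean(sample_a), mean_b = mean(sample_b),
         n_a = length(sample_a), n_b = length(sample_b), test = test)
}
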