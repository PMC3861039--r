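# ggplot2 presentation layer. Heatmaps and gain/loss plots use the
# hydrophobicity ordering of the amino acids; all computation lives in the
# analysis functions, these only draw.

aa_hydro_factor <- function(x) factor(x, levels = hydrophobicity_order())

#' @describeIn exchange_counts Heatmap of the count matrix, amino acids
#'   ordered by increasing hydrophobicity.
#' @param object,x An `exchange_counts` object.
#' @param ... Unused.
#' @method autoplot exchange_counts
#' @export
autoplot.exchange_counts <- function(object, ...) {
  long <- tidy.exchange_counts(object)
  ggplot2::ggplot(long, ggplot2::aes(aa_hydro_factor(.data$to),
                                     aa_hydro_factor(.data$from),
                                     fill = log10(.data$count + 1))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10(count + 1)") +
    ggplot2::scale_y_discrete(limits = rev(hydrophobicity_order())) +
    ggplot2::labs(x = "derived amino acid", y = "ancestral amino acid",
                  title = object$label) +
    ggplot2::theme_minimal()
}

#' Plot the significance classes of a matrix contrast
#'
#' Heatmap of the [classify_cells()] output using the classic colour
#' scheme: green for excess in A, orange for excess in B, blue for cells
#' absent in A, white for not significant.
#'
#' @param object A `significance_matrix` tibble.
#' @param ... Unused.
#' @method autoplot significance_matrix
#' @export
autoplot.significance_matrix <- function(object, ...) {
  labs <- attr(object, "labels")
  cols <- c(MORE_IN_A = "#2ca02c", MORE_IN_B = "#ff7f0e",
            ABSENT_IN_A = "#1f77b4", NOT_SIGNIFICANT = "white")
  ggplot2::ggplot(object, ggplot2::aes(aa_hydro_factor(.data$to),
                                       aa_hydro_factor(.data$from),
                                       fill = .data$class)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = cols) +
    ggplot2::scale_y_discrete(limits = rev(hydrophobicity_order())) +
    ggplot2::labs(x = paste0("derived (B = ", labs[["b"]], ")"),
                  y = paste0("ancestral (A = ", labs[["a"]], ")")) +
    ggplot2::theme_minimal()
}

#' Gain/loss asymmetry plot
#'
#' Mutations-to against mutations-from for each amino acid, coloured by CpG
#' class (red: CpG in some codon; yellow: some codon starts with G; blue:
#' neither), with the identity line separating gainers from losers.
#'
#' @param gl Output of [gain_loss()].
#' @return A ggplot object.
#' @export
plot_gain_loss <- function(gl) {
  cols <- c(RED = "#d62728", YELLOW = "#e6b800", BLUE = "#1f77b4")
  ggplot2::ggplot(gl, ggplot2::aes(.data$from_total, .data$to_total,
                                   colour = .data$cpg_class,
                                   label = .data$aa)) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_text(fontface = "bold") +
    ggplot2::scale_colour_manual(values = cols) +
    ggplot2::labs(x = "mutations from", y = "mutations to") +
    ggplot2::theme_minimal()
}

#' Side-by-side exchange profiles of two datasets
#'
#' @param a,b `exchange_counts` objects.
#' @param aa Source amino acid.
#' @return A ggplot object with paired bars of target percentages.
#' @export
plot_exchange_profile <- function(a, b, aa) {
  pa <- exchange_profile(a, aa) |> dplyr::mutate(set = a$label)
  pb <- exchange_profile(b, aa) |> dplyr::mutate(set = b$label)
  ggplot2::ggplot(dplyr::bind_rows(pa, pb),
                  ggplot2::aes(.data$to, .data$percent, fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "derived amino acid", y = "% of mutations",
                  title = paste("Mutations from", aa)) +
    ggplot2::theme_minimal()
}

#' @describeIn dcfreq Bubble plot of the rate matrix (area proportional to
#'   rate), hydrophobicity ordering for amino-acid matrices.
#' @param object,x A `rate_matrix`.
#' @param ... Unused.
#' @method autoplot rate_matrix
#' @export
autoplot.rate_matrix <- function(object, ...) {
  long <- tidy.rate_matrix(object)
  long <- long[long$rate > 0, ]
  if (object$level == "aa") {
    long$from <- aa_hydro_factor(long$from)
    long$to <- aa_hydro_factor(long$to)
  }
  ggplot2::ggplot(long, ggplot2::aes(.data$to, .data$from,
                                     size = .data$rate)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "to", y = "from", title = object$label) +
    ggplot2::theme_minimal() +
    (if (object$level == "codon")
       ggplot2::theme(axis.text = ggplot2::element_blank()) else NULL)
}

#' @describeIn pca_compare Scatter of the first two principal components,
#'   coloured by provenance tag.
#' @param object A `matrix_pca` object.
#' @param ... Unused.
#' @method autoplot matrix_pca
#' @export
autoplot.matrix_pca <- function(object, ...) {
  ev <- object$explained_variance
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2, colour = .data$tag,
                               label = .data$name)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, show.legend = FALSE, size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.0f%%)", 100 * ev[1]),
                  y = sprintf("PC2 (%.0f%%)", 100 * ev[2])) +
    ggplot2::theme_minimal()
}

#' @describeIn summarize_changes Histograms of the per-event mass and
#'   hydrophobicity changes.
#' @param object,x A `change_summary`.
#' @param ... Unused.
#' @method autoplot change_summary
#' @export
autoplot.change_summary <- function(object, ...) {
  d <- object$deltas[object$deltas$count > 0, ]
  long <- tidyr::pivot_longer(d, c("d_hydrophobicity", "d_mass"),
                              names_to = "property", values_to = "delta")
  ggplot2::ggplot(long, ggplot2::aes(.data$delta,
                                     weight = .data$count)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::facet_wrap(~property, scales = "free") +
    ggplot2::labs(x = "change (mutant - wild type)", y = "events") +
    ggplot2::theme_minimal()
}

#' Mutability bar plot
#'
#' @param mt Output of [mutability()]; bars ordered by decreasing
#'   mutability and coloured by CpG class.
#' @return A ggplot object.
#' @export
plot_mutability <- function(mt) {
  mt <- dplyr::mutate(mt, cpg_class = cpg_class(.data$aa),
                      aa = stats::reorder(.data$aa, -.data$mutability))
  cols <- c(RED = "#d62728", YELLOW = "#e6b800", BLUE = "#1f77b4")
  ggplot2::ggplot(mt, ggplot2::aes(.data$aa, .data$mutability,
                                   fill = .data$cpg_class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = cols) +
    ggplot2::labs(x = NULL, y = "mutability (events per residue)") +
    ggplot2::theme_minimal()
}
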