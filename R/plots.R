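#' Plot per-region AT/GC skew
#'
#' Paired bar chart of AT and GC skew per composition row, the usual way
#' strand asymmetry is displayed across mitogenome regions.
#'
#' @param report A [composition_report()] tibble (or any tibble with `label`,
#'   `at_skew`, `gc_skew`).
#' @return A ggplot object.
#' @export
plot_skew <- function(report) {
  long <- report |>
    select("label", "at_skew", "gc_skew") |>
    tidyr::pivot_longer(c("at_skew", "gc_skew"),
                        names_to = "statistic", values_to = "skew") |>
    mutate(
      statistic = ifelse(.data$statistic == "at_skew", "AT skew", "GC skew"),
      label = factor(.data$label, levels = unique(report$label))
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$skew,
                                     fill = .data$statistic)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "skew", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot relative synonymous codon usage
#'
#' RSCU bars grouped by amino acid; stop codons are omitted (they carry no
#' RSCU).
#'
#' @param usage A [codon_usage()] tibble.
#' @return A ggplot object.
#' @export
plot_rscu <- function(usage) {
  dat <- usage |>
    filter(.data$amino_acid != "*", !is.na(.data$rscu))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$amino_acid, y = .data$rscu,
                                    group = .data$codon)) +
    ggplot2::geom_col(position = "stack", color = "white", linewidth = 0.2,
                      fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "amino acid", y = "RSCU") +
    ggplot2::theme_minimal()
}

#' Plot a fitted maximum-likelihood tree
#'
#' Base-graphics phylogram via ape, with bootstrap supports (if present) on
#' internal nodes.
#'
#' @param x A `mito_ml_fit`.
#' @param ... Passed to `ape::plot.phylo()`.
#' @return `x`, invisibly.
#' @export
plot.mito_ml_fit <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  if (!is.null(x$tree$node.label)) {
    ape::nodelabels(x$tree$node.label, frame = "none", adj = c(1.1, -0.3),
                    cex = 0.8)
  }
  invisible(x)
}

#' @export
autoplot.mito_ml_fit <- function(object, ...) {
  dat <- tidy(object) |>
    filter(is.finite(.data$estimate))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "estimate",
                  title = "GTR+F+I+G4 parameter estimates") +
    ggplot2::theme_minimal()
}
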