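#' Heatmap of net microbial flux contributions
#'
#' Tile plot of the scaled (microbiome minus germ-free) flux layer; masked
#' entries are blank.
#'
#' @param object a `flux_matrix`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.flux_matrix <- function(object, ...) {
  td <- tidy(object)
  td$scaled[!is.na(td$mask)] <- NA_real_
  ggplot2::ggplot(td, ggplot2::aes(x = .data$metabolite, y = .data$sample,
                                   fill = .data$scaled)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90",
                                  name = "scaled flux\n(mmol/day)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-sample read coverage distributions
#'
#' @param object a `mapping_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mapping_report <- function(object, ...) {
  td <- tidyr::pivot_longer(
    object$per_sample[, c("sample_id", "species_coverage", "mapped_coverage",
                          "mapped_of_species_reads")],
    -"sample_id", names_to = "statistic", values_to = "coverage")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$coverage)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue") +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::scale_x_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "per-sample read coverage", y = "samples") +
    ggplot2::theme_minimal()
}

#' Volcano-style view of an association family
#'
#' Standardized estimates against -log10 FDR, labelled by metabolite, with
#' the 0.05 FDR line.
#'
#' @param assoc one tidy association tibble (e.g. the `age` element of
#'   [flux_association_battery()]).
#' @param alpha FDR reference line, default 0.05.
#' @return a ggplot object.
#' @export
plot_associations <- function(assoc, alpha = 0.05) {
  d <- assoc[!is.na(assoc$fdr), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate,
                                  y = -log10(.data$fdr),
                                  label = .data$outcome_metabolite)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = "standardized estimate", y = "-log10 FDR") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
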