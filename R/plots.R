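#' Volcano plot of differential eccDNA abundance
#'
#' @param object an `ecc_diff` object.
#' @param ... unused.
#' @return a ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot ecc_diff
#' @export
autoplot.ecc_diff <- function(object, ...) {
  d <- object$result %>% mutate(neglogp = -log10(pmax(.data$p_value, 1e-300)))
  ggplot2::ggplot(d, ggplot2::aes(.data$log2fc, .data$neglogp,
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-object$lfc_cut, object$lfc_cut),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(object$p_cut),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (tumor / control)",
                  y = "-log10 P", colour = "significant") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot

#' Rainfall plot of inter-mutation distances
#'
#' Classic kataegis visualization: per SNV, the distance to the previous
#' SNV on the same chromosome on a log scale, with detected events
#' highlighted.
#'
#' @param snvs SNV tibble (`chrom`, `pos`).
#' @param events optional event tibble from [detect_kataegis()].
#' @return a ggplot object.
#' @export
plot_rainfall <- function(snvs, events = NULL) {
  d <- snvs %>% arrange(.data$chrom, .data$pos) %>%
    group_by(.data$chrom) %>%
    mutate(imd = .data$pos - lag(.data$pos)) %>%
    ungroup() %>% filter(!is.na(.data$imd), .data$imd > 0)
  g <- ggplot2::ggplot(d, ggplot2::aes(.data$pos, .data$imd)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "inter-mutation distance (bp)") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    g <- g + ggplot2::geom_rect(
      data = events,
      ggplot2::aes(xmin = .data$first_pos, xmax = .data$last_pos),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "firebrick", alpha = 0.2)
  }
  g
}

#' Bar chart of circle size-class fractions
#'
#' @param profile result of [gc_and_size_profile()].
#' @return a ggplot object.
#' @export
plot_size_classes <- function(profile) {
  ggplot2::ggplot(profile$size_fractions,
                  ggplot2::aes(.data$size_class, .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "size class", y = "fraction of circles") +
    ggplot2::theme_minimal()
}

#' Element profile plot (circle fractions and enrichment)
#'
#' @param profile tibble from [element_profile()].
#' @return a ggplot object.
#' @export
plot_element_profile <- function(profile) {
  d <- profile %>%
    tidyr::pivot_longer(c("fraction_of_circles", "enrichment"),
                        names_to = "measure", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$class, .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' 96-context mutational spectrum plot
#'
#' @param spectrum tibble from [classify_96()].
#' @return a ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  d <- spectrum %>% mutate(context = factor(.data$context, .data$context))
  ggplot2::ggplot(d, ggplot2::aes(.data$context, .data$count,
                                  fill = .data$substitution)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(~substitution, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "SNV count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   legend.position = "none")
}
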