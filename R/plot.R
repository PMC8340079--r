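#' Plot an annotated spectrum
#'
#' Stick spectrum of the peak list, colored by annotation status; the
#' top-ranked glycoform labels the most intense peaks.
#'
#' @param object A `glyco_annotation`.
#' @param label_top Number of most intense peaks to label with their
#'   top-ranked glycoform.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot glyco_annotation
#' @export
autoplot.glyco_annotation <- function(object, label_top = 5, ...) {
  peaks <- as_tibble(object) |>
    group_by(.data$peak_id) |>
    summarise(mass = first(.data$peak_mass),
              intensity = first(.data$intensity),
              top = first(.data$glycoform),
              status = dplyr::case_when(
                any(.data$unannotated) ~ "unannotated",
                any(.data$is_adduct_satellite) ~ "Na adduct",
                TRUE ~ "annotated"
              ),
              .groups = "drop")
  lab <- head(arrange(filter(peaks, !is.na(.data$top)),
                      desc(.data$intensity)), label_top)
  ggplot2::ggplot(peaks, ggplot2::aes(x = .data$mass, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mass, yend = 0,
                                       color = .data$status)) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(label = .data$top), angle = 90,
                       hjust = -0.05, size = 2.8) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0, 0.25))) +
    ggplot2::labs(x = "neutral mass (Da)", y = "relative intensity",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a site-specific glycan library
#'
#' Per-site abundance bars, one facet per site.
#'
#' @param object A `glyco_library`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot glyco_library
#' @export
autoplot.glyco_library <- function(object, ...) {
  df <- as_tibble(object)
  df$site <- factor(df$site, levels = unique(df$site))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$glycan, -.data$abundance),
                                   y = .data$abundance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$site), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "relative abundance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
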