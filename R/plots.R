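# ggplot2 methods for the result objects. Kept deliberately plain:
# diagnostic figures, not publication styling.

#' @describeIn capillary_map Plot the capillary points (and fibre outlines
#'   when present) within the frame.
#' @param object A `capillary_map`.
#' @param ... Unused.
#' @export
autoplot.capillary_map <- function(object, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(object$fibres)) {
    fib <- purrr::imap_dfr(object$fibres,
                           ~ tibble(x = .x$x, y = .x$y, fibre = .y))
    p <- p + ggplot2::geom_polygon(
      data = fib,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$fibre),
      fill = NA, colour = "grey60", linewidth = 0.3)
  }
  p +
    ggplot2::geom_point(
      data = object$capillaries,
      ggplot2::aes(x = .data$x_um, y = .data$y_um),
      colour = "red3", size = 0.8) +
    ggplot2::coord_fixed(xlim = c(0, object$frame_width),
                         ylim = c(0, object$frame_height)) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("Capillary map (%s)", object$region_label))
}

#' @describeIn tessellate Plot the domain polygons filled by area.
#' @param object A `domain_tessellation`.
#' @export
autoplot.domain_tessellation <- function(object, ...) {
  df <- purrr::imap_dfr(object$domains, function(p, i) {
    tibble(x = p$x, y = p$y, domain = i, area = object$areas[i])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$domain,
                                   fill = .data$area)) +
    ggplot2::geom_polygon(colour = "white", linewidth = 0.2) +
    ggplot2::geom_point(data = object$sites,
                        ggplot2::aes(x = .data$x_um, y = .data$y_um),
                        inherit.aes = FALSE, size = 0.5) +
    ggplot2::scale_fill_viridis_c(name = "CDA (µm²)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = "Capillary domains (trapping regions)")
}

#' @describeIn solve_frame Raster plot of the PO2 field.
#' @param object An `oxygen_field`.
#' @export
autoplot.oxygen_field <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                   fill = .data$po2_mmHg)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "PO2 (mmHg)", option = "inferno") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("Tissue PO2 (mean %.1f mmHg, hypoxic %.2g%%)",
                                  object$mean_PO2, object$hypoxic_fraction))
}

#' @describeIn tension_trace Line plot of the tension trace with the
#'   stimulation window shaded.
#' @param object A `tension_trace`.
#' @param ... Unused.
#' @export
autoplot.tension_trace <- function(object, ...) {
  w <- stimulation_window(object)
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$tension)) +
    ggplot2::annotate("rect", xmin = w[1], xmax = w[2], ymin = -Inf,
                      ymax = Inf, alpha = 0.1) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "tension (a.u.)")
}

#' @describeIn flow_trace Line plot of the flow trace with the stimulation
#'   window shaded.
#' @param object A `flow_trace`.
#' @param ... Unused.
#' @export
autoplot.flow_trace <- function(object, ...) {
  w <- stimulation_window(object)
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$flow)) +
    ggplot2::annotate("rect", xmin = w[1], xmax = w[2], ymin = -Inf,
                      ymax = Inf, alpha = 0.1) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "flow (ml/min)")
}

#' Volcano plot of a metabolomics contrast
#'
#' log2 fold change against -log10 FDR-adjusted p, with the significance
#' threshold drawn.
#'
#' @param volcano A [volcano_table()] result.
#' @param fdr_threshold Significance line (default 0.05; a relaxed 0.2
#'   screen is sometimes used for heatmap inclusion).
#' @return A ggplot object.
#' @export
plot_volcano <- function(volcano, fdr_threshold = 0.05) {
  ggplot2::ggplot(volcano,
                  ggplot2::aes(x = .data$log2_fold_change,
                               y = -log10(.data$fdr_adjusted_p),
                               colour = .data$fdr_adjusted_p < fdr_threshold)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = -log10(fdr_threshold),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red3", `FALSE` = "grey50"),
                                 name = sprintf("FDR < %g", fdr_threshold)) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 FDR-adjusted p")
}
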