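# Track figure: the query as a horizontal bar coloured by similarity class
# (white unique, gray globally similar, cyan locally repetitive), probe
# amplicons drawn above it, and the extra binding sites of repetitive probes
# as filled bars at the probe track's baseline.

#' Track plot of a probe design
#'
#' @param object A [fish_design()] result.
#' @param genes Optional gene annotation tibble (`label`, `start`, `end`) to
#'   overlay above the background.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fish_design <- function(object, genes = NULL, ...) {
  regions <- tidy(object$mask)
  regions$label <- factor(regions$label, levels = MASK_LEVELS)
  fill <- c(UNIQUE = "white", SIMILAR_GLOBAL = "gray70", SIMILAR_LOCAL = "cyan")
  t <- object$targets
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = 0, ymax = 1, fill = .data$label),
      colour = NA) +
    ggplot2::scale_fill_manual(values = fill, drop = FALSE,
                               name = "similarity") +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%.0f kb", x / 1000)) +
    ggplot2::scale_y_continuous(limits = c(0, 3), breaks = NULL) +
    ggplot2::labs(x = sprintf("position in %s", object$query$id), y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
  if (nrow(t)) {
    bind <- tidy(object, "binding")
    bind <- bind[bind$kind == "repetitive", ]
    if (nrow(bind)) {
      p <- p + ggplot2::geom_rect(
        data = bind,
        ggplot2::aes(xmin = .data$binding_start, xmax = .data$binding_end),
        ymin = 1.25, ymax = 1.45, fill = "darkgreen", alpha = 0.5)
    }
    bars <- mutate(t, colour = ifelse(.data$kind == "single_copy",
                                      "steelblue4", "darkgreen"))
    p <- p +
      ggplot2::geom_rect(
        data = bars,
        ggplot2::aes(xmin = .data$start, xmax = .data$end),
        ymin = 1.5, ymax = 1.9, fill = bars$colour) +
      ggplot2::geom_text(
        data = bars,
        ggplot2::aes(x = (.data$start + .data$end) / 2, label = .data$label),
        y = 2.15, size = 3)
  }
  if (!is.null(genes) && nrow(genes)) {
    p <- p +
      ggplot2::geom_rect(
        data = as_tibble(genes),
        ggplot2::aes(xmin = .data$start, xmax = .data$end),
        ymin = 2.4, ymax = 2.7, fill = "firebrick") +
      ggplot2::geom_text(
        data = as_tibble(genes),
        ggplot2::aes(x = (.data$start + .data$end) / 2, label = .data$label),
        y = 2.9, size = 3)
  }
  p
}

#' Render the track figure to an image file
#'
#' Deterministic for a fixed design: the same input renders byte-identical
#' output.
#'
#' @param design A [fish_design()] result.
#' @param path Output path (`.png`).
#' @param genes Optional gene annotation overlay (see
#'   [autoplot.fish_design()]).
#' @return `path`, invisibly.
#' @export
render_tracks <- function(design, path, genes = NULL) {
  p <- autoplot(design, genes = genes)
  grDevices::png(path, width = design$config$plot_width,
                 height = design$config$plot_height, units = "in", res = 150)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}
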