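#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an HSQC match as an overlay of predicted and experimental peaks
#'
#' Experimental peaks are drawn as open circles, predicted peaks as filled
#' triangles, and matched pairs are connected by segments. Axes are
#' reversed as in conventional HSQC display (shifts decrease to the right
#' and upwards).
#'
#' @param object An `hsqc_match` (use `keep_peaks = TRUE` data: the match
#'   stores only pair indices, so the original peak lists are required).
#' @param predicted,experimental The peak lists passed to [match_hsqc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hsqc_match
#' @export
autoplot.hsqc_match <- function(object, predicted, experimental, ...) {
  predicted <- check_peaks(predicted)
  experimental <- check_peaks(experimental)
  seg <- object$pairs
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(
      data = experimental,
      ggplot2::aes(h_ppm, c_ppm, shape = "experimental"),
      size = 3, stroke = 0.8
    ) +
    ggplot2::geom_point(
      data = predicted,
      ggplot2::aes(h_ppm, c_ppm, shape = "predicted"),
      size = 2
    ) +
    ggplot2::scale_shape_manual(NULL, values = c(experimental = 1, predicted = 17)) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = expression(delta ~ {}^1 * H ~ "(ppm)"),
      y = expression(delta ~ {}^13 * C ~ "(ppm)"),
      title = sprintf("matching ratio %.2f", object$matching_ratio)
    ) +
    ggplot2::theme_minimal()
  if (nrow(seg) > 0) {
    segdf <- tibble(
      x = predicted$h_ppm[seg$pred_idx], y = predicted$c_ppm[seg$pred_idx],
      xend = experimental$h_ppm[seg$exp_idx],
      yend = experimental$c_ppm[seg$exp_idx]
    )
    p <- p + ggplot2::geom_segment(
      data = segdf,
      ggplot2::aes(x = x, y = y, xend = xend, yend = yend),
      linetype = 2, linewidth = 0.3, colour = "grey40"
    )
  }
  p
}

#' Stem plot of an annotated MS2 spectrum
#'
#' Matched peaks are highlighted and labelled with their fragment formula.
#'
#' @param object An `ms2_annotation` from [annotate_spectrum()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ms2_annotation
#' @export
autoplot.ms2_annotation <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = mz)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = mz, y = 0, yend = rel_intensity, colour = matched),
      linewidth = 0.6
    ) +
    ggplot2::scale_colour_manual(
      "matched", values = c(`TRUE` = "#D55E00", `FALSE` = "grey55")
    ) +
    ggplot2::labs(x = "m/z", y = "relative intensity") +
    ggplot2::theme_minimal()
  lab <- df[df$matched, , drop = FALSE]
  if (nrow(lab) > 0) {
    p <- p + ggplot2::geom_text(
      data = lab,
      ggplot2::aes(y = rel_intensity, label = formula),
      vjust = -0.4, size = 2.8
    )
  }
  p
}

#' Plot a theoretical (and optionally observed) isotope pattern
#'
#' @param theoretical Pattern tibble from [isotope_pattern()].
#' @param observed Optional observed pattern for side-by-side comparison.
#' @return A ggplot object.
#' @export
plot_isotope_pattern <- function(theoretical, observed = NULL) {
  df <- mutate(theoretical, which = "theoretical")
  if (!is.null(observed)) {
    obs <- as_tibble(observed)
    if (!"mass" %in% names(obs)) obs$mass <- theoretical$mass[seq_len(nrow(obs))]
    df <- bind_rows(df, mutate(obs, which = "observed"))
  }
  ggplot2::ggplot(df, ggplot2::aes(mass, abundance, colour = which)) +
    ggplot2::geom_segment(ggplot2::aes(xend = mass, y = 0, yend = abundance),
                          linewidth = 0.8,
                          position = ggplot2::position_dodge(width = 0.15)) +
    ggplot2::labs(x = "mass (Da)", y = "relative abundance", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot deconvoluted HSQC peak groups
#'
#' @param grouped_hsqc Output of [group_peaks_by_connectivity()].
#' @return A ggplot object with one colour per spin-system group.
#' @export
plot_hsqc_groups <- function(grouped_hsqc) {
  stopifnot("group" %in% names(grouped_hsqc))
  ggplot2::ggplot(grouped_hsqc,
                  ggplot2::aes(h_ppm, c_ppm, colour = group)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = expression(delta ~ {}^1 * H ~ "(ppm)"),
      y = expression(delta ~ {}^13 * C ~ "(ppm)")
    ) +
    ggplot2::theme_minimal()
}
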