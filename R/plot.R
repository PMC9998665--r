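#' Plot a measurement overlay
#'
#' Renders the slice with the rim line (blue) and the perpendicular
#' segment(s) from each corneal apex to the rim line, mirroring the
#' clinical presentation of the measurement.
#'
#' @param object An `exo_measurement` from [measure_slice()].
#' @param ... Unused.
#' @return A ggplot object (image coordinates; row axis points down).
#' @export
autoplot.exo_measurement <- function(object, ...) {
  img <- object$slice$pixels
  df <- tibble(
    col = rep(seq_len(ncol(img)), each = nrow(img)),
    row = rep(seq_len(nrow(img)), ncol(img)),
    value = as.vector(img))
  lms <- object$landmarks
  rim <- lms[lms$landmark %in% c("rim_apex_a", "rim_apex_b"), ]
  cor <- lms[grepl("^cornea_", lms$landmark), ]
  a <- object$line["a"]; b <- object$line["b"]; cc <- object$line["c"]
  segs <- dplyr::mutate(cor,
    s = a * .data$col + b * .data$row + cc,
    foot_col = .data$col - .data$s * a,
    foot_row = .data$row - .data$s * b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255), guide = "none") +
    ggplot2::geom_line(data = rim, color = "#3366ff", linewidth = 0.8) +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(xend = .data$foot_col, yend = .data$foot_row),
      color = "orange", linewidth = 0.8) +
    ggplot2::geom_point(data = rbind(rim[c("row", "col")], cor[c("row", "col")]),
                        color = "red", size = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "row (px)",
                  title = sprintf("%s view: %s", object$view,
                                  paste(sprintf("%s %.1f mm",
                                                object$distances$eye,
                                                object$distances$distance_mm),
                                        collapse = ", ")))
}

#' Bland-Altman and scatter plots for an agreement report
#'
#' @param object An `exo_agreement` from [agreement_report()].
#' @param type `"bland_altman"` (differences vs means with bias and limits
#'   of agreement) or `"scatter"` (method 2 vs method 1 with identity line).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.exo_agreement <- function(object,
                                   type = c("bland_altman", "scatter"), ...) {
  type <- match.arg(type)
  df <- tibble(x = object$x, y = object$y)
  if (type == "bland_altman") {
    ba <- object$bland_altman
    df <- dplyr::mutate(df, mean = (.data$x + .data$y) / 2,
                        diff = .data$x - .data$y)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::geom_hline(yintercept = ba$bias, color = "blue") +
      ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                          linetype = "dashed", color = "red") +
      ggplot2::labs(x = sprintf("mean of %s and %s", object$labels[1],
                                object$labels[2]),
                    y = sprintf("%s - %s", object$labels[1], object$labels[2]),
                    title = sprintf("Bland-Altman: bias %.3f, LoA [%.3f, %.3f]",
                                    ba$bias, ba$loa_low, ba$loa_high))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
      ggplot2::labs(x = object$labels[1], y = object$labels[2],
                    title = sprintf("CCC %.4f, ICC %.4f, r %.4f",
                                    object$ccc, object$icc, object$pearson_r))
  }
}
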