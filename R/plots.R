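# ggplot2 views of lookup tables, shift analyses and triplet frequencies.

#' @describeIn lookup_table `autoplot()` method: tile map of the rounded
#'   virtual motor scores over the integer sensory grid (bar chart for
#'   single-feature sets; faceted by contralateral scores for `ICSens`).
#' @param object A `vms_lookup` tibble.
#' @param ... Unused.
#' @method autoplot vms_lookup
#' @export
autoplot.vms_lookup <- function(object, ...) {
  fs <- attr(object, "feature_set")
  df <- as_tibble(object)
  if (fs %in% c("ILT", "IPP")) {
    f <- if (fs == "ILT") "ilt" else "ipp"
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = factor(.data[[f]]), y = .data$raw)) +
        ggplot2::geom_col(fill = "grey40") +
        ggplot2::geom_hline(yintercept = 4.5, linetype = "dashed") +
        ggplot2::geom_text(ggplot2::aes(label = .data$rounded), vjust = -0.4) +
        ggplot2::labs(x = paste(fs, "sensory score"), y = "raw virtual motor score",
                      title = paste0(fs, " lookup table (dashed: rounding threshold for grade 5)")) +
        ggplot2::theme_minimal()
    )
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$ilt), y = factor(.data$ipp),
                                        fill = .data$rounded)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f (%d)", .data$raw, .data$rounded)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "grey30", limits = c(0, 5)) +
    ggplot2::labs(x = "ipsilateral light touch", y = "ipsilateral pinprick",
                  fill = "rounded MS") +
    ggplot2::theme_minimal()
  if (fs == "ICSens") {
    p <- p + ggplot2::facet_grid(.data$cpp ~ .data$clt, labeller = ggplot2::label_both)
  }
  p
}

#' @describeIn analyze_shift `autoplot()` method: bar chart of the shift
#'   distribution (segments caudal) over the included sides.
#' @param object A `vms_shift` object.
#' @param ... Unused.
#' @method autoplot vms_shift
#' @export
autoplot.vms_shift <- function(object, ...) {
  df <- dplyr::count(object$records, .data$shift)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$shift), y = .data$n)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "shift of recalculated vs true motor level (segments, + = caudal)",
                  y = "sides",
                  title = paste0("Motor level shift, ", object$model_name)) +
    ggplot2::theme_minimal()
}

#' Plot segmental triplet frequencies
#'
#' Bar chart of the most frequent (light touch, pinprick, motor) score
#' triplets in a triplet table, the package's view of the motor-sensory
#' coupling structure of a cohort.
#'
#' @param rows Triplet tibble from [extract_triplets()].
#' @param top_n How many triplets to show (default 10).
#' @return A ggplot object.
#' @export
plot_triplet_frequencies <- function(rows, top_n = 10L) {
  df <- rows %>%
    dplyr::count(.data$ilt, .data$ipp, .data$ms) %>%
    dplyr::mutate(
      triplet = sprintf("LT=%d PP=%d MS=%d", .data$ilt, .data$ipp, .data$ms),
      pct = 100 * .data$n / sum(.data$n)
    ) %>%
    dplyr::arrange(dplyr::desc(.data$n)) %>%
    head(top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$triplet, .data$pct),
                                   y = .data$pct)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of triplets") +
    ggplot2::theme_minimal()
}
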