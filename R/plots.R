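# ggplot2 views of the main result types.

#' Plot exclusive replicate-overlap counts (UpSet-style bars)
#'
#' @param counts Tibble from [upset_counts()].
#' @return A ggplot object.
#' @export
plot_upset <- function(counts) {
  counts$combination <- factor(
    counts$combination,
    levels = counts$combination[order(counts$degree, counts$combination)]
  )
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$combination, y = .data$count)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = "replicate combination (exclusive)",
                  y = "precursor ions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot an isotope EIC triplet
#'
#' @param eic_triplet List of three EIC tibbles (isotopes 0..2).
#' @param peak Optional one-row peak call from [call_peak()]; drawn as
#'   boundaries and apex.
#' @return A ggplot object.
#' @export
plot_eic <- function(eic_triplet, peak = NULL) {
  df <- purrr::imap(eic_triplet, function(e, i) {
    e$isotope <- paste0("M+", as.integer(i) - 1L)
    e
  }) |> dplyr::bind_rows()
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rt, y = .data$intensity,
                                        colour = .data$isotope)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "retention time (min)", y = "intensity",
                  colour = "isotope") +
    ggplot2::theme_minimal()
  if (!is.null(peak) && isTRUE(peak$detected)) {
    p <- p +
      ggplot2::geom_vline(xintercept = c(peak$rt_start, peak$rt_end),
                          linetype = "dashed", colour = "grey40") +
      ggplot2::geom_vline(xintercept = peak$apex_rt, colour = "grey10")
  }
  p
}

#' Calibration plot for an iRT model
#'
#' Standards with the fitted line; residual SD in the subtitle.
#'
#' @param object An `irt_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.irt_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed_rt,
                                   y = .data$reference_irt)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "observed RT (min)", y = "reference iRT",
      title = paste0("iRT calibration",
                     if (!is.na(object$run_id)) paste0(" - ", object$run_id)),
      subtitle = sprintf("iRT = %.3f RT %+.2f, residual SD %.3g",
                         object$slope, object$intercept, object$residual_sd)
    ) +
    ggplot2::theme_minimal()
}

#' Mobility-library overview plot
#'
#' Mean 1/K0 against precursor charge with the per-precursor extraction
#' window as vertical ranges.
#'
#' @param entries Tibble from [build_mobility_library()].
#' @return A ggplot object.
#' @export
plot_mobility_library <- function(entries) {
  ggplot2::ggplot(entries,
                  ggplot2::aes(x = factor(.data$z), y = .data$mean_inv_k0)) +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$mean_inv_k0 - .data$window_width / 2,
                   ymax = .data$mean_inv_k0 + .data$window_width / 2),
      colour = "grey60", position = ggplot2::position_jitter(width = 0.15,
                                                             seed = 1)
    ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "charge", y = expression("1/K"[0] ~ "(V s/cm"^2 * ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
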