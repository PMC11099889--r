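# Precursor-specific ion-mobility library: per (cross-link identity, charge),
# the mean 1/K0 and its observed range across all contributing XSMs, exported
# in Skyline's ion-mobility library CSV form.

#' Build a precursor-specific ion-mobility library
#'
#' Aggregates filtered target XSMs by precursor key (cross-link identity plus
#' charge): mean 1/K0, observed (min, max) range, and an extraction window
#' width equal to the range floored at `min_window` so single-observation
#' precursors still get a usable window.
#'
#' @param xsms Filtered XSM tibble with `inv_k0` present.
#' @param min_window Minimum total window width in V s/cm^2. The default 0.05
#'   (i.e. +/- 0.025) matches the mobility tolerance used when merging scans.
#' @return A tibble with one row per precursor: `precursor`, `peptide_a`,
#'   `peptide_b`, `pos_a`, `pos_b`, `z`, `mean_inv_k0`, `inv_k0_min`,
#'   `inv_k0_max`, `n_observations`, `window_width`; ordered by key.
#' @export
build_mobility_library <- function(xsms, min_window = 0.05) {
  miss <- is.na(xsms$inv_k0)
  if (any(miss)) {
    warning(sum(miss), " XSM(s) without 1/K0 skipped", call. = FALSE)
    xsms <- xsms[!miss, ]
  }
  xsms$precursor <- precursor_key(xsms)
  xsms |>
    dplyr::group_by(.data$precursor) |>
    dplyr::summarise(
      peptide_a = .data$peptide_a[1], peptide_b = .data$peptide_b[1],
      pos_a = .data$pos_a[1], pos_b = .data$pos_b[1], z = .data$z[1],
      mean_inv_k0 = mean(.data$inv_k0),
      inv_k0_min = min(.data$inv_k0),
      inv_k0_max = max(.data$inv_k0),
      n_observations = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      window_width = pmax(.data$inv_k0_max - .data$inv_k0_min, min_window)
    ) |>
    dplyr::arrange(.data$precursor)
}

#' Write an ion-mobility library as Skyline-compatible CSV
#'
#' Columns: textual precursor identifier (both sequences, link positions and
#' charge, unambiguous), charge, ion mobility (mean 1/K0 to 4 decimals),
#' units (`inverse_K0_Vsec_per_cm2`) and window width. Decimal points are
#' locale-independent.
#'
#' @param entries Library tibble from [build_mobility_library()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_skyline_im_csv <- function(entries, path) {
  if (nrow(entries) == 0L) stop("no library entries to write", call. = FALSE)
  out <- tibble::tibble(
    precursor = entries$precursor,
    charge = entries$z,
    ion_mobility = sprintf("%.4f", entries$mean_inv_k0),
    ion_mobility_units = "inverse_K0_Vsec_per_cm2",
    window_width = sprintf("%.4f", entries$window_width)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a Skyline ion-mobility library CSV
#'
#' @param path CSV written by [write_skyline_im_csv()].
#' @return A tibble with `precursor`, `charge`, `ion_mobility` (numeric),
#'   `ion_mobility_units`, `window_width` (numeric).
#' @export
read_skyline_im_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df$charge <- as.integer(df$charge)
  df$ion_mobility <- as.numeric(df$ion_mobility)
  df$window_width <- as.numeric(df$window_width)
  df
}
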