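# Indexed retention time (iRT) calibration: a per-run affine map from
# observed retention time to the run-independent iRT scale, anchored on
# spiked standard peptides, plus RT-window prediction for matching
# identifications between runs and against negative controls.

#' Fit a linear iRT calibration for one run
#'
#' Ordinary least squares of `reference_irt ~ observed_rt`. With
#' `robust = TRUE` and at least 6 standards, the single worst outlier is
#' refitted away when its residual exceeds 3 residual SDs.
#'
#' @param standards Data frame with columns `reference_irt` and `observed_rt`
#'   (minutes), optionally `name`; at least 2 rows with distinct RTs.
#' @param run_id Optional run label stored on the model.
#' @param robust Apply the single-worst-outlier rule.
#' @return An object of class `irt_model` with `slope`, `intercept`
#'   (iRT = slope * RT + intercept), `residual_sd`, `n_standards`, and the
#'   standards table.
#' @examples
#' fit_irt(data.frame(reference_irt = c(0, 50, 100), observed_rt = c(10, 20, 30)))
#' @export
fit_irt <- function(standards, run_id = NA_character_, robust = FALSE) {
  stopifnot(all(c("reference_irt", "observed_rt") %in% names(standards)))
  standards <- tibble::as_tibble(standards)
  if (nrow(standards) < 2L) stop("need at least 2 standards", call. = FALSE)
  if (stats::sd(standards$observed_rt) == 0) {
    stop("zero retention-time variance among standards", call. = FALSE)
  }
  fit <- stats::lm(reference_irt ~ observed_rt, data = standards)
  used <- standards
  if (robust && nrow(standards) >= 6L) {
    res <- stats::residuals(fit)
    sdres <- stats::sd(res)
    worst <- which.max(abs(res))
    if (sdres > 0 && abs(res[worst]) > 3 * sdres) {
      used <- standards[-worst, ]
      fit <- stats::lm(reference_irt ~ observed_rt, data = used)
    }
  }
  coefs <- stats::coef(fit)
  res <- stats::residuals(fit)
  structure(
    list(run_id = run_id,
         slope = unname(coefs["observed_rt"]),
         intercept = unname(coefs["(Intercept)"]),
         residual_sd = if (nrow(used) > 2L) stats::sd(res) else 0,
         n_standards = nrow(used),
         standards = used),
    class = "irt_model"
  )
}

#' @export
print.irt_model <- function(x, ...) {
  cat("<iRT calibration>",
      if (!is.na(x$run_id)) paste0(" run ", x$run_id), "\n",
      "  iRT = ", format(x$slope, digits = 6), " * RT + ",
      format(x$intercept, digits = 6), "\n",
      "  residual SD ", format(x$residual_sd, digits = 4), " iRT units over ",
      x$n_standards, " standards\n", sep = "")
  invisible(x)
}

#' Broom-style one-row model summary for an iRT calibration
#'
#' @param x An `irt_model`.
#' @param ... Unused.
#' @return One-row tibble: `run_id`, `slope`, `intercept`, `residual_sd`,
#'   `n_standards`.
#' @export
glance.irt_model <- function(x, ...) {
  tibble::tibble(run_id = x$run_id, slope = x$slope, intercept = x$intercept,
                 residual_sd = x$residual_sd, n_standards = x$n_standards)
}

#' Broom-style per-standard table for an iRT calibration
#'
#' @param x An `irt_model`.
#' @param ... Unused.
#' @return Tibble of the standards used with fitted iRT and residuals.
#' @export
tidy.irt_model <- function(x, ...) {
  out <- x$standards
  out$fitted_irt <- to_irt(x, out$observed_rt)
  out$residual <- out$reference_irt - out$fitted_irt
  tibble::as_tibble(out)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Convert observed retention time to iRT
#'
#' @param model An `irt_model`.
#' @param rt Retention time(s) in minutes.
#' @return iRT value(s).
#' @export
to_irt <- function(model, rt) {
  stopifnot(inherits(model, "irt_model"))
  model$slope * rt + model$intercept
}

#' Predict the run-local retention time (and window) of an iRT
#'
#' Inverts the calibration: `RT = (iRT - intercept) / slope`. The half-width
#' of the matching window is `max(k * residual_sd / slope, floor)`, so a
#' perfectly calibrated run still gets a usable window.
#'
#' @param model An `irt_model`.
#' @param irt iRT value(s).
#' @param k Multiplier on the residual SD (default 3).
#' @param floor_min Minimum half-width in minutes (default 0.5).
#' @return Tibble with `rt` (minutes), `rt_min`, `rt_max`, `half_width`.
#' @export
predict_rt <- function(model, irt, k = 3, floor_min = 0.5) {
  stopifnot(inherits(model, "irt_model"))
  if (model$slope <= 0) stop("non-positive calibration slope", call. = FALSE)
  rt <- (irt - model$intercept) / model$slope
  hw <- max(k * model$residual_sd / model$slope, floor_min)
  tibble::tibble(rt = rt, rt_min = rt - hw, rt_max = rt + hw, half_width = hw)
}

#' Consensus iRT index across runs
#'
#' Projects each run's observed XSM retention times onto the iRT scale via
#' that run's calibration and aggregates per precursor: the consensus iRT
#' (mean across runs) and its spread (max - min).
#'
#' @param xsms XSM tibble (filtered targets).
#' @param irt_models Named list of `irt_model`s, one per `run_id`.
#' @return Tibble: `precursor`, `consensus_irt`, `irt_spread`, `n_runs`.
#' @export
index_precursors <- function(xsms, irt_models) {
  xsms$precursor <- precursor_key(xsms)
  xsms$irt <- purrr::map2_dbl(xsms$run_id, xsms$rt_min, function(run, rt) {
    m <- irt_models[[run]]
    if (is.null(m)) return(NA_real_)
    to_irt(m, rt)
  })
  xsms |>
    dplyr::filter(!is.na(.data$irt)) |>
    dplyr::group_by(.data$precursor) |>
    dplyr::summarise(
      consensus_irt = mean(.data$irt),
      irt_spread = max(.data$irt) - min(.data$irt),
      n_runs = dplyr::n_distinct(.data$run_id),
      .groups = "drop"
    )
}
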