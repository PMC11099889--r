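# Study report: the reporting surfaces of the workflow - per-precursor
# validation verdicts, replicate-overlap (UpSet) counts, the iRT index of
# confirmed cross-links, and the negative-control contrast.

#' Build the study report
#'
#' Aggregates validation output into deterministic tables: the validation
#' table itself, exclusive replicate-overlap counts of XSM-level
#' identifications (UpSet form), the iRT index of validated precursors, the
#' negative-control contrast, and summary counts per verdict including the
#' fraction of assessed precursors that carried XSMs in every sample
#' replicate.
#'
#' @param validation Tibble from [validate_study()] (the `per_run`
#'   list-column is optional).
#' @param filtered_xsms Filtered target XSM tibble.
#' @param irt_models Named list of per-run `irt_model`s (may be `NULL`).
#' @param run_manifest Run manifest tibble.
#' @return A list of class `xl_report`: `validation`, `upset`, `irt_index`,
#'   `control_contrast`, `summary`.
#' @export
build_report <- function(validation, filtered_xsms, irt_models = NULL,
                         run_manifest = NULL) {
  filtered_xsms$precursor <- precursor_key(filtered_xsms)
  rep_runs <- if (!is.null(run_manifest)) {
    run_manifest$run_id[!run_manifest$is_control]
  } else unique(filtered_xsms$run_id)

  upset <- if (length(rep_runs) == 0L) {
    tibble::tibble(combination = character(0), degree = integer(0),
                   count = integer(0))
  } else {
    id_sets <- purrr::map(rep_runs, function(run) {
      unique(filtered_xsms$precursor[filtered_xsms$run_id == run])
    })
    names(id_sets) <- rep_runs
    upset_counts(id_sets)
  }

  irt_index <- if (!is.null(irt_models)) {
    idx <- index_precursors(filtered_xsms, irt_models)
    idx[idx$precursor %in%
          validation$precursor[validation$verdict == "validated"], ]
  } else {
    tibble::tibble(precursor = character(0), consensus_irt = numeric(0),
                   irt_spread = numeric(0), n_runs = integer(0))
  }

  control_contrast <- if ("per_run" %in% names(validation) &&
                          is.list(validation$per_run)) {
    validation |>
      dplyr::select("precursor", "per_run") |>
      tidyr::unnest("per_run") |>
      dplyr::filter(.data$is_control) |>
      dplyr::select("precursor", control_run = "run_id",
                    peak_found = "detected", control_apex_rt = "apex_rt")
  } else {
    validation |>
      dplyr::select("precursor", peak_found = "control_detected")
  }

  xsm_counts <- filtered_xsms |>
    dplyr::filter(.data$run_id %in% rep_runs) |>
    dplyr::distinct(.data$precursor, .data$run_id) |>
    dplyr::count(.data$precursor, name = "n_runs_with_xsm")
  assessed <- dplyr::left_join(validation, xsm_counts, by = "precursor")
  assessed$n_runs_with_xsm[is.na(assessed$n_runs_with_xsm)] <- 0L
  validated <- assessed[assessed$verdict == "validated", ]
  verdicts <- c("validated", "rejected_fdr", "rejected_control",
                "rejected_replicates", "not_detected")
  summary <- tibble::tibble(
    n_precursors = nrow(assessed),
    !!!stats::setNames(
      purrr::map_int(verdicts, ~ sum(assessed$verdict == .x)),
      paste0("n_", verdicts)
    ),
    frac_xsm_all_replicates = if (nrow(validated)) {
      mean(validated$n_runs_with_xsm == length(rep_runs))
    } else NA_real_
  )

  structure(
    list(
      validation = if ("per_run" %in% names(validation)) {
        dplyr::select(validation, -"per_run")
      } else validation,
      upset = upset,
      irt_index = irt_index,
      control_contrast = control_contrast,
      summary = summary
    ),
    class = c("xl_report", "list")
  )
}

#' @export
print.xl_report <- function(x, ...) {
  s <- x$summary
  cat("<study report>\n",
      "  precursors assessed: ", s$n_precursors, "\n",
      "  validated:           ", s$n_validated, "\n",
      "  rejected (FDR/control/replicates): ", s$n_rejected_fdr, "/",
      s$n_rejected_control, "/", s$n_rejected_replicates, "\n",
      "  not detected:        ", s$n_not_detected, "\n",
      "  with XSMs in all replicates: ",
      if (is.na(s$frac_xsm_all_replicates)) "NA" else
        sprintf("%.0f%%", 100 * s$frac_xsm_all_replicates), "\n", sep = "")
  invisible(x)
}
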