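# Peptide-centric validation: for every cross-link precursor that survived
# FDR filtering, extract ion chromatograms of its first three isotopes from
# every run (sample replicates and cross-linker-free negative controls)
# inside the predicted retention-time window and the library mobility window,
# call chromatographic peaks, and confirm the cross-link only when it passes
# the three-criterion conjunction: XSM-level q-value at most alpha, a
# detected peak in all sample replicates, and no detected peak in any
# negative control.

#' Extract an ion chromatogram from an MS1 peak source
#'
#' The trace is evaluated on the union of source scan times inside the RT
#' window (no resampling); at each time the intensities of all peaks within
#' `ppm` of `mz` and inside the mobility window are summed.
#'
#' @param source MS1 peak tibble with columns `rt_min`, `mz`, `intensity`,
#'   `inv_k0` (one run).
#' @param mz Target m/z in Th.
#' @param ppm Extraction tolerance in parts per million.
#' @param rt_window Numeric length-2 `(min, max)` in minutes.
#' @param im_center,im_halfwidth Mobility window; `NA` disables the mobility
#'   filter.
#' @return A tibble with columns `rt`, `intensity` (possibly 0 rows).
#' @export
extract_eic <- function(source, mz, ppm = 10, rt_window,
                        im_center = NA_real_, im_halfwidth = NA_real_) {
  if (ppm <= 0) stop("ppm must be positive", call. = FALSE)
  stopifnot(mz > 0, length(rt_window) == 2L, rt_window[1] <= rt_window[2])
  in_rt <- source$rt_min >= rt_window[1] & source$rt_min <= rt_window[2]
  grid <- sort(unique(source$rt_min[in_rt]))
  half <- mz * ppm * 1e-6
  hit <- in_rt & abs(source$mz - mz) <= half
  if (!is.na(im_center) && !is.na(im_halfwidth)) {
    hit <- hit & !is.na(source$inv_k0) &
      abs(source$inv_k0 - im_center) <= im_halfwidth
  }
  sums <- tapply(source$intensity[hit], factor(source$rt_min[hit], levels = grid),
                 sum, default = 0)
  tibble::tibble(rt = grid, intensity = as.numeric(sums))
}

# Align several EICs on the intersection of their RT grids.
align_traces <- function(eics) {
  grids <- purrr::map(eics, "rt")
  common <- Reduce(intersect, grids)
  purrr::map(eics, function(e) e$intensity[match(common, e$rt)]) |>
    (\(ints) list(rt = common, traces = ints))()
}

#' Call a chromatographic peak from an isotope EIC triplet
#'
#' The three isotope traces are aligned on their common RT grid and summed;
#' the apex is the grid maximum; boundaries extend from the apex until the
#' summed trace falls to 5% of the apex or rises again (local minimum).
#' Noise is the median absolute deviation of the off-peak region scaled to an
#' SD (1.4826 * MAD); the isotope-coelution score is the minimum pairwise
#' Pearson correlation of the three traces inside the boundaries. A peak is
#' `detected` when S/N and coelution both reach their thresholds.
#'
#' @param eic_triplet List of three EIC tibbles (isotopes k = 0, 1, 2).
#' @param sn_threshold Minimum signal-to-noise.
#' @param coelution_threshold Minimum isotope-coelution score.
#' @return One-row tibble: `detected`, `apex_rt`, `rt_start`, `rt_end`,
#'   `apex_intensity`, `area`, `sn`, `coelution`.
#' @export
call_peak <- function(eic_triplet, sn_threshold = 3, coelution_threshold = 0.8) {
  stopifnot(length(eic_triplet) == 3L)
  empty <- tibble::tibble(
    detected = FALSE, apex_rt = NA_real_, rt_start = NA_real_,
    rt_end = NA_real_, apex_intensity = 0, area = 0, sn = 0, coelution = 0
  )
  al <- align_traces(eic_triplet)
  if (length(al$rt) < 3L) return(empty)
  total <- Reduce(`+`, al$traces)
  if (all(total <= 0)) return(empty)
  apex <- which.max(total)
  lo <- apex
  while (lo > 1L && total[lo - 1L] > 0.05 * total[apex] &&
         total[lo - 1L] <= total[lo]) lo <- lo - 1L
  hi <- apex
  while (hi < length(total) && total[hi + 1L] > 0.05 * total[apex] &&
         total[hi + 1L] <= total[hi]) hi <- hi + 1L
  inside <- seq(lo, hi)
  off <- total[-inside]
  noise <- if (length(off) >= 3L) 1.4826 * stats::mad(off, constant = 1) else 0
  sn <- if (noise > 0) total[apex] / noise else Inf
  coel <- if (length(inside) >= 3L) {
    pairs <- utils::combn(3L, 2L)
    cors <- apply(pairs, 2L, function(p) {
      a <- al$traces[[p[1]]][inside]; b <- al$traces[[p[2]]][inside]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
      stats::cor(a, b)
    })
    min(cors)
  } else 0
  area <- sum(diff(al$rt[inside]) *
                (total[inside][-1] + total[inside][-length(inside)]) / 2)
  tibble::tibble(
    detected = is.infinite(sn) || sn >= sn_threshold,
    apex_rt = al$rt[apex], rt_start = al$rt[lo], rt_end = al$rt[hi],
    apex_intensity = total[apex], area = area,
    sn = sn, coelution = coel
  ) |>
    dplyr::mutate(detected = .data$detected & .data$coelution >= coelution_threshold)
}

#' Combine the three validation criteria into a verdict
#'
#' Encodes the acceptance rule: a cross-link precursor is `validated` iff it
#' passes the XSM-level FDR, is detected in all sample replicates, and is
#' absent from every negative control. Rejection reasons take precedence in
#' the order FDR, then control contamination, then replicate coverage; a
#' precursor seen in no replicate at all is `not_detected`.
#'
#' @param fdr_pass Logical: best XSM q-value at most alpha.
#' @param n_detected,n_replicates Detected / total sample replicate runs.
#' @param control_detected Logical: any negative-control peak.
#' @return Character verdict.
#' @export
verdict_of <- function(fdr_pass, n_detected, n_replicates, control_detected) {
  if (!fdr_pass) return("rejected_fdr")
  if (control_detected) return("rejected_control")
  if (n_detected == n_replicates && n_replicates > 0L) return("validated")
  if (n_detected == 0L) return("not_detected")
  "rejected_replicates"
}

#' Validate one cross-link precursor across runs
#'
#' For each run, predicts the local RT window by projecting the consensus iRT
#' through the run's calibration, extracts the first three isotope EICs
#' inside that window and the library mobility window, and calls a peak.
#' The verdict follows [verdict_of()].
#'
#' @param key Precursor key (see [precursor_key()]).
#' @param run_manifest Tibble: `run_id`, `is_control` (logical),
#'   `replicate_group`.
#' @param ms1_sources Named list (by run_id) of MS1 peak tibbles.
#' @param library_entry One row of [build_mobility_library()] output, or
#'   `NULL` (yields `not_detected` with a warning).
#' @param irt_models Named list of `irt_model`s per run.
#' @param consensus_irt Consensus iRT of the precursor.
#' @param q_value Best XSM q-value of the precursor.
#' @param mono_mz Monoisotopic precursor m/z.
#' @param alpha FDR criterion level.
#' @param ppm EIC extraction tolerance.
#' @param sn_threshold,coelution_threshold Peak-call thresholds.
#' @return One-row tibble with the verdict plus a `per_run` list-column of
#'   per-run peak calls.
#' @export
validate_precursor <- function(key, run_manifest, ms1_sources, library_entry,
                               irt_models, consensus_irt, q_value, mono_mz,
                               alpha = 0.05, ppm = 10,
                               sn_threshold = 3, coelution_threshold = 0.8) {
  if (is.null(library_entry) || nrow(library_entry) == 0L) {
    warning("no mobility library entry for ", key, call. = FALSE)
    return(tibble::tibble(
      precursor = key, q_value = q_value, verdict = "not_detected",
      n_detected = 0L, n_replicates = sum(!run_manifest$is_control),
      control_detected = FALSE, per_run = list(tibble::tibble())
    ))
  }
  z <- library_entry$z[1]
  im_center <- library_entry$mean_inv_k0[1]
  im_halfwidth <- library_entry$window_width[1] / 2
  per_run <- purrr::map(seq_len(nrow(run_manifest)), function(i) {
    run <- run_manifest$run_id[i]
    model <- irt_models[[run]]
    src <- ms1_sources[[run]]
    if (is.null(model) || is.null(src) || is.na(consensus_irt)) {
      return(tibble::tibble(run_id = run,
                            is_control = run_manifest$is_control[i],
                            detected = FALSE, apex_rt = NA_real_,
                            sn = 0, coelution = 0))
    }
    win <- predict_rt(model, consensus_irt)
    eics <- purrr::map(0:2, function(k) {
      extract_eic(src, isotope_mz(mono_mz, z, k), ppm = ppm,
                  rt_window = c(win$rt_min, win$rt_max),
                  im_center = im_center, im_halfwidth = im_halfwidth)
    })
    pk <- call_peak(eics, sn_threshold, coelution_threshold)
    tibble::tibble(run_id = run, is_control = run_manifest$is_control[i],
                   detected = pk$detected, apex_rt = pk$apex_rt,
                   sn = pk$sn, coelution = pk$coelution)
  }) |> dplyr::bind_rows()
  reps <- per_run[!per_run$is_control, ]
  ctrl <- per_run[per_run$is_control, ]
  tibble::tibble(
    precursor = key,
    q_value = q_value,
    verdict = verdict_of(q_value <= alpha, sum(reps$detected), nrow(reps),
                         any(ctrl$detected)),
    n_detected = sum(reps$detected),
    n_replicates = nrow(reps),
    control_detected = any(ctrl$detected),
    per_run = list(per_run)
  )
}

#' Validate every FDR-surviving precursor of a study
#'
#' Orchestrates [build_mobility_library()], [index_precursors()] and
#' [validate_precursor()] over all precursors of a filtered XSM set.
#'
#' @param filtered_xsms Filtered target XSM tibble (with q-values).
#' @param run_manifest,ms1_sources,irt_models See [validate_precursor()].
#' @param alpha,ppm,sn_threshold,coelution_threshold Criteria parameters.
#' @param min_window Mobility window floor (see [build_mobility_library()]).
#' @return Validation tibble, one row per precursor.
#' @export
validate_study <- function(filtered_xsms, run_manifest, ms1_sources,
                           irt_models, alpha = 0.05, ppm = 10,
                           sn_threshold = 3, coelution_threshold = 0.8,
                           min_window = 0.05) {
  lib <- build_mobility_library(filtered_xsms, min_window = min_window)
  idx <- index_precursors(filtered_xsms, irt_models)
  filtered_xsms$precursor <- precursor_key(filtered_xsms)
  # theoretical monoisotopic m/z from the sequences (peptide-centric);
  # observed precursor m/z only as fallback for unparseable records
  theo_mz <- function(pa, pb, qa, qb, z, obs) {
    tryCatch(
      precursor_mz(crosslink_mass(crosslink(pa, pb, qa, qb)), z),
      error = function(e) obs
    )
  }
  best_q <- filtered_xsms |>
    dplyr::group_by(.data$precursor) |>
    dplyr::summarise(
      q_value = min(.data$q_value),
      mz = theo_mz(.data$peptide_a[1], .data$peptide_b[1], .data$pos_a[1],
                   .data$pos_b[1], .data$z[1], mean(.data$mz)),
      .groups = "drop"
    )
  purrr::map(best_q$precursor, function(key) {
    entry <- lib[lib$precursor == key, ]
    irt_row <- idx[idx$precursor == key, ]
    validate_precursor(
      key, run_manifest, ms1_sources,
      library_entry = if (nrow(entry)) entry else NULL,
      irt_models = irt_models,
      consensus_irt = if (nrow(irt_row)) irt_row$consensus_irt else NA_real_,
      q_value = best_q$q_value[best_q$precursor == key],
      mono_mz = best_q$mz[best_q$precursor == key],
      alpha = alpha, ppm = ppm,
      sn_threshold = sn_threshold, coelution_threshold = coelution_threshold
    )
  }) |> dplyr::bind_rows()
}

#' Exclusive intersection counts for an UpSet summary
#'
#' For every non-empty combination of set names, counts the elements that
#' belong to exactly those sets; counts sum to the size of the union.
#'
#' @param id_sets Named list of character vectors (e.g. precursor keys
#'   identified per replicate run).
#' @return Tibble: `combination` (names joined by `&`), `degree`, `count`,
#'   sorted by degree then combination.
#' @export
upset_counts <- function(id_sets) {
  stopifnot(length(id_sets) >= 1L, !is.null(names(id_sets)))
  ids <- unique(unlist(id_sets))
  if (length(ids) == 0L) {
    return(tibble::tibble(combination = character(0), degree = integer(0),
                          count = integer(0)))
  }
  membership <- vapply(id_sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1L) membership <- matrix(membership, nrow = 1L,
                                              dimnames = list(NULL, names(id_sets)))
  combo <- apply(membership, 1L, function(row) {
    paste(names(id_sets)[row], collapse = "&")
  })
  tab <- table(combo)
  tibble::tibble(
    combination = names(tab),
    degree = purrr::map_int(strsplit(names(tab), "&", fixed = TRUE), length),
    count = as.integer(tab)
  ) |>
    dplyr::arrange(.data$degree, .data$combination)
}

#' Match identifications between runs via detected peaks
#'
#' Classifies each (precursor, sample-replicate run) as `xsm_and_peak`
#' (search identification plus chromatographic evidence), `peak_only` (no
#' XSM in that run, but the EIC peak was found at the aligned iRT and
#' mobility - the identification transfers from another replicate), or
#' `no_peak`. Summarises the fraction of precursors with XSMs in every
#' replicate versus those completed by peak-only transfer.
#'
#' @param validation Output of [validate_study()].
#' @param filtered_xsms Filtered XSM tibble.
#' @return List with `per_run` (long classification tibble) and `summary`
#'   (one-row tibble: `n_precursors`, `frac_xsm_all_replicates`,
#'   `frac_recovered_by_transfer`).
#' @export
match_between_runs <- function(validation, filtered_xsms) {
  filtered_xsms$precursor <- precursor_key(filtered_xsms)
  xsm_runs <- filtered_xsms |>
    dplyr::distinct(.data$precursor, .data$run_id) |>
    dplyr::mutate(has_xsm = TRUE)
  per_run <- validation |>
    dplyr::select("precursor", "per_run") |>
    tidyr::unnest("per_run") |>
    dplyr::filter(!.data$is_control) |>
    dplyr::left_join(xsm_runs, by = c("precursor", "run_id")) |>
    dplyr::mutate(
      has_xsm = !is.na(.data$has_xsm),
      status = dplyr::case_when(
        .data$has_xsm & .data$detected ~ "xsm_and_peak",
        .data$detected ~ "peak_only",
        TRUE ~ "no_peak"
      )
    )
  by_prec <- per_run |>
    dplyr::group_by(.data$precursor) |>
    dplyr::summarise(
      xsm_all = all(.data$has_xsm),
      detected_all = all(.data$detected),
      transfer_complete = !all(.data$has_xsm) && all(.data$detected),
      .groups = "drop"
    )
  list(
    per_run = per_run |>
      dplyr::select("precursor", "run_id", "has_xsm", "detected", "status"),
    summary = tibble::tibble(
      n_precursors = nrow(by_prec),
      frac_xsm_all_replicates = if (nrow(by_prec)) mean(by_prec$xsm_all) else NA_real_,
      frac_recovered_by_transfer = if (nrow(by_prec)) mean(by_prec$transfer_complete) else NA_real_
    )
  )
}
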