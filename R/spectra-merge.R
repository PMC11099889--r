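# Grouping of ion-mobility-resolved DDA MS/MS scans into compounds and
# merging them into consensus spectra, mirroring the compound-detection step
# that precedes database searching: scans whose precursors agree in m/z,
# retention time and 1/K0 belong to one eluting compound.

#' Construct a table of MS/MS spectrum records
#'
#' One row per scan. `peaks` is a list-column of two-column matrices
#' (`mz`, `intensity`), kept sorted by m/z.
#'
#' @param run_id,scan_id Character vectors.
#' @param precursor_mz Precursor m/z in Th.
#' @param precursor_charge Integer; 0 means unknown.
#' @param rt Retention time in minutes.
#' @param inv_k0 Inverse reduced ion mobility in V s/cm^2; `NA` if unknown.
#' @param peaks List of matrices / data frames with columns mz, intensity.
#' @param precursor_intensity Optional precursor intensity (used to rank
#'   cluster seeds); defaults to the summed fragment intensity.
#' @return A tibble of class `xl_spectra`.
#' @export
spectrum_records <- function(run_id, scan_id, precursor_mz, precursor_charge,
                             rt, inv_k0, peaks,
                             precursor_intensity = NA_real_) {
  peaks <- purrr::map(peaks, function(pk) {
    pk <- as.matrix(as.data.frame(pk)[, 1:2])
    colnames(pk) <- c("mz", "intensity")
    if (any(pk[, "intensity"] < 0)) stop("negative peak intensity", call. = FALSE)
    pk[order(pk[, "mz"]), , drop = FALSE]
  })
  out <- tibble::tibble(
    run_id = as.character(run_id),
    scan_id = as.character(scan_id),
    precursor_mz = as.numeric(precursor_mz),
    precursor_charge = as.integer(precursor_charge),
    rt = as.numeric(rt),
    inv_k0 = as.numeric(inv_k0),
    precursor_intensity = as.numeric(precursor_intensity),
    peaks = peaks
  )
  out$precursor_intensity <- ifelse(
    is.na(out$precursor_intensity),
    purrr::map_dbl(out$peaks, ~ sum(.x[, "intensity"])),
    out$precursor_intensity
  )
  if (any(out$rt < 0, na.rm = TRUE)) stop("negative retention time", call. = FALSE)
  class(out) <- c("xl_spectra", class(out))
  out
}

#' Group scans into compounds by precursor m/z, RT and ion mobility
#'
#' Greedy seeded clustering: records are ranked by descending precursor
#' intensity (ties broken by ascending m/z, then scan_id); the highest-ranked
#' unassigned record seeds a cluster and absorbs every unassigned record
#' within all three tolerances *of the seed* (membership is not transitive,
#' which bounds within-cluster spread at the stated tolerances). The result
#' is a deterministic partition independent of input order.
#'
#' @param records A spectrum-record tibble (see [spectrum_records()]).
#' @param tol_rt Retention-time tolerance in minutes.
#' @param tol_mz Absolute precursor m/z tolerance in Th.
#' @param tol_im 1/K0 tolerance in V s/cm^2.
#' @return The input tibble with an integer `cluster` column; cluster ids are
#'   ordered by seed rank.
#' @export
group_spectra <- function(records, tol_rt = 0.75, tol_mz = 0.015,
                          tol_im = 0.025) {
  if (tol_rt < 0 || tol_mz < 0 || tol_im < 0) {
    stop("tolerances must be non-negative", call. = FALSE)
  }
  n <- nrow(records)
  if (n == 0L) {
    records$cluster <- integer(0)
    return(records)
  }
  rank_order <- order(-records$precursor_intensity, records$precursor_mz,
                      records$scan_id)
  cluster <- rep(NA_integer_, n)
  next_id <- 1L
  for (i in rank_order) {
    if (!is.na(cluster[i])) next
    members <- is.na(cluster) &
      abs(records$precursor_mz - records$precursor_mz[i]) <= tol_mz &
      abs(records$rt - records$rt[i]) <= tol_rt &
      abs(records$inv_k0 - records$inv_k0[i]) <= tol_im
    members[i] <- TRUE
    cluster[members] <- next_id
    next_id <- next_id + 1L
  }
  records$cluster <- cluster
  records
}

# Tolerance-bin centroided peaks pooled from cluster members: ascending m/z
# sweep; a peak opens a new bin when it is more than `tol` above the running
# intensity-weighted bin centre. Intensities sum; m/z is the weighted mean.
bin_peaks <- function(mz, intensity, tol = 0.02) {
  if (length(mz) == 0L) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("mz", "intensity"))))
  }
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  bin <- integer(length(mz))
  bin[1] <- 1L
  centre <- mz[1]; wsum <- intensity[1]
  for (i in seq_along(mz)[-1]) {
    if (mz[i] - centre <= tol) {
      bin[i] <- bin[i - 1L]
      wsum <- wsum + intensity[i]
      centre <- if (wsum > 0) {
        (centre * (wsum - intensity[i]) + mz[i] * intensity[i]) / wsum
      } else mean(c(centre, mz[i]))
    } else {
      bin[i] <- bin[i - 1L] + 1L
      centre <- mz[i]; wsum <- intensity[i]
    }
  }
  agg_int <- tapply(intensity, bin, sum)
  agg_mz <- tapply(mz * intensity, bin, sum) / ifelse(agg_int > 0, agg_int, 1)
  zero <- agg_int == 0
  if (any(zero)) agg_mz[zero] <- tapply(mz, bin, mean)[zero]
  cbind(mz = as.numeric(agg_mz), intensity = as.numeric(agg_int))
}

#' Merge a cluster of scans into one consensus spectrum
#'
#' Fragment peaks from all members are pooled and tolerance-binned (intensity
#' = sum, m/z = intensity-weighted mean). The consensus precursor m/z and the
#' ion-mobilogram centre (1/K0) are intensity-weighted means over members;
#' the apex RT is the RT of the highest-precursor-intensity member.
#'
#' @param members Rows of one cluster from [group_spectra()].
#' @param frag_bin_tol Fragment binning width in Th.
#' @param compound_id Identifier for the consensus compound.
#' @return A one-row tibble with list-columns for members and peaks.
#' @export
merge_cluster <- function(members, frag_bin_tol = 0.02,
                          compound_id = NULL) {
  if (nrow(members) == 0L) stop("empty cluster", call. = FALSE)
  w <- members$precursor_intensity
  if (all(w == 0)) w <- rep(1, nrow(members))
  pooled_mz <- unlist(purrr::map(members$peaks, ~ .x[, "mz"]))
  pooled_int <- unlist(purrr::map(members$peaks, ~ .x[, "intensity"]))
  picked <- bin_peaks(pooled_mz, pooled_int, tol = frag_bin_tol)
  charges <- unique(members$precursor_charge[members$precursor_charge > 0L])
  charge <- if (length(charges) == 1L) charges else if (length(charges) == 0L) 0L else {
    # conflicting member charges: majority vote, ties to the lowest charge
    tab <- sort(table(members$precursor_charge[members$precursor_charge > 0L]),
                decreasing = TRUE)
    as.integer(names(tab)[1])
  }
  apex <- which.max(members$precursor_intensity)
  tibble::tibble(
    compound_id = compound_id %||%
      paste0(members$run_id[1], ":c",
             if ("cluster" %in% names(members)) members$cluster[1] else 1L),
    run_id = members$run_id[1],
    member_scan_ids = list(members$scan_id),
    n_members = nrow(members),
    precursor_mz = sum(members$precursor_mz * w) / sum(w),
    charge = charge,
    rt_apex = members$rt[apex],
    rt_min = min(members$rt), rt_max = max(members$rt),
    inv_k0_center = if (all(is.na(members$inv_k0))) NA_real_ else
      sum(members$inv_k0 * w, na.rm = TRUE) / sum(w[!is.na(members$inv_k0)]),
    inv_k0_min = suppressWarnings(min(members$inv_k0, na.rm = TRUE)),
    inv_k0_max = suppressWarnings(max(members$inv_k0, na.rm = TRUE)),
    precursor_intensity = sum(members$precursor_intensity),
    peaks = list(picked)
  )
}

#' Group and merge a whole run into consensus spectra
#'
#' Convenience wrapper: [group_spectra()] then [merge_cluster()] per cluster.
#'
#' @inheritParams group_spectra
#' @inheritParams merge_cluster
#' @return A tibble of consensus spectra, one row per compound.
#' @export
merge_spectra <- function(records, tol_rt = 0.75, tol_mz = 0.015,
                          tol_im = 0.025, frag_bin_tol = 0.02) {
  grouped <- group_spectra(records, tol_rt, tol_mz, tol_im)
  if (nrow(grouped) == 0L) {
    return(merge_cluster(spectrum_records("r", "s", 1, 1, 0, 1,
                                          list(cbind(1, 1))))[0, ])
  }
  grouped |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_map(~ merge_cluster(.x, frag_bin_tol = frag_bin_tol,
                                     compound_id = paste0(.x$run_id[1], ":c", .y$cluster))) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$compound_id)
}

#' Infer charge from an isotope peak pattern
#'
#' Tries every charge in `z_range` and picks the one whose expected isotope
#' spacing (1.0033548 / z) best matches the observed adjacent peak spacings
#' by least mean absolute error; returns 0 (unknown) when even the best
#' charge misses by more than `tol`.
#'
#' @param isotope_peaks Matrix/data frame with columns mz, intensity, at
#'   least 2 rows.
#' @param z_range Candidate charges.
#' @param tol Maximum acceptable mean spacing error in Th.
#' @return An integer charge, 0 if undetermined.
#' @export
infer_charge <- function(isotope_peaks, z_range = 1:8, tol = 0.01) {
  pk <- as.matrix(as.data.frame(isotope_peaks))
  if (nrow(pk) < 2L) return(0L)
  spacings <- diff(sort(pk[, 1]))
  err <- vapply(z_range, function(z) {
    mean(abs(spacings - ISOTOPE_SPACING / z))
  }, numeric(1))
  best <- which.min(err)
  if (err[best] > tol) 0L else as.integer(z_range[best])
}

#' Write consensus spectra to an MGF peak list
#'
#' Standard Mascot generic format with one `BEGIN IONS` block per compound:
#' `PEPMASS` (m/z and precursor intensity), signed `CHARGE`, `RTINSECONDS`,
#' and a `TITLE` of the exact form
#' `compound=<id> run=<run id> 1/K0=<value to 4 decimals>` so the ion
#' mobility survives into downstream search results.
#'
#' @param consensus Tibble from [merge_spectra()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(consensus, path) {
  # accept raw spectrum records (e.g. from read_mgf) as well as consensus rows
  if (!"compound_id" %in% names(consensus) && "scan_id" %in% names(consensus)) {
    consensus <- dplyr::rename(consensus, compound_id = "scan_id",
                               rt_apex = "rt", inv_k0_center = "inv_k0",
                               charge = "precursor_charge")
  }
  lines <- character(0)
  fmt <- function(x) trimws(formatC(x, format = "fg", digits = 10))
  for (i in seq_len(nrow(consensus))) {
    r <- consensus[i, ]
    title <- sprintf("compound=%s run=%s 1/K0=%.4f",
                     r$compound_id, r$run_id,
                     if (is.na(r$inv_k0_center)) NA_real_ else r$inv_k0_center)
    if (is.na(r$inv_k0_center)) {
      title <- sprintf("compound=%s run=%s", r$compound_id, r$run_id)
    }
    block <- c(
      "BEGIN IONS",
      paste0("TITLE=", title),
      sprintf("PEPMASS=%s %s", fmt(r$precursor_mz), fmt(r$precursor_intensity)),
      if (r$charge > 0L) sprintf("CHARGE=%d+", r$charge),
      sprintf("RTINSECONDS=%s", fmt(r$rt_apex * 60)),
      {
        pk <- r$peaks[[1]]
        if (nrow(pk) > 0) sprintf("%s %s", fmt(pk[, "mz"]), fmt(pk[, "intensity"]))
      },
      "END IONS"
    )
    lines <- c(lines, block)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an MGF peak list
#'
#' Tolerant of unknown header keys. The ion mobility is taken from a
#' `1/K0=` token in the TITLE if present, else from a `1/K0=` header line;
#' records without either get `inv_k0 = NA` (mobility unknown). `PEPMASS`
#' may carry an intensity as a second token.
#'
#' @param path MGF file path.
#' @return A spectrum-record tibble (one row per `BEGIN IONS` block) with an
#'   extra `title` column.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  recs <- list()
  i <- 1L; n <- length(lines)
  in_block <- FALSE
  hdr <- list(); mzv <- numeric(0); intv <- numeric(0); begin_line <- 0L
  flush <- function(hdr, mzv, intv) {
    title <- hdr$TITLE %||% ""
    ik0 <- NA_real_
    m <- regmatches(title, regexpr("1/K0=[0-9.]+", title))
    if (length(m) == 1L) {
      ik0 <- as.numeric(sub("1/K0=", "", m))
    } else if (!is.null(hdr$`1/K0`)) {
      ik0 <- as.numeric(hdr$`1/K0`)
    }
    pep <- strsplit(trimws(hdr$PEPMASS %||% "0"), "[ \t]+")[[1]]
    charge <- 0L
    if (!is.null(hdr$CHARGE)) {
      charge <- as.integer(sub("[+-]$", "", trimws(hdr$CHARGE)))
      if (grepl("-$", trimws(hdr$CHARGE))) charge <- -charge
    }
    compound <- sub("^.*compound=([^ ]+).*$", "\\1", title)
    if (compound == title) compound <- title
    run <- sub("^.*run=([^ ]+).*$", "\\1", title)
    if (run == title) run <- ""
    tibble::tibble(
      run_id = run,
      scan_id = compound,
      title = title,
      precursor_mz = as.numeric(pep[1]),
      precursor_charge = charge,
      rt = as.numeric(hdr$RTINSECONDS %||% NA) / 60,
      inv_k0 = ik0,
      precursor_intensity = if (length(pep) >= 2L) as.numeric(pep[2]) else NA_real_,
      peaks = list({
        o <- order(mzv)
        cbind(mz = mzv[o], intensity = intv[o])
      })
    )
  }
  while (i <= n) {
    line <- trimws(lines[i])
    if (line == "BEGIN IONS") {
      if (in_block) stop("nested BEGIN IONS at line ", i, call. = FALSE)
      in_block <- TRUE; hdr <- list(); mzv <- numeric(0); intv <- numeric(0)
      begin_line <- i
    } else if (line == "END IONS") {
      if (!in_block) stop("END IONS without BEGIN IONS at line ", i, call. = FALSE)
      recs[[length(recs) + 1L]] <- flush(hdr, mzv, intv)
      in_block <- FALSE
    } else if (in_block && nzchar(line)) {
      if (grepl("=", line, fixed = TRUE)) {
        key <- sub("=.*$", "", line)
        hdr[[key]] <- sub("^[^=]*=", "", line)
      } else {
        tok <- strsplit(line, "[ \t]+")[[1]]
        mzv <- c(mzv, as.numeric(tok[1]))
        intv <- c(intv, if (length(tok) >= 2L) as.numeric(tok[2]) else 0)
      }
    }
    i <- i + 1L
  }
  if (in_block) {
    stop("BEGIN IONS at line ", begin_line, " never closed", call. = FALSE)
  }
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0L) {
    out <- spectrum_records(character(0), character(0), numeric(0), integer(0),
                            numeric(0), numeric(0), list())
    out$title <- character(0)
  }
  pi <- out$precursor_intensity
  out <- spectrum_records(out$run_id, out$scan_id, out$precursor_mz,
                          out$precursor_charge, out$rt, out$inv_k0, out$peaks,
                          precursor_intensity = pi)
  out$title <- if (length(recs)) purrr::map_chr(recs, "title") else character(0)
  out
}
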