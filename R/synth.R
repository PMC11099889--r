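# Seeded synthetic XL-MS studies with full ground truth: a tryptic digest of
# a synthetic test protein, DSBU cross-links and reversed-sequence decoys,
# per-run MS1 peak tables with Gaussian elution profiles, XSM tables with
# DDA-like stochastic sampling, spiked iRT standards, technical replicates
# and cross-linker-free negative controls. Everything is reproducible from
# one integer seed.

# run code with a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Synthetic test protein sequence
#'
#' A deterministic pseudo-random 300-residue sequence with tryptic-like K/R
#' frequency and a realistic share of S/T/Y linkable residues. This is a
#' synthetic stand-in for a real serum-albumin digest, used so the whole
#' pipeline is testable offline; it is not any real protein.
#'
#' @param length Sequence length.
#' @param seed RNG seed.
#' @return A single character string.
#' @export
synthetic_protein <- function(length = 300, seed = 42) {
  aa <- names(RESIDUE_MASS)
  # roughly vertebrate average composition, K/R slightly enriched
  freq <- c(G = 7, A = 8, S = 7, P = 5, V = 6, T = 5, C = 2, L = 9, I = 5,
            N = 4, D = 5, Q = 4, K = 7, E = 7, M = 2, H = 2, F = 4, R = 6,
            Y = 3, W = 1)
  with_seed(seed, {
    paste(sample(aa, length, replace = TRUE, prob = freq[aa]), collapse = "")
  })
}

#' In-silico tryptic digestion
#'
#' Fully specific cleavage C-terminal to every K and R (no proline
#' exception), all products with up to `missed_cleavages` internal K/R and
#' length inside `[min_len, max_len]`.
#'
#' @param protein Protein sequence string.
#' @param missed_cleavages Maximum internal K/R count.
#' @param min_len,max_len Peptide length bounds.
#' @return Tibble: `sequence`, `start`, `end` (1-based protein coordinates),
#'   `n_missed`, `is_nterm` (protein N-terminal peptide), ordered by start
#'   then length.
#' @export
digest <- function(protein, missed_cleavages = 3, min_len = 5, max_len = 50) {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (nchar(protein) == 0L) stop("empty protein sequence", call. = FALSE)
  residues <- strsplit(protein, "")[[1]]
  cut_after <- which(residues %in% c("K", "R"))
  # fully cleaved segment boundaries
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, length(residues))
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  n_seg <- length(starts)
  rows <- list()
  for (i in seq_len(n_seg)) {
    for (j in i:min(i + missed_cleavages, n_seg)) {
      s <- starts[i]; e <- ends[j]
      len <- e - s + 1L
      if (len < min_len || len > max_len) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sequence = substr(protein, s, e), start = s, end = e,
        n_missed = j - i, is_nterm = s == 1L
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(sequence = character(0), start = integer(0),
                          end = integer(0), n_missed = integer(0),
                          is_nterm = logical(0)))
  }
  dplyr::arrange(out, .data$start, .data$end)
}

# Linkable positions inside a digest peptide: reactive residues, excluding a
# C-terminal K (a linked lysine is not cleaved, so it must sit on a missed
# cleavage), plus position 1 of the protein N-terminal peptide.
linkable_positions <- function(pep_row, linker = dsbu_linker()) {
  residues <- strsplit(pep_row$sequence, "")[[1]]
  pos <- which(residues %in% linker$reactive_residues)
  n <- length(residues)
  pos <- pos[!(pos == n & residues[n] == "K")]
  if (linker$n_term && pep_row$is_nterm && !(1L %in% pos)) pos <- c(1L, pos)
  pos
}

#' Sample random cross-links from a digest
#'
#' Draws `n` distinct cross-links with both link sites uniform over the
#' linkable positions of randomly chosen peptide pairs.
#'
#' @param peptides Digest tibble from [digest()].
#' @param n Number of cross-links.
#' @param seed RNG seed.
#' @param linker An [linker_spec()].
#' @return Tibble: `peptide_a`, `peptide_b`, `pos_a`, `pos_b`, `site_a`,
#'   `site_b` (protein coordinates), with a-side <= b-side lexicographically.
#' @export
sample_crosslinks <- function(peptides, n, seed = 1, linker = dsbu_linker()) {
  stopifnot(n >= 1)
  cand <- peptides[purrr::map_int(seq_len(nrow(peptides)), function(i) {
    length(linkable_positions(peptides[i, ], linker))
  }) > 0L, ]
  if (nrow(cand) < 1L) {
    stop("no peptides with linkable residues for ", linker$name, call. = FALSE)
  }
  with_seed(seed, {
    seen <- character(0)
    rows <- list()
    guard <- 0L
    while (length(rows) < n) {
      guard <- guard + 1L
      if (guard > 1000L * n) {
        stop("not enough distinct linkable pairs", call. = FALSE)
      }
      ij <- sample(nrow(cand), 2L, replace = TRUE)
      pa <- cand[ij[1], ]; pb <- cand[ij[2], ]
      la <- linkable_positions(pa, linker); lb <- linkable_positions(pb, linker)
      posa <- la[sample.int(length(la), 1L)]
      posb <- lb[sample.int(length(lb), 1L)]
      id <- xl_identity(pa$sequence, pb$sequence, posa, posb)
      if (pa$sequence == pb$sequence && posa == posb) next
      if (id %in% seen) next
      seen <- c(seen, id)
      # canonical orientation: a-side lexicographically first
      if (paste0(pa$sequence, "@", posa) <= paste0(pb$sequence, "@", posb)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          peptide_a = pa$sequence, peptide_b = pb$sequence,
          pos_a = posa, pos_b = posb,
          site_a = pa$start + posa - 1L, site_b = pb$start + posb - 1L
        )
      } else {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          peptide_a = pb$sequence, peptide_b = pa$sequence,
          pos_a = posb, pos_b = posa,
          site_a = pb$start + posb - 1L, site_b = pa$start + posa - 1L
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

# Reverse a peptide keeping its C-terminal K/R anchor in place - the decoy
# construction used for the target-decoy competition.
reverse_keep_anchor <- function(sequence) {
  n <- nchar(sequence)
  if (n <= 2L) return(sequence)
  body <- substr(sequence, 1L, n - 1L)
  paste0(paste(rev(strsplit(body, "")[[1]]), collapse = ""),
         substr(sequence, n, n))
}

#' Default configuration of a synthetic study
#'
#' The defaults emulate the structure of the benchmark experiment the
#' workflow targets: four technical replicates at one collision-energy
#' profile plus one cross-linker-free negative control, DSBU cross-links of
#' a tryptic digest, per-precursor 1/K0, and iRT standards spiked into every
#' run.
#'
#' @param n_true_xl True cross-links planted in the sample replicates.
#' @param n_decoy Decoy (reversed-sequence) cross-links given XSMs.
#' @param n_replicates Sample replicate runs.
#' @param n_controls Negative-control runs.
#' @param n_contaminants True cross-links whose signal is also planted in the
#'   controls (must end up `rejected_control`).
#' @param p_xsm Per-run probability that a true cross-link receives an XSM
#'   (DDA sampling stochasticity).
#' @param mz_jitter_ppm Gaussian m/z jitter SD for MGF fragment peaks, in ppm.
#' @param ms1_jitter_ppm Per-scan MS1 m/z jitter SD in ppm (TOF-typical;
#'   small against the 10 ppm extraction window).
#' @param im_jitter_sd 1/K0 jitter SD in V s/cm^2.
#' @param rt_sigma Chromatographic peak SD in minutes.
#' @param scan_interval MS1 scan spacing in minutes.
#' @param target_score_mean,target_score_sd,decoy_score_mean,decoy_score_sd
#'   Score model (truncated at 0) for target and decoy XSMs.
#' @param n_noise_peaks Random matrix peaks per run.
#' @param protein_length,protein_seed Synthetic protein parameters.
#' @return A named list.
#' @export
study_config <- function(n_true_xl = 20, n_decoy = 20, n_replicates = 4,
                         n_controls = 1, n_contaminants = 2, p_xsm = 0.5,
                         mz_jitter_ppm = 5, ms1_jitter_ppm = 2,
                         im_jitter_sd = 0.005,
                         rt_sigma = 0.06, scan_interval = 0.05,
                         target_score_mean = 40, target_score_sd = 8,
                         decoy_score_mean = 18, decoy_score_sd = 6,
                         n_noise_peaks = 1000,
                         protein_length = 300, protein_seed = 42) {
  as.list(environment())
}

# Fixed reference table for the synthetic iRT standard set (10 peptide-like
# standards spanning the usual 0..100 scale).
irt_reference_standards <- function() {
  tibble::tibble(
    name = sprintf("SYNIRT%02d", 1:10),
    reference_irt = seq(0, 100, length.out = 10)
  )
}

# mobility model: 1/K0 as an affine function of m/z per charge state, inside
# the 0.73..1.60 V s/cm^2 TIMS range
model_inv_k0 <- function(mz, z) {
  pmin(pmax(0.45 + 0.05 * z + 0.5 * mz / 1000, 0.73), 1.60)
}

#' Generate a complete synthetic study
#'
#' Writes per-run merged MGF, MS1 peak tables (CSV: `rt_min, mz, intensity,
#' inv_k0`), XSM CSVs, per-run iRT standard observations, a run manifest and
#' a ground-truth JSON into `out_dir` (when given), and returns everything
#' in memory. True cross-link elution signal (first three isotopes, shared
#' Gaussian profile) is planted in every sample replicate; XSMs are drawn
#' per replicate with probability `p_xsm` (at least one run per true
#' cross-link so each is assessable); decoys receive XSMs from a shifted
#' score null and no MS1 signal; controls carry matrix peaks, iRT standards
#' and the planted contaminants only.
#'
#' @param config List from [study_config()].
#' @param seed Integer master seed.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return Invisible list: `truth` (cross-link table with per-run
#'   coordinates), `run_manifest`, `xsms` (unfiltered tibble),
#'   `ms1_sources` (named list of per-run peak tibbles), `standards`
#'   (long per-run observations), `irt_reference`, `consensus` (per-run MGF
#'   consensus tibbles), `config`, `seed`, `files`.
#' @export
generate_study <- function(config = study_config(), seed = 7, out_dir = NULL) {
  cfg <- utils::modifyList(study_config(), config)
  protein <- synthetic_protein(cfg$protein_length, cfg$protein_seed)
  peps <- digest(protein)
  with_seed(seed, {
    truth <- sample_crosslinks(peps, cfg$n_true_xl,
                               seed = sample.int(2^30, 1))
    # decoy cross-links: reversed-sequence peptides, flagged and attached to
    # a decoy accession
    decoy_pool <- peps
    decoy_pool$sequence <- vapply(peps$sequence, reverse_keep_anchor, "")
    decoys <- sample_crosslinks(decoy_pool, cfg$n_decoy,
                                seed = sample.int(2^30, 1))
    acc <- "SYNP01"
    truth$protein <- acc
    decoys$protein <- paste0("DECOY_", acc)

    # per-XL physical truth
    describe_xl <- function(df, prefix) {
      n <- nrow(df)
      df$xl_label <- sprintf("%s%02d", prefix, seq_len(n))
      df$z <- sample(3:4, n, replace = TRUE)
      df$mass <- vapply(seq_len(n), function(i) {
        crosslink_mass(crosslink(df$peptide_a[i], df$peptide_b[i],
                                 df$pos_a[i], df$pos_b[i]))
      }, numeric(1))
      df$mz <- precursor_mz(df$mass, df$z)
      df$true_irt <- stats::runif(n, 10, 90)
      df$inv_k0 <- model_inv_k0(df$mz, df$z)
      df$abundance <- stats::rlnorm(n, log(5000), 0.4)
      df
    }
    truth <- describe_xl(truth, "XL")
    decoys <- describe_xl(decoys, "DEC")
    truth$is_contaminant <- seq_len(nrow(truth)) <= cfg$n_contaminants

    # run manifest and per-run true RT calibrations (iRT = a * RT + b)
    runs <- tibble::tibble(
      run_id = c(sprintf("rep%d", seq_len(cfg$n_replicates)),
                 sprintf("ctrl%d", seq_len(cfg$n_controls))),
      is_control = c(rep(FALSE, cfg$n_replicates), rep(TRUE, cfg$n_controls)),
      replicate_group = c(rep("low_ce", cfg$n_replicates),
                          rep("control", cfg$n_controls)),
      cal_slope = stats::rnorm(cfg$n_replicates + cfg$n_controls, 5, 0.1),
      cal_intercept = stats::rnorm(cfg$n_replicates + cfg$n_controls, -50, 1)
    )
    ref <- irt_reference_standards()

    rt_of <- function(irt, run) {
      (irt - runs$cal_intercept[runs$run_id == run]) /
        runs$cal_slope[runs$run_id == run]
    }

    # iRT standard observations per run (small RT noise)
    standards <- tidyr::crossing(run_id = runs$run_id, ref) |>
      dplyr::rowwise() |>
      dplyr::mutate(observed_rt = rt_of(.data$reference_irt, .data$run_id) +
                      stats::rnorm(1, 0, 0.02)) |>
      dplyr::ungroup()

    isotope_ratio <- c(1, 0.85, 0.55)
    # one MS1 scan grid per run: every peak's RT lies on it, as on a real
    # instrument cycle
    rt_lo <- min((10 - runs$cal_intercept) / runs$cal_slope)
    rt_hi <- max((90 - runs$cal_intercept) / runs$cal_slope)
    scan_grid <- seq(rt_lo - 2, rt_hi + 2, by = cfg$scan_interval)
    plant_signal <- function(xl_row, run) {
      apex_rt <- rt_of(xl_row$true_irt, run) + stats::rnorm(1, 0, 0.03)
      grid <- scan_grid[abs(scan_grid - apex_rt) <= 4 * cfg$rt_sigma]
      purrr::map(0:2, function(k) {
        mzk <- isotope_mz(xl_row$mz, xl_row$z, k)
        tibble::tibble(
          rt_min = grid,
          mz = mzk * (1 + stats::rnorm(length(grid), 0, cfg$ms1_jitter_ppm * 1e-6)),
          intensity = xl_row$abundance * isotope_ratio[k + 1L] *
            exp(-(grid - apex_rt)^2 / (2 * cfg$rt_sigma^2)),
          inv_k0 = xl_row$inv_k0 + stats::rnorm(length(grid), 0, cfg$im_jitter_sd)
        )
      }) |>
        dplyr::bind_rows() |>
        dplyr::mutate(xl_label = xl_row$xl_label, apex_rt = apex_rt)
    }

    matrix_peaks <- function() {
      tibble::tibble(
        rt_min = sample(scan_grid, cfg$n_noise_peaks, replace = TRUE),
        mz = stats::runif(cfg$n_noise_peaks, 300, 1400),
        intensity = stats::rlnorm(cfg$n_noise_peaks, log(50), 0.6),
        inv_k0 = stats::runif(cfg$n_noise_peaks, 0.73, 1.60),
        xl_label = NA_character_, apex_rt = NA_real_
      )
    }

    ms1_sources <- list()
    apex_table <- list()
    for (run in runs$run_id) {
      is_ctrl <- runs$is_control[runs$run_id == run]
      planted <- if (is_ctrl) truth[truth$is_contaminant, , drop = FALSE] else truth
      sig <- purrr::map(seq_len(nrow(planted)),
                        function(i) plant_signal(planted[i, ], run)) |>
        dplyr::bind_rows()
      if (nrow(sig) > 0) {
        apex_table[[run]] <- sig |>
          dplyr::distinct(.data$xl_label, .data$apex_rt) |>
          dplyr::mutate(run_id = run)
      }
      src <- dplyr::bind_rows(sig, matrix_peaks()) |>
        dplyr::arrange(.data$rt_min)
      ms1_sources[[run]] <- src[, c("rt_min", "mz", "intensity", "inv_k0")]
    }
    apex_table <- dplyr::bind_rows(apex_table)

    # XSM sampling: true XLs get an XSM per replicate with prob p_xsm (at
    # least one run overall); decoys get one XSM in one random replicate
    draw_score <- function(n, mean, sd) pmax(stats::rnorm(n, mean, sd), 0)
    rep_runs <- runs$run_id[!runs$is_control]
    xsm_rows <- list()
    for (i in seq_len(nrow(truth))) {
      got <- stats::runif(length(rep_runs)) < cfg$p_xsm
      if (!any(got)) got[sample.int(length(rep_runs), 1L)] <- TRUE
      for (run in rep_runs[got]) {
        apx <- apex_table$apex_rt[apex_table$xl_label == truth$xl_label[i] &
                                    apex_table$run_id == run]
        xsm_rows[[length(xsm_rows) + 1L]] <- tibble::tibble(
          run_id = run, scan = paste0(run, ":", truth$xl_label[i]),
          peptide_a = truth$peptide_a[i], peptide_b = truth$peptide_b[i],
          pos_a = truth$pos_a[i], pos_b = truth$pos_b[i],
          protein_a = truth$protein[i], protein_b = truth$protein[i],
          site_a = truth$site_a[i], site_b = truth$site_b[i],
          score = draw_score(1, cfg$target_score_mean, cfg$target_score_sd),
          decoy = FALSE,
          mz = truth$mz[i] * (1 + stats::rnorm(1, 0, cfg$ms1_jitter_ppm * 1e-6)),
          z = truth$z[i],
          rt_min = apx + stats::rnorm(1, 0, 0.02),
          inv_k0 = truth$inv_k0[i] + stats::rnorm(1, 0, cfg$im_jitter_sd),
          xl_label = truth$xl_label[i]
        )
      }
    }
    for (i in seq_len(nrow(decoys))) {
      run <- sample(rep_runs, 1L)
      xsm_rows[[length(xsm_rows) + 1L]] <- tibble::tibble(
        run_id = run, scan = paste0(run, ":", decoys$xl_label[i]),
        peptide_a = decoys$peptide_a[i], peptide_b = decoys$peptide_b[i],
        pos_a = decoys$pos_a[i], pos_b = decoys$pos_b[i],
        protein_a = decoys$protein[i], protein_b = decoys$protein[i],
        site_a = decoys$site_a[i], site_b = decoys$site_b[i],
        score = draw_score(1, cfg$decoy_score_mean, cfg$decoy_score_sd),
        decoy = TRUE,
        mz = decoys$mz[i] * (1 + stats::rnorm(1, 0, cfg$ms1_jitter_ppm * 1e-6)),
        z = decoys$z[i],
        rt_min = rt_of(decoys$true_irt[i], run) + stats::rnorm(1, 0, 0.05),
        inv_k0 = decoys$inv_k0[i] + stats::rnorm(1, 0, cfg$im_jitter_sd),
        xl_label = decoys$xl_label[i]
      )
    }
    xsms <- dplyr::bind_rows(xsm_rows)

    # per-run consensus spectra for the identified compounds (theoretical
    # fragments with m/z jitter), exported as merged MGF
    consensus <- purrr::map(rep_runs, function(run) {
      sub <- xsms[xsms$run_id == run & !xsms$decoy, ]
      if (nrow(sub) == 0L) return(NULL)
      purrr::map(seq_len(nrow(sub)), function(j) {
        xl <- crosslink(sub$peptide_a[j], sub$peptide_b[j],
                        sub$pos_a[j], sub$pos_b[j])
        fr <- fragment_ions(xl, max_charge = 2L, series = c("b", "y"))
        fr <- fr[fr$mz < 1700, ]
        tibble::tibble(
          compound_id = sub$scan[j], run_id = run,
          member_scan_ids = list(sub$scan[j]), n_members = 1L,
          precursor_mz = sub$mz[j], charge = sub$z[j],
          rt_apex = sub$rt_min[j], rt_min = sub$rt_min[j],
          rt_max = sub$rt_min[j],
          inv_k0_center = sub$inv_k0[j],
          inv_k0_min = sub$inv_k0[j], inv_k0_max = sub$inv_k0[j],
          precursor_intensity = stats::rlnorm(1, log(1e4), 0.5),
          peaks = list(cbind(
            mz = sort(fr$mz * (1 + stats::rnorm(nrow(fr), 0,
                                                cfg$mz_jitter_ppm * 1e-6))),
            intensity = stats::rlnorm(nrow(fr), log(100), 1)
          ))
        )
      }) |> dplyr::bind_rows()
    })
    names(consensus) <- rep_runs
    consensus <- consensus[!purrr::map_lgl(consensus, is.null)]

    files <- character(0)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      w <- function(name) file.path(out_dir, name)
      for (run in names(ms1_sources)) {
        readr::write_csv(ms1_sources[[run]], w(paste0(run, ".ms1.csv")),
                         progress = FALSE)
        files <- c(files, w(paste0(run, ".ms1.csv")))
      }
      for (run in names(consensus)) {
        write_mgf(consensus[[run]], w(paste0(run, ".mgf")))
        files <- c(files, w(paste0(run, ".mgf")))
      }
      for (run in unique(xsms$run_id)) {
        readr::write_csv(dplyr::select(xsms[xsms$run_id == run, ],
                                       -"xl_label"),
                         w(paste0(run, ".xsms.csv")), progress = FALSE)
        files <- c(files, w(paste0(run, ".xsms.csv")))
      }
      readr::write_csv(standards, w("irt_standards.csv"), progress = FALSE)
      readr::write_csv(dplyr::select(runs, -"cal_slope", -"cal_intercept"),
                       w("run_manifest.csv"), progress = FALSE)
      write_fasta(stats::setNames(protein, acc), w("synthetic_protein.fasta"))
      jsonlite::write_json(
        list(seed = seed, config = cfg,
             truth = truth, decoys = decoys,
             calibrations = runs),
        w("truth.json"), auto_unbox = TRUE, digits = NA
      )
      files <- c(files, w("irt_standards.csv"), w("run_manifest.csv"),
                 w("synthetic_protein.fasta"), w("truth.json"))
    }

    invisible(list(
      protein = protein, truth = truth, decoys = decoys,
      run_manifest = runs[, c("run_id", "is_control", "replicate_group")],
      calibrations = runs, xsms = xsms, ms1_sources = ms1_sources,
      standards = standards, irt_reference = ref,
      consensus = consensus, config = cfg, seed = seed, files = files
    ))
  })
}
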