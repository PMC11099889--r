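# Study-level configuration and the staged pipeline:
# merge -> fdr -> imlib -> irt -> validate -> report.

#' Load and validate a study configuration
#'
#' YAML (or equivalent list) with a run manifest and workflow parameters.
#' Defaults: scan-merge tolerances 0.75 min / 0.015 Th / 0.025 V s/cm^2,
#' 10 ppm EIC extraction, global FDR 0.05, minimum score 15, DSBU linker.
#' All schema violations are reported at once; path fields are checked when
#' present (the FASTA is only required by the ProXL stage and is validated
#' lazily there).
#'
#' @param path YAML file path, or a list with the same structure.
#' @param base_dir Directory against which relative paths resolve; defaults
#'   to the YAML file's directory.
#' @return A validated `xl_config` list.
#' @export
load_study_config <- function(path, base_dir = NULL) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(base_dir)) {
    base_dir <- if (is.character(path)) dirname(path) else "."
  }
  defaults <- list(
    tolerances = list(rt = 0.75, mz = 0.015, im = 0.025, ppm = 10,
                      frag_bin = 0.02),
    fdr = list(alpha = 0.05, min_score = 15),
    validation = list(sn_threshold = 3, coelution_threshold = 0.8,
                      min_im_window = 0.05),
    linker = "DSBU",
    paths = list()
  )
  cfg <- utils::modifyList(defaults, cfg)
  errors <- character(0)
  if (is.null(cfg$runs) || length(cfg$runs) == 0L) {
    errors <- c(errors, "no runs defined")
  } else {
    labels <- purrr::map_chr(cfg$runs, ~ .x$label %||% NA_character_)
    if (anyNA(labels)) errors <- c(errors, "every run needs a label")
    dup <- labels[duplicated(labels)]
    if (length(dup)) {
      errors <- c(errors, paste0("duplicate run label: ",
                                 paste(unique(dup), collapse = ", ")))
    }
    for (r in cfg$runs) {
      for (f in c("mgf", "xsm", "ms1")) {
        if (!is.null(r[[f]])) {
          p <- file.path(base_dir, r[[f]])
          if (!file.exists(p)) {
            errors <- c(errors, paste0("run ", r$label %||% "?", ": missing ",
                                       f, " file ", r[[f]]))
          }
        }
      }
    }
  }
  tol <- unlist(cfg$tolerances)
  if (any(tol <= 0)) errors <- c(errors, "tolerances must be positive")
  if (cfg$fdr$alpha <= 0 || cfg$fdr$alpha > 1) {
    errors <- c(errors, "fdr alpha must be in (0, 1]")
  }
  if (!is.null(cfg$paths$standards) &&
      !file.exists(file.path(base_dir, cfg$paths$standards))) {
    errors <- c(errors, paste0("missing standards file ", cfg$paths$standards))
  }
  if (length(errors)) {
    stop("invalid study configuration:\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  }
  cfg$base_dir <- base_dir
  class(cfg) <- c("xl_config", "list")
  cfg
}

run_manifest_of <- function(config) {
  tibble::tibble(
    run_id = purrr::map_chr(config$runs, "label"),
    is_control = purrr::map_lgl(config$runs, ~ isTRUE(.x$control)),
    replicate_group = purrr::map_chr(config$runs,
                                     ~ .x$replicate_group %||% "default")
  )
}

log_stage <- function(records, out_dir, stage, detail) {
  message("[", stage, "] ", detail)
  rec <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              stage = stage, detail = detail)
  jsonl <- file.path(out_dir, "pipeline_log.jsonl")
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = jsonl, append = TRUE, sep = "")
  invisible(rec)
}

#' Run the staged analysis pipeline
#'
#' Executes the requested stages in dependency order
#' `merge -> fdr -> imlib -> irt -> validate -> report`, writing each
#' stage's outputs under `out_dir`. Re-runs skip stages whose outputs
#' already exist unless `force = TRUE`. A machine-readable JSONL log of
#' stages is appended alongside the outputs.
#'
#' @param config An `xl_config` from [load_study_config()].
#' @param steps Stages to run (dependencies must have run before or be
#'   included).
#' @param out_dir Output directory.
#' @param force Recompute even when outputs exist.
#' @return Invisible named list of the in-memory stage results.
#' @export
run_pipeline <- function(config,
                         steps = c("merge", "fdr", "imlib", "irt",
                                   "validate", "report"),
                         out_dir = file.path(config$base_dir, "out"),
                         force = FALSE) {
  stage_order <- c("merge", "fdr", "imlib", "irt", "validate", "report")
  steps <- stage_order[stage_order %in% steps]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- run_manifest_of(config)
  results <- list()
  bd <- config$base_dir
  outp <- function(name) file.path(out_dir, name)

  if ("merge" %in% steps) {
    for (r in config$runs) {
      if (is.null(r$mgf)) next
      dst <- outp(paste0(r$label, ".merged.mgf"))
      if (file.exists(dst) && !force) {
        log_stage(NULL, out_dir, "merge", paste0(r$label, ": up to date, skipped"))
        next
      }
      recs <- read_mgf(file.path(bd, r$mgf))
      recs$run_id <- r$label
      cons <- merge_spectra(recs, tol_rt = config$tolerances$rt,
                            tol_mz = config$tolerances$mz,
                            tol_im = config$tolerances$im,
                            frag_bin_tol = config$tolerances$frag_bin)
      write_mgf(cons, dst)
      log_stage(NULL, out_dir, "merge",
                paste0(r$label, ": ", nrow(recs), " scans -> ",
                       nrow(cons), " compounds"))
    }
  }

  filtered_path <- outp("xsms.filtered.csv")
  if ("fdr" %in% steps) {
    if (file.exists(filtered_path) && !force) {
      log_stage(NULL, out_dir, "fdr", "up to date, skipped")
    } else {
      paths <- purrr::map_chr(config$runs, ~ .x$xsm %||% NA_character_)
      paths <- file.path(bd, paths[!is.na(paths)])
      if (length(paths) == 0L) stop("fdr stage: no XSM inputs", call. = FALSE)
      xsms <- read_xsm_csv(paths)
      xsms <- assign_global_fdr(xsms)
      filtered <- filter_at_fdr(xsms, alpha = config$fdr$alpha,
                                min_score = config$fdr$min_score)
      readr::write_csv(filtered, filtered_path, progress = FALSE)
      log_stage(NULL, out_dir, "fdr",
                paste0(nrow(xsms), " XSMs -> ", nrow(filtered),
                       " targets at q<=", config$fdr$alpha))
    }
  }
  read_filtered <- function() {
    if (!file.exists(filtered_path)) {
      stop("validate/imlib stage: missing input ", filtered_path,
           "; run the fdr stage first", call. = FALSE)
    }
    readr::read_csv(filtered_path, show_col_types = FALSE, progress = FALSE)
  }

  if ("imlib" %in% steps) {
    dst <- outp("im_library.csv")
    if (file.exists(dst) && !force) {
      log_stage(NULL, out_dir, "imlib", "up to date, skipped")
    } else {
      lib <- build_mobility_library(
        read_filtered(), min_window = config$validation$min_im_window)
      write_skyline_im_csv(lib, dst)
      log_stage(NULL, out_dir, "imlib", paste0(nrow(lib), " library entries"))
    }
  }

  irt_models <- NULL
  if (any(c("irt", "validate", "report") %in% steps)) {
    if (is.null(config$paths$standards)) {
      stop("irt stage: no standards file configured", call. = FALSE)
    }
    standards <- readr::read_csv(file.path(bd, config$paths$standards),
                                 show_col_types = FALSE, progress = FALSE)
    irt_models <- standards |>
      dplyr::group_split(.data$run_id) |>
      purrr::map(~ fit_irt(.x, run_id = .x$run_id[1]))
    names(irt_models) <- purrr::map_chr(irt_models, "run_id")
    if ("irt" %in% steps) {
      models_df <- dplyr::bind_rows(purrr::map(irt_models, glance))
      readr::write_csv(models_df, outp("irt_models.csv"), progress = FALSE)
      log_stage(NULL, out_dir, "irt",
                paste0(nrow(models_df), " run calibrations fitted"))
    }
  }

  validation <- NULL
  if ("validate" %in% steps) {
    dst <- outp("validation_report.csv")
    filtered <- read_filtered()
    ms1 <- purrr::map(config$runs, function(r) {
      if (is.null(r$ms1)) return(NULL)
      readr::read_csv(file.path(bd, r$ms1), show_col_types = FALSE,
                      progress = FALSE)
    })
    names(ms1) <- purrr::map_chr(config$runs, "label")
    ms1 <- ms1[!purrr::map_lgl(ms1, is.null)]
    validation <- validate_study(
      filtered, manifest, ms1, irt_models,
      alpha = config$fdr$alpha, ppm = config$tolerances$ppm,
      sn_threshold = config$validation$sn_threshold,
      coelution_threshold = config$validation$coelution_threshold,
      min_window = config$validation$min_im_window
    )
    readr::write_csv(dplyr::select(validation, -"per_run"), dst,
                     progress = FALSE)
    log_stage(NULL, out_dir, "validate",
              paste0(sum(validation$verdict == "validated"), "/",
                     nrow(validation), " precursors validated"))
    results$validation <- validation
  }

  if ("report" %in% steps) {
    if (is.null(validation)) {
      dst <- outp("validation_report.csv")
      if (!file.exists(dst)) {
        stop("report stage: missing input ", dst,
             "; run the validate stage first", call. = FALSE)
      }
      validation <- readr::read_csv(dst, show_col_types = FALSE,
                                    progress = FALSE)
    }
    filtered <- read_filtered()
    rep <- build_report(validation, filtered, irt_models, manifest)
    for (nm in names(rep)) {
      if (is.data.frame(rep[[nm]])) {
        readr::write_csv(rep[[nm]], outp(paste0("report_", nm, ".csv")),
                         progress = FALSE)
      }
    }
    log_stage(NULL, out_dir, "report", "report tables written")
    results$report <- rep
  }

  results$irt_models <- irt_models
  invisible(results)
}
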