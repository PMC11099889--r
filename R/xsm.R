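# Cross-link spectrum match (XSM) tables: reading the documented CSV schema,
# merging runs, global target-decoy FDR, and ProXL XML export.

XSM_COLUMNS <- c("run_id", "scan", "peptide_a", "peptide_b", "pos_a", "pos_b",
                 "protein_a", "protein_b", "site_a", "site_b", "score",
                 "decoy", "mz", "z", "rt_min", "inv_k0")

# Charge-agnostic, order-invariant cross-link identity used for deduplication
# and library keys: the two (sequence, position) halves sorted lexicographically.
xl_identity <- function(peptide_a, peptide_b, pos_a, pos_b) {
  a <- paste0(peptide_a, "@", pos_a)
  b <- paste0(peptide_b, "@", pos_b)
  ifelse(a <= b, paste(a, b, sep = "--"), paste(b, a, sep = "--"))
}

#' Precursor key of an XSM table
#'
#' Cross-link identity (unordered pair of sequence@position) plus charge;
#' the unit that ion-mobility library entries and validation records track.
#'
#' @param xsms An XSM tibble.
#' @return Character vector of keys.
#' @export
precursor_key <- function(xsms) {
  paste0(xl_identity(xsms$peptide_a, xsms$peptide_b, xsms$pos_a, xsms$pos_b),
         "/", xsms$z)
}

#' Read a cross-link spectrum match CSV
#'
#' Expects the documented header: `run_id, scan, peptide_a, peptide_b, pos_a,
#' pos_b, protein_a, protein_b, site_a, site_b, score, decoy, mz, z, rt_min,
#' inv_k0`. The decoy flag accepts 0/1/true/false. Duplicate
#' (run, scan, cross-link) rows are dropped with a warning; unparsable rows
#' are skipped with a logged count.
#'
#' @param path CSV file path(s); multiple files are concatenated.
#' @return An XSM tibble of class `xl_xsm` with an attached `provenance`
#'   attribute listing source files.
#' @export
read_xsm_csv <- function(path) {
  sets <- purrr::map(path, function(p) {
    df <- suppressWarnings(
      readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
    )
    missing <- setdiff(XSM_COLUMNS, names(df))
    if (length(missing) > 0L) {
      stop("missing column: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    df <- dplyr::select(df, dplyr::all_of(XSM_COLUMNS))
    df$decoy <- tolower(as.character(df$decoy)) %in% c("1", "true")
    df$score <- suppressWarnings(as.numeric(df$score))
    df$z <- suppressWarnings(as.integer(df$z))
    bad <- !is.finite(df$score) | is.na(df$z) | df$z < 1L
    if (any(bad)) {
      warning(sum(bad), " unparsable row(s) skipped in ", p, call. = FALSE)
      df <- df[!bad, ]
    }
    as_xsm_set(df, provenance = p)
  })
  merge_xsm_sets(sets)
}

as_xsm_set <- function(df, provenance = character(0)) {
  df <- tibble::as_tibble(df)
  key <- paste(df$run_id, df$scan,
               xl_identity(df$peptide_a, df$peptide_b, df$pos_a, df$pos_b),
               sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate (run, scan, cross-link) row(s) dropped",
            call. = FALSE)
    df <- df[!dup, ]
  }
  attr(df, "provenance") <- provenance
  class(df) <- unique(c("xl_xsm", class(df)))
  df
}

#' Merge XSM sets from several searches into one
#'
#' Union with the duplicate rule of [read_xsm_csv()]; provenance is
#' concatenated. Typically applied to per-run or per-collision-energy search
#' results before the global FDR is estimated.
#'
#' @param sets List of XSM tibbles.
#' @return One merged XSM tibble.
#' @export
merge_xsm_sets <- function(sets) {
  if (length(sets) == 0L) stop("no input sets", call. = FALSE)
  prov <- unlist(purrr::map(sets, ~ attr(.x, "provenance") %||% character(0)))
  as_xsm_set(dplyr::bind_rows(sets), provenance = prov)
}

#' Assign global target-decoy q-values
#'
#' At every score threshold the FDR is estimated as
#' `#decoys above / #targets above` (1 when no targets remain); the q-value of
#' a record is the minimum estimated FDR over all thresholds at or below its
#' score, which makes q monotone non-increasing in score. Tied scores share
#' one threshold.
#'
#' @param xsms XSM tibble with a logical `decoy` column.
#' @return The tibble, sorted by descending score, with a `q_value` column.
#' @export
assign_global_fdr <- function(xsms) {
  if (nrow(xsms) == 0L) {
    xsms$q_value <- numeric(0)
    return(xsms)
  }
  if (!any(xsms$decoy)) {
    warning("no decoy records: q-values are all 0 and uncalibrated",
            call. = FALSE)
    xsms$q_value <- 0
    return(xsms[order(-xsms$score), ])
  }
  o <- order(-xsms$score)
  s <- xsms$score[o]
  d <- cumsum(xsms$decoy[o])
  t <- cumsum(!xsms$decoy[o])
  fdr <- ifelse(t == 0, 1, d / t)
  # tied scores share the threshold at the last tied record
  last_of_tie <- rev(!duplicated(rev(s)))
  fdr_at_threshold <- fdr
  fdr_at_threshold[!last_of_tie] <- NA_real_
  fdr_at_threshold <- rev(zoo_na_locf(rev(fdr_at_threshold)))
  q <- rev(cummin(rev(fdr_at_threshold)))
  out <- xsms[o, ]
  out$q_value <- pmin(q, 1)
  attr(out, "provenance") <- attr(xsms, "provenance")
  class(out) <- unique(c("xl_xsm", class(out)))
  out
}

# last-observation-carried-forward for the tie handling above
zoo_na_locf <- function(x) {
  idx <- cummax(ifelse(is.na(x), 0L, seq_along(x)))
  out <- x[idx]
  out[idx == 0L] <- NA_real_
  out
}

#' Filter XSMs at a global FDR and minimum score
#'
#' Keeps target records with `q_value <= alpha` and `score >= min_score`;
#' decoys are excluded from the output.
#'
#' @param xsms XSM tibble with q-values (see [assign_global_fdr()]).
#' @param alpha Global FDR level in (0, 1].
#' @param min_score Minimum search-engine score.
#' @return Filtered XSM tibble.
#' @export
filter_at_fdr <- function(xsms, alpha = 0.05, min_score = 15) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  if (!"q_value" %in% names(xsms)) {
    stop("q_values not assigned; run assign_global_fdr() first", call. = FALSE)
  }
  out <- dplyr::filter(xsms, !.data$decoy, .data$q_value <= alpha,
                       .data$score >= min_score)
  attr(out, "provenance") <- attr(xsms, "provenance")
  class(out) <- unique(c("xl_xsm", class(out)))
  out
}

#' Write filtered XSMs as ProXL XML
#'
#' Emits the ProXL import-schema subset bundled with the package: a linker
#' element with per-linkable-site specification, the search program and its
#' score declaration, one reported-peptide element per distinct cross-link,
#' and one PSM per XSM with scan reference and score. Protein accessions must
#' resolve in the FASTA and the stated link sites must agree with it.
#'
#' @param xsms Filtered target XSM tibble.
#' @param fasta_path FASTA with the searched protein sequences.
#' @param path Output XML path.
#' @param search_program Name reported as the search program.
#' @param linker An [linker_spec()]; default DSBU.
#' @return `path`, invisibly.
#' @export
write_proxl_xml <- function(xsms, fasta_path, path,
                            search_program = "xlpasef", linker = dsbu_linker()) {
  fasta <- read_fasta(fasta_path)
  accs <- unique(c(xsms$protein_a, xsms$protein_b))
  missing <- setdiff(accs, names(fasta))
  if (length(missing) > 0L) {
    stop("accession absent from FASTA: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  doc <- xml2::xml_new_root("proxl_input")
  xml2::xml_set_attr(doc, "fasta_filename", basename(fasta_path))
  linkers <- xml2::xml_add_child(doc, "linkers")
  lk <- xml2::xml_add_child(linkers, "linker", name = linker$name)
  sites <- c(linker$reactive_residues, if (linker$n_term) "nterm")
  for (s in sites) {
    xml2::xml_add_child(lk, "linkable_site", site = s)
  }
  sp <- xml2::xml_add_child(doc, "search_program", name = search_program)
  xml2::xml_add_child(sp, "score", name = "score", direction = "higher_is_better")
  rp_parent <- xml2::xml_add_child(doc, "reported_peptides")
  xsms$xl_id <- xl_identity(xsms$peptide_a, xsms$peptide_b,
                            xsms$pos_a, xsms$pos_b)
  for (id in unique(xsms$xl_id)) {
    grp <- xsms[xsms$xl_id == id, ]
    first <- grp[1, ]
    rp <- xml2::xml_add_child(rp_parent, "reported_peptide",
                              reported_peptide_string = id, type = "crosslink")
    for (side in c("a", "b")) {
      pep <- xml2::xml_add_child(
        rp, "peptide",
        sequence = first[[paste0("peptide_", side)]],
        linked_position = as.character(first[[paste0("pos_", side)]]),
        protein = first[[paste0("protein_", side)]],
        protein_position = as.character(first[[paste0("site_", side)]])
      )
    }
    psms <- xml2::xml_add_child(rp, "psms")
    for (j in seq_len(nrow(grp))) {
      xml2::xml_add_child(
        psms, "psm",
        scan_number = grp$scan[j],
        run = grp$run_id[j],
        precursor_charge = as.character(grp$z[j]),
        score = formatC(grp$score[j], format = "fg", digits = 10)
      )
    }
  }
  schema <- xml2::read_xml(system.file("extdata", "proxl-subset.xsd",
                                       package = "xlpasef"))
  ok <- xml2::xml_validate(doc, schema)
  if (!ok) {
    stop("ProXL XML failed schema validation: ",
         paste(attr(ok, "errors"), collapse = "; "), call. = FALSE)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read ProXL XML written by [write_proxl_xml()]
#'
#' Internal round-trip reader covering the bundled schema subset.
#'
#' @param path XML file path.
#' @return A tibble with one row per PSM (sequences, positions, proteins,
#'   charge, scan, run, score).
#' @export
read_proxl_xml <- function(path) {
  doc <- xml2::read_xml(path)
  rps <- xml2::xml_find_all(doc, ".//reported_peptide")
  rows <- purrr::map(rps, function(rp) {
    peps <- xml2::xml_find_all(rp, "./peptide")
    psms <- xml2::xml_find_all(rp, "./psms/psm")
    tibble::tibble(
      peptide_a = xml2::xml_attr(peps[[1]], "sequence"),
      peptide_b = xml2::xml_attr(peps[[2]], "sequence"),
      pos_a = as.integer(xml2::xml_attr(peps[[1]], "linked_position")),
      pos_b = as.integer(xml2::xml_attr(peps[[2]], "linked_position")),
      protein_a = xml2::xml_attr(peps[[1]], "protein"),
      protein_b = xml2::xml_attr(peps[[2]], "protein"),
      site_a = as.integer(xml2::xml_attr(peps[[1]], "protein_position")),
      site_b = as.integer(xml2::xml_attr(peps[[2]], "protein_position")),
      scan = xml2::xml_attr(psms, "scan_number"),
      run_id = xml2::xml_attr(psms, "run"),
      z = as.integer(xml2::xml_attr(psms, "precursor_charge")),
      score = as.numeric(xml2::xml_attr(psms, "score"))
    )
  })
  dplyr::bind_rows(rows)
}

# Minimal FASTA reader/writer (header word -> sequence).
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  id <- sub("^>([^ ]+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- tapply(ifelse(hdr, "", lines), grp, paste0, collapse = "")
  stats::setNames(toupper(as.character(seqs)), id)
}

write_fasta <- function(seqs, path) {
  lines <- unlist(purrr::imap(as.list(seqs), function(s, id) {
    c(paste0(">", id), gsub("(.{60})", "\\1\n", s) |> strsplit("\n") |> unlist())
  }))
  writeLines(lines, path)
  invisible(path)
}
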