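# Independent oracles used to cross-check package computations. These are
# deliberately separate, naive implementations: plain loops, their own
# constants, no calls into the code paths they verify.

# residue + atomic monoisotopic masses typed independently from standard
# reference tables (amino-acid residue = amino acid minus water)
ORACLE_RESIDUE <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
ORACLE_H2O <- 18.01056
ORACLE_PROTON <- 1.00728

oracle_peptide_mass <- function(seq) {
  m <- ORACLE_H2O
  for (ch in strsplit(seq, "")[[1]]) m <- m + ORACLE_RESIDUE[[ch]]
  m
}

# exhaustive fragment enumeration for a cross-linked pair: every a/b/y
# ordinal of both peptides, three linker states for link-spanning fragments,
# all charges; returns the expected row count and a sorted m/z multiset
oracle_fragment_enumeration <- function(seq_a, seq_b, pos_a, pos_b,
                                        max_charge,
                                        bu = 85.05276, buur = 111.03203) {
  co <- 12 + 15.99491
  out <- list()
  sides <- list(list(s = seq_a, pos = pos_a, partner = seq_b),
                list(s = seq_b, pos = pos_b, partner = seq_a))
  for (side in sides) {
    n <- nchar(side$s)
    for (ord in 1:(n - 1)) {
      for (series in c("a", "b", "y")) {
        if (series %in% c("a", "b")) {
          piece <- substr(side$s, 1, ord)
          base <- oracle_peptide_mass(piece) - ORACLE_H2O
          if (series == "a") base <- base - co
          spans <- side$pos <= ord
        } else {
          piece <- substr(side$s, n - ord + 1, n)
          base <- oracle_peptide_mass(piece)
          spans <- side$pos > n - ord
        }
        masses <- if (spans) {
          c(base + bu + buur + oracle_peptide_mass(side$partner),
            base + bu, base + buur)
        } else base
        for (m in masses) {
          for (z in 1:max_charge) {
            out[[length(out) + 1L]] <- (m + z * ORACLE_PROTON) / z
          }
        }
      }
    }
  }
  sort(unlist(out))
}

# brute-force restatement of the seeded greedy clustering rule
oracle_greedy_cluster <- function(df, tol_rt, tol_mz, tol_im) {
  assigned <- rep(NA_integer_, nrow(df))
  cid <- 0L
  repeat {
    open <- which(is.na(assigned))
    if (length(open) == 0L) break
    # highest precursor intensity, ties by m/z then scan_id
    o <- open[order(-df$precursor_intensity[open], df$precursor_mz[open],
                    df$scan_id[open])]
    seed <- o[1]
    cid <- cid + 1L
    for (i in open) {
      if (abs(df$precursor_mz[i] - df$precursor_mz[seed]) <= tol_mz &&
          abs(df$rt[i] - df$rt[seed]) <= tol_rt &&
          abs(df$inv_k0[i] - df$inv_k0[seed]) <= tol_im) {
        assigned[i] <- cid
      }
    }
  }
  assigned
}

# O(n^2) threshold-scan q-values: for each record, min over all score
# thresholds <= its score of decoys/targets at or above the threshold
oracle_qvalues <- function(score, decoy) {
  thresholds <- sort(unique(score))
  fdr_at <- vapply(thresholds, function(th) {
    d <- sum(decoy & score >= th)
    t <- sum(!decoy & score >= th)
    if (t == 0) 1 else d / t
  }, numeric(1))
  vapply(score, function(s) {
    min(1, min(fdr_at[thresholds <= s]))
  }, numeric(1))
}

# second, naive tryptic digester: enumerate all substrings, keep those whose
# boundaries are valid cleavage sites with a bounded internal K/R count
oracle_digest_count <- function(protein, missed = 3, min_len = 5,
                                max_len = 50) {
  res <- strsplit(protein, "")[[1]]
  n <- length(res)
  count <- 0L
  for (s in 1:n) {
    if (s > 1 && !(res[s - 1] %in% c("K", "R"))) next
    for (e in s:n) {
      if (e < n && !(res[e] %in% c("K", "R"))) next
      len <- e - s + 1
      if (len < min_len || len > max_len) next
      internal <- if (e > s) sum(res[s:(e - 1)] %in% c("K", "R")) else 0L
      if (internal <= missed) count <- count + 1L
    }
  }
  count
}

# per-element exclusive membership classification for UpSet counts
oracle_upset <- function(id_sets) {
  ids <- unique(unlist(id_sets))
  combos <- vapply(ids, function(id) {
    paste(names(id_sets)[vapply(id_sets, function(s) id %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  table(combos)
}

# small helper: build a spectrum-record tibble quickly in tests
quick_records <- function(mz, rt, im, intensity = NULL, run = "r1",
                          charge = 2L) {
  n <- length(mz)
  spectrum_records(
    run_id = rep(run, n), scan_id = sprintf("s%02d", seq_len(n)),
    precursor_mz = mz, precursor_charge = rep(charge, n), rt = rt,
    inv_k0 = im,
    peaks = replicate(n, cbind(mz = c(200, 300), intensity = c(10, 20)),
                      simplify = FALSE),
    precursor_intensity = intensity %||% rep(100, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
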