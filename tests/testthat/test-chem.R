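# DSBU chemistry: element masses, peptide and cross-link masses, isotopes,
# and the cleavable-linker fragment enumeration.

test_that("signature fragment compositions have the expected monoisotopic masses", {
  expect_equal(monoisotopic_mass("C4H7NO"), 85.05276, tolerance = 1e-7)
  expect_equal(monoisotopic_mass("C5H5NO2"), 111.03203, tolerance = 1e-7)
  expect_identical(monoisotopic_mass(""), 0)
  expect_error(monoisotopic_mass("C2Xx3"), "unknown element symbol: Xx")
})

test_that("composition mass is additive", {
  parts <- c("C4H7NO", "C5H5NO2", "H2O", "C6H12O6", "SO4")
  whole <- paste0(parts, collapse = "")
  expect_equal(monoisotopic_mass(whole),
               sum(vapply(parts, monoisotopic_mass, numeric(1))),
               tolerance = 1e-9)
})

test_that("DSBU cleavage fragments conserve the intact linker mass", {
  lk <- dsbu_linker()
  expect_equal(lk$fragment_a_mass + lk$fragment_b_mass, lk$intact_mass,
               tolerance = 1e-4)
  expect_setequal(lk$reactive_residues, c("K", "S", "T", "Y"))
  expect_true(lk$n_term)
  expect_error(
    linker_spec(intact_mass = 200),
    "mass conservation"
  )
})

test_that("peptide masses match an independent residue-table summation", {
  expect_equal(peptide_mass(peptide("KFWGK", fixed_mods = NULL)),
               664.36967, tolerance = 1e-4)
  expect_equal(peptide_mass(peptide("KQTALVELLK", fixed_mods = NULL)),
               1141.70704, tolerance = 1e-4)
  expect_equal(peptide_mass(peptide("G", fixed_mods = NULL)),
               57.02146 + 18.01056, tolerance = 1e-4)
  # fixed and variable modifications add their deltas
  expect_equal(peptide_mass(peptide("ACGK")),
               peptide_mass(peptide("ACGK", fixed_mods = NULL)) + 57.02146,
               tolerance = 1e-9)
  expect_equal(
    peptide_mass(peptide("AMGK", variable_mods = c("2" = 15.99491))),
    peptide_mass(peptide("AMGK")) + 15.99491,
    tolerance = 1e-9
  )
  expect_error(peptide("ABZ"), "unknown residue")
  expect_error(peptide("AMGK", variable_mods = c("9" = 15.99491)),
               "position outside")
})

test_that("cross-link mass is the two peptides plus the intact linker, symmetric", {
  xl <- crosslink(peptide("KQTALVELLK", fixed_mods = NULL),
                  peptide("KFWGK", fixed_mods = NULL), 1, 1)
  expect_equal(crosslink_mass(xl), 2002.16150, tolerance = 1e-3)
  lk <- dsbu_linker()
  expect_equal(crosslink_mass(xl),
               peptide_mass(xl$alpha) + peptide_mass(xl$beta) +
                 lk$fragment_a_mass + lk$fragment_b_mass,
               tolerance = 1e-9)
  swapped <- crosslink(peptide("KFWGK", fixed_mods = NULL),
                       peptide("KQTALVELLK", fixed_mods = NULL), 1, 1)
  expect_equal(crosslink_mass(swapped), crosslink_mass(xl))
  expect_error(crosslink("AGLV", "KFWGK", 2, 1), "not a reactive site")
})

test_that("precursor and isotope m/z follow the protonation conventions", {
  xl <- crosslink(peptide("KQTALVELLK", fixed_mods = NULL),
                  peptide("KFWGK", fixed_mods = NULL), 1, 1)
  mz3 <- precursor_mz(crosslink_mass(xl), 3)
  expect_equal(mz3, 668.39444, tolerance = 1e-3)
  expect_equal(precursor_mz(1000, 1), 1001.00728, tolerance = 1e-5)
  expect_equal(precursor_mz(1000, 2), 501.00728, tolerance = 1e-5)
  expect_error(precursor_mz(1000, 0), "positive integer")
  expect_equal(isotope_mz(668.39444, 3, 1), 668.72890, tolerance = 1e-4)
  expect_equal(isotope_mz(500, 2, 2), 501.00335, tolerance = 1e-4)
  expect_identical(isotope_mz(500, 2, 0), 500)
  # strictly decreasing in z, strictly increasing in k
  expect_true(all(diff(precursor_mz(2000, 1:6)) < 0))
  expect_true(all(diff(isotope_mz(668.39, 3, 0:5)) > 0))
})

test_that("fragments not spanning the link carry no linker; spanning ones come as a doublet plus intact", {
  xl <- crosslink(peptide("KFWGK", fixed_mods = NULL),
                  peptide("KQTALVELLK", fixed_mods = NULL), 1, 1)
  fr <- fragment_ions(xl, max_charge = 1)
  y4 <- fr[fr$source_peptide == "alpha" & fr$series == "y" & fr$ordinal == 4, ]
  expect_identical(y4$linker_state, "none")
  expect_equal(y4$mz, oracle_peptide_mass("FWGK") + 1.00728, tolerance = 1e-3)
  b2 <- fr[fr$source_peptide == "alpha" & fr$series == "b" & fr$ordinal == 2, ]
  expect_setequal(b2$linker_state, c("intact", "retains_Bu", "retains_BuUr"))
  bu <- b2$neutral_mass[b2$linker_state == "retains_Bu"]
  buur <- b2$neutral_mass[b2$linker_state == "retains_BuUr"]
  expect_equal(buur - bu, 111.03203 - 85.05276, tolerance = 1e-4)
})

test_that("b/y complementarity holds for every split of random peptides", {
  set.seed(11)
  aa <- c("G","A","S","P","V","T","L","N","D","Q","K","E","F","R","Y","W")
  for (rep in 1:10) {
    seq <- paste(c(sample(aa, sample(5:13, 1), replace = TRUE), "K"),
                 collapse = "")
    p <- peptide(seq, fixed_mods = NULL)
    sites <- which(strsplit(seq, "")[[1]] %in% c("K", "S", "T", "Y"))
    xl <- crosslink(peptide("GSGKGSG", fixed_mods = NULL), p, 4,
                    sites[sample.int(length(sites), 1)])
    fr <- fragment_ions(xl, max_charge = 1)
    beta <- fr[fr$source_peptide == "beta", ]
    lk <- xl$linker
    partner <- peptide_mass(xl$alpha)
    # bare neutral fragment mass with any linker contribution removed
    bare <- function(row) {
      switch(row$linker_state,
             none = row$neutral_mass,
             intact = row$neutral_mass - lk$intact_mass - partner,
             retains_Bu = row$neutral_mass - lk$fragment_a_mass,
             retains_BuUr = row$neutral_mass - lk$fragment_b_mass)
    }
    n <- nchar(seq)
    checked <- 0L
    for (i in seq_len(n - 1)) {
      b_i <- beta[beta$series == "b" & beta$ordinal == i, ][1, ]
      y_ni <- beta[beta$series == "y" & beta$ordinal == n - i, ][1, ]
      expect_equal(bare(b_i) + bare(y_ni), peptide_mass(p), tolerance = 1e-9)
      checked <- checked + 1L
    }
    expect_gt(checked, 0L)
  }
})

test_that("fragment enumeration matches the brute-force oracle for random pairs", {
  set.seed(42)
  aa <- c("G","A","S","P","V","T","L","N","D","Q","K","E","F","R","Y","W")
  for (rep in 1:50) {
    mk <- function() {
      repeat {
        s <- paste(sample(aa, sample(5:10, 1), replace = TRUE), collapse = "")
        pos <- which(strsplit(s, "")[[1]] %in% c("K", "S", "T", "Y"))
        if (length(pos) > 0) {
          return(list(s = s, pos = pos[sample.int(length(pos), 1)]))
        }
      }
    }
    a <- mk(); b <- mk()
    zmax <- sample(1:3, 1)
    fr <- fragment_ions(crosslink(peptide(a$s, fixed_mods = NULL),
                                  peptide(b$s, fixed_mods = NULL),
                                  a$pos, b$pos),
                        max_charge = zmax)
    oracle <- oracle_fragment_enumeration(a$s, b$s, a$pos, b$pos, zmax)
    expect_identical(nrow(fr), length(oracle))
    expect_equal(sort(fr$mz), oracle, tolerance = 1e-3)
  }
})

test_that("fragment set is invariant under alpha/beta swap up to relabeling", {
  xl1 <- crosslink(peptide("KFWGK", fixed_mods = NULL),
                   peptide("KQTALVELLK", fixed_mods = NULL), 1, 1)
  xl2 <- crosslink(peptide("KQTALVELLK", fixed_mods = NULL),
                   peptide("KFWGK", fixed_mods = NULL), 1, 1)
  f1 <- fragment_ions(xl1, 2)
  f2 <- fragment_ions(xl2, 2)
  expect_equal(sort(f1$mz), sort(f2$mz), tolerance = 1e-12)
})
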