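# EIC extraction, peak calling, verdict logic, UpSet accounting and
# match-between-runs.

flat_source <- function(rt = seq(9, 11, by = 0.05)) {
  tibble::tibble(rt_min = rt, mz = 400, intensity = 5, inv_k0 = 1.0)
}

planted_source <- function(mz0 = 668.3944, z = 3, apex = 10, sigma = 0.06,
                           height = 1000, rt = seq(9, 11, by = 0.05),
                           ratios = c(1, 0.8, 0.5), inv_k0 = 1.0) {
  sig <- purrr::map(0:2, function(k) {
    tibble::tibble(
      rt_min = rt,
      mz = isotope_mz(mz0, z, k),
      intensity = height * ratios[k + 1] * exp(-(rt - apex)^2 / (2 * sigma^2)),
      inv_k0 = inv_k0
    )
  })
  dplyr::bind_rows(sig)
}

test_that("EIC windows follow the ppm arithmetic and tolerate empty sources", {
  src <- planted_source()
  # acceptance half-window at 668.3944 Th and 10 ppm
  expect_equal(668.3944 * 10e-6, 0.006684, tolerance = 1e-4)
  hit <- extract_eic(src, 668.3944, 10, c(9, 11))
  expect_gt(sum(hit$intensity), 0)
  nothing <- extract_eic(flat_source(), 900, 10, c(9, 11))
  expect_true(all(nothing$intensity == 0))
  expect_identical(nrow(extract_eic(flat_source(), 400, 10, c(50, 60))), 0L)
  expect_error(extract_eic(src, 668.39, -1, c(9, 11)), "ppm")
})

test_that("a planted elution peak is fully recovered and extraction is linear", {
  src <- planted_source()
  e <- extract_eic(src, 668.3944, 10, c(9, 11))
  planted_total <- sum(src$intensity[abs(src$mz - 668.3944) < 0.01])
  expect_equal(sum(e$intensity), planted_total, tolerance = 1e-6)
  doubled <- src; doubled$intensity <- 2 * doubled$intensity
  e2 <- extract_eic(doubled, 668.3944, 10, c(9, 11))
  expect_equal(e2$intensity, 2 * e$intensity, tolerance = 1e-12)
  # mobility window excludes off-mobility peaks
  off <- extract_eic(src, 668.3944, 10, c(9, 11), im_center = 1.3,
                     im_halfwidth = 0.025)
  expect_true(all(off$intensity == 0))
})

test_that("peak calling detects a coeluting triplet and localises the apex", {
  src <- dplyr::bind_rows(planted_source(apex = 10), flat_source())
  eics <- purrr::map(0:2, function(k) {
    extract_eic(src, isotope_mz(668.3944, 3, k), 10, c(9, 11))
  })
  pk <- call_peak(eics)
  expect_true(pk$detected)
  expect_lte(abs(pk$apex_rt - 10), 0.05)          # within one grid step
  expect_gte(pk$coelution, 0.8)
  expect_gte(pk$sn, 3)
  expect_true(pk$rt_start <= pk$apex_rt && pk$apex_rt <= pk$rt_end)
})

test_that("peak calling rejects isotope-incoherent or empty signals", {
  # only the monoisotope has signal: coelution collapses
  rt <- seq(9, 11, by = 0.05)
  mono <- tibble::tibble(rt = rt,
                         intensity = 1000 * exp(-(rt - 10)^2 / (2 * 0.06^2)))
  noise1 <- tibble::tibble(rt = rt, intensity = abs(sin(rt * 40)) * 3)
  noise2 <- tibble::tibble(rt = rt, intensity = abs(cos(rt * 31)) * 3)
  pk <- call_peak(list(mono, noise1, noise2))
  expect_lt(pk$coelution, 0.8)
  expect_false(pk$detected)
  zero <- tibble::tibble(rt = rt, intensity = 0)
  expect_false(call_peak(list(zero, zero, zero))$detected)
})

test_that("verdict logic is the exact three-criterion conjunction with stated precedence", {
  for (fdr in c(TRUE, FALSE)) for (all_reps in c(TRUE, FALSE))
    for (ctrl in c(TRUE, FALSE)) {
      n_det <- if (all_reps) 4L else 2L
      v <- verdict_of(fdr, n_det, 4L, ctrl)
      if (!fdr) {
        expect_identical(v, "rejected_fdr")
      } else if (ctrl) {
        expect_identical(v, "rejected_control")
      } else if (all_reps) {
        expect_identical(v, "validated")
      } else {
        expect_identical(v, "rejected_replicates")
      }
    }
  expect_identical(verdict_of(TRUE, 0L, 4L, FALSE), "not_detected")
})

test_that("exclusive UpSet counts partition the union and match per-element brute force", {
  counts <- upset_counts(list(A = c("1", "2", "3"), B = c("2", "3", "4")))
  expect_identical(counts$count[counts$combination == "A"], 1L)
  expect_identical(counts$count[counts$combination == "B"], 1L)
  expect_identical(counts$count[counts$combination == "A&B"], 2L)
  expect_identical(sum(counts$count), 4L)
  same <- upset_counts(list(X = c("a", "b"), Y = c("a", "b")))
  expect_identical(same$combination, "X&Y")
  expect_identical(same$count, 2L)
  set.seed(17)
  for (rep in 1:5) {
    sets <- purrr::map(1:4, ~ as.character(sample(200, sample(20:80, 1))))
    names(sets) <- LETTERS[1:4]
    got <- upset_counts(sets)
    want <- oracle_upset(sets)
    expect_identical(sum(got$count), length(unique(unlist(sets))))
    for (i in seq_len(nrow(got))) {
      expect_identical(got$count[i],
                       as.integer(want[[got$combination[i]]]))
    }
  }
})

test_that("match-between-runs classifies transferred identifications", {
  per_run <- function(detected) {
    tibble::tibble(run_id = paste0("rep", 1:4), is_control = FALSE,
                   detected = detected, apex_rt = 10, sn = 10, coelution = 1)
  }
  validation <- tibble::tibble(
    precursor = c("p1", "p2"),
    q_value = 0.01, verdict = "validated", n_detected = 4L,
    n_replicates = 4L, control_detected = FALSE,
    per_run = list(per_run(rep(TRUE, 4)), per_run(rep(TRUE, 4)))
  )
  # p1 has an XSM in one run only; p2 in all four
  xs <- tibble::tibble(
    run_id = c("rep1", paste0("rep", 1:4)),
    scan = paste0("s", 1:5),
    peptide_a = c("AKGLSK", rep("GYLLVK", 4)),
    peptide_b = "TESTLK", pos_a = 2L, pos_b = 5L,
    protein_a = "P", protein_b = "P", site_a = 1L, site_b = 2L,
    score = 40, decoy = FALSE, mz = 800, z = 3L, rt_min = 10, inv_k0 = 1
  )
  keys <- unique(precursor_key(xs))
  validation$precursor <- c(keys[1], keys[2])
  got <- match_between_runs(validation, xs)
  p1 <- got$per_run[got$per_run$precursor == keys[1], ]
  expect_identical(sum(p1$status == "xsm_and_peak"), 1L)
  expect_identical(sum(p1$status == "peak_only"), 3L)
  p2 <- got$per_run[got$per_run$precursor == keys[2], ]
  expect_identical(sum(p2$status == "peak_only"), 0L)
  expect_equal(got$summary$frac_xsm_all_replicates, 0.5)
  expect_equal(got$summary$frac_recovered_by_transfer, 0.5)
})

test_that("planted cohort fractions are reported exactly", {
  # 40% of precursors carry XSMs in all replicates, 60% in one run only but
  # with peaks everywhere: the report must split them exactly
  set.seed(23)
  n_all <- 4; n_one <- 6
  peps <- c("AKGLSK", "GYLLVK", "SLYGGK", "PEPTKR", "TESTLK",
            "AYGGSK", "LLTTKK", "GSGKGS", "VVNPSK", "QQETLK")
  mk_xs <- function(pep, runs) {
    tibble::tibble(
      run_id = runs, scan = paste0(runs, ":", pep),
      peptide_a = pep, peptide_b = "WWDDLK", pos_a = 2L, pos_b = 5L,
      protein_a = "P", protein_b = "P", site_a = 1L, site_b = 2L,
      score = 40, decoy = FALSE, mz = 800, z = 3L, rt_min = 10, inv_k0 = 1
    )
  }
  xs <- dplyr::bind_rows(
    purrr::map(peps[1:n_all], ~ mk_xs(.x, paste0("rep", 1:4))),
    purrr::map(peps[n_all + 1:n_one], ~ mk_xs(.x, "rep2"))
  )
  validation <- tibble::tibble(
    precursor = unique(precursor_key(xs)),
    q_value = 0.01, verdict = "validated", n_detected = 4L,
    n_replicates = 4L, control_detected = FALSE,
    per_run = purrr::map(1:10, ~ tibble::tibble(
      run_id = paste0("rep", 1:4), is_control = FALSE, detected = TRUE,
      apex_rt = 10, sn = 10, coelution = 1
    ))
  )
  got <- match_between_runs(validation, xs)
  expect_equal(got$summary$frac_xsm_all_replicates, n_all / (n_all + n_one))
  expect_equal(got$summary$frac_recovered_by_transfer, n_one / (n_all + n_one))
})
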