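# Compound grouping and consensus-spectrum merging.

test_that("records inside the merge tolerances form one compound, outside split", {
  one <- group_spectra(quick_records(c(500.000, 500.010), c(10.0, 10.5),
                                     c(0.80, 0.81)))
  expect_identical(length(unique(one$cluster)), 1L)
  two <- group_spectra(quick_records(c(500.000, 500.010), c(10.0, 10.5),
                                     c(0.80, 0.90)))
  expect_identical(length(unique(two$cluster)), 2L)
  # degenerate: zero tolerances isolate every record
  iso <- group_spectra(quick_records(c(500, 500.001, 500.002), rep(10, 3),
                                     rep(0.8, 3)),
                       tol_rt = 0, tol_mz = 0, tol_im = 0)
  expect_identical(length(unique(iso$cluster)), 3L)
  expect_error(group_spectra(quick_records(500, 10, 0.8), tol_rt = -1),
               "non-negative")
})

test_that("clustering is a partition, order-invariant, and equals the brute-force oracle", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    recs <- quick_records(
      mz = 500 + sample(0:40, n, TRUE) * 0.005,
      rt = 10 + sample(0:8, n, TRUE) * 0.3,
      im = 0.8 + sample(0:6, n, TRUE) * 0.01,
      intensity = sample(50:500, n, TRUE)
    )
    grouped <- group_spectra(recs)
    expect_false(anyNA(grouped$cluster))                 # covers all records
    oracle <- oracle_greedy_cluster(recs, 0.75, 0.015, 0.025)
    expect_identical(grouped$cluster, oracle)
    # shuffling input leaves the induced partition unchanged
    perm <- sample(n)
    shuffled <- group_spectra(recs[perm, ])
    key <- function(cl, ids) {
      split(ids, cl) |> lapply(sort) |> (\(x) x[order(vapply(x, `[`, "", 1))])()
    }
    expect_identical(key(shuffled$cluster, shuffled$scan_id),
                     key(grouped$cluster, grouped$scan_id))
  }
})

test_that("order invariance holds over many shuffles of one instance", {
  set.seed(99)
  recs <- quick_records(
    mz = 500 + sample(0:20, 15, TRUE) * 0.01,
    rt = 10 + runif(15, 0, 2), im = 0.8 + runif(15, 0, 0.05),
    intensity = sample(10:500, 15)
  )
  ref <- group_spectra(recs)
  ref_sets <- split(ref$scan_id, ref$cluster) |> lapply(sort)
  ref_sets <- unname(ref_sets[order(vapply(ref_sets, `[`, "", 1))])
  for (i in 1:100) {
    sh <- group_spectra(recs[sample(nrow(recs)), ])
    sets <- split(sh$scan_id, sh$cluster) |> lapply(sort)
    sets <- unname(sets[order(vapply(sets, `[`, "", 1))])
    expect_identical(sets, ref_sets)
  }
})

test_that("consensus merging takes weighted means and conserves intensity", {
  recs <- spectrum_records(
    run_id = c("r", "r"), scan_id = c("s1", "s2"),
    precursor_mz = c(500.000, 500.004), precursor_charge = c(3L, 3L),
    rt = c(10, 10.2), inv_k0 = c(0.80, 0.82),
    peaks = list(cbind(mz = 300.000, intensity = 10),
                 cbind(mz = 300.010, intensity = 30)),
    precursor_intensity = c(100, 300)
  )
  cons <- merge_cluster(recs)
  expect_equal(cons$inv_k0_center, 0.815)                       # weighted mean
  expect_equal(cons$rt_apex, 10.2)              # highest-intensity member RT
  pk <- cons$peaks[[1]]
  expect_identical(nrow(pk), 1L)
  expect_equal(pk[1, "mz"], 300.0075, ignore_attr = TRUE)
  expect_equal(pk[1, "intensity"], 40, ignore_attr = TRUE)
  # intensity conservation against member total
  expect_equal(sum(pk[, "intensity"]),
               sum(vapply(recs$peaks, function(p) sum(p[, "intensity"]),
                          numeric(1))),
               tolerance = 1e-6)
  # single-member cluster passes peaks through unchanged
  single <- merge_cluster(recs[1, ])
  expect_equal(single$peaks[[1]][, "mz"], recs$peaks[[1]][, "mz"],
               ignore_attr = TRUE)
  expect_error(merge_cluster(recs[0, ]), "empty cluster")
})

test_that("charge inference recovers z from isotope spacings and refuses bad patterns", {
  expect_identical(infer_charge(cbind(c(668.3944, 668.7289, 669.0633),
                                      c(100, 80, 40))), 3L)
  expect_identical(infer_charge(cbind(c(500.0, 501.0034), c(10, 5))), 1L)
  expect_identical(infer_charge(cbind(c(500.0, 500.7), c(10, 5))), 0L)
  expect_identical(infer_charge(cbind(500.0, 10)), 0L)
})

test_that("MGF write/read round-trips and the second write is byte-identical", {
  recs <- quick_records(c(500.25, 612.5), c(10, 12), c(0.85, 1.02),
                        intensity = c(1000, 2000), charge = 3L)
  cons <- merge_spectra(recs, tol_mz = 0)
  f1 <- withr::local_tempfile(fileext = ".mgf")
  f2 <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(cons, f1)
  txt <- readLines(f1)
  expect_true(any(grepl("RTINSECONDS=600", txt)))
  expect_true(any(grepl("CHARGE=3\\+", txt)))
  expect_true(any(grepl("1/K0=0.8500", txt)))
  back <- read_mgf(f1)
  expect_equal(back$precursor_mz, cons$precursor_mz)
  expect_equal(back$rt, cons$rt_apex)
  expect_equal(back$inv_k0, round(cons$inv_k0_center, 4))
  write_mgf(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  # empty list gives a valid empty file
  f3 <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(cons[0, ], f3)
  expect_identical(nrow(read_mgf(f3)), 0L)
})

test_that("MGF dialect quirks are tolerated: missing mobility, PEPMASS intensity, bad nesting", {
  f <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=scan 1", "PEPMASS=500.1 12345",
               "CHARGE=2+", "RTINSECONDS=60", "100.5 10", "END IONS"), f)
  rec <- read_mgf(f)
  expect_true(is.na(rec$inv_k0))                     # mobility-unknown flag
  expect_equal(rec$precursor_mz, 500.1)
  expect_equal(rec$precursor_intensity, 12345)       # second token is intensity
  writeLines(c("BEGIN IONS", "TITLE=x", "BEGIN IONS", "END IONS"), f)
  expect_error(read_mgf(f), "line 3")
  writeLines(c("BEGIN IONS", "TITLE=x"), f)
  expect_error(read_mgf(f), "never closed")
})
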