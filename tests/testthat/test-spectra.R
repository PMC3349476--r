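make_1d <- function(shifts, mult = "unknown", intensity = 1) {
  data.frame(nucleus = "C13", shift_ppm = shifts, intensity = intensity,
             multiplicity = mult)
}

test_that("datasets validate nucleus windows and experiment names", {
  ds <- spectral_dataset(make_1d(c(18.3, 57.8), c("CH3", "CH2")))
  expect_s3_class(ds, "spectral_dataset")
  expect_error(spectral_dataset(make_1d(300)), "window")
  expect_error(
    spectral_dataset(correlations = data.frame(
      experiment = "HSQC", f1_ppm = 25, f2_ppm = 50)),
    "proton window")
  expect_error(
    spectral_dataset(correlations = data.frame(
      experiment = "XYZ", f1_ppm = 2, f2_ppm = 50)),
    "unknown experiment")
})

test_that("experiment aliases are normalized to canonical types", {
  ds <- spectral_dataset(correlations = data.frame(
    experiment = c("HSQC", "HETCOR", "HSQC-TOCSY", "HMBC", "COSY"),
    f1_ppm = c(2, 3, 4, 2, 2), f2_ppm = c(20, 30, 40, 120, 3)))
  expect_equal(ds$correlations$experiment,
               c("ONEBOND_CH", "ONEBOND_CH", "ONEBOND_CH", "LONGRANGE_CH",
                 "COSY_HH"))
})

test_that("peak tables round-trip through CSV and JSON", {
  ds <- simulate_dataset(mols$ethyl_acetate, simulation_config(seed = 5))
  pk <- tempfile(fileext = ".csv")
  co <- tempfile(fileext = ".csv")
  write_peak_tables(ds, pk, co)
  back <- read_peak_tables(c(pk, co))
  expect_equal(back$peaks$shift_ppm, ds$peaks$shift_ppm, tolerance = 1e-4)
  expect_equal(back$correlations$f1_ppm, ds$correlations$f1_ppm,
               tolerance = 1e-4)
  expect_equal(back$correlations$experiment, ds$correlations$experiment)

  js <- tempfile(fileext = ".json")
  write_peak_tables(ds, js, format = "json")
  back2 <- read_peak_tables(js, format = "json")
  expect_equal(back2$peaks$shift_ppm, ds$peaks$shift_ppm, tolerance = 1e-4)
  expect_equal(NROW(back2$correlations), NROW(ds$correlations))
})

test_that("a 13C-only table is readable and flagged for dereplication only", {
  p <- tempfile(fileext = ".csv")
  utils::write.csv(make_1d(c(20.1, 35.2, 77.0)), p, row.names = FALSE)
  ds <- read_peak_tables(p)
  expect_equal(sum(ds$peaks$nucleus == "C13"), 3L)
  expect_equal(NROW(ds$correlations), 0L)
  expect_true(c13_only(ds))
  out <- utils::capture.output(print(ds))
  expect_true(any(grepl("dereplication possible", out)))
})

test_that("malformed rows are rejected with their location", {
  p <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(nucleus = c("C13", "C13"),
                              shift_ppm = c(20, 300)), p, row.names = FALSE)
  expect_error(read_peak_tables(p), "row 2")
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(foo = 1), p2, row.names = FALSE)
  expect_error(read_peak_tables(p2), "neither")
})

test_that("consistency triage counts superfluous signals and unmatched 2D", {
  mf <- parse_formula("C20H28O2")
  # 25 distinct shifts for 20 carbons -> 5 superfluous
  ds <- spectral_dataset(make_1d(seq(10, 130, length.out = 25)))
  rep <- check_consistency(ds, mf)
  sup <- rep$issues[rep$issues$code == "superfluous_signals", ]
  expect_equal(sup$count, 5L)
  expect_equal(rep$purity_class, "average")

  ds2 <- spectral_dataset(make_1d(c(20, 30)), data.frame(
    experiment = "ONEBOND_CH", f1_ppm = 3.1, f2_ppm = 77.2))
  rep2 <- check_consistency(ds2, parse_formula("C2H6O"))
  expect_true("unmatched_correlation" %in% rep2$issues$code)

  # self-consistent simulated data: no issues, class good
  ds3 <- simulate_dataset(mols$toluene)
  rep3 <- check_consistency(ds3, mol_formula(mols$toluene))
  expect_equal(NROW(rep3$issues), 0L)
  expect_equal(rep3$purity_class, "good")
})

test_that("H-budget violations are reject-level", {
  ds <- spectral_dataset(make_1d(c(10, 20, 30), c("CH3", "CH3", "CH3")))
  rep <- check_consistency(ds, parse_formula("C3H4O"))
  expect_true(any(rep$issues$severity == "reject"))
  expect_error(build_mcd(parse_formula("C3H4O"), ds), "rejected")
})

test_that("purity class is monotone in the number of incidences", {
  mf <- parse_formula("C5H10O")
  classes <- c("good", "average", "poor", "bad")
  seen <- integer(0)
  for (extra in c(0, 6, 12, 22)) {
    ds <- spectral_dataset(make_1d(seq(10, 140, length.out = 5 + extra)))
    rep <- check_consistency(ds, mf)
    seen <- c(seen, match(rep$purity_class, classes))
  }
  expect_true(all(diff(seen) >= 0))
})
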