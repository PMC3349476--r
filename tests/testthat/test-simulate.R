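test_that("random molecules are valence-legal, connected and deterministic", {
  a <- random_molecule(8, seed = 7)
  b <- random_molecule(8, seed = 7)
  expect_identical(canonical_key(a), canonical_key(b))
  expect_identical(a$bonds, b$bonds)
  expect_identical(canonical_key(random_molecule(1, "C", 3)),
                   canonical_key(mol_graph("C", 4, NULL)))
  for (i in 1:200) {
    s <- random_molecule(4 + i %% 9, seed = 10000 + i)
    expect_silent(validate_mol_graph(s))
  }
})

test_that("noiseless full-coverage ethanol data matches hand enumeration", {
  ds <- simulate_dataset(mols$ethanol)
  cp <- ds$peaks[ds$peaks$nucleus == "C13", ]
  expect_equal(NROW(cp), 2L)
  expect_setequal(cp$multiplicity, c("CH3", "CH2"))
  ob <- ds$correlations[ds$correlations$experiment == "ONEBOND_CH", ]
  expect_equal(NROW(ob), 2L)
  # HMBC: CH3->CH2 (distance 1) and CH2->CH3 (distance 1); O carries the
  # exchangeable H and emits nothing
  hm <- ds$correlations[ds$correlations$experiment == "LONGRANGE_CH", ]
  expect_equal(NROW(hm), 2L)
  cosy <- ds$correlations[ds$correlations$experiment == "COSY_HH", ]
  expect_equal(NROW(cosy), 1L)
})

test_that("symmetric molecules collapse to one signal per orbit", {
  ds <- simulate_dataset(mols$benzene)
  cp <- ds$peaks[ds$peaks$nucleus == "C13", ]
  expect_equal(NROW(cp), 1L)
  expect_equal(cp$intensity, 6)
  sc <- c2_symmetric_scaffold()
  dsc <- simulate_dataset(sc)
  cpc <- dsc$peaks[dsc$peaks$nucleus == "C13", ]
  expect_equal(NROW(cpc), 10L)
  expect_true(all(cpc$intensity == 2))
})

test_that("coverage knobs control emitted correlations", {
  cfg0 <- simulation_config(hmbc_coverage = 0)
  ds <- simulate_dataset(mols$ethyl_acetate, cfg0)
  expect_equal(sum(ds$correlations$experiment == "LONGRANGE_CH"), 0L)
  cfg_nc <- simulation_config(cosy_coverage = 0)
  ds2 <- simulate_dataset(mols$ethyl_acetate, cfg_nc)
  expect_equal(sum(ds2$correlations$experiment == "COSY_HH"), 0L)
})

test_that("simulation is deterministic per seed and varies across seeds", {
  s <- mols$ethyl_acetate
  d1 <- simulate_dataset(s, simulation_config(noise_sigma = 1, seed = 5))
  d2 <- simulate_dataset(s, simulation_config(noise_sigma = 1, seed = 5))
  d3 <- simulate_dataset(s, simulation_config(noise_sigma = 1, seed = 6))
  expect_identical(d1$peaks, d2$peaks)
  expect_identical(d1$correlations, d2$correlations)
  expect_false(identical(d1$peaks$shift_ppm, d3$peaks$shift_ppm))
})

test_that("simulated shifts respect the MCD typing windows", {
  for (s in random_panel(25, sizes = 4:9, seed0 = 11000L)) {
    sh <- simulate_shifts(s)
    cls <- nmrcase:::.carbon_class(s)
    for (i in which(s$element == "C")) {
      if (cls[i] == "sp3") expect_lt(sh[i], 36)
      if (cls[i] == "carbonyl") expect_gte(sh[i], 160)
      if (cls[i] == "sp2") expect_lt(sh[i], 160)
    }
  }
})

test_that("nonstandard long-range correlations appear only when requested", {
  s <- mols$toluene  # has 4-bond H..C pairs across the ring
  ds_std <- simulate_dataset(s, simulation_config(seed = 3))
  ds_ns <- simulate_dataset(s, simulation_config(nonstandard_rate = 1,
                                                 seed = 3))
  n_std <- sum(ds_std$correlations$experiment == "LONGRANGE_CH")
  n_ns <- sum(ds_ns$correlations$experiment == "LONGRANGE_CH")
  expect_gt(n_ns, n_std)
  # with nonstandard data the MCD must be built with widened windows for
  # the truth to survive
  mcd <- build_mcd(mol_formula(s), ds_ns, options = list(nonstandard = TRUE))
  gen <- generate(mcd)
  expect_true(canonical_key(s) %in% names(gen$candidates))
})

test_that("round-trip recovers simple molecules at rank 1", {
  r <- round_trip(mols$ethanol)
  expect_true(r$recovered)
  expect_equal(r$rank, 1L)
  r2 <- round_trip(mols$acetone, simulation_config(seed = 2))
  expect_true(r2$recovered)
  expect_equal(r2$rank, 1L)
})

test_that("lower HMBC coverage cannot shrink the candidate space", {
  panel <- random_panel(6, sizes = 4:6, seed0 = 12000L)
  opts <- generation_options(max_structures = 1500L)
  med_n <- function(cov) {
    stats::median(vapply(seq_along(panel), function(i) {
      rt <- round_trip(panel[[i]],
                       simulation_config(hmbc_coverage = cov, seed = i),
                       options = opts)
      rt$n_candidates
    }, numeric(1)))
  }
  n_full <- med_n(1)
  n_half <- med_n(0.5)
  n_none <- med_n(0)
  expect_lte(n_full, n_half)
  expect_lte(n_half, n_none)
})
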