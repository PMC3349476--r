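test_that("hybridization windows follow the 13C interpretation rules", {
  expect_equal(assign_hybridization(15, 3), "sp3")
  expect_equal(assign_hybridization(128.5, 1), "sp2")
  expect_setequal(assign_hybridization(85, 0), c("sp3", "sp"))
  expect_setequal(assign_hybridization(100, 0), c("sp2", "sp"))
  expect_equal(assign_hybridization(175, 0), "sp2")
  expect_equal(assign_hybridization(-5, 2), "sp3")
  # never empty across the whole window
  for (s in seq(-20, 250, by = 2.5)) {
    expect_gt(length(assign_hybridization(s)), 0)
  }
})

test_that("ethanol-like input builds the expected skeleton", {
  ds <- spectral_dataset(
    data.frame(nucleus = "C13", shift_ppm = c(18.3, 57.8), intensity = 1,
               multiplicity = c("CH3", "CH2")),
    data.frame(experiment = "ONEBOND_CH", f1_ppm = c(1.2, 3.7),
               f2_ppm = c(18.3, 57.8)))
  mcd <- build_mcd(parse_formula("C2H6O"), ds)
  expect_equal(NROW(mcd$atoms), 3L)
  expect_equal(mcd$atoms$element, c("C", "C", "O"))
  expect_equal(mcd$exchangeable_h, 1L)
  expect_equal(mcd$hetero[1], "forbidden")   # CH3 at 18.3
  expect_equal(mcd$hetero[2], "undefined")   # CH2 at 57.8
  expect_equal(mcd$hyb[[1]], "sp3")
})

test_that("coincident shifts are expanded by symmetry multiplicities", {
  # benzene-like: one signal, six carbons
  ds <- spectral_dataset(
    data.frame(nucleus = "C13", shift_ppm = 128.4, intensity = 6,
               multiplicity = "CH"))
  expect_equal(detect_shift_symmetry(ds, parse_formula("C6H6")), 6L)
  # ten signals at near-equal intensity for twenty carbons
  ds2 <- spectral_dataset(
    data.frame(nucleus = "C13", shift_ppm = seq(20, 150, length.out = 10),
               intensity = 2, multiplicity = "C"))
  expect_equal(detect_shift_symmetry(ds2, parse_formula("C20H20Br2N4O2")),
               rep(2L, 10))
  # identity when counts agree
  ds3 <- spectral_dataset(
    data.frame(nucleus = "C13", shift_ppm = c(10, 20, 30, 40, 50),
               intensity = 1, multiplicity = "C"))
  expect_equal(detect_shift_symmetry(ds3, parse_formula("C5H12")), rep(1L, 5))
  # MCD duplicates the atoms
  sc <- c2_symmetric_scaffold()
  dsc <- simulate_dataset(sc)
  mcd <- build_mcd(mol_formula(sc), dsc)
  expect_equal(sum(mcd$atoms$element == "C"), 20L)
  expect_true(all(table(mcd$atoms$signal[mcd$atoms$element == "C"]) == 2L))
})

test_that("carbons cannot be typed without one-bond or multiplicity data", {
  ds <- spectral_dataset(
    data.frame(nucleus = "C13", shift_ppm = c(18.3, 57.8), intensity = 1,
               multiplicity = "unknown"))
  expect_error(build_mcd(parse_formula("C2H6O"), ds), "cannot type carbons")
})

test_that("COSY and HMBC become distance-window constraints", {
  ds <- spectral_dataset(
    data.frame(nucleus = "C13", shift_ppm = c(18.3, 57.8), intensity = 1,
               multiplicity = c("CH3", "CH2")),
    data.frame(experiment = c("ONEBOND_CH", "ONEBOND_CH", "COSY_HH",
                              "LONGRANGE_CH"),
               f1_ppm = c(1.2, 3.7, 1.2, 1.2),
               f2_ppm = c(18.3, 57.8, 3.7, 57.8)))
  mcd <- build_mcd(parse_formula("C2H6O"), ds)
  srcs <- vapply(mcd$constraints, `[[`, character(1), "source")
  expect_setequal(unique(srcs), c("COSY", "HMBC"))
  cosy <- mcd$constraints[[which(srcs == "COSY")[1]]]
  expect_equal(c(cosy$min_bonds, cosy$max_bonds), c(1L, 1L))
  expect_false(cosy$ambiguous)
  hmbc <- mcd$constraints[[which(srcs == "HMBC")[1]]]
  expect_equal(c(hmbc$min_bonds, hmbc$max_bonds), c(1L, 2L))
})

test_that("shift-coincident targets produce ambiguous candidate sets", {
  ds <- spectral_dataset(
    data.frame(nucleus = "C13", shift_ppm = c(18.0, 18.2, 120.0),
               intensity = 1, multiplicity = c("CH3", "CH3", "CH")),
    data.frame(experiment = c("ONEBOND_CH", "ONEBOND_CH", "ONEBOND_CH",
                              "LONGRANGE_CH"),
               f1_ppm = c(0.9, 1.4, 6.5, 6.5),
               f2_ppm = c(18.0, 18.2, 120.0, 18.1)))
  mcd <- build_mcd(parse_formula("C3H8"), ds)
  # HMBC target 18.1 matches both methyls within 0.5 ppm
  hm <- Filter(function(co) co$source == "HMBC", mcd$constraints)
  expect_equal(length(hm), 1L)
  expect_length(hm[[1]]$candidates, 2L)
  expect_true(hm[[1]]$ambiguous)
})

test_that("orphan correlations are reported, not dropped", {
  ds <- spectral_dataset(
    data.frame(nucleus = "C13", shift_ppm = c(18.3, 57.8), intensity = 1,
               multiplicity = c("CH3", "CH2")),
    data.frame(experiment = c("ONEBOND_CH", "LONGRANGE_CH"),
               f1_ppm = c(1.2, 9.9), f2_ppm = c(18.3, 57.8)))
  mcd <- build_mcd(parse_formula("C2H6O"), ds)
  expect_equal(length(mcd$orphans), 1L)
  expect_match(mcd$orphans[[1]]$reason, "proton matches no carbon")
})

test_that("simulated constraints are always satisfied by the source structure",
{
  # constraint soundness: noiseless simulated data never contradicts truth
  panel <- c(unname(mols), random_panel(25, sizes = 4:9, seed0 = 5000L))
  for (s in panel) {
    ds <- simulate_dataset(s, simulation_config(seed = 17))
    mcd <- build_mcd(mol_formula(s), ds)
    # re-index truth onto the MCD atom order via generation is unnecessary:
    # constraints are checked on the truth graph re-labelled by matching
    # shifts through the generator in the round-trip tests; here we check
    # the weaker direct property on structures whose atom order already
    # matches (simulate preserves atom indices only through shifts), so
    # instead assert that generation recovers the truth, which implies
    # every constraint admits it
    gen <- generate(mcd, generation_options(max_structures = 5000))
    expect_true(canonical_key(s) %in% names(gen$candidates),
                info = format(mol_formula(s)))
  }
})

test_that("widening tolerances never decreases ambiguous constraints", {
  ds <- simulate_dataset(mols$ethyl_acetate, simulation_config(seed = 2))
  mcd <- build_mcd(mol_formula(mols$ethyl_acetate), ds)
  n_amb <- function(tol_c) {
    cons <- constraints_from_correlations(ds, mcd, tol_c = tol_c)
    orph <- attr(cons, "orphans")
    disc <- sum(vapply(orph, function(o)
      grepl("ambiguous", o$reason), logical(1)))
    sum(vapply(cons, `[[`, logical(1), "ambiguous")) + disc
  }
  vals <- vapply(c(0.1, 0.5, 2, 8, 30), n_amb, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("hydrogen bookkeeping is conserved in the MCD", {
  for (s in random_panel(15, sizes = 4:8, seed0 = 6000L)) {
    ds <- simulate_dataset(s, simulation_config(seed = 3))
    mf <- mol_formula(s)
    mcd <- build_mcd(mf, ds)
    mult <- table(mcd$atoms$signal[mcd$atoms$element == "C"])
    h_on_c <- sum(mcd$atoms$attached_h[mcd$atoms$element == "C"])
    cnt <- unclass(mf)["H"]
    expect_equal(h_on_c + mcd$exchangeable_h, unname(cnt))
  }
})

test_that("MCD serializes to JSON and DOT", {
  ds <- simulate_dataset(mols$ethanol)
  mcd <- build_mcd(parse_formula("C2H6O"), ds)
  js <- mcd_to_json(mcd)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$formula, "C2H6O")
  expect_equal(NROW(parsed$atoms), 3L)
  dot <- mcd_to_dot(mcd)
  expect_match(dot, "graph mcd")
  expect_match(dot, "color=blue")  # sp3 carbons present
})
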