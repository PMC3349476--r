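test_that("unconstrained enumeration reproduces known isomer counts", {
  count <- function(f) length(generate(mcd_from_formula(parse_formula(f)))$candidates)
  expect_equal(count("CH4"), 1L)
  expect_equal(count("C2H6O"), 2L)   # ethanol, dimethyl ether
  expect_equal(count("C3H8O"), 3L)
  expect_equal(count("C4H10"), 2L)
  expect_equal(count("C2H6O"), length(oracle_enumerate_naive(parse_formula("C2H6O"))))
})

test_that("generation equals the naive enumerate-then-filter oracle", {
  for (f in c("C2H6O", "C3H8O", "C3H6O", "C2H7N", "C3H9N", "C4H8",
              "C2H4O2", "C3H4")) {
    mf <- parse_formula(f)
    expect_identical(generator_key_set(mf), oracle_enumerate_naive(mf),
                     label = f)
  }
})

test_that("generation equals a pair-major oracle at larger sizes", {
  for (f in c("C4H8O", "C5H12", "C5H8", "C4H5N", "C4H6O")) {
    mf <- parse_formula(f)
    expect_identical(generator_key_set(mf), oracle_enumerate_pairmajor(mf),
                     label = f)
  }
})

test_that("candidate structures always satisfy their own constraints", {
  for (s in random_panel(10, sizes = 4:7, seed0 = 7000L)) {
    ds <- simulate_dataset(s, simulation_config(seed = 23))
    mcd <- build_mcd(mol_formula(s), ds)
    gen <- generate(mcd)
    for (cand in gen$candidates) {
      expect_no_violations(cand, mcd)
    }
    # element counts and H totals match the formula
    for (cand in gen$candidates) {
      expect_identical(format(mol_formula(cand)), format(mol_formula(s)))
      expect_silent(validate_mol_graph(cand))
    }
  }
})

test_that("constraints only ever filter the unconstrained candidate set", {
  s <- mols$ethyl_acetate
  ds <- simulate_dataset(s, simulation_config(seed = 9))
  mf <- mol_formula(s)
  mcd_con <- build_mcd(mf, ds)
  free_keys <- generator_key_set(mf)
  con <- generate(mcd_con)
  expect_true(all(names(con$candidates) %in% free_keys))
  # the constrained set equals the unconstrained set filtered by
  # check_constraints (modulo atom typing, which fixes the H layout):
  # every unconstrained candidate passing all constraints under some
  # shift-compatible relabeling must be present; at minimum the truth is
  expect_true(canonical_key(s) %in% names(con$candidates))
})

test_that("explicit distance violations are detected", {
  # ethanol with a [1,1] constraint between the methyl carbon and oxygen:
  # true path length is 2, so exactly one violation
  eth <- mols$ethanol
  ds <- simulate_dataset(eth)
  mcd <- build_mcd(parse_formula("C2H6O"), ds)
  # identify the MCD methyl carbon (attached_h == 3) and the oxygen
  methyl <- which(mcd$atoms$attached_h == 3L)
  oxy <- which(mcd$atoms$element == "O")
  mcd$constraints <- list(nmrcase:::new_constraint(methyl, oxy, 1L, 1L,
                                                   "FRAGMENT"))
  # ethanol in MCD atom order: methyl must sit next to CH2, not O
  cand <- mol_graph(mcd$atoms$element, c(3, 2, 1),
                    data.frame(from = c(methyl, setdiff(1:3, c(methyl, oxy))),
                               to = c(setdiff(1:3, c(methyl, oxy)), oxy),
                               order = 1),
                    shift = mcd$atoms$shift)
  v <- check_constraints(cand, mcd)
  expect_equal(NROW(v), 1L)
  expect_match(v$detail, "outside \\[1,1\\]")
})

test_that("symmetry pruning changes work, never results", {
  forms <- c("C4H10", "C5H8", "C4H8O", "C3H9N")
  for (f in forms) {
    mf <- parse_formula(f)
    on_ <- generate(mcd_from_formula(mf), generation_options(use_symmetry = TRUE))
    off <- generate(mcd_from_formula(mf), generation_options(use_symmetry = FALSE))
    expect_setequal(names(on_$candidates), names(off$candidates))
    expect_lte(on_$counters$nodes, off$counters$nodes)
  }
})

test_that("orbit-swapped assignments satisfy assignment-aware constraints", {
  # p-xylene: swapping the two methyl carbons is an automorphism; the
  # swapped assignment must violate nothing
  s <- mols$p_xylene
  ds <- simulate_dataset(s, simulation_config(seed = 4))
  mcd <- build_mcd(mol_formula(s), ds)
  gen <- generate(mcd)
  expect_true(canonical_key(s) %in% names(gen$candidates))
  truth <- gen$candidates[[canonical_key(s)]]
  orb <- atom_orbits(truth)
  swap <- which(orb == orb[which(truth$element == "C" & truth$h == 3)[1]])
  s2 <- truth
  s2$shift[swap] <- truth$shift[rev(swap)]
  expect_no_violations(s2, mcd)
})

test_that("infeasible inputs fail fast with a reason", {
  expect_error(generate(mcd_from_formula(parse_formula("C2H7O"))),
               "free valence is odd")
})

test_that("caps return partial results with an abort status", {
  mf <- parse_formula("C6H6")
  res <- generate(mcd_from_formula(mf), generation_options(max_structures = 5))
  expect_equal(res$status, "aborted_cap")
  expect_equal(length(res$candidates), 5L)
  res2 <- generate(mcd_from_formula(mf),
                   generation_options(time_budget = 1e-6))
  expect_equal(res2$status, "aborted_time")
})

test_that("generation is deterministic", {
  mf <- parse_formula("C4H8O")
  a <- generate(mcd_from_formula(mf))
  b <- generate(mcd_from_formula(mf))
  expect_identical(names(a$candidates), names(b$candidates))
  expect_identical(a$counters, b$counters)
})

test_that("shift symmetry detection needs a consistent multiplicity split", {
  ds <- spectral_dataset(
    data.frame(nucleus = "C13", shift_ppm = c(10, 20, 30), intensity = 1,
               multiplicity = "C"))
  expect_error(detect_shift_symmetry(ds, parse_formula("C2H6")),
               "superfluous")
})
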