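test_that("every library record retrieves itself at rank 1 with score 0", {
  lib <- fixture_lib()
  for (r in lib) {
    res <- search_by_shifts(r$shifts, lib, tol = 2)
    expect_equal(res$id[1], r$id)
    expect_equal(res$score[1], 0)
    expect_equal(res$unmatched_query[1], 0L)
  }
})

test_that("perturbed queries stay matched with the right score", {
  lib <- fixture_lib()
  r <- lib[[1]]
  q <- r$shifts
  q[1] <- q[1] + 1.5
  res <- search_by_shifts(q, lib, tol = 2)
  expect_equal(res$id[1], r$id)
  expect_equal(res$score[1], 1.5 / length(q), tolerance = 1e-9)
  expect_equal(res$flagged_over_2ppm[1], 0L)
})

test_that("identity retrieval survives gaussian noise at sigma 0.5", {
  lib <- fixture_lib()
  set.seed(99)
  ok <- 0L
  for (r in lib) {
    q <- r$shifts + stats::rnorm(length(r$shifts), 0, 0.5)
    res <- search_by_shifts(q, lib, tol = 2)
    if (NROW(res) > 0L && res$id[1] == r$id) ok <- ok + 1L
  }
  expect_gte(ok / length(lib), 0.99)
})

test_that("queries matching nothing return an empty result", {
  lib <- fixture_lib()
  res <- search_by_shifts(c(240, 245, 248), lib, tol = 2)
  expect_equal(NROW(res), 0L)
})

test_that("formula and mass searches behave as exact filters", {
  lib <- fixture_lib()
  r <- lib[[3]]
  hits <- search_by_formula(r$mf, lib)
  expect_true(r$id %in% names(hits))
  hits2 <- search_by_mass(r$mass, 0, lib)
  expect_equal(names(hits2)[1], r$id)
  expect_equal(NROW(search_by_mass(9999.9, 0, lib)), 0L)
})

test_that("matching maximises pairs then minimises deviation", {
  m <- nmrcase:::match_shift_sets(c(10, 11), c(10.8, 12.9), tol = 2)
  expect_equal(m$matched, 2L)
  # optimal monotone pairing: 10-10.8 and 11-12.9 (cost 2.7), not crossing
  expect_equal(m$cost, 2.7, tolerance = 1e-9)
  m2 <- nmrcase:::match_shift_sets(c(10), c(10.5, 11.4), tol = 2)
  expect_equal(m2$matched, 1L)
  expect_equal(m2$cost, 0.5)
})

test_that("fragment hits require every fragment shift to match", {
  # fragments: toluene ring orbit shifts as a 'fragment', plus a decoy
  frag_ok <- mols$toluene
  frag_bad <- mols$toluene
  frag_bad$shift[7] <- 95  # move the methyl far away from any query shift
  flib <- build_library(list(ok = frag_ok, bad = frag_bad))
  q <- sort(unique(mols$toluene$shift))
  hits <- search_fragments(q, flib, tol = 0.5)
  expect_equal(hits$id, "ok")
  # nested fragments: larger first
  small <- mols$benzene
  flib2 <- build_library(list(small = small, big = frag_ok))
  hits2 <- search_fragments(c(q, 128.4), flib2, tol = 0.5)
  expect_equal(hits2$id[1], "big")
})

test_that("fragment hits convert to frozen bond constraints", {
  s <- mols$ethyl_acetate
  ds <- simulate_dataset(s, simulation_config(seed = 13))
  mcd <- build_mcd(mol_formula(s), ds)
  # fragment: the acetate half with shifts copied from the simulated peaks
  cpeaks <- ds$peaks[ds$peaks$nucleus == "C13", ]
  truth_in_mcd_order <- generate(mcd)$candidates[[canonical_key(s)]]
  frag <- truth_in_mcd_order
  n_before <- length(mcd$constraints)
  mcd2 <- fragment_to_constraints(frag, mcd, tol = 0.2)
  expect_gt(length(mcd2$constraints), n_before)
  added <- mcd2$constraints[(n_before + 1):length(mcd2$constraints)]
  expect_true(all(vapply(added, `[[`, character(1), "source") == "FRAGMENT"))
  # generation under the frozen fragment still contains the truth
  gen <- generate(mcd2)
  expect_true(canonical_key(s) %in% names(gen$candidates))
})

test_that("libraries round-trip through SDF with their index", {
  lib <- build_library(list(toluene = mols$toluene,
                            pyridine = mols$pyridine,
                            ethanol = mols$ethanol))
  path <- tempfile(fileext = ".sdf")
  write_library_sdf(lib, path)
  expect_true(file.exists(paste0(path, ".json")))
  lib2 <- read_library_sdf(path)
  expect_setequal(names(lib2), names(lib))
  for (nm in names(lib)) {
    expect_equal(lib2[[nm]]$shifts, lib[[nm]]$shifts, tolerance = 1e-4)
    expect_identical(canonical_key(lib2[[nm]]$structure),
                     canonical_key(lib[[nm]]$structure))
  }
})
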