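test_that("HOSE codes respect symmetry and distinguish environments", {
  hb <- nmrcase:::hose_codes(mols$benzene)
  expect_length(unique(hb), 1L)
  expect_false(hose_code(mols$ethanol, 1) == hose_code(mols$ethanol, 2))
  expect_error(hose_code(mols$ethanol, 3), "carbon")
})

test_that("HOSE codes are invariant under relabeling, per orbit", {
  set.seed(31)
  for (s in random_panel(12, sizes = 5:9, seed0 = 8000L)) {
    codes <- nmrcase:::hose_codes(s)
    n <- length(s$element)
    perm <- sample(n)
    inv <- order(perm)
    b <- s$bonds
    s2 <- mol_graph(s$element[inv], s$h[inv],
                    data.frame(from = perm[b$from], to = perm[b$to],
                               order = b$order), validate = FALSE)
    codes2 <- nmrcase:::hose_codes(s2)
    for (a in as.integer(names(codes))) {
      expect_identical(codes[[as.character(a)]],
                       codes2[[as.character(perm[a])]])
    }
    # orbit-equivalent atoms share codes
    orb <- atom_orbits(s)
    carb <- as.integer(names(codes))
    for (o in unique(orb[carb])) {
      expect_length(unique(codes[as.character(carb[orb[carb] == o])]), 1L)
    }
  }
})

test_that("sphere-k codes are literal prefixes of deeper codes", {
  for (s in list(mols$toluene, mols$ethyl_acetate, c2_symmetric_scaffold())) {
    for (a in which(s$element == "C")) {
      codes <- lapply(1:5, function(k) hose_code(s, a, k))
      for (k in 2:5) {
        expect_true(startsWith(codes[[k]], codes[[k - 1]]))
      }
    }
  }
})

test_that("prediction walks spheres outward-in and averages matches", {
  # two sphere-1 matches average to the prediction
  eth <- mols$ethanol
  db <- shift_db()
  code1 <- nmrcase:::hose_truncate(hose_code(eth, 1), 1)
  assign(nmrcase:::.db_key(1, code1),
         list(shift = c(20, 24), source = c("a", "b")), envir = db$map)
  p <- predict_c13(eth, db)
  i <- which(p$atom == 1)
  expect_equal(p$predicted[i], 22)
  expect_equal(p$sphere_used[i], 1L)
  expect_equal(p$n_matches[i], 2L)

  # empty db: fallback baselines, flagged
  p0 <- predict_c13(eth, shift_db())
  expect_true(all(p0$n_matches == 0L))
  expect_equal(p0$predicted[p0$atom == 1], 30)   # plain sp3
  expect_equal(p0$predicted[p0$atom == 2], 70)   # O-bound sp3
  pb <- predict_c13(mols$benzene, shift_db())
  expect_true(all(pb$predicted == 125))
  pa <- predict_c13(mols$acetone, shift_db())
  expect_equal(pa$predicted[pa$atom == 2], 175)  # carbonyl
})

test_that("self-prediction is exact and deeper spheres win the lookup", {
  for (s in random_panel(20, sizes = 4:9, seed0 = 9000L)) {
    s$shift <- simulate_shifts(s)
    db <- shift_db()
    db_insert_structure(db, s)
    p <- predict_c13(s, db)
    expect_equal(p$predicted, s$shift[p$atom], tolerance = 1e-12)
    expect_true(all(p$sphere_used == 4L))
    expect_true(all(p$n_matches >= 1L))
  }
})

test_that("mean absolute deviation handles fixed and free assignment", {
  expect_equal(mean_abs_deviation(c(1, 2, 3), c(1, 2, 3))$d13c, 0)
  expect_equal(mean_abs_deviation(c(10, 20), c(12, 18))$d13c, 2)
  expect_equal(mean_abs_deviation(c(10, 20), c(19, 11), "free")$d13c, 1)
  expect_error(mean_abs_deviation(1:3, 1:2), "length")
})

test_that("the true structure outranks decoys once its shifts are known", {
  for (i in 1:10) {
    s <- random_molecule(5 + (i %% 4), seed = 400 + i)
    s$shift <- simulate_shifts(s)
    db <- shift_db()
    db_insert_structure(db, s, source = "truth")
    # decoys: other generated isomers of the same formula carrying the
    # truth's experimental shifts
    gen <- generate(mcd_from_formula(mol_formula(s)),
                    generation_options(max_structures = 60))
    key <- canonical_key(s)
    cands <- gen$candidates
    exp_shifts <- sort(s$shift[!is.na(s$shift)])
    cands <- lapply(cands, function(cand) {
      carb <- which(cand$element == "C")
      cand$shift[carb] <- exp_shifts[seq_along(carb)]
      cand
    })
    if (!key %in% names(cands)) next
    rk <- rank_candidates(cands, db, true_key = key)
    expect_equal(rk$true_rank, 1L, info = paste("molecule", i))
    expect_lt(rk$table$d13c[1], 1e-9)
  }
})

test_that("ranking is a stable total order under permutation", {
  s <- mols$toluene
  db <- shift_db()
  db_insert_structure(db, s)
  gen <- generate(mcd_from_formula(mol_formula(s)),
                  generation_options(max_structures = 40))
  cands <- gen$candidates
  r1 <- rank_candidates(cands, db)
  set.seed(2)
  r2 <- rank_candidates(cands[sample(length(cands))], db)
  expect_identical(r1$table$key, r2$table$key)
  expect_equal(r1$table$d13c, r2$table$d13c)
})

test_that("shift database round-trips through its text format", {
  db <- shift_db()
  db_insert_structure(db, mols$toluene, source = "tol")
  db_insert_structure(db, mols$pyridine, source = "pyr")
  path <- tempfile(fileext = ".tsv")
  write_shift_db(db, path)
  db2 <- read_shift_db(path)
  p1 <- predict_c13(mols$toluene, db)
  p2 <- predict_c13(mols$toluene, db2)
  expect_equal(p1$predicted, p2$predicted)
  expect_equal(p1$sphere_used, p2$sphere_used)
})
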