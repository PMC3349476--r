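# Shared fixtures built in code at test time.

mols <- example_molecules()

# small deterministic panel of random molecules
random_panel <- function(n, sizes = 4:9, seed0 = 3000L,
                         pool = c("C", "N", "O")) {
  lapply(seq_len(n), function(i) {
    random_molecule(sizes[1 + (i - 1) %% length(sizes)], pool,
                    seed = seed0 + i)
  })
}

# fixture library shared across dereplication tests (built once)
fixture_lib <- local({
  lib <- NULL
  function() {
    if (is.null(lib)) lib <<- build_fixture_library(40L, seed = 60L)
    lib
  }
})

expect_no_violations <- function(structure, mcd) {
  v <- check_constraints(structure, mcd)
  expect_equal(NROW(v), 0L, info = paste(v$detail, collapse = " | "))
}
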