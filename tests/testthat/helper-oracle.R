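# Independent brute-force oracles for the structure generator.

# Fully naive oracle: every bond-order assignment over all atom pairs is
# materialised (base-4 grid), then filtered by exact valence, connectivity
# and canonical deduplication. Feasible up to ~5 heavy atoms.
oracle_enumerate_naive <- function(mf) {
  syms <- rep(names(mf), unclass(mf))
  el <- syms[syms != "H"]
  el <- el[order(match(el, c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I",
                             "Na")))]
  n <- length(el)
  v <- standard_valence(el)
  h_total <- sum(syms == "H")
  keys <- character(0)

  if (n == 1L) {
    if (h_total == v[1]) {
      keys <- canonical_key(mol_graph(el, h_total, NULL))
    }
    return(sort(unique(keys)))
  }
  pairs <- t(utils::combn(n, 2))
  p <- nrow(pairs)
  combos <- as.matrix(expand.grid(rep(list(0:3), p)))
  inc <- matrix(0L, p, n)
  for (k in seq_len(p)) inc[k, pairs[k, ]] <- 1L
  deg <- combos %*% inc

  # all H distributions
  hsets <- list()
  rec_h <- function(i, left, acc) {
    if (i > n) {
      if (left == 0L) hsets[[length(hsets) + 1L]] <<- acc
      return(invisible())
    }
    for (hh in 0:min(v[i], left)) rec_h(i + 1L, left - hh, c(acc, hh))
  }
  rec_h(1L, h_total, integer(0))

  for (h in hsets) {
    f <- v - h
    ok_rows <- which(apply(deg, 1, function(d) all(d == f)))
    for (r in ok_rows) {
      ords <- combos[r, ]
      sel <- ords > 0L
      if (!any(sel)) next
      bonds <- data.frame(from = pairs[sel, 1], to = pairs[sel, 2],
                          order = as.integer(ords[sel]))
      s <- mol_graph(el, h, bonds, validate = FALSE)
      if (!nmrcase:::is_connected_graph(s)) next
      keys <- c(keys, canonical_key(s))
    }
  }
  sort(unique(keys))
}

# Pair-major recursive oracle with only running-degree pruning: a second,
# structurally different enumeration used at sizes where the naive grid is
# too large.
oracle_enumerate_pairmajor <- function(mf) {
  syms <- rep(names(mf), unclass(mf))
  el <- syms[syms != "H"]
  el <- el[order(match(el, c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I",
                             "Na")))]
  n <- length(el)
  v <- standard_valence(el)
  h_total <- sum(syms == "H")
  keys <- new.env(parent = emptyenv())

  hsets <- list()
  rec_h <- function(i, left, acc) {
    if (i > n) {
      if (left == 0L) hsets[[length(hsets) + 1L]] <<- acc
      return(invisible())
    }
    for (hh in 0:min(v[i], left)) rec_h(i + 1L, left - hh, c(acc, hh))
  }
  rec_h(1L, h_total, integer(0))

  pairs <- if (n > 1L) t(utils::combn(n, 2)) else matrix(0L, 0, 2)
  # first pair index at which each atom's degree is already final
  # (lexicographic pair order: once the row index passes i, atom i gains
  # no further bonds)
  final_before <- integer(nrow(pairs))
  if (nrow(pairs) > 0L) {
    final_before <- pairs[, 1] - 1L
  }
  for (h in hsets) {
    f <- v - h
    if (sum(f) %% 2L != 0L) next
    ords <- integer(nrow(pairs))
    deg <- integer(n)
    rec_p <- function(k) {
      if (k <= nrow(pairs)) {
        fin <- final_before[k]
        if (fin > 0L && any(deg[seq_len(fin)] != f[seq_len(fin)])) {
          return(invisible())
        }
      }
      if (k > nrow(pairs)) {
        if (all(deg == f)) {
          sel <- ords > 0L
          if (n > 1L && !any(sel)) return(invisible())
          bonds <- if (any(sel)) {
            data.frame(from = pairs[sel, 1], to = pairs[sel, 2],
                       order = ords[sel])
          } else NULL
          s <- mol_graph(el, h, bonds, validate = FALSE)
          if (nmrcase:::is_connected_graph(s)) {
            assign(canonical_key(s), TRUE, envir = keys)
          }
        }
        return(invisible())
      }
      a <- pairs[k, 1]; b <- pairs[k, 2]
      for (o in 0:min(3L, f[a] - deg[a], f[b] - deg[b])) {
        ords[k] <<- o
        deg[a] <<- deg[a] + o
        deg[b] <<- deg[b] + o
        rec_p(k + 1L)
        deg[a] <<- deg[a] - o
        deg[b] <<- deg[b] - o
        ords[k] <<- 0L
      }
    }
    rec_p(1L)
  }
  sort(ls(keys))
}

generator_key_set <- function(mf) {
  res <- generate(mcd_from_formula(mf))
  expect_identical(res$status, "completed")
  sort(names(res$candidates))
}
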