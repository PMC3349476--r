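# Dereplication: pre-screening searches of 13C shift sets, molecular
# formulas and monoisotopic masses against structure and fragment libraries.
# The shift matcher solves the one-to-one matching exactly: because the
# cost is |delta shift| in one dimension, a maximum-cardinality
# minimum-cost matching always exists among monotone (non-crossing)
# pairings, found by dynamic programming over the two sorted shift lists.

#' Create a library record
#'
#' @param id Record identifier.
#' @param structure A `mol_graph` with per-atom 13C assignments.
#' @param shifts Optional explicit shift list; by default the distinct
#'   assigned carbon shifts (one per observed signal -- symmetry-equivalent
#'   carbons and carbons whose shifts coincide, as in a Kekule
#'   representation of an aromatic ring, collapse to one entry, exactly as
#'   in a recorded peak list).
#' @return Object of class `library_record`.
#' @export
library_record <- function(id, structure, shifts = NULL) {
  mf <- mol_formula(structure)
  if (is.null(shifts)) {
    carbons <- which(structure$element == "C")
    shifts <- unique(round(structure$shift[carbons], 6))
  }
  if (anyNA(shifts)) {
    stop("library record '", id, "' has unassigned carbon orbits",
         call. = FALSE)
  }
  rec <- list(id = id, structure = structure, mf = mf,
              mass = monoisotopic_mass(mf),
              shifts = sort(as.numeric(shifts)))
  class(rec) <- "library_record"
  rec
}

#' Build a structure library
#'
#' @param structures Named list of assigned `mol_graph` objects, or a list
#'   of `library_record`s.
#' @param ids Optional ids (defaults to names).
#' @return Object of class `structure_library` (list of records).
#' @export
build_library <- function(structures, ids = NULL) {
  if (length(structures) > 0L && inherits(structures[[1]], "library_record")) {
    recs <- structures
  } else {
    if (is.null(ids)) ids <- names(structures) %||% paste0("rec_", seq_along(structures))
    recs <- Map(library_record, ids, structures)
  }
  names(recs) <- vapply(recs, `[[`, character(1), "id")
  structure(recs, class = "structure_library")
}

#' @export
print.structure_library <- function(x, ...) {
  cat("<structure_library> ", length(x), " records\n", sep = "")
  invisible(x)
}

#' Write / read a structure library as SDF plus JSON index
#'
#' Structures go to `<path>` as SDF with assignment tags; a sidecar JSON
#' index (`<path>.json`) holds id, formula and monoisotopic mass.
#'
#' @param library A `structure_library`.
#' @param path SDF output path.
#' @rdname library_io
#' @export
write_library_sdf <- function(library, path) {
  write_structures_sdf(lapply(library, `[[`, "structure"), path,
                       ids = names(library))
  idx <- lapply(library, function(r)
    list(id = r$id, mf = format(r$mf), mass = r$mass))
  jsonlite::write_json(unname(idx), paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname library_io
#' @export
read_library_sdf <- function(path) {
  structures <- read_structures_sdf(path)
  build_library(structures)
}

# Exact maximum-cardinality, then minimum-total-|delta|, monotone matching
# of two sorted shift lists under a tolerance window. Returns matched
# count, total cost and the matched deviations.
match_shift_sets <- function(query, ref, tol) {
  a <- sort(query)
  b <- sort(ref)
  n <- length(a)
  m <- length(b)
  if (n == 0L || m == 0L) {
    return(list(matched = 0L, cost = 0, deviations = numeric(0)))
  }
  # dp over prefixes: maximise matched, minimise cost
  M <- matrix(0L, n + 1L, m + 1L)
  Co <- matrix(0, n + 1L, m + 1L)
  Ch <- matrix(0L, n + 1L, m + 1L)  # 1 skip a, 2 skip b, 3 match
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      best_m <- M[i, j + 1L]; best_c <- Co[i, j + 1L]; ch <- 1L
      if (M[i + 1L, j] > best_m ||
          (M[i + 1L, j] == best_m && Co[i + 1L, j] < best_c)) {
        best_m <- M[i + 1L, j]; best_c <- Co[i + 1L, j]; ch <- 2L
      }
      d <- abs(a[i] - b[j])
      if (d <= tol) {
        mm <- M[i, j] + 1L
        cc <- Co[i, j] + d
        if (mm > best_m || (mm == best_m && cc < best_c)) {
          best_m <- mm; best_c <- cc; ch <- 3L
        }
      }
      M[i + 1L, j + 1L] <- best_m
      Co[i + 1L, j + 1L] <- best_c
      Ch[i + 1L, j + 1L] <- ch
    }
  }
  devs <- numeric(0)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    ch <- Ch[i + 1L, j + 1L]
    if (ch == 3L) {
      devs <- c(devs, abs(a[i] - b[j]))
      i <- i - 1L; j <- j - 1L
    } else if (ch == 1L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(matched = M[n + 1L, m + 1L], cost = Co[n + 1L, m + 1L],
       deviations = devs)
}

#' Search a library by 13C shifts
#'
#' Matches the query shift set one-to-one against every record's per-orbit
#' shifts within the tolerance (exact maximum matching, then minimum mean
#' absolute deviation). Records matching fewer than `min_match_fraction`
#' of the query shifts are dropped. Results are sorted by total unmatched
#' count (ascending), then score, then id. Matched pairs deviating by more
#' than 2 ppm are counted in `flagged_over_2ppm`, mirroring the red-flag
#' highlighting convention for library hits.
#'
#' @param query Numeric vector of 13C shifts (ppm).
#' @param library A `structure_library`.
#' @param tol Matching tolerance in ppm (default 2).
#' @param min_match_fraction Minimum fraction of query shifts that must
#'   match (default 0.9).
#' @return Data frame of class `match_results`: id, score (mean matched
#'   |delta|, ppm), matched, unmatched_query, unmatched_record,
#'   flagged_over_2ppm.
#' @export
search_by_shifts <- function(query, library, tol = 2, min_match_fraction = 0.9) {
  stopifnot(length(query) > 0L, tol > 0)
  rows <- lapply(library, function(r) {
    m <- match_shift_sets(query, r$shifts, tol)
    data.frame(id = r$id,
               score = if (m$matched > 0L) m$cost / m$matched else 0,
               matched = m$matched,
               unmatched_query = length(query) - m$matched,
               unmatched_record = length(r$shifts) - m$matched,
               flagged_over_2ppm = sum(m$deviations > 2),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(res)) res <- data.frame(id = character(0), score = numeric(0),
                                      matched = integer(0),
                                      unmatched_query = integer(0),
                                      unmatched_record = integer(0),
                                      flagged_over_2ppm = integer(0))
  res <- res[res$matched >= min_match_fraction * length(query), , drop = FALSE]
  res <- res[order(res$unmatched_query + res$unmatched_record, res$score,
                   res$id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("match_results", "data.frame")
  res
}

#' Search a library by molecular formula or monoisotopic mass
#'
#' @param mf A `molecular_formula` (exact equality).
#' @param library A `structure_library`.
#' @return The matching records (a `structure_library`), sorted by id for
#'   formula search and by absolute mass error for mass search.
#' @rdname search_by_formula
#' @export
search_by_formula <- function(mf, library) {
  key <- format(mf)
  hits <- Filter(function(r) format(r$mf) == key, library)
  hits <- hits[order(vapply(hits, `[[`, character(1), "id"))]
  structure(hits, class = "structure_library")
}

#' @param mass Query monoisotopic mass (Da).
#' @param tol Mass tolerance in Da (0 demands exact equality).
#' @rdname search_by_formula
#' @export
search_by_mass <- function(mass, tol, library) {
  err <- vapply(library, function(r) abs(r$mass - mass), numeric(1))
  hits <- library[err <= tol]
  hits <- hits[order(err[err <= tol],
                     vapply(hits, `[[`, character(1), "id"))]
  structure(hits, class = "structure_library")
}

#' Search a fragment library by 13C shifts
#'
#' A fragment hits when every one of its assigned shifts matches a
#' distinct query shift within the tolerance. Hits are ranked by fragment
#' size (descending), then score; each hit can be exported as
#' fixed-substructure constraints for the generator via
#' [fragment_to_constraints()].
#'
#' @param query Numeric vector of 13C shifts.
#' @param fragment_library A `structure_library` of fragments with
#'   assigned shifts.
#' @param tol Tolerance in ppm (default 2).
#' @return Data frame: id, size, score.
#' @export
search_fragments <- function(query, fragment_library, tol = 2) {
  rows <- lapply(fragment_library, function(r) {
    m <- match_shift_sets(query, r$shifts, tol)
    if (m$matched < length(r$shifts)) return(NULL)
    data.frame(id = r$id, size = length(r$shifts),
               score = if (m$matched > 0L) m$cost / m$matched else 0,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  res <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
    else data.frame(id = character(0), size = integer(0), score = numeric(0))
  res <- res[order(-res$size, res$score, res$id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Convert a fragment hit into MCD fragment constraints
#'
#' Maps each assigned fragment carbon to the MCD atoms whose shift lies
#' within the tolerance, then freezes every carbon-carbon fragment bond as
#' a window-\[1,1\] constraint. Bonds whose two endpoints both map
#' ambiguously are skipped (overlapping/unresolvable fragment placements
#' are rejected rather than merged).
#'
#' @param fragment A `mol_graph` with assigned shifts.
#' @param mcd The target `mcd`.
#' @param tol Shift matching tolerance in ppm (default 0.5).
#' @return The updated `mcd` with added FRAGMENT constraints.
#' @export
fragment_to_constraints <- function(fragment, mcd, tol = 0.5) {
  fmap <- lapply(seq_along(fragment$element), function(i) {
    if (fragment$element[i] != "C" || is.na(fragment$shift[i])) return(integer(0))
    which(mcd$atoms$element == "C" &
            abs(mcd$atoms$shift - fragment$shift[i]) <= tol)
  })
  b <- fragment$bonds
  for (k in seq_len(NROW(b))) {
    fa <- fmap[[b$from[k]]]
    ta <- fmap[[b$to[k]]]
    if (length(fa) == 0L || length(ta) == 0L) next
    if (length(fa) == 1L) {
      mcd$constraints[[length(mcd$constraints) + 1L]] <-
        new_constraint(fa, ta, 1L, 1L, "FRAGMENT")
    } else if (length(ta) == 1L) {
      mcd$constraints[[length(mcd$constraints) + 1L]] <-
        new_constraint(ta, fa, 1L, 1L, "FRAGMENT")
    }
  }
  mcd
}
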