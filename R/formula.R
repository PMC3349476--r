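# Molecular formula arithmetic: parsing, Hill serialization, RDBE, masses,
# and exhaustive formula search from a monoisotopic mass.

# Element table. Standard valences are the closed-shell defaults used by the
# structure generator (no hypervalent S/P unless explicitly extended there).
# Average weights: 2021 IUPAC standard atomic weights (conventional values for
# interval elements); monoisotopic: mass of the most abundant isotope.
.element_table <- data.frame(
  symbol  = c("C", "H", "N", "O", "S", "P", "F", "Cl", "Br", "I", "Na"),
  valence = c(4L, 1L, 3L, 2L, 2L, 3L, 1L, 1L, 1L, 1L, 1L),
  weight  = c(12.011, 1.008, 14.007, 15.999, 32.06, 30.974,
              18.998403, 35.45, 79.904, 126.90447, 22.989769),
  mono    = c(12, 1.00782503224, 14.0030740044, 15.9949146196,
              31.9720711744, 30.9737619984, 18.9984031627, 34.968852682,
              78.9183376, 126.9044719, 22.9897692820),
  stringsAsFactors = FALSE
)

.allowed_elements <- .element_table$symbol

.element_prop <- function(symbols, prop) {
  .element_table[[prop]][match(symbols, .element_table$symbol)]
}

#' Standard valence of an element
#'
#' @param element Character vector of element symbols.
#' @return Integer vector of default (closed-shell) valences.
#' @export
standard_valence <- function(element) {
  v <- .element_prop(element, "valence")
  if (anyNA(v)) {
    stop("no standard valence configured for element(s): ",
         paste(unique(element[is.na(v)]), collapse = ", "), call. = FALSE)
  }
  v
}

#' Parse a molecular formula
#'
#' Parses text such as `"C10H10O2N2"` into a `molecular_formula` object: a
#' named integer vector of element counts stored in Hill order (C, then H,
#' then remaining elements alphabetically; all alphabetical when no carbon
#' is present). Implicit counts of 1 are allowed (`"CH4"`).
#'
#' @param text A single non-empty formula string.
#' @return A `molecular_formula` object.
#' @examples
#' parse_formula("C10H10O2N2")
#' rdbe(parse_formula("C20H20Br2N4O2"))
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("formula must be a single character string", call. = FALSE)
  }
  s <- gsub("[[:space:]]", "", text)
  if (!nzchar(s)) {
    stop("empty molecular formula string", call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  tokens <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    # locate first unconsumed character for the error message
    covered <- rep(FALSE, nchar(s))
    for (i in seq_along(m)) {
      covered[m[i]:(m[i] + attr(m, "match.length")[i] - 1L)] <- TRUE
    }
    bad <- substr(s, which(!covered)[1L], nchar(s))
    stop("malformed formula near '", bad, "'", call. = FALSE)
  }
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- sub("^[A-Z][a-z]?", "", tokens)
  unknown <- setdiff(syms, .allowed_elements)
  if (length(unknown) > 0L) {
    stop("unknown element symbol: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  n <- ifelse(cnts == "", 1L, suppressWarnings(as.integer(cnts)))
  if (anyNA(n) || any(n < 1L)) {
    bad <- tokens[which(is.na(n) | n < 1L)[1L]]
    stop("malformed count in token '", bad, "'", call. = FALSE)
  }
  counts <- tapply(n, syms, sum)
  molecular_formula(stats::setNames(as.integer(counts), names(counts)))
}

#' Construct a molecular formula from element counts
#'
#' @param counts Named integer vector or list, element symbol -> count.
#' @return A `molecular_formula` object (counts in Hill order, zeros dropped).
#' @export
molecular_formula <- function(counts) {
  counts <- unlist(counts)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be named by element symbol", call. = FALSE)
  }
  unknown <- setdiff(names(counts), .allowed_elements)
  if (length(unknown) > 0L) {
    stop("unknown element symbol: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 0)) stop("negative element count", call. = FALSE)
  counts <- counts[counts > 0]
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(counts[hill_order(names(counts))], class = "molecular_formula")
}

# Hill ordering of element symbols: C, H, then alphabetical; if no carbon,
# everything alphabetical.
hill_order <- function(symbols) {
  if ("C" %in% symbols) {
    rest <- sort(setdiff(symbols, c("C", "H")))
    match(c("C", intersect("H", symbols), rest), symbols)
  } else {
    order(symbols)
  }
}

#' @export
format.molecular_formula <- function(x, ...) {
  paste0(names(x), ifelse(unclass(x) == 1L, "", unclass(x)), collapse = "")
}

#' @export
as.character.molecular_formula <- function(x, ...) format(x)

#' @export
print.molecular_formula <- function(x, ...) {
  cat(format(x), " (MW ", round(average_mass(x), 2),
      ", monoisotopic ", round(monoisotopic_mass(x), 4),
      ", RDBE ", rdbe(x), ")\n", sep = "")
  invisible(x)
}

# Count lookup that tolerates absent elements.
formula_count <- function(mf, element) {
  n <- unclass(mf)[element]
  ifelse(is.na(n), 0L, n)
}

#' Ring and double-bond equivalents
#'
#' RDBE = 1 + sum over atoms of n_i (v_i - 2) / 2 with the standard valences
#' (C=4, N/P=3, O/S=2, H/halogen/Na=1). Integer for closed-shell formulas,
#' half-integer otherwise.
#'
#' @param mf A `molecular_formula`.
#' @return Numeric RDBE value.
#' @examples
#' rdbe(parse_formula("C10H10O2N2")) # 7
#' @export
rdbe <- function(mf) {
  stopifnot(inherits(mf, "molecular_formula"))
  v <- standard_valence(names(mf))
  1 + sum(unclass(mf) * (v - 2)) / 2
}

#' Average (standard atomic weight) mass
#'
#' @param mf A `molecular_formula`.
#' @return Mass in Da using standard atomic weights.
#' @export
average_mass <- function(mf) {
  stopifnot(inherits(mf, "molecular_formula"))
  sum(unclass(mf) * .element_prop(names(mf), "weight"))
}

#' Monoisotopic mass
#'
#' @param mf A `molecular_formula`.
#' @return Mass in Da using the most abundant isotope of each element.
#' @export
monoisotopic_mass <- function(mf) {
  stopifnot(inherits(mf, "molecular_formula"))
  sum(unclass(mf) * .element_prop(names(mf), "mono"))
}

#' Enumerate molecular formulas matching a monoisotopic mass
#'
#' Exhaustive search over the supplied element count ranges; every returned
#' formula has monoisotopic mass within the tolerance of the query. Results
#' are sorted by absolute mass error, ties broken by Hill string.
#'
#' @param mass Query monoisotopic mass in Da.
#' @param tol Tolerance, in Da (default) or ppm.
#' @param element_ranges Named list, element symbol -> `c(min, max)` count.
#' @param tol_unit `"da"` or `"ppm"`.
#' @return List of `molecular_formula` objects (possibly empty).
#' @examples
#' formulas_from_mass(16.0313, 0.001, list(C = c(0, 2), H = c(0, 6)))
#' @export
formulas_from_mass <- function(mass, tol, element_ranges,
                               tol_unit = c("da", "ppm")) {
  tol_unit <- match.arg(tol_unit)
  if (!is.numeric(tol) || tol <= 0) stop("tolerance must be > 0", call. = FALSE)
  tol_da <- if (tol_unit == "ppm") mass * tol * 1e-6 else tol
  syms <- names(element_ranges)
  unknown <- setdiff(syms, .allowed_elements)
  if (length(unknown) > 0L) {
    stop("unknown element symbol: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rng <- lapply(element_ranges, function(r) {
    r <- as.numeric(r)
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] || r[1] < 0) {
      stop("element ranges must be finite [min, max] with min >= 0",
           call. = FALSE)
    }
    as.integer(r)
  })
  mono <- .element_prop(syms, "mono")
  ord <- order(-mono)  # heaviest first for tighter pruning
  syms <- syms[ord]; rng <- rng[ord]; mono <- mono[ord]
  # minimum achievable mass of the remaining elements, for pruning
  min_rest <- rev(cumsum(rev(vapply(seq_along(syms),
    function(i) mono[i] * rng[[i]][1], numeric(1)))))
  min_rest <- c(min_rest[-1], 0)

  out <- list()
  recurse <- function(i, counts, acc) {
    if (i > length(syms)) {
      if (abs(acc - mass) <= tol_da && sum(counts) > 0L) {
        out[[length(out) + 1L]] <<- stats::setNames(counts, syms)
      }
      return(invisible())
    }
    for (n in rng[[i]][1]:rng[[i]][2]) {
      m <- acc + n * mono[i]
      if (m + min_rest[i] > mass + tol_da) break
      recurse(i + 1L, c(counts, n), m)
    }
  }
  recurse(1L, integer(0), 0)
  mfs <- lapply(out, molecular_formula)
  if (length(mfs) == 0L) return(mfs)
  err <- vapply(mfs, function(f) abs(monoisotopic_mass(f) - mass), numeric(1))
  txt <- vapply(mfs, format, character(1))
  mfs[order(err, txt)]
}
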