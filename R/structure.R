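# Molecular graph container used throughout: heavy atoms with attached-H
# counts, bonds with orders 1-3, and an optional per-atom experimental
# 13C shift assignment.

#' Construct a molecular graph
#'
#' Heavy-atom molecular graph with explicit bond orders and implicit
#' hydrogens stored as per-atom counts. Valences must be exactly satisfied:
#' for every atom, attached H + total bond order equals the element's
#' standard valence.
#'
#' @param element Character vector of heavy-atom element symbols.
#' @param h Integer vector, attached hydrogens per heavy atom.
#' @param bonds Data frame (or matrix) with columns `from`, `to`, `order`;
#'   one row per bonded atom pair, orders in 1:3.
#' @param shift Optional numeric vector of assigned experimental 13C shifts
#'   (NA for heteroatoms/unassigned carbons).
#' @param validate Check valences and connectivity (default TRUE).
#' @return An object of class `mol_graph`.
#' @export
mol_graph <- function(element, h, bonds = NULL, shift = NULL, validate = TRUE) {
  n <- length(element)
  h <- as.integer(h)
  if (length(h) != n) stop("h must have one entry per atom", call. = FALSE)
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(from = integer(0), to = integer(0), order = integer(0))
  } else {
    bonds <- as.data.frame(bonds)[, c("from", "to", "order")]
    bonds[] <- lapply(bonds, as.integer)
    swap <- bonds$from > bonds$to
    tmp <- bonds$from[swap]
    bonds$from[swap] <- bonds$to[swap]
    bonds$to[swap] <- tmp
    bonds <- bonds[order(bonds$from, bonds$to), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  if (is.null(shift)) shift <- rep(NA_real_, n)
  x <- structure(list(element = as.character(element), h = h,
                      bonds = bonds, shift = as.numeric(shift)),
                 class = "mol_graph")
  if (validate) validate_mol_graph(x)
  x
}

#' Validate a molecular graph
#'
#' Checks element symbols, exact valence satisfaction, bond sanity and
#' connectivity. Returns the object invisibly or stops with a message.
#'
#' @param x A `mol_graph`.
#' @export
validate_mol_graph <- function(x) {
  n <- length(x$element)
  if (n < 1L) stop("structure must contain at least one heavy atom", call. = FALSE)
  v <- standard_valence(x$element)
  b <- x$bonds
  if (NROW(b) > 0L) {
    if (any(b$from < 1L | b$to > n | b$from >= b$to)) {
      stop("bond endpoints out of range", call. = FALSE)
    }
    if (any(b$order < 1L | b$order > 3L)) {
      stop("bond orders must be in 1:3", call. = FALSE)
    }
    if (anyDuplicated(b[, c("from", "to")])) {
      stop("duplicate bond between the same atom pair", call. = FALSE)
    }
  }
  deg <- bond_order_sums(x)
  if (any(x$h < 0L)) stop("negative attached-H count", call. = FALSE)
  bad <- which(x$h + deg != v)
  if (length(bad) > 0L) {
    stop("valence not satisfied at atom(s) ", paste(bad, collapse = ", "),
         " (", paste(x$element[bad], collapse = ","), ")", call. = FALSE)
  }
  if (!is_connected_graph(x)) stop("molecular graph is disconnected", call. = FALSE)
  invisible(x)
}

# total bond order incident to each atom
bond_order_sums <- function(x) {
  n <- length(x$element)
  deg <- integer(n)
  b <- x$bonds
  if (NROW(b) > 0L) {
    for (k in seq_len(NROW(b))) {
      deg[b$from[k]] <- deg[b$from[k]] + b$order[k]
      deg[b$to[k]] <- deg[b$to[k]] + b$order[k]
    }
  }
  deg
}

# pi electrons engaged per atom: sum of (order - 1) over incident bonds
pi_counts <- function(x) {
  n <- length(x$element)
  p <- integer(n)
  b <- x$bonds
  if (NROW(b) > 0L) {
    for (k in seq_len(NROW(b))) {
      extra <- b$order[k] - 1L
      p[b$from[k]] <- p[b$from[k]] + extra
      p[b$to[k]] <- p[b$to[k]] + extra
    }
  }
  p
}

as_igraph_skeleton <- function(x) {
  igraph::graph_from_data_frame(
    d = if (NROW(x$bonds)) x$bonds[, c("from", "to")] else
      data.frame(from = integer(0), to = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_along(x$element)))
}

is_connected_graph <- function(x) {
  if (length(x$element) == 1L) return(TRUE)
  g <- as_igraph_skeleton(x)
  igraph::is_connected(g)
}

# Shortest bond-path distance matrix over the heavy-atom skeleton.
bond_distances <- function(x) {
  g <- as_igraph_skeleton(x)
  d <- igraph::distances(g)
  idx <- as.integer(rownames(d))
  d[order(idx), order(idx), drop = FALSE]
}

#' Molecular formula of a structure
#'
#' @param x A `mol_graph`.
#' @return A `molecular_formula` including attached hydrogens.
#' @export
mol_formula <- function(x) {
  counts <- table(x$element)
  counts <- stats::setNames(as.integer(counts), names(counts))
  hsum <- sum(x$h)
  if (hsum > 0L) counts["H"] <- formula_count_safe(counts, "H") + hsum
  molecular_formula(counts)
}

formula_count_safe <- function(counts, el) {
  if (el %in% names(counts)) counts[[el]] else 0L
}

#' Graph-theoretic RDBE recount
#'
#' Recomputes ring-and-double-bond equivalents directly from the graph:
#' (bonds - atoms + components) + number of pi bonds. For a valence-legal
#' connected structure this equals `rdbe(mol_formula(x))`.
#'
#' @param x A `mol_graph`.
#' @return Numeric RDBE.
#' @export
rdbe_graph <- function(x) {
  g <- as_igraph_skeleton(x)
  comps <- igraph::count_components(g)
  rings <- NROW(x$bonds) - length(x$element) + comps
  rings + sum(pmax(x$bonds$order - 1L, 0L))
}

# --- canonical form ---------------------------------------------------------

# Colored simple graph encoding: one vertex per atom (color from element and
# H count), one auxiliary vertex per bond (color from bond order) connected
# to both endpoints. Lets BLISS canonicalization see bond orders.
.colored_encoding <- function(x) {
  n <- length(x$element)
  nb <- NROW(x$bonds)
  el_idx <- match(x$element, .allowed_elements)
  colors <- c(el_idx * 8L + pmin(x$h, 7L), 200L + x$bonds$order)
  edges <- integer(0)
  if (nb > 0L) {
    bv <- n + seq_len(nb)
    edges <- as.integer(rbind(c(rbind(x$bonds$from, bv)),
                              c(rbind(x$bonds$to, bv))))
    # interleave: for bond k edges (from,bv) and (to,bv)
    edges <- c(rbind(x$bonds$from, bv, x$bonds$to, bv))
  }
  g <- igraph::make_empty_graph(n = n + nb, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  list(graph = g, colors = colors, n_atoms = n)
}

#' Canonical key of a molecular graph
#'
#' A relabeling-invariant string identifying the heavy-atom graph (element,
#' attached-H count and bond orders; the shift assignment is deliberately
#' excluded so that duplicate structures differing only in NMR assignment
#' collapse to one key). Uses BLISS canonical labeling on a colored encoding.
#'
#' @param structure A `mol_graph`.
#' @return A character scalar.
#' @export
canonical_key <- function(structure) {
  enc <- .colored_encoding(structure)
  perm <- igraph::canonical_permutation(enc$graph,
                                        colors = enc$colors)$labeling
  g2 <- igraph::permute(enc$graph, perm)
  cols <- integer(length(enc$colors))
  cols[perm] <- enc$colors
  e <- igraph::as_edgelist(g2, names = FALSE)
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  paste0(paste(cols, collapse = ","), "|",
         paste(e[, 1], e[, 2], sep = "-", collapse = ","))
}

#' Atom orbits under the automorphism group
#'
#' Partitions heavy atoms into symmetry-equivalence classes (orbits) of the
#' graph automorphism group, respecting element, attached-H count and bond
#' orders. Symmetric molecules (e.g. benzene) have fewer orbits than atoms.
#'
#' @param structure A `mol_graph`.
#' @return Integer vector of orbit ids (1-based, one per atom).
#' @export
atom_orbits <- function(structure) {
  enc <- .colored_encoding(structure)
  n <- enc$n_atoms
  gens <- igraph::automorphism_group(enc$graph, colors = enc$colors)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (p in gens) {
    p <- as.integer(p)
    for (i in seq_len(n)) {
      ri <- find(i); rj <- find(p[i])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", format(mol_formula(x)), ": ",
      length(x$element), " heavy atoms, ", NROW(x$bonds), " bonds",
      if (any(!is.na(x$shift))) ", 13C assignment present" else "",
      "\n", sep = "")
  invisible(x)
}

# --- SDF I/O ----------------------------------------------------------------

#' Write structures to an SDF file (MOL V2000)
#'
#' Heavy atoms only; hydrogens are implicit (recoverable from standard
#' valences). Assigned 13C shifts are stored in a `<C13_ASSIGNMENT>` data
#' field as `index:ppm` lines; a `<CANONICAL_KEY>` field is included.
#'
#' @param structures List of `mol_graph` objects.
#' @param path Output file path.
#' @param ids Optional character vector of molecule names.
#' @return `path`, invisibly.
#' @export
write_structures_sdf <- function(structures, path, ids = NULL) {
  if (inherits(structures, "mol_graph")) structures <- list(structures)
  if (is.null(ids)) ids <- paste0("mol_", seq_along(structures))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(structures)) {
    s <- structures[[i]]
    n <- length(s$element)
    nb <- NROW(s$bonds)
    writeLines(c(ids[i], "  nmrcase", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb), con)
    for (a in seq_len(n)) {
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         0, 0, 0, s$element[a]), con)
    }
    if (nb > 0L) {
      for (k in seq_len(nb)) {
        writeLines(sprintf("%3d%3d%3d  0", s$bonds$from[k], s$bonds$to[k],
                           s$bonds$order[k]), con)
      }
    }
    writeLines("M  END", con)
    assigned <- which(!is.na(s$shift))
    if (length(assigned) > 0L) {
      writeLines("> <C13_ASSIGNMENT>", con)
      writeLines(sprintf("%d:%.4f", assigned, s$shift[assigned]), con)
      writeLines("", con)
    }
    writeLines("> <C13_SHIFTS>", con)
    writeLines(paste(sprintf("%.4f", s$shift[assigned]), collapse = " "), con)
    writeLines("", con)
    writeLines("$$$$", con)
  }
  invisible(path)
}

#' Read structures from an SDF file
#'
#' Minimal MOL V2000 reader for the dialect written by
#' [write_structures_sdf()].
#' Implicit hydrogens are reconstructed as standard valence minus total
#' bond order; `<C13_ASSIGNMENT>` tags are restored into the shift slot.
#'
#' @param path SDF file path.
#' @return List of `mol_graph` objects, named by molecule title.
#' @export
read_structures_sdf <- function(path) {
  lines <- readLines(path)
  # split records on $$$$
  recs <- split(lines, cumsum(c(0, head(lines, -1) == "$$$$")))
  out <- list()
  for (rec in recs) {
    rec <- rec[rec != "$$$$"]
    if (length(rec) < 4L || !any(grepl("V2000", rec))) next
    title <- trimws(rec[1])
    cl <- rec[4]
    n <- as.integer(substr(cl, 1, 3))
    nb <- as.integer(substr(cl, 4, 6))
    atoms <- rec[5:(4 + n)]
    element <- trimws(substr(atoms, 32, 34))
    bonds <- data.frame(from = integer(0), to = integer(0), order = integer(0))
    if (nb > 0L) {
      bl <- rec[(5 + n):(4 + n + nb)]
      bonds <- data.frame(from = as.integer(substr(bl, 1, 3)),
                          to = as.integer(substr(bl, 4, 6)),
                          order = as.integer(substr(bl, 7, 9)))
    }
    deg <- integer(n)
    for (k in seq_len(NROW(bonds))) {
      deg[bonds$from[k]] <- deg[bonds$from[k]] + bonds$order[k]
      deg[bonds$to[k]] <- deg[bonds$to[k]] + bonds$order[k]
    }
    h <- pmax(standard_valence(element) - deg, 0L)
    shift <- rep(NA_real_, n)
    tagline <- grep("^> *<C13_ASSIGNMENT>", rec)
    if (length(tagline) == 1L) {
      j <- tagline + 1L
      while (j <= length(rec) && nzchar(trimws(rec[j])) &&
             !startsWith(rec[j], ">")) {
        parts <- strsplit(trimws(rec[j]), ":")[[1]]
        shift[as.integer(parts[1])] <- as.numeric(parts[2])
        j <- j + 1L
      }
    }
    s <- mol_graph(element, h, bonds, shift)
    out[[length(out) + 1L]] <- s
    names(out)[length(out)] <- title
  }
  out
}
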