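# Molecular connectivity diagram (MCD): typed skeleton atoms for every heavy
# atom of the formula plus bond-distance-window constraints derived from the
# 2D correlations. The MCD is the input contract of the structure generator.

#' Possible hybridization states for a 13C shift
#'
#' Default interpretation windows: below 60 ppm sp3; 60-90 ppm sp3 or sp
#' (heteroatom-bearing sp3 or alkyne); 90-115 ppm sp2 or sp; 115-160 ppm
#' sp2; at and above 160 ppm sp2 (carbonyl-type carbon, which additionally
#' forces an obligatory heteroatom neighbour during MCD construction).
#' Never returns an empty set. Breakpoints can be overridden per call.
#'
#' @param shift 13C shift in ppm.
#' @param attached_h Attached hydrogen count (currently informative only).
#' @param breaks Numeric breakpoints `c(sp3_hi, sp3sp_hi, sp2sp_hi, co_lo)`,
#'   default `c(60, 90, 115, 160)`.
#' @return Character vector, a subset of `c("sp3", "sp2", "sp")`.
#' @export
assign_hybridization <- function(shift, attached_h = 0,
                                 breaks = c(60, 90, 115, 160)) {
  stopifnot(length(shift) == 1L, is.finite(shift))
  if (shift < breaks[1]) return("sp3")
  if (shift < breaks[2]) return(c("sp3", "sp"))
  if (shift <= breaks[3]) return(c("sp2", "sp"))
  "sp2"
}

#' Detect molecular symmetry from the 13C peak list
#'
#' When a molecule is symmetric, equivalent carbons coincide and the 13C
#' peak list shows fewer distinct signals than the formula's carbon count.
#' This assigns an integer multiplicity (atoms per signal) to every signal,
#' guided by relative intensities, such that multiplicities sum to the
#' carbon count. Returns the identity map (all 1) when signal count equals
#' carbon count.
#'
#' @param dataset A `spectral_dataset` with a 13C peak list.
#' @param mf The `molecular_formula`.
#' @return Integer vector of multiplicities, one per 13C peak (in peak-list
#'   order).
#' @export
detect_shift_symmetry <- function(dataset, mf) {
  cpeaks <- dataset$peaks[dataset$peaks$nucleus == "C13", , drop = FALSE]
  if (NROW(cpeaks) == 0L) stop("no 13C peak list present", call. = FALSE)
  n_c <- formula_count(mf, "C")
  s <- NROW(cpeaks)
  if (s == n_c) return(rep(1L, s))
  if (s > n_c) {
    stop("more 13C signals (", s, ") than carbons (", n_c,
         "); resolve superfluous signals first", call. = FALSE)
  }
  inten <- cpeaks$intensity
  if (any(!is.finite(inten)) || all(inten == 0)) inten <- rep(1, s)
  # proportional allocation, then distribute the rounding remainder to the
  # signals with the largest fractional parts
  raw <- inten * n_c / sum(inten)
  m <- pmax(1L, as.integer(floor(raw)))
  rem <- n_c - sum(m)
  if (rem > 0L) {
    ord <- order(raw - floor(raw), decreasing = TRUE)
    i <- 1L
    while (rem > 0L) {
      m[ord[(i - 1L) %% s + 1L]] <- m[ord[(i - 1L) %% s + 1L]] + 1L
      rem <- rem - 1L
      i <- i + 1L
    }
  } else if (rem < 0L) {
    ord <- order(raw - floor(raw))
    i <- 1L
    while (rem < 0L && i <= s * n_c) {
      j <- ord[(i - 1L) %% s + 1L]
      if (m[j] > 1L) {
        m[j] <- m[j] - 1L
        rem <- rem + 1L
      }
      i <- i + 1L
    }
  }
  if (sum(m) != n_c || any(m < 1L)) {
    stop("no integer multiplicity assignment found for ", s, " signals and ",
         n_c, " carbons; supply multiplicities manually", call. = FALSE)
  }
  m
}

# attached-H per 13C signal: multiplicity labels where present, else 0/1
# inferred per signal from the one-bond table
.attached_h_per_signal <- function(cpeaks, correlations, tol_c) {
  mult_h <- c(C = 0L, CH = 1L, CH2 = 2L, CH3 = 3L)
  hh <- unname(mult_h[cpeaks$multiplicity])
  if (anyNA(hh)) {
    ob <- correlations[correlations$experiment == "ONEBOND_CH", , drop = FALSE]
    if (NROW(ob) == 0L) {
      stop("cannot type carbons: no multiplicity labels and no one-bond ",
           "(HSQC-type) data", call. = FALSE)
    }
    miss <- which(is.na(hh))
    hh[miss] <- vapply(cpeaks$shift_ppm[miss], function(sh) {
      if (any(abs(ob$f2_ppm - sh) <= tol_c)) 1L else 0L
    }, integer(1))
  }
  as.integer(hh)
}

#' Build the molecular connectivity diagram
#'
#' Consolidates the molecular formula and the spectral dataset into one
#' object: one skeleton atom per heavy atom (carbons matched to 13C signals
#' and duplicated according to detected symmetry multiplicities), attached-H
#' counts from multiplicity labels or the one-bond table, hybridization sets
#' from shift windows, heteroatom-neighbour flags (`forbidden` for
#' CH2/CH3 below 36 ppm, `obligatory` at/above 160 ppm, else `undefined`),
#' the exchangeable-proton count (formula H not placed on carbons), and the
#' connectivity constraints extracted from COSY/HMBC-type correlations.
#'
#' @param mf A `molecular_formula`.
#' @param dataset A `spectral_dataset`; must pass [check_consistency()]
#'   without reject-level issues.
#' @param options List: `tol_c` (default 0.5 ppm), `tol_h` (0.05 ppm),
#'   `nonstandard` (widen long-range windows to \[1,3\] carbon bonds, default
#'   FALSE), `hetero_cutoff` (36 ppm), `carbonyl_cutoff` (160 ppm).
#' @return An object of class `mcd`.
#' @export
build_mcd <- function(mf, dataset, options = list()) {
  stopifnot(inherits(mf, "molecular_formula"),
            inherits(dataset, "spectral_dataset"))
  opt <- utils::modifyList(list(tol_c = 0.5, tol_h = 0.05,
                                nonstandard = FALSE, hetero_cutoff = 36,
                                carbonyl_cutoff = 160), options)
  report <- check_consistency(dataset, mf, tol_c = opt$tol_c)
  if (has_reject(report)) {
    stop("dataset rejected by consistency triage: ",
         paste(report$issues$message[report$issues$severity == "reject"],
               collapse = "; "), call. = FALSE)
  }
  cpeaks <- dataset$peaks[dataset$peaks$nucleus == "C13", , drop = FALSE]
  if (NROW(cpeaks) == 0L) stop("cannot type carbons: no 13C peak list",
                               call. = FALSE)
  mult <- detect_shift_symmetry(dataset, mf)
  sig_h <- .attached_h_per_signal(cpeaks, dataset$correlations, opt$tol_c)

  # carbon skeleton atoms, duplicated per symmetry multiplicity
  sig_idx <- rep(seq_len(NROW(cpeaks)), mult)
  c_shift <- cpeaks$shift_ppm[sig_idx]
  c_h <- sig_h[sig_idx]
  n_cc <- length(sig_idx)
  if (n_cc != formula_count(mf, "C")) {
    stop("carbon count mismatch after symmetry resolution: ", n_cc, " vs ",
         formula_count(mf, "C"), call. = FALSE)
  }
  hetero_syms <- rep(names(mf), unclass(mf))
  hetero_syms <- hetero_syms[!hetero_syms %in% c("C", "H")]
  atoms <- data.frame(
    index = seq_len(n_cc + length(hetero_syms)),
    element = c(rep("C", n_cc), hetero_syms),
    shift = c(c_shift, rep(NA_real_, length(hetero_syms))),
    attached_h = c(c_h, rep(NA_integer_, length(hetero_syms))),
    signal = c(sig_idx, rep(NA_integer_, length(hetero_syms))),
    stringsAsFactors = FALSE)
  hyb <- vector("list", NROW(atoms))
  hetero <- rep("undefined", NROW(atoms))
  for (i in seq_len(n_cc)) {
    hyb[[i]] <- assign_hybridization(c_shift[i], c_h[i])
    if (c_shift[i] >= opt$carbonyl_cutoff) {
      hetero[i] <- "obligatory"
    } else if (c_shift[i] < opt$hetero_cutoff && c_h[i] %in% c(2L, 3L)) {
      hetero[i] <- "forbidden"
    }
  }
  exch <- formula_count(mf, "H") - sum(c_h)
  if (exch < 0L) {
    stop("negative exchangeable-proton count: carbons carry ", sum(c_h),
         " H but the formula has only ", formula_count(mf, "H"),
         call. = FALSE)
  }
  x <- structure(list(atoms = atoms, hyb = hyb, hetero = hetero,
                      constraints = list(), exchangeable_h = as.integer(exch),
                      mf = mf, options = opt, orphans = list()),
                 class = "mcd")
  cons <- constraints_from_correlations(dataset, x,
                                        tol_c = opt$tol_c, tol_h = opt$tol_h,
                                        nonstandard = opt$nonstandard)
  x$constraints <- cons
  x$orphans <- attr(cons, "orphans")
  x
}

new_constraint <- function(from, candidates, min_bonds, max_bonds, source) {
  candidates <- sort(setdiff(as.integer(candidates), as.integer(from)))
  stopifnot(length(candidates) > 0L, min_bonds >= 1L, min_bonds <= max_bonds)
  list(from = as.integer(from), candidates = candidates,
       min_bonds = as.integer(min_bonds), max_bonds = as.integer(max_bonds),
       source = source, ambiguous = length(candidates) > 1L)
}

#' Extract connectivity constraints from 2D correlations
#'
#' Translates correlations into carbon-carbon (or carbon-nitrogen)
#' bond-distance windows. COSY cross-peaks are read as vicinal couplings:
#' adjacent carbons, window \[1,1\]. Long-range CH correlations are 2-3 bond
#' H-C couplings: window \[1,2\] between the proton-bearing carbon and the
#' target carbon, widened to \[1,3\] under `nonstandard`. Long-range NH
#' correlations constrain the proton-bearing carbon against the nitrogens
#' with the same window. A coordinate matching several skeleton atoms
#' within tolerance yields an ambiguous constraint whose candidate set is
#' the full match; the constraint is satisfied if any candidate is. When
#' the proton coordinate itself is ambiguous across different signals the
#' constraint is emitted in the reverse direction when that is sound, and
#' otherwise discarded (recorded among the orphans). Correlations matching
#' no skeleton atom are listed as orphans, never silently dropped.
#'
#' @param dataset A `spectral_dataset`.
#' @param mcd An `mcd` (or its atoms table plus one-bond data context).
#' @param tol_c,tol_h Matching tolerances, ppm.
#' @param nonstandard Widen long-range windows to 3 carbon bonds.
#' @return List of constraints; attribute `orphans` holds unmatched rows.
#' @export
constraints_from_correlations <- function(dataset, mcd, tol_c = 0.5,
                                          tol_h = 0.05, nonstandard = FALSE) {
  atoms <- mcd$atoms
  corr <- dataset$correlations
  hmax <- if (nonstandard) 3L else 2L
  # proton shifts attached to each carbon atom, from the one-bond table;
  # an atom can carry several candidate protons when carbon coordinates
  # overlap within tolerance
  ob <- corr[corr$experiment == "ONEBOND_CH", , drop = FALSE]
  proton_of <- rep(list(numeric(0)), NROW(atoms))
  for (k in seq_len(NROW(ob))) {
    hit <- which(atoms$element == "C" &
                   abs(atoms$shift - ob$f2_ppm[k]) <= tol_c)
    for (a in hit) proton_of[[a]] <- c(proton_of[[a]], ob$f1_ppm[k])
  }
  carbons_of_proton <- function(hppm) {
    which(vapply(proton_of, function(p) any(abs(p - hppm) <= tol_h),
                 logical(1)))
  }
  # distinct proton shifts per signal: > 1 means the proton-to-copy mapping
  # within that signal is ambiguous (overlapped distinct carbons), so
  # per-copy constraint emission is not sound for it
  signal_protons <- tapply(seq_len(NROW(atoms)), atoms$signal, function(idx) {
    length(unique(round(unlist(proton_of[idx]) / max(tol_h, 1e-6))))
  })
  cons <- list()
  orphans <- list()
  orphan <- function(row, why) {
    orphans[[length(orphans) + 1L]] <<- c(as.list(row), reason = why)
  }
  one_signal <- function(idx) length(unique(atoms$signal[idx])) == 1L
  from_safe <- function(idx) {
    # per-copy emission is sound for a single atom, or for the symmetric
    # copies of one signal carrying one shared proton shift
    if (length(idx) == 1L) return(TRUE)
    if (!one_signal(idx)) return(FALSE)
    sp <- signal_protons[as.character(atoms$signal[idx[1]])]
    !is.na(sp) && sp <= 1L
  }

  emit_longrange <- function(fr, tg, row, min_b, max_b, src) {
    if (length(fr) == 0L) { orphan(row, "proton matches no carbon"); return() }
    if (length(tg) == 0L) { orphan(row, "target matches no atom"); return() }
    if (from_safe(fr)) {
      for (f in fr) {
        cand <- setdiff(tg, f)
        if (length(cand) > 0L) {
          cons[[length(cons) + 1L]] <<- new_constraint(f, cand, min_b, max_b, src)
        }
      }
    } else if (length(tg) == 1L) {
      # the distance window is symmetric: anchor at the unambiguous target
      # and make the ambiguous proton carbons the candidate set
      cand <- setdiff(fr, tg)
      if (length(cand) > 0L) {
        cons[[length(cons) + 1L]] <<- new_constraint(tg, cand, min_b, max_b, src)
      }
    } else {
      orphan(row, "ambiguous on both axes; discarded")
    }
  }

  for (k in seq_len(NROW(corr))) {
    row <- corr[k, ]
    if (row$experiment == "COSY_HH") {
      fr <- carbons_of_proton(row$f1_ppm)
      tg <- carbons_of_proton(row$f2_ppm)
      emit_longrange(fr, tg, row, 1L, 1L, "COSY")
    } else if (row$experiment == "LONGRANGE_CH") {
      fr <- carbons_of_proton(row$f1_ppm)
      tg <- which(atoms$element == "C" & abs(atoms$shift - row$f2_ppm) <= tol_c)
      emit_longrange(fr, tg, row, 1L, hmax, "HMBC")
    } else if (row$experiment == "LONGRANGE_NH") {
      fr <- carbons_of_proton(row$f1_ppm)
      tg <- which(atoms$element == "N")
      emit_longrange(fr, tg, row, 1L, hmax, "HMBC")
    }
  }
  attr(cons, "orphans") <- orphans
  cons
}

#' Add fixed-substructure (fragment) constraints to an MCD
#'
#' Freezes known bonds: each row of `pairs` becomes a window-\[1,1\]
#' constraint with source `FRAGMENT` (black lines in the diagram).
#'
#' @param mcd An `mcd`.
#' @param pairs Two-column matrix/data frame of atom index pairs.
#' @return The updated `mcd`.
#' @export
add_fragment_constraints <- function(mcd, pairs) {
  pairs <- as.matrix(pairs)
  for (k in seq_len(NROW(pairs))) {
    mcd$constraints[[length(mcd$constraints) + 1L]] <-
      new_constraint(pairs[k, 1], pairs[k, 2], 1L, 1L, "FRAGMENT")
  }
  mcd
}

#' @export
print.mcd <- function(x, ...) {
  nc <- sum(x$atoms$element == "C")
  namb <- sum(vapply(x$constraints, `[[`, logical(1), "ambiguous"))
  cat("<mcd> ", format(x$mf), ": ", NROW(x$atoms), " skeleton atoms (",
      nc, " C), ", length(x$constraints), " constraints (", namb,
      " ambiguous), ", x$exchangeable_h, " exchangeable H\n", sep = "")
  if (length(x$orphans) > 0L) {
    cat("  ", length(x$orphans), " orphan correlations\n", sep = "")
  }
  invisible(x)
}

#' Serialize an MCD to JSON
#'
#' @param mcd An `mcd`.
#' @param path Optional output path; when NULL the JSON string is returned.
#' @export
mcd_to_json <- function(mcd, path = NULL) {
  obj <- list(
    formula = format(mcd$mf),
    exchangeable_h = mcd$exchangeable_h,
    atoms = cbind(mcd$atoms,
                  hybridization = vapply(mcd$hyb, function(h)
                    paste(h, collapse = "/"), character(1)),
                  hetero_neighbor = mcd$hetero),
    constraints = lapply(mcd$constraints, function(co)
      list(from = co$from, candidates = co$candidates,
           min_bonds = co$min_bonds, max_bonds = co$max_bonds,
           source = co$source, ambiguous = co$ambiguous)))
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' Export an MCD as Graphviz DOT
#'
#' Mirrors the diagram conventions: COSY edges blue, long-range edges
#' green, fragment edges black, dashed when ambiguous; node colour encodes
#' hybridization (sp3 blue, sp2 pink, mixed black).
#'
#' @param mcd An `mcd`.
#' @return Character scalar of DOT source.
#' @export
mcd_to_dot <- function(mcd) {
  lines <- c("graph mcd {")
  for (i in seq_len(NROW(mcd$atoms))) {
    a <- mcd$atoms[i, ]
    col <- if (a$element != "C") "gray"
      else if (identical(mcd$hyb[[i]], "sp3")) "blue"
      else if (identical(mcd$hyb[[i]], "sp2")) "pink"
      else "black"
    lab <- if (a$element == "C")
      sprintf("C%d\\n%.1f", a$index, a$shift) else
      sprintf("%s%d", a$element, a$index)
    lines <- c(lines, sprintf("  a%d [label=\"%s\", color=%s];",
                              a$index, lab, col))
  }
  for (co in mcd$constraints) {
    col <- switch(co$source, COSY = "blue", FRAGMENT = "black", "green")
    style <- if (co$ambiguous) "dashed" else "solid"
    for (t in co$candidates) {
      lines <- c(lines, sprintf("  a%d -- a%d [color=%s, style=%s];",
                                co$from, t, col, style))
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}
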