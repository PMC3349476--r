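# Exhaustive structure generation: backtracking bond placement over the MCD
# skeleton with forward constraint checking, symmetry-aware branch pruning
# and canonical-key deduplication. Emitted structures always pass
# check_constraints(); when status is "completed" the candidate list is
# exhaustive with respect to the constraint semantics.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generation options
#'
#' @param max_structures Cap on deduplicated candidates (abort beyond).
#' @param time_budget Wall-clock budget in seconds (abort beyond).
#' @param nonstandard_hmbc Interpret long-range CH correlations as up to
#'   4-bond couplings (window \[1,3\] in carbon bonds). Applied at MCD
#'   construction; recorded here for provenance.
#' @param use_symmetry Prune branches that only permute interchangeable
#'   atoms. Never changes the candidate set, only the nodes explored.
#' @param seed Accepted for interface compatibility; the search is fully
#'   deterministic and the seed does not influence results.
#' @return A list of class `generation_options`.
#' @export
generation_options <- function(max_structures = 20000L, time_budget = Inf,
                               nonstandard_hmbc = FALSE, use_symmetry = TRUE,
                               seed = NULL) {
  stopifnot(max_structures >= 1L, time_budget > 0)
  structure(list(max_structures = as.integer(max_structures),
                 time_budget = time_budget,
                 nonstandard_hmbc = isTRUE(nonstandard_hmbc),
                 use_symmetry = isTRUE(use_symmetry), seed = seed),
            class = "generation_options")
}

#' Untyped MCD from a molecular formula alone
#'
#' Builds a skeleton with one atom per heavy atom, no shift typing, no
#' constraints and every hydrogen free; [generate()] then enumerates all
#' valence-legal connected constitutional isomers.
#'
#' @param mf A `molecular_formula`.
#' @return An `mcd`.
#' @export
mcd_from_formula <- function(mf) {
  stopifnot(inherits(mf, "molecular_formula"))
  syms <- rep(names(mf), unclass(mf))
  syms <- syms[syms != "H"]
  if (length(syms) == 0L) {
    stop("formula has no heavy atoms", call. = FALSE)
  }
  syms <- syms[order(match(syms, .allowed_elements))]
  atoms <- data.frame(index = seq_along(syms), element = syms,
                      shift = NA_real_, attached_h = NA_integer_,
                      signal = NA_integer_, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, hyb = vector("list", length(syms)),
                 hetero = rep("undefined", length(syms)),
                 constraints = list(),
                 exchangeable_h = formula_count(mf, "H"),
                 mf = mf, options = list(), orphans = list()),
            class = "mcd")
}


# Deterministic atom processing order: breadth-first over the constraint
# graph from the most-constrained atom, so that constraint partners are
# saturated close together and early pruning can decide their windows;
# ties broken by descending free valence, then index.
.atom_order <- function(n, f, cons, pair_req) {
  W <- pair_req
  for (co in cons) {
    W[co$from, co$candidates] <- TRUE
    W[co$candidates, co$from] <- TRUE
  }
  deg <- rowSums(W)
  chosen <- integer(0)
  remaining <- seq_len(n)
  while (length(remaining) > 0L) {
    links <- if (length(chosen) == 0L) deg[remaining] else
      rowSums(W[remaining, chosen, drop = FALSE])
    pick <- remaining[order(-links, -f[remaining], remaining)][1L]
    chosen <- c(chosen, pick)
    remaining <- setdiff(remaining, pick)
  }
  chosen
}

# constraint-role signature per atom, used to decide interchangeability
.constraint_signature <- function(n, constraints) {
  sig <- rep("", n)
  for (ci in seq_along(constraints)) {
    co <- constraints[[ci]]
    sig[co$from] <- paste0(sig[co$from], "F", ci, ";")
    sig[co$candidates] <- paste0(sig[co$candidates], "c", ci, ";")
  }
  sig
}

#' Generate all candidate structures consistent with an MCD
#'
#' Backtracking bond placement over the free valences: hydrogens not fixed
#' by the data are distributed exhaustively over the remaining valence
#' (exchangeable OH/NH combinatorics included), then bond orders 1-3 are
#' assigned pair by pair with forward pruning on valence, hybridization
#' (pi-bond budget), heteroatom-neighbour flags, adjacency (window \[1,1\])
#' constraints and saturated-fragment disconnection. Every complete graph
#' is verified against all distance-window constraints
#' ([check_constraints()]) and deduplicated by [canonical_key()]. Ambiguous
#' constraints are existential: one satisfied candidate target suffices.
#'
#' @param mcd An `mcd` from [build_mcd()] or [mcd_from_formula()].
#' @param options A [generation_options()] list.
#' @return An object of class `generation_result`: `candidates` (list of
#'   `mol_graph`, named by canonical key), `status` (`completed`,
#'   `aborted_cap` or `aborted_time`) and `counters`.
#' @examples
#' res <- generate(mcd_from_formula(parse_formula("C2H6O")))
#' length(res$candidates)  # 2: ethanol and dimethyl ether
#' @export
generate <- function(mcd, options = generation_options()) {
  stopifnot(inherits(mcd, "mcd"))
  if (!inherits(options, "generation_options")) {
    options <- do.call(generation_options, options)
  }
  t0 <- proc.time()[["elapsed"]]
  atoms <- mcd$atoms
  n <- NROW(atoms)
  el <- atoms$element
  v <- standard_valence(el)
  fixed <- !is.na(atoms$attached_h)
  h_fixed_sum <- sum(atoms$attached_h[fixed])
  pool <- mcd$exchangeable_h
  total_h <- h_fixed_sum + pool

  if ((sum(v) - total_h) %% 2L != 0L) {
    stop("no structures possible: total free valence is odd (",
         sum(v) - total_h, ")", call. = FALSE)
  }

  hetero_flag <- mcd$hetero %||% rep("undefined", n)
  pi_of <- c(sp3 = 0L, sp2 = 1L, sp = 2L)
  pi_allowed <- vector("list", n)
  for (i in seq_len(n)) {
    s <- if (length(mcd$hyb) >= i) mcd$hyb[[i]] else NULL
    cand <- if (is.null(s) || length(s) == 0L) 0:2 else unname(pi_of[s])
    pa <- intersect(cand, 0:max(v[i] - 1L, 0L))
    pi_allowed[[i]] <- if (length(pa) == 0L) 0L else sort(pa)
  }
  pi_maxv <- vapply(pi_allowed, max, integer(1))

  cons <- mcd$constraints
  csig <- .constraint_signature(n, cons)
  # Constraints with max_bonds <= 2 become exactly decidable once the
  # anchor atom and every candidate are saturated: a saturated atom's
  # neighbour set is final, and any 1- or 2-bond path uses only edges
  # incident to the anchor or a candidate. Index them per involved atom
  # for early pruning.
  adj_cons <- vector("list", n)
  for (ci in seq_along(cons)) {
    if (cons[[ci]]$max_bonds <= 2L) {
      inv <- c(cons[[ci]]$from, cons[[ci]]$candidates)
      for (a in inv) adj_cons[[a]] <- c(adj_cons[[a]], ci)
    }
  }
  # adjacency demanded outright: an unambiguous [1,1] constraint forces
  # its bond, so the search never explores branches omitting it
  pair_req <- matrix(FALSE, n, n)
  for (co in cons) {
    if (co$min_bonds == 1L && co$max_bonds == 1L &&
        length(co$candidates) == 1L) {
      pair_req[co$from, co$candidates] <- TRUE
      pair_req[co$candidates, co$from] <- TRUE
    }
  }
  # pair admissibility from hetero_neighbor = forbidden
  pair_ok <- matrix(TRUE, n, n)
  forb <- which(el == "C" & hetero_flag == "forbidden")
  het <- which(el != "C")
  if (length(forb) && length(het)) {
    pair_ok[forb, het] <- FALSE
    pair_ok[het, forb] <- FALSE
  }

  # interchangeability class (element, valence, hetero flag, hybridization,
  # shift signal, constraint roles); used for symmetric branch pruning
  twin_base <- paste(el, v, hetero_flag,
                     vapply(pi_allowed, paste, character(1), collapse = ""),
                     ifelse(is.na(atoms$signal), "-", atoms$signal), csig)

  st <- new.env(parent = emptyenv())
  st$keys <- new.env(parent = emptyenv())
  st$cands <- list()
  st$nodes <- 0L
  st$rejects <- 0L
  st$status <- "completed"
  st$halt <- FALSE

  check_budget <- function() {
    if (st$halt) return(TRUE)
    if (st$nodes %% 512L == 0L &&
        proc.time()[["elapsed"]] - t0 > options$time_budget) {
      st$status <- "aborted_time"
      st$halt <- TRUE
      return(TRUE)
    }
    FALSE
  }

  # ---- hydrogen distributions over atoms with free H ----
  free_idx <- which(!fixed)
  h_base <- ifelse(fixed, atoms$attached_h, 0L)
  dist_groups <- twin_base[free_idx]
  distributions <- list()
  enum_h <- function(i, left, acc) {
    if (i > length(free_idx)) {
      if (left == 0L) distributions[[length(distributions) + 1L]] <<- acc
      return(invisible())
    }
    a <- free_idx[i]
    hi <- min(v[a] - (if (n > 1L) 1L else 0L), left)
    # remaining capacity prune
    if (i < length(free_idx)) {
      cap_rest <- sum(pmin(v[free_idx[(i + 1):length(free_idx)]] -
                             (if (n > 1L) 1L else 0L), left))
    } else cap_rest <- 0L
    for (hh in 0:hi) {
      if (left - hh > cap_rest) next
      # symmetry: within a group of interchangeable atoms require
      # non-increasing H counts
      if (options$use_symmetry && i > 1L &&
          dist_groups[i] == dist_groups[i - 1L] && hh > acc[i - 1L]) next
      enum_h(i + 1L, left - hh, c(acc, hh))
    }
  }
  if (length(free_idx) == 0L) {
    if (pool == 0L) distributions <- list(integer(0)) else distributions <- list()
  } else {
    enum_h(1L, pool, integer(0))
  }

  # ---- search over one H distribution ----
  search_distribution <- function(h_all) {
    f <- v - h_all
    if (any(f < 0L)) return(invisible())
    if (sum(f) %% 2L != 0L) return(invisible())
    if (n > 1L && (any(f < 1L) || sum(f) < 2L * (n - 1L))) return(invisible())
    if (n == 1L) {
      if (f[1] == 0L) emit_leaf(matrix(0L, 1, 1), h_all)
      return(invisible())
    }
    seqc <- .atom_order(n, f, cons, pair_req)
    B <- matrix(0L, n, n)
    rem <- f
    pi_used <- integer(n)
    pi_cap <- pmin(pi_maxv, pmax(f - 1L, 0L))
    finalized <- logical(n)
    twin_sig <- paste(twin_base, f)

    connectivity_ok <- function() {
      # no saturated proper subgraph may exist
      seen <- logical(n)
      stack <- integer(n)
      for (s0 in seq_len(n)) {
        if (seen[s0]) next
        seen[s0] <- TRUE
        stack[1L] <- s0
        top <- 1L
        size <- 1L
        remsum <- rem[s0]
        while (top > 0L) {
          q <- stack[top]
          top <- top - 1L
          nb <- which(B[q, ] > 0L)
          for (w in nb) {
            if (!seen[w]) {
              seen[w] <- TRUE
              top <- top + 1L
              stack[top] <- w
              size <- size + 1L
              remsum <- remsum + rem[w]
            }
          }
        }
        if (size < n && remsum == 0L) return(FALSE)
      }
      TRUE
    }

    finish_atom <- function(k) {
      a <- seqc[k]
      ok <- pi_used[a] %in% pi_allowed[[a]]
      if (ok && hetero_flag[a] == "obligatory") {
        ok <- any(B[a, ] > 0L & el != "C")
      }
      if (ok && length(adj_cons[[a]]) > 0L) {
        finalized[a] <<- TRUE
        for (ci in adj_cons[[a]]) {
          co <- cons[[ci]]
          if (co$max_bonds == 1L) {
            # adjacency is final once the anchor (or a sole candidate) is
            # saturated, whatever the rest of the graph does
            if (finalized[co$from] && !any(B[co$from, co$candidates] > 0L)) {
              ok <- FALSE
              break
            }
            if (length(co$candidates) == 1L && finalized[co$candidates] &&
                B[co$from, co$candidates] == 0L) {
              ok <- FALSE
              break
            }
            next
          }
          if (!all(finalized[c(co$from, co$candidates)])) next
          sat <- FALSE
          for (cc in co$candidates) {
            d1 <- B[co$from, cc] > 0L
            if (co$min_bonds <= 1L && co$max_bonds >= 1L && d1) {
              sat <- TRUE
              break
            }
            if (co$max_bonds >= 2L && !d1 &&
                any(B[co$from, ] > 0L & B[, cc] > 0L)) {
              sat <- TRUE
              break
            }
          }
          if (!sat) {
            ok <- FALSE
            break
          }
        }
        if (!ok) finalized[a] <<- FALSE
      } else if (ok) {
        finalized[a] <<- TRUE
      }
      if (ok && !connectivity_ok()) {
        finalized[a] <<- FALSE
        ok <- FALSE
      }
      if (!ok) {
        st$rejects <- st$rejects + 1L
        return(invisible())
      }
      do_atom(k + 1L)
      finalized[a] <<- FALSE
    }

    compose <- function(a, k, plist, idx, need, untouched0) {
      st$nodes <- st$nodes + 1L
      if (check_budget()) return(invisible())
      if (need == 0L) {
        finish_atom(k)
        return(invisible())
      }
      if (idx > length(plist)) {
        st$rejects <- st$rejects + 1L
        return(invisible())
      }
      avail <- sum(pmin.int(3L, rem[plist[idx:length(plist)]]))
      if (need > avail) {
        st$rejects <- st$rejects + 1L
        return(invisible())
      }
      p <- plist[idx]
      maxb <- min(3L, need, rem[p],
                  1L + min(pi_cap[a] - pi_used[a], pi_cap[p] - pi_used[p]))
      if (!pair_ok[a, p]) maxb <- 0L
      minb <- if (pair_req[a, p]) 1L else 0L
      if (maxb < minb) {
        st$rejects <- st$rejects + 1L
        return(invisible())
      }
      if (options$use_symmetry && maxb > 0L && untouched0[p]) {
        # cap by the order given to the nearest preceding interchangeable twin
        if (idx > 1L) {
          for (j in (idx - 1L):1L) {
            q <- plist[j]
            if (untouched0[q] && twin_sig[p] == twin_sig[q]) {
              maxb <- min(maxb, B[a, q])
              break
            }
          }
        }
      }
      for (b in maxb:minb) {
        if (b > 0L) {
          B[a, p] <<- b
          B[p, a] <<- b
          rem[a] <<- rem[a] - b
          rem[p] <<- rem[p] - b
          if (b > 1L) {
            pi_used[a] <<- pi_used[a] + (b - 1L)
            pi_used[p] <<- pi_used[p] + (b - 1L)
          }
        }
        compose(a, k, plist, idx + 1L, need - b, untouched0)
        if (b > 0L) {
          B[a, p] <<- 0L
          B[p, a] <<- 0L
          rem[a] <<- rem[a] + b
          rem[p] <<- rem[p] + b
          if (b > 1L) {
            pi_used[a] <<- pi_used[a] - (b - 1L)
            pi_used[p] <<- pi_used[p] - (b - 1L)
          }
        }
        if (st$halt) return(invisible())
      }
    }

    do_atom <- function(k) {
      if (st$halt) return(invisible())
      if (k > n) {
        emit_leaf(B, h_all)
        return(invisible())
      }
      a <- seqc[k]
      plist <- if (k < n) seqc[(k + 1L):n] else integer(0)
      # a still-required bond to a partner with no remaining valence can
      # never be placed
      if (any(pair_req[a, plist] & B[a, plist] == 0L & rem[plist] == 0L) ||
          rem[a] < sum(pair_req[a, plist] & B[a, plist] == 0L)) {
        st$rejects <- st$rejects + 1L
        return(invisible())
      }
      plist <- plist[rem[plist] > 0L]
      # allocate demanded bonds first: forcing them early collapses the
      # branching before any free valence is spent elsewhere
      req_first <- pair_req[a, plist] & B[a, plist] == 0L
      plist <- c(plist[req_first], plist[!req_first])
      untouched0 <- rem == f
      compose(a, k, plist, 1L, rem[a], untouched0)
    }

    do_atom(1L)
  }

  emit_leaf <- function(B, h_all) {
    ut <- which(upper.tri(B) & B > 0L, arr.ind = TRUE)
    bonds <- data.frame(from = ut[, 1], to = ut[, 2],
                        order = B[ut])
    s <- mol_graph(el, h_all, bonds, shift = atoms$shift, validate = FALSE)
    viol <- check_constraints(s, mcd)
    if (NROW(viol) > 0L) {
      st$rejects <- st$rejects + 1L
      return(invisible())
    }
    key <- canonical_key(s)
    if (!exists(key, envir = st$keys, inherits = FALSE)) {
      assign(key, TRUE, envir = st$keys)
      st$cands[[key]] <- s
      if (length(st$cands) >= options$max_structures) {
        st$status <- "aborted_cap"
        st$halt <- TRUE
      }
    }
  }

  full_h <- function(hf) {
    h_all <- h_base
    if (length(free_idx) > 0L) h_all[free_idx] <- hf
    as.integer(h_all)
  }
  for (hf in distributions) {
    search_distribution(full_h(hf))
    if (st$halt) break
  }

  structure(list(candidates = st$cands, status = st$status,
                 counters = list(nodes = st$nodes,
                                 constraint_rejections = st$rejects),
                 options = options, mf = mcd$mf),
            class = "generation_result")
}

#' @export
print.generation_result <- function(x, ...) {
  cat("<generation_result> ", length(x$candidates), " candidate structures (",
      x$status, "); ", x$counters$nodes, " nodes explored, ",
      x$counters$constraint_rejections, " rejections\n", sep = "")
  invisible(x)
}

#' Check a complete structure against MCD constraints
#'
#' A structure satisfies a constraint when the shortest bond path from the
#' constraint's atom to at least one candidate target lies within
#' `[min_bonds, max_bonds]` (ambiguous constraints are existential over
#' their candidates). Hybridization sets are respected when the number of
#' pi bonds engaged by a carbon matches one of its admissible states, and
#' heteroatom-neighbour flags when forbidden carbons have no heteroatom
#' neighbour and obligatory carbons have at least one.
#'
#' @param structure A complete `mol_graph` whose atom indices match the MCD.
#' @param mcd The `mcd`.
#' @return Data frame of violations (empty when fully consistent).
#' @export
check_constraints <- function(structure, mcd) {
  n <- length(structure$element)
  viol <- data.frame(type = character(0), detail = character(0))
  add <- function(type, detail) {
    viol[nrow(viol) + 1L, ] <<- list(type, detail)
  }
  D <- bond_distances(structure)
  for (ci in seq_along(mcd$constraints)) {
    co <- mcd$constraints[[ci]]
    d <- D[co$from, co$candidates]
    if (!any(d >= co$min_bonds & d <= co$max_bonds)) {
      add("distance", sprintf(
        "%s constraint %d: atom %d to {%s} outside [%d,%d] (distances %s)",
        co$source, ci, co$from, paste(co$candidates, collapse = ","),
        co$min_bonds, co$max_bonds, paste(d, collapse = ",")))
    }
  }
  pi_of <- c(sp3 = 0L, sp2 = 1L, sp = 2L)
  p <- pi_counts(structure)
  adj <- matrix(FALSE, n, n)
  if (NROW(structure$bonds) > 0L) {
    adj[cbind(structure$bonds$from, structure$bonds$to)] <- TRUE
    adj[cbind(structure$bonds$to, structure$bonds$from)] <- TRUE
  }
  hetero_nb <- vapply(seq_len(n), function(i)
    any(adj[i, ] & structure$element != "C"), logical(1))
  for (i in seq_len(n)) {
    s <- if (length(mcd$hyb) >= i) mcd$hyb[[i]] else NULL
    if (!is.null(s) && length(s) > 0L && !(p[i] %in% unname(pi_of[s]))) {
      add("hybridization", sprintf(
        "atom %d engages %d pi bonds, admissible states %s", i, p[i],
        paste(s, collapse = "/")))
    }
    flag <- (mcd$hetero %||% "undefined")[i]
    if (identical(flag, "forbidden") && hetero_nb[i]) {
      add("hetero_neighbor", sprintf("atom %d has a forbidden heteroatom neighbour", i))
    }
    if (identical(flag, "obligatory") && !hetero_nb[i]) {
      add("hetero_neighbor", sprintf("atom %d lacks an obligatory heteroatom neighbour", i))
    }
  }
  viol
}
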