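# Full blind-trial workflow: dereplicate first, then consistency triage,
# MCD construction, exhaustive generation, and 13C-deviation ranking.

#' Elucidate a structure from a formula and peak tables
#'
#' Runs the complete workflow in memory. Dereplication is attempted first
#' when a library is supplied: an exact hit (rank 1, score 0, nothing
#' unmatched) stops the run as "solved by library search" unless
#' `force_generate` is set. Otherwise the dataset must pass consistency
#' triage (reject-level issues abort), the molecular connectivity diagram
#' is built, all candidates consistent with it are generated, and the
#' candidates are ranked by mean absolute 13C deviation against the shift
#' database.
#'
#' @param dataset A `spectral_dataset`.
#' @param mf A `molecular_formula` (or formula string).
#' @param library Optional `structure_library` for dereplication.
#' @param db Optional `shift_db` for ranking (an empty one is used when
#'   NULL; all predictions then fall back to class baselines).
#' @param options A [generation_options()].
#' @param mcd_options Options passed to [build_mcd()].
#' @param derep_tol Dereplication shift tolerance, ppm (default 2).
#' @param force_generate Run generation even after an exact library hit.
#' @return Object of class `case_elucidation` with elements `solved_by`
#'   (`"library"` or `"generation"`), `derep`, `diagnostics`, `mcd`,
#'   `generation`, `ranking`.
#' @export
elucidate <- function(dataset, mf, library = NULL, db = NULL,
                      options = generation_options(),
                      mcd_options = list(), derep_tol = 2,
                      force_generate = FALSE) {
  if (is.character(mf)) mf <- parse_formula(mf)
  out <- list(mf = mf, solved_by = NA_character_, derep = NULL,
              diagnostics = NULL, mcd = NULL, generation = NULL,
              ranking = NULL)
  class(out) <- "case_elucidation"

  cshifts <- dataset$peaks$shift_ppm[dataset$peaks$nucleus == "C13"]
  if (!is.null(library) && length(cshifts) > 0L) {
    hits <- search_by_shifts(cshifts, library, tol = derep_tol)
    out$derep <- hits
    exact <- NROW(hits) > 0L && hits$score[1] == 0 &&
      hits$unmatched_query[1] == 0L && hits$unmatched_record[1] == 0L
    if (exact && !force_generate) {
      out$solved_by <- "library"
      return(out)
    }
  }

  out$diagnostics <- check_consistency(dataset, mf)
  if (has_reject(out$diagnostics)) {
    stop("dataset rejected: ",
         paste(out$diagnostics$issues$message[
           out$diagnostics$issues$severity == "reject"], collapse = "; "),
         call. = FALSE)
  }
  out$mcd <- build_mcd(mf, dataset, options = mcd_options)
  out$generation <- generate(out$mcd, options)
  if (length(out$generation$candidates) > 0L) {
    out$ranking <- rank_candidates(out$generation$candidates,
                                   db %||% shift_db())
  }
  out$solved_by <- "generation"
  out
}

#' @export
print.case_elucidation <- function(x, ...) {
  cat("<case_elucidation> ", format(x$mf), "\n", sep = "")
  if (identical(x$solved_by, "library")) {
    cat("  solved by library search: ", x$derep$id[1], " (score ",
        sprintf("%.3f", x$derep$score[1]), " ppm)\n", sep = "")
    return(invisible(x))
  }
  if (!is.null(x$derep) && NROW(x$derep) > 0L) {
    cat("  best library hit: ", x$derep$id[1], " (score ",
        sprintf("%.2f", x$derep$score[1]), " ppm, ",
        x$derep$unmatched_query[1], " unmatched)\n", sep = "")
  }
  if (!is.null(x$generation)) {
    cat("  ", length(x$generation$candidates), " candidates (",
        x$generation$status, ")\n", sep = "")
  }
  if (!is.null(x$ranking)) {
    cat("  top candidate d13C = ", sprintf("%.3f", x$ranking$table$d13c[1]),
        " ppm (", x$ranking$table$quality[1], ")\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.case_elucidation <- function(object, ...) {
  print(object)
  if (!is.null(object$diagnostics)) print(object$diagnostics)
  if (!is.null(object$ranking)) print(object$ranking)
  invisible(object)
}

#' Plot candidate ranking
#'
#' Bar plot of the mean absolute 13C deviation of the top candidates.
#'
#' @param x A `case_elucidation`.
#' @param n Number of candidates to show.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.case_elucidation <- function(x, n = 20L, ...) {
  if (is.null(x$ranking)) {
    stop("no ranking to plot (solved by library search?)", call. = FALSE)
  }
  tab <- utils::head(x$ranking$table, n)
  graphics::barplot(tab$d13c, names.arg = tab$rank,
                    xlab = "candidate rank", ylab = "d13C (ppm)", ...)
  graphics::abline(h = 2.2, lty = 2)
  invisible(x)
}

#' Run the elucidation workflow with file artifacts
#'
#' Thin orchestration over [elucidate()] for the command line: reads peak
#' tables, optionally a library (SDF) and a shift database (TSV), and
#' writes the MCD (JSON), candidates (SDF), ranking (CSV) and a plain-text
#' report into the output directory.
#'
#' @param config List: `mf` (formula string, required), `peaks` (character
#'   vector of peak-table paths, required), `format` ("csv"/"json"),
#'   `library` (SDF path), `db` (TSV path), `out_dir` (required),
#'   `max_structures`, `time_budget`, `nonstandard_hmbc`, `use_symmetry`,
#'   `seed`, `derep_tol`, `force_generate`. Unknown keys are rejected.
#' @return The `case_elucidation`, invisibly; artifacts on disk.
#' @export
run_elucidate <- function(config) {
  known <- c("mf", "peaks", "format", "library", "db", "out_dir",
             "max_structures", "time_budget", "nonstandard_hmbc",
             "use_symmetry", "seed", "derep_tol", "force_generate")
  extra <- setdiff(names(config), known)
  if (length(extra) > 0L) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  for (req in c("mf", "peaks", "out_dir")) {
    if (is.null(config[[req]])) stop("config key '", req, "' is required",
                                     call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  cat("resolved config:\n", jsonlite::toJSON(config, auto_unbox = TRUE,
                                             pretty = TRUE, digits = NA),
      "\n", file = logf, sep = "")

  dataset <- read_peak_tables(config$peaks, format = config$format %||% "csv")
  library <- if (!is.null(config$library)) read_library_sdf(config$library)
  db <- if (!is.null(config$db)) read_shift_db(config$db)
  opts <- generation_options(
    max_structures = config$max_structures %||% 20000L,
    time_budget = config$time_budget %||% Inf,
    nonstandard_hmbc = config$nonstandard_hmbc %||% FALSE,
    use_symmetry = config$use_symmetry %||% TRUE,
    seed = config$seed)
  res <- elucidate(dataset, config$mf, library = library, db = db,
                   options = opts,
                   mcd_options = list(nonstandard = opts$nonstandard_hmbc),
                   derep_tol = config$derep_tol %||% 2,
                   force_generate = isTRUE(config$force_generate))

  report <- file.path(config$out_dir, "report.txt")
  if (identical(res$solved_by, "library")) {
    writeLines(c(sprintf("solved by library search: %s", res$derep$id[1]),
                 utils::capture.output(print(res$derep))), report)
    return(invisible(res))
  }
  mcd_to_json(res$mcd, file.path(config$out_dir, "mcd.json"))
  if (!is.null(res$ranking)) {
    write_structures_sdf(res$ranking$structures,
                         file.path(config$out_dir, "candidates.sdf"),
                         ids = res$ranking$table$key)
    utils::write.csv(res$ranking$table,
                     file.path(config$out_dir, "ranking.csv"),
                     row.names = FALSE)
  }
  writeLines(utils::capture.output(summary(res)), report)
  invisible(res)
}

# --- curated example molecules ---------------------------------------------

#' Curated example molecules with assigned 13C shifts
#'
#' A small set of common small molecules hand-encoded as heavy-atom graphs
#' with approximate literature 13C chemical shifts, used for examples and
#' as realistic dereplication fixtures.
#'
#' @return Named list of `mol_graph` objects.
#' @export
example_molecules <- function() {
  b <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(from = m[, 1], to = m[, 2], order = m[, 3])
  }
  ring6 <- b(1,2,2, 2,3,1, 3,4,2, 4,5,1, 5,6,2, 6,1,1)  # Kekule benzene core
  list(
    ethanol = mol_graph(c("C", "C", "O"), c(3, 2, 1),
                        b(1,2,1, 2,3,1), shift = c(18.3, 57.8, NA)),
    dimethyl_ether = mol_graph(c("C", "O", "C"), c(3, 0, 3),
                               b(1,2,1, 2,3,1), shift = c(59.5, NA, 59.5)),
    acetone = mol_graph(c("C", "C", "O", "C"), c(3, 0, 0, 3),
                        b(1,2,1, 2,3,2, 2,4,1),
                        shift = c(30.8, 206.3, NA, 30.8)),
    acetic_acid = mol_graph(c("C", "C", "O", "O"), c(3, 0, 0, 1),
                            b(1,2,1, 2,3,2, 2,4,1),
                            shift = c(20.8, 178.1, NA, NA)),
    benzene = mol_graph(rep("C", 6), rep(1, 6), ring6,
                        shift = rep(128.4, 6)),
    toluene = mol_graph(c(rep("C", 6), "C"), c(0, 1, 1, 1, 1, 1, 3),
                        rbind(ring6, c(1, 7, 1)),
                        shift = c(137.8, 129.3, 128.5, 125.6, 128.5, 129.3,
                                  21.4)),
    phenol = mol_graph(c(rep("C", 6), "O"), c(0, 1, 1, 1, 1, 1, 1),
                       rbind(ring6, c(1, 7, 1)),
                       shift = c(155.4, 115.7, 130.1, 121.1, 130.1, 115.7,
                                 NA)),
    pyridine = mol_graph(c("N", rep("C", 5)), c(0, 1, 1, 1, 1, 1), ring6,
                         shift = c(NA, 149.9, 123.8, 136.0, 123.8, 149.9)),
    furan = mol_graph(c("O", "C", "C", "C", "C"), c(0, 1, 1, 1, 1),
                      b(1,2,1, 2,3,2, 3,4,1, 4,5,2, 5,1,1),
                      shift = c(NA, 142.8, 109.6, 109.6, 142.8)),
    ethyl_acetate = mol_graph(c("C", "C", "O", "O", "C", "C"),
                              c(3, 0, 0, 0, 2, 3),
                              b(1,2,1, 2,3,2, 2,4,1, 4,5,1, 5,6,1),
                              shift = c(21.0, 171.1, NA, NA, 60.4, 14.2)),
    p_xylene = mol_graph(c(rep("C", 6), "C", "C"),
                         c(0, 1, 1, 0, 1, 1, 3, 3),
                         rbind(ring6, c(1, 7, 1), c(4, 8, 1)),
                         shift = c(134.7, 129.1, 129.1, 134.7, 129.1, 129.1,
                                   20.9, 20.9)),
    cyclohexane = mol_graph(rep("C", 6), rep(2, 6),
                            b(1,2,1, 2,3,1, 3,4,1, 4,5,1, 5,6,1, 6,1,1),
                            shift = rep(26.9, 6))
  )
}

#' A C2-symmetric bis-aryl test scaffold
#'
#' Synthetic construction of a C2-symmetric molecule with formula
#' C20H20Br2N4O2 (two identical halves joined by a biaryl bond; each half
#' a substituted benzene carrying Br, a methoxy group, a nitrile and an
#' N-methylaminomethyl chain). Ten carbon environments for twenty carbons,
#' mirroring the coincident-shift situation of a C2-axis natural product.
#' The structure is a synthetic stand-in, not the natural product itself.
#'
#' @return A `mol_graph` (shifts unassigned).
#' @export
c2_symmetric_scaffold <- function() {
  # per-half layout (offset 0 / 14):
  #   1-6   ring carbons (Kekule), 1 = biaryl link position, 6 bears the ring H
  #   7     Br on c2
  #   8,9   methoxy O-CH3 on c3
  #   10,11 nitrile C%N on c4
  #   12,13,14 CH2-NH-CH3 chain on c5
  el_half <- c("C", "C", "C", "C", "C", "C", "Br", "O", "C", "C", "N",
               "C", "N", "C")
  h_half <- c(0, 0, 0, 0, 0, 1, 0, 0, 3, 0, 0, 2, 1, 3)
  mk_half <- function(off) {
    data.frame(
      from  = off + c(1, 2, 3, 4, 5, 6, 2, 3, 8, 4, 10, 5, 12, 13),
      to    = off + c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10, 11, 12, 13, 14),
      order =        c(2, 1, 2, 1, 2, 1, 1, 1, 1, 1, 3, 1, 1, 1))
  }
  bonds <- rbind(mk_half(0L), mk_half(14L),
                 data.frame(from = 1L, to = 15L, order = 1L))
  mol_graph(c(el_half, el_half), c(h_half, h_half), bonds)
}
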