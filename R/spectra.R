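# 1D peak lists, 2D correlation tables, their CSV/JSON dialects, and the
# data-quality triage that decides whether a dataset is fit for elucidation.

.c13_window <- c(-20, 250)
.h1_window <- c(-2, 20)
.n15_window <- c(-50, 900)

.experiments <- c("ONEBOND_CH", "LONGRANGE_CH", "COSY_HH", "LONGRANGE_NH")
# f1 is always the proton axis, f2 the heteronucleus (or second proton) axis
.f1_windows <- list(ONEBOND_CH = .h1_window, LONGRANGE_CH = .h1_window,
                    COSY_HH = .h1_window, LONGRANGE_NH = .h1_window)
.f2_windows <- list(ONEBOND_CH = .c13_window, LONGRANGE_CH = .c13_window,
                    COSY_HH = .h1_window, LONGRANGE_NH = .n15_window)
# experiment aliases normalized at parse time (HSQC-TOCSY/HETCOR family)
.experiment_aliases <- c(
  HSQC = "ONEBOND_CH", HMQC = "ONEBOND_CH", HETCOR = "ONEBOND_CH",
  "HSQC-DEPT" = "ONEBOND_CH", "HSQC-TOCSY" = "ONEBOND_CH",
  HMBC = "LONGRANGE_CH", COLOC = "LONGRANGE_CH", CIGAR = "LONGRANGE_CH",
  COSY = "COSY_HH", "DQF-COSY" = "COSY_HH", TOCSY = "COSY_HH",
  "N15-HMBC" = "LONGRANGE_NH")

.multiplicities <- c("C", "CH", "CH2", "CH3", "unknown")

empty_peaks <- function() {
  data.frame(nucleus = character(0), shift_ppm = numeric(0),
             intensity = numeric(0), multiplicity = character(0))
}

empty_correlations <- function() {
  data.frame(experiment = character(0), f1_ppm = numeric(0),
             f2_ppm = numeric(0), intensity = numeric(0),
             ambiguous = logical(0))
}

#' Construct a spectral dataset
#'
#' Container for tabulated 1D peaks and 2D correlations. 1D peaks carry
#' `nucleus` (`"C13"`/`"H1"`), `shift_ppm`, `intensity` and a `multiplicity`
#' label from DEPT/edited-HSQC (`C`, `CH`, `CH2`, `CH3` or `unknown`).
#' Correlations carry `experiment` (one-bond CH, long-range CH, COSY HH or
#' long-range NH; common experiment names such as HSQC/HMBC/COSY are
#' normalized), proton coordinate `f1_ppm`, partner coordinate `f2_ppm`,
#' `intensity` and an `ambiguous` flag. Shift windows are enforced:
#' 13C in \[-20, 250\] ppm, 1H in \[-2, 20\] ppm.
#'
#' @param peaks Data frame of 1D peaks (columns as above; intensity and
#'   multiplicity optional).
#' @param correlations Data frame of 2D correlations.
#' @param provenance Free-text description of the data source.
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(peaks = NULL, correlations = NULL,
                             provenance = "") {
  peaks <- normalize_peaks(peaks)
  correlations <- normalize_correlations(correlations)
  structure(list(peaks = peaks, correlations = correlations,
                 provenance = provenance),
            class = "spectral_dataset")
}

normalize_peaks <- function(peaks, source = "peaks") {
  if (is.null(peaks) || NROW(peaks) == 0L) return(empty_peaks())
  peaks <- as.data.frame(peaks)
  need <- c("nucleus", "shift_ppm")
  miss <- setdiff(need, names(peaks))
  if (length(miss) > 0L) {
    stop(source, ": missing mandatory column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(peaks$intensity)) peaks$intensity <- 1
  if (is.null(peaks$multiplicity)) peaks$multiplicity <- "unknown"
  peaks <- peaks[, c("nucleus", "shift_ppm", "intensity", "multiplicity")]
  peaks$nucleus <- toupper(as.character(peaks$nucleus))
  peaks$nucleus[peaks$nucleus %in% c("13C", "C")] <- "C13"
  peaks$nucleus[peaks$nucleus %in% c("1H", "H")] <- "H1"
  bad <- which(!peaks$nucleus %in% c("C13", "H1"))
  if (length(bad) > 0L) {
    stop(source, ": unknown nucleus '", peaks$nucleus[bad[1]], "' at row ",
         bad[1], call. = FALSE)
  }
  peaks$shift_ppm <- as.numeric(peaks$shift_ppm)
  peaks$intensity <- as.numeric(peaks$intensity)
  if (any(is.na(peaks$shift_ppm))) {
    stop(source, ": unparseable shift at row ",
         which(is.na(peaks$shift_ppm))[1], call. = FALSE)
  }
  if (any(peaks$intensity < 0, na.rm = TRUE)) {
    stop(source, ": negative intensity at row ",
         which(peaks$intensity < 0)[1], call. = FALSE)
  }
  win <- ifelse(peaks$nucleus == "C13", 1L, 2L)
  lo <- c(.c13_window[1], .h1_window[1])[win]
  hi <- c(.c13_window[2], .h1_window[2])[win]
  bad <- which(peaks$shift_ppm < lo | peaks$shift_ppm > hi)
  if (length(bad) > 0L) {
    stop(source, ": shift ", peaks$shift_ppm[bad[1]], " ppm outside the ",
         peaks$nucleus[bad[1]], " window at row ", bad[1], call. = FALSE)
  }
  peaks$multiplicity <- as.character(peaks$multiplicity)
  peaks$multiplicity[is.na(peaks$multiplicity) |
                       !peaks$multiplicity %in% .multiplicities] <- "unknown"
  rownames(peaks) <- NULL
  peaks
}

normalize_correlations <- function(correlations, source = "correlations") {
  if (is.null(correlations) || NROW(correlations) == 0L) {
    return(empty_correlations())
  }
  x <- as.data.frame(correlations)
  need <- c("experiment", "f1_ppm", "f2_ppm")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop(source, ": missing mandatory column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(x$intensity)) x$intensity <- 1
  if (is.null(x$ambiguous)) x$ambiguous <- FALSE
  x <- x[, c("experiment", "f1_ppm", "f2_ppm", "intensity", "ambiguous")]
  x$experiment <- toupper(as.character(x$experiment))
  alias <- .experiment_aliases[x$experiment]
  x$experiment[!is.na(alias)] <- alias[!is.na(alias)]
  bad <- which(!x$experiment %in% .experiments)
  if (length(bad) > 0L) {
    stop(source, ": unknown experiment '", x$experiment[bad[1]], "' at row ",
         bad[1], call. = FALSE)
  }
  x$f1_ppm <- as.numeric(x$f1_ppm)
  x$f2_ppm <- as.numeric(x$f2_ppm)
  x$intensity <- as.numeric(x$intensity)
  x$ambiguous <- as.logical(x$ambiguous)
  for (k in seq_len(NROW(x))) {
    w1 <- .f1_windows[[x$experiment[k]]]
    w2 <- .f2_windows[[x$experiment[k]]]
    if (is.na(x$f1_ppm[k]) || is.na(x$f2_ppm[k])) {
      stop(source, ": unparseable coordinate at row ", k, call. = FALSE)
    }
    if (x$f1_ppm[k] < w1[1] || x$f1_ppm[k] > w1[2]) {
      stop(source, ": f1 = ", x$f1_ppm[k], " ppm outside the proton window ",
           "for ", x$experiment[k], " at row ", k, call. = FALSE)
    }
    if (x$f2_ppm[k] < w2[1] || x$f2_ppm[k] > w2[2]) {
      stop(source, ": f2 = ", x$f2_ppm[k], " ppm outside the window for ",
           x$experiment[k], " at row ", k, call. = FALSE)
    }
  }
  rownames(x) <- NULL
  x
}

#' @export
print.spectral_dataset <- function(x, ...) {
  nC <- sum(x$peaks$nucleus == "C13")
  nH <- sum(x$peaks$nucleus == "H1")
  tab <- table(x$correlations$experiment)
  cat("<spectral_dataset> ", nC, " 13C peaks, ", nH, " 1H peaks",
      if (length(tab)) paste0("; ", paste(names(tab), tab, sep = ": ",
                                          collapse = ", ")) else "",
      "\n", sep = "")
  if (c13_only(x)) {
    cat("  13C-only dataset: dereplication possible, structure generation not\n")
  }
  invisible(x)
}

#' Is a dataset 13C-peaks-only?
#'
#' TRUE when the dataset holds a 13C peak list but no correlations and no
#' proton data; such data supports dereplication but not MCD construction.
#'
#' @param dataset A `spectral_dataset`.
#' @export
c13_only <- function(dataset) {
  sum(dataset$peaks$nucleus == "C13") > 0L &&
    NROW(dataset$correlations) == 0L &&
    sum(dataset$peaks$nucleus == "H1") == 0L
}

#' Read peak tables from CSV or JSON files
#'
#' Each file holds either a 1D peak table (columns
#' `nucleus,shift_ppm,intensity,multiplicity`) or a 2D correlation table
#' (columns `experiment,f1_ppm,f2_ppm,intensity,ambiguous`); the kind is
#' detected from the header. All shifts are ppm. Rows violating nucleus
#' windows are rejected with their row number.
#'
#' @param paths Character vector of file paths.
#' @param format `"csv"` or `"json"` (JSON mirrors the CSV schema as an
#'   array of row objects, or an object with `peaks`/`correlations` arrays).
#' @return A `spectral_dataset` combining all files.
#' @examples
#' # simulated example tables shipped with the package
#' paths <- system.file("extdata",
#'   c("simulated_ethyl_acetate_peaks.csv",
#'     "simulated_ethyl_acetate_correlations.csv"), package = "nmrcase")
#' read_peak_tables(paths)
#' @export
read_peak_tables <- function(paths, format = c("csv", "json")) {
  format <- match.arg(format)
  peaks <- empty_peaks()
  corrs <- empty_correlations()
  for (p in paths) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
    tabs <- if (format == "csv") {
      list(utils::read.csv(p, stringsAsFactors = FALSE))
    } else {
      obj <- jsonlite::fromJSON(p, simplifyDataFrame = TRUE)
      if (is.data.frame(obj)) list(obj) else
        Filter(function(t) NROW(t) > 0, obj[c("peaks", "correlations")])
    }
    for (tab in tabs) {
      if (all(c("nucleus", "shift_ppm") %in% names(tab))) {
        peaks <- rbind(peaks, normalize_peaks(tab, source = basename(p)))
      } else if (all(c("experiment", "f1_ppm", "f2_ppm") %in% names(tab))) {
        corrs <- rbind(corrs, normalize_correlations(tab, source = basename(p)))
      } else {
        stop(basename(p), ": table is neither a 1D peak list ",
             "(nucleus, shift_ppm) nor a 2D correlation table ",
             "(experiment, f1_ppm, f2_ppm)", call. = FALSE)
      }
    }
  }
  spectral_dataset(peaks, corrs, provenance = paste(paths, collapse = "; "))
}

#' Write peak tables
#'
#' Inverse of [read_peak_tables()]: writes the 1D peak list and the 2D
#' correlation table in the package CSV or JSON dialect.
#'
#' @param dataset A `spectral_dataset`.
#' @param peaks_path,correlations_path Output paths (either may be NULL to
#'   skip). For JSON, give `peaks_path` only; both tables go in one file.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, the paths written.
#' @export
write_peak_tables <- function(dataset, peaks_path = NULL,
                              correlations_path = NULL,
                              format = c("csv", "json")) {
  format <- match.arg(format)
  written <- character(0)
  if (format == "json") {
    stopifnot(!is.null(peaks_path))
    jsonlite::write_json(list(peaks = dataset$peaks,
                              correlations = dataset$correlations),
                         peaks_path, digits = NA, auto_unbox = TRUE)
    written <- peaks_path
  } else {
    if (!is.null(peaks_path)) {
      utils::write.csv(dataset$peaks, peaks_path, row.names = FALSE)
      written <- c(written, peaks_path)
    }
    if (!is.null(correlations_path)) {
      utils::write.csv(dataset$correlations, correlations_path,
                       row.names = FALSE)
      written <- c(written, correlations_path)
    }
  }
  invisible(written)
}

# --- consistency triage -----------------------------------------------------

#' Check a dataset against a molecular formula
#'
#' Rule-based triage mirroring the accept/reject decisions made on submitted
#' data: superfluous 13C signals (more distinct signals than carbons),
#' one-bond correlations implying more attached hydrogens than the formula
#' allows, 2D carbon coordinates matching no 1D carbon peak, and
#' near-degenerate duplicate signals. Always returns a report; severities
#' are `info`, `warn` and `reject` (rejects block MCD construction).
#'
#' The overall `purity_class` is set from the total number of incidences:
#' fewer than 5 is `good`, 5-10 `average`, 11-20 `poor`, more than 20 `bad`.
#'
#' @param dataset A `spectral_dataset`.
#' @param mf A `molecular_formula`.
#' @param tol_c Matching tolerance between 2D carbon coordinates and 1D 13C
#'   peaks, ppm (default 0.5).
#' @param dup_tol Two 13C peaks closer than this are reported as
#'   near-degenerate duplicates (default 0.05 ppm).
#' @return An object of class `nmr_diagnostics`: `issues` data frame
#'   (severity, code, message, count) and `purity_class`.
#' @export
check_consistency <- function(dataset, mf, tol_c = 0.5, dup_tol = 0.05) {
  stopifnot(inherits(dataset, "spectral_dataset"),
            inherits(mf, "molecular_formula"))
  issues <- data.frame(severity = character(0), code = character(0),
                       message = character(0), count = integer(0))
  add <- function(severity, code, message, count = 1L) {
    issues[nrow(issues) + 1L, ] <<- list(severity, code, message,
                                         as.integer(count))
  }
  cpeaks <- dataset$peaks[dataset$peaks$nucleus == "C13", , drop = FALSE]
  n_c <- formula_count(mf, "C")
  n_h <- formula_count(mf, "H")

  if (NROW(cpeaks) > 0L) {
    excess <- NROW(cpeaks) - n_c
    if (excess > 0L) {
      add("warn", "superfluous_signals",
          sprintf("%d distinct 13C signals for %d carbons in %s (%d superfluous)",
                  NROW(cpeaks), n_c, format(mf), excess), excess)
    }
    # near-degenerate duplicates
    sh <- sort(cpeaks$shift_ppm)
    ndup <- sum(diff(sh) < dup_tol)
    if (ndup > 0L) {
      add("info", "near_degenerate",
          sprintf("%d pairs of 13C signals closer than %.3g ppm", ndup,
                  dup_tol), ndup)
    }
  }

  # one-bond H budget: each distinct one-bond carbon coordinate implies >= 1
  # attached H; multiplicity labels sharpen the count when present
  ob <- dataset$correlations[
    dataset$correlations$experiment == "ONEBOND_CH", , drop = FALSE]
  if (NROW(cpeaks) > 0L) {
    mult_h <- c(C = 0L, CH = 1L, CH2 = 2L, CH3 = 3L, unknown = NA_integer_)
    imph <- mult_h[cpeaks$multiplicity]
    if (!anyNA(imph)) {
      if (sum(imph) > n_h) {
        add("reject", "h_budget",
            sprintf("multiplicities imply %d carbon-attached H but %s has only %d H",
                    sum(imph), format(mf), n_h))
      }
    } else if (NROW(ob) > 0L) {
      n_prot <- length(unique(round(ob$f2_ppm / tol_c)))
      if (n_prot > n_h) {
        add("reject", "h_budget",
            sprintf("one-bond data implies >= %d attached H but %s has only %d H",
                    n_prot, format(mf), n_h))
      }
    }
  }

  # 2D carbon coordinates with no matching 1D carbon
  c2d <- dataset$correlations[
    dataset$correlations$experiment %in% c("ONEBOND_CH", "LONGRANGE_CH"), ,
    drop = FALSE]
  if (NROW(c2d) > 0L && NROW(cpeaks) > 0L) {
    unmatched <- vapply(c2d$f2_ppm, function(f2) {
      min(abs(cpeaks$shift_ppm - f2)) > tol_c
    }, logical(1))
    if (any(unmatched)) {
      add("warn", "unmatched_correlation",
          sprintf("%d 2D carbon coordinates match no 1D 13C peak within %.2g ppm (e.g. %.2f ppm)",
                  sum(unmatched), tol_c, c2d$f2_ppm[which(unmatched)[1]]),
          sum(unmatched))
    }
  }

  incidences <- sum(issues$count)
  purity <- if (incidences < 5) "good" else if (incidences <= 10) "average"
            else if (incidences <= 20) "poor" else "bad"
  structure(list(issues = issues, purity_class = purity,
                 incidences = incidences),
            class = "nmr_diagnostics")
}

#' @export
print.nmr_diagnostics <- function(x, ...) {
  cat("<nmr_diagnostics> purity: ", x$purity_class, " (", x$incidences,
      " incidences)\n", sep = "")
  if (NROW(x$issues) == 0L) {
    cat("  no issues\n")
  } else {
    for (i in seq_len(NROW(x$issues))) {
      cat("  [", x$issues$severity[i], "] ", x$issues$code[i], ": ",
          x$issues$message[i], "\n", sep = "")
    }
  }
  invisible(x)
}

has_reject <- function(report) {
  any(report$issues$severity == "reject")
}
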