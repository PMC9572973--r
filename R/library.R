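# Reference-library storage: a flat TSV with one row per standard compound,
# list-valued UV peak columns pipe-separated, empty cell = attribute absent.

.library_columns <- c(
  "code", "name", "abbreviation", "compound_class", "rf_mpa", "rf_mpb",
  "hue_dev254", "hue_dev366", "hue_np366", "hue_vsa366", "hue_vsa_white",
  "fl_pre_max", "fl_pre_min", "uv_pre", "fl_np_max", "uv_np",
  "fl_vs_max", "uv_vs_max"
)

.hue_columns <- c("hue_dev254", "hue_dev366", "hue_np366",
                  "hue_vsa366", "hue_vsa_white")
.lambda_scalar_columns <- c("fl_pre_max", "fl_pre_min", "fl_np_max",
                            "fl_vs_max", "uv_vs_max")

.split_peaks <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(v)) return(numeric(0))
    p <- as.numeric(strsplit(v, "|", fixed = TRUE)[[1]])
    p[p != 0] # a printed 0 is a placeholder for an absent peak, never 0 nm
  })
}

.join_peaks <- function(x) {
  vapply(x, function(p) paste(p, collapse = "|"), character(1))
}

#' Load a reference library of standard compounds
#'
#' Reads a tab-separated library file (UTF-8, header row, one standard per
#' row; see Details) and validates every entry. UV peak-list columns are
#' pipe-separated; zeros and empty cells encode absent peaks and are never
#' stored as wavelengths.
#'
#' @details Required columns: `code`, `name`, `abbreviation`,
#' `compound_class`, `rf_mpa`, `rf_mpb`, `hue_dev254`, `hue_dev366`,
#' `hue_np366`, `hue_vsa366`, `hue_vsa_white`, `fl_pre_max`, `fl_pre_min`,
#' `uv_pre`, `fl_np_max`, `uv_np`, `fl_vs_max`, `uv_vs_max`. Validation
#' enforces unique contiguous codes, Rf in \[0, 1], hues in \[0, 360),
#' wavelengths in \[190, 900] nm, and ascending UV peak lists of length 1-3.
#'
#' @param source Path to a tab-separated library file.
#' @return A data frame of class `hptlc_library` with list columns `uv_pre`
#'   and `uv_np`.
#' @seealso [hptlc_library()] for the packaged 107-standard library,
#'   [write_library()] for the inverse operation.
#' @export
load_library <- function(source) {
  raw <- read.delim(source, sep = "\t", header = TRUE,
                    colClasses = "character", fileEncoding = "UTF-8",
                    check.names = FALSE)
  missing_cols <- setdiff(.library_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("library file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lib <- data.frame(
    code = as.integer(raw$code),
    name = raw$name,
    abbreviation = raw$abbreviation,
    compound_class = raw$compound_class,
    stringsAsFactors = FALSE
  )
  for (col in c("rf_mpa", "rf_mpb", .hue_columns, .lambda_scalar_columns)) {
    lib[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
    lib[[col]][!nzchar(trimws(ifelse(is.na(raw[[col]]), "", raw[[col]])))] <- NA_real_
  }
  lib$uv_pre <- .split_peaks(raw$uv_pre)
  lib$uv_np <- .split_peaks(raw$uv_np)
  lib <- lib[, .library_columns]
  class(lib) <- c("hptlc_library", "data.frame")
  validate_library(lib)
  lib
}

validate_library <- function(lib) {
  fail <- function(row, field, msg) {
    stop(sprintf("library validation: row %s (code %s), field '%s': %s",
                 row, lib$code[row], field, msg), call. = FALSE)
  }
  if (anyDuplicated(lib$code)) {
    dup <- lib$code[duplicated(lib$code)][1]
    stop("library validation: duplicate code ", dup, call. = FALSE)
  }
  if (!identical(sort(lib$code), seq_len(nrow(lib)))) {
    stop("library validation: codes must be contiguous 1..n", call. = FALSE)
  }
  for (i in seq_len(nrow(lib))) {
    for (col in c("rf_mpa", "rf_mpb")) {
      v <- lib[[col]][i]
      if (is.na(v) || v < 0 || v > 1) fail(i, col, "Rf must be in [0, 1]")
    }
    for (col in .hue_columns) {
      v <- lib[[col]][i]
      if (is.na(v) || v < 0 || v >= 360) fail(i, col, "hue must be in [0, 360)")
    }
    for (col in .lambda_scalar_columns) {
      v <- lib[[col]][i]
      if (!is.na(v) && (v < 190 || v > 900)) {
        fail(i, col, "wavelength must be in [190, 900] nm")
      }
    }
    for (col in c("uv_pre", "uv_np")) {
      p <- lib[[col]][[i]]
      if (col == "uv_pre" && (length(p) < 1 || length(p) > 3)) {
        fail(i, col, "need 1-3 UV maxima")
      }
      if (any(p < 190 | p > 900)) fail(i, col, "wavelength must be in [190, 900] nm")
      if (is.unsorted(p, strictly = TRUE) && length(p) > 1) {
        fail(i, col, "UV maxima must be ascending")
      }
    }
  }
  invisible(lib)
}

#' Write a reference library back to its TSV format
#'
#' Inverse of [load_library()]: `load_library(write_library(lib, f))` returns
#' entries identical field-for-field.
#'
#' @param lib An `hptlc_library`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  out <- as.data.frame(lib)
  out$uv_pre <- .join_peaks(lib$uv_pre)
  out$uv_np <- .join_peaks(lib$uv_np)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' The packaged reference library of 107 standards
#'
#' Loads the library of chromatographic and spectral signatures distributed
#' with the package: 107 phenolic and related standards (flavonoids,
#' hydroxybenzoic/hydroxycinnamic acid derivatives, simple phenols and a few
#' non-phenolic honey constituents), each with Rf values in two mobile phases
#' (MPA = toluene:ethyl acetate:formic acid 2:8:1, MPB = 6:5:1), hue angles
#' under five imaging conditions, fluorescence maxima/minima and UV-Vis
#' maxima before derivatisation, and fluorescence/UV-Vis maxima after NP-PEG
#' and after vanillin-sulfuric-acid (VSA) derivatisation.
#'
#' @return An `hptlc_library` with 107 entries.
#' @examples
#' lib <- hptlc_library()
#' summary(lib)
#' @export
hptlc_library <- function() {
  load_library(system.file("extdata", "phenolic_standards.tsv",
                           package = "hptlcID", mustWork = TRUE))
}

#' @export
print.hptlc_library <- function(x, ...) {
  cat("HPTLC reference library:", nrow(x), "standards,",
      length(unique(x$compound_class)), "compound classes\n")
  NextMethod()
}

#' Summarise a reference library
#'
#' Reports the entry count, the exact Rf extrema per mobile phase, the
#' histogram of UV-Vis peak counts (1, 2 or 3 maxima per standard) and the
#' hue extrema per imaging condition.
#'
#' @param object An `hptlc_library`.
#' @param ... Unused.
#' @return A list of class `hptlc_summary`.
#' @export
summary.hptlc_library <- function(object, ...) {
  if (nrow(object) == 0) stop("cannot summarise an empty library", call. = FALSE)
  npk <- lengths(object$uv_pre)
  hist <- vapply(1:3, function(k) sum(npk == k), integer(1))
  names(hist) <- as.character(1:3)
  stopifnot(sum(hist) == nrow(object))
  res <- list(
    n_entries = nrow(object),
    rf_range = list(MPA = range(object$rf_mpa), MPB = range(object$rf_mpb)),
    uv_peak_histogram = hist,
    hue_range = lapply(object[.hue_columns], range)
  )
  class(res) <- "hptlc_summary"
  res
}

#' @export
print.hptlc_summary <- function(x, ...) {
  cat("Library of", x$n_entries, "standards\n")
  cat(sprintf("  Rf (MPA): %.3f - %.3f\n", x$rf_range$MPA[1], x$rf_range$MPA[2]))
  cat(sprintf("  Rf (MPB): %.3f - %.3f\n", x$rf_range$MPB[1], x$rf_range$MPB[2]))
  cat("  UV-Vis peak counts:",
      paste(sprintf("%s peak(s): %d", names(x$uv_peak_histogram),
                    x$uv_peak_histogram), collapse = ", "), "\n")
  for (h in names(x$hue_range)) {
    cat(sprintf("  hue %-13s %6.1f - %6.1f deg\n", paste0(h, ":"),
                x$hue_range[[h]][1], x$hue_range[[h]][2]))
  }
  invisible(x)
}

.view_table <- data.frame(
  label = c("1A", "1B", "2A", "2B"),
  mobile_phase = c("MPA", "MPA", "MPB", "MPB"),
  derivatisation = c("NP-PEG", "VSA", "NP-PEG", "VSA"),
  stringsAsFactors = FALSE
)

#' Select one of the four database views
#'
#' The library is consulted through four views, one per combination of mobile
#' phase and derivatisation reagent: 1A = (MPA, NP-PEG), 1B = (MPA, VSA),
#' 2A = (MPB, NP-PEG), 2B = (MPB, VSA). A view projects each entry onto the
#' attributes its cascade filters on: the Rf of its mobile phase, the shared
#' pre-derivatisation hues and spectra summaries, and the post-derivatisation
#' fields of its reagent. Views project; they never drop entries.
#'
#' @param library An `hptlc_library`.
#' @param label One of `"1A"`, `"1B"`, `"2A"`, `"2B"`.
#' @param codes Optional integer codes restricting the view to a candidate
#'   subset (e.g. the survivors of an Rf pre-filter recorded on a specific
#'   plate run).
#' @return A list of class `hptlc_view` with elements `label`,
#'   `mobile_phase`, `derivatisation` and `entries`.
#' @export
select_view <- function(library, label, codes = NULL) {
  row <- .view_table[.view_table$label == label, ]
  if (nrow(row) != 1) {
    stop("unknown view label '", label, "' (use 1A, 1B, 2A or 2B)", call. = FALSE)
  }
  entries <- as.data.frame(library)
  entries$rf <- if (row$mobile_phase == "MPA") entries$rf_mpa else entries$rf_mpb
  keep <- c("code", "name", "abbreviation", "compound_class", "rf",
            "hue_dev254", "hue_dev366", "fl_pre_max", "fl_pre_min", "uv_pre")
  keep <- if (row$derivatisation == "NP-PEG") {
    c(keep, "hue_np366", "fl_np_max", "uv_np")
  } else {
    c(keep, "hue_vsa366", "hue_vsa_white", "fl_vs_max", "uv_vs_max")
  }
  entries <- entries[, keep]
  if (!is.null(codes)) {
    missing <- setdiff(codes, entries$code)
    if (length(missing) > 0) {
      stop("codes not in library: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    entries <- entries[match(codes, entries$code), ]
    rownames(entries) <- NULL
  }
  structure(list(label = row$label, mobile_phase = row$mobile_phase,
                 derivatisation = row$derivatisation, entries = entries),
            class = "hptlc_view")
}

#' @export
print.hptlc_view <- function(x, ...) {
  cat(sprintf("Database view %s (%s, %s): %d candidate standards\n",
              x$label, x$mobile_phase, x$derivatisation, nrow(x$entries)))
  invisible(x)
}
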