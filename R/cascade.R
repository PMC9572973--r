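# The cascading tolerance filter: an ordered sequence of conjunctive
# predicates, each comparing one band attribute against every remaining
# candidate. Stages are independent, so the final survivor set is the plain
# conjunction over all stages; the ordered trace exists for auditability.

#' Filtering tolerances for the candidate cascade
#'
#' Defaults are the validated operating tolerances of the method: Rf
#' plus/minus 0.05 (inter-run Rf drift), hue plus/minus 60 degrees,
#' fluorescence and pre-derivatisation UV-Vis maxima plus/minus 15 nm, and
#' post-derivatisation UV-Vis maxima plus/minus 60 nm (derivatisation and pH
#' shifts cause larger bathochromic/hypsochromic displacement). All bounds
#' are inclusive. Hue comparison is circular unless `wrap_hue = FALSE`.
#'
#' @param rf_tol Rf tolerance (unitless, default 0.05).
#' @param hue_tol Hue tolerance in degrees (default 60).
#' @param lambda_tol Wavelength tolerance in nm for fluorescence and
#'   pre-derivatisation UV-Vis maxima (default 15).
#' @param uv_post_tol Wavelength tolerance in nm for post-derivatisation
#'   UV-Vis maxima (default 60).
#' @param wrap_hue Compare hues around the colour circle (default `TRUE`).
#' @return A list of class `hptlc_thresholds`.
#' @export
hptlc_thresholds <- function(rf_tol = 0.05, hue_tol = 60, lambda_tol = 15,
                             uv_post_tol = 60, wrap_hue = TRUE) {
  vals <- c(rf_tol = rf_tol, hue_tol = hue_tol, lambda_tol = lambda_tol,
            uv_post_tol = uv_post_tol)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("tolerances must be finite and >= 0", call. = FALSE)
  }
  structure(list(rf_tol = rf_tol, hue_tol = hue_tol, lambda_tol = lambda_tol,
                 uv_post_tol = uv_post_tol, wrap_hue = isTRUE(wrap_hue)),
            class = "hptlc_thresholds")
}

# stage name -> band/entry field, tolerance slot and comparison kind
.stage_defs <- function() {
  data.frame(
    stage = c("rf", "hue_dev254", "hue_dev366", "hue_np366", "hue_vsa366",
              "hue_vsa_white", "fl_pre_max", "fl_pre_min", "uv_pre_lambda",
              "uv_pre_peaks", "fl_np_max", "uv_np_max", "fl_vs_max",
              "uv_vs_max"),
    band_field = c("rf", "hue_dev254", "hue_dev366", "hue_np366", "hue_vsa366",
                   "hue_vsa_white", "fl_pre_max", "fl_pre_min", "uv_pre",
                   "uv_pre", "fl_np_max", "uv_np_max", "fl_vs_max",
                   "uv_vs_max"),
    entry_field = c("rf", "hue_dev254", "hue_dev366", "hue_np366", "hue_vsa366",
                    "hue_vsa_white", "fl_pre_max", "fl_pre_min", "uv_pre",
                    "uv_pre", "fl_np_max", "uv_np", "fl_vs_max",
                    "uv_vs_max"),
    tol_slot = c("rf_tol", rep("hue_tol", 5), rep("lambda_tol", 4),
                 "lambda_tol", "uv_post_tol", "lambda_tol", "uv_post_tol"),
    kind = c("interval", rep("hue", 5), "interval", "interval", "first_peak",
             "peak_list", "interval", "first_peak_entry", "interval",
             "interval"),
    stringsAsFactors = FALSE
  )
}

#' Ordered filter stages for a database view
#'
#' A views (NP-PEG derivatisation) run 10 stages: Rf, the three hue filters
#' (254 nm, 366 nm, post-NP-PEG 366 nm), fluorescence maximum and minimum,
#' UV-Vis first maximum, UV-Vis peak count, post-derivatisation fluorescence
#' maximum and post-derivatisation UV-Vis maximum. B views (VSA) run 11
#' stages: the post-derivatisation hue filter is replaced by the two VSA hue
#' filters (366 nm and white light), and the post-derivatisation spectral
#' filters use the VSA fields. The fluorescence minimum is only recorded
#' before derivatisation, so no post-derivatisation minimum stage exists.
#'
#' @param view_label One of `"1A"`, `"1B"`, `"2A"`, `"2B"`.
#' @return Character vector of stage names.
#' @export
stage_sequence <- function(view_label) {
  if (!view_label %in% .view_table$label) {
    stop("unknown view label '", view_label, "'", call. = FALSE)
  }
  pre <- c("rf", "hue_dev254", "hue_dev366")
  mid <- c("fl_pre_max", "fl_pre_min", "uv_pre_lambda", "uv_pre_peaks")
  if (view_label %in% c("1A", "2A")) {
    c(pre, "hue_np366", mid, "fl_np_max", "uv_np_max")
  } else {
    c(pre, "hue_vsa366", "hue_vsa_white", mid, "fl_vs_max", "uv_vs_max")
  }
}

#' Tolerance-interval predicate
#'
#' `TRUE` when `|query - candidate| <= tol`, boundary inclusive. With
#' `circular = TRUE` the difference is the circular hue distance (see
#' [hue_distance()]). Vectorised over `candidate`.
#'
#' @param query_value Measured band value.
#' @param candidate_value Library value(s).
#' @param tol Inclusive tolerance.
#' @param circular Compare on the hue circle.
#' @return Logical vector; `NA` candidate values compare `FALSE`.
#' @export
passes_interval <- function(query_value, candidate_value, tol, circular = FALSE) {
  d <- if (circular) {
    hue_distance(query_value, ifelse(is.na(candidate_value), 0, candidate_value))
  } else {
    abs(query_value - candidate_value)
  }
  out <- d <= tol
  out[is.na(candidate_value)] <- FALSE
  out
}

#' UV-Vis peak-list predicate
#'
#' A candidate's UV-Vis maxima match the query's when both lists have the
#' same number of peaks and each positionally paired maximum (both sorted
#' ascending) agrees within the tolerance. A one-peak query therefore
#' eliminates all two- and three-peak candidates outright.
#'
#' @param query_peaks,candidate_peaks Ascending numeric vectors of maxima (nm).
#' @param tol Inclusive tolerance in nm.
#' @return Logical scalar.
#' @export
passes_uv_peaks <- function(query_peaks, candidate_peaks, tol) {
  if (length(query_peaks) == 0 || length(candidate_peaks) == 0) return(FALSE)
  if (length(query_peaks) != length(candidate_peaks)) return(FALSE)
  all(abs(sort(query_peaks) - sort(candidate_peaks)) <= tol)
}

#' Construct a band observation
#'
#' The attribute slots mirror a library entry's view projection; all are
#' optional except `rf` (the primary filter cannot run without it, though a
#' cascade may be started from a recorded Rf-survivor list via the `stages`
#' argument of [run_cascade()]). `uv_pre` is the ascending list of UV-Vis
#' maxima; `uv_np_max`/`uv_vs_max` are the post-derivatisation first maxima.
#'
#' @param rf Retention factor in \[0, 1].
#' @param hue_dev254,hue_dev366,hue_np366,hue_vsa366,hue_vsa_white Hue angles
#'   in degrees, \[0, 360).
#' @param fl_pre_max,fl_pre_min Fluorescence maximum/minimum (nm) before
#'   derivatisation.
#' @param uv_pre Ascending UV-Vis maxima (nm) before derivatisation.
#' @param fl_np_max,uv_np_max Post-NP-PEG fluorescence/UV-Vis maxima (nm).
#' @param fl_vs_max,uv_vs_max Post-VSA fluorescence/UV-Vis maxima (nm).
#' @param spectra Optional named list of [band_spectrum()] objects.
#' @return A list of class `band_observation`.
#' @export
band_observation <- function(rf = NULL, hue_dev254 = NULL, hue_dev366 = NULL,
                             hue_np366 = NULL, hue_vsa366 = NULL,
                             hue_vsa_white = NULL, fl_pre_max = NULL,
                             fl_pre_min = NULL, uv_pre = NULL,
                             fl_np_max = NULL, uv_np_max = NULL,
                             fl_vs_max = NULL, uv_vs_max = NULL,
                             spectra = NULL) {
  b <- list(rf = rf, hue_dev254 = hue_dev254, hue_dev366 = hue_dev366,
            hue_np366 = hue_np366, hue_vsa366 = hue_vsa366,
            hue_vsa_white = hue_vsa_white, fl_pre_max = fl_pre_max,
            fl_pre_min = fl_pre_min, uv_pre = uv_pre, fl_np_max = fl_np_max,
            uv_np_max = uv_np_max, fl_vs_max = fl_vs_max,
            uv_vs_max = uv_vs_max, spectra = spectra)
  if (!is.null(rf) && (rf < 0 || rf > 1)) {
    stop("rf must be in [0, 1]", call. = FALSE)
  }
  hues <- c("hue_dev254", "hue_dev366", "hue_np366", "hue_vsa366", "hue_vsa_white")
  for (h in hues) {
    v <- b[[h]]
    if (!is.null(v) && (v < 0 || v >= 360)) {
      stop(h, " must be in [0, 360)", call. = FALSE)
    }
  }
  for (l in c("fl_pre_max", "fl_pre_min", "fl_np_max", "uv_np_max",
              "fl_vs_max", "uv_vs_max")) {
    v <- b[[l]]
    if (!is.null(v) && (v < 190 || v > 900)) {
      stop(l, " must be in [190, 900] nm", call. = FALSE)
    }
  }
  if (!is.null(uv_pre)) {
    if (length(uv_pre) < 1 || length(uv_pre) > 3 ||
        any(uv_pre < 190 | uv_pre > 900) ||
        (length(uv_pre) > 1 && is.unsorted(uv_pre, strictly = TRUE))) {
      stop("uv_pre must be 1-3 ascending wavelengths in [190, 900] nm",
           call. = FALSE)
    }
  }
  class(b) <- "band_observation"
  b
}

#' Read a band observation from a YAML key-value file
#'
#' Keys mirror the library schema (`rf`, `hue_dev254`, ..., `uv_pre` as a
#' list, `fl_np_max`, `uv_np_max`, `fl_vs_max`, `uv_vs_max`).
#'
#' @param path Path to a YAML file.
#' @return A `band_observation`.
#' @export
read_band <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- setdiff(names(formals(band_observation)), "spectra")
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown band attribute(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(band_observation, lapply(vals, function(v) {
    if (length(v) > 1) as.numeric(unlist(v)) else as.numeric(v)
  }))
}

.band_value <- function(band, field) {
  v <- band[[field]]
  if (is.null(v) || length(v) == 0 || all(is.na(v))) NULL else v
}

.stage_tol <- function(def, thresholds) thresholds[[def$tol_slot]]

# one stage applied to a view's entries; returns logical keep vector
.apply_stage <- function(def, band, entries, thresholds) {
  q <- .band_value(band, def$band_field)
  ev <- entries[[def$entry_field]]
  tol <- .stage_tol(def, thresholds)
  switch(def$kind,
    interval = passes_interval(q, ev, tol, circular = FALSE),
    hue = passes_interval(q, ev, tol, circular = thresholds$wrap_hue),
    first_peak = { # query's first UV maximum vs candidate's first
      first <- vapply(ev, function(p) if (length(p)) p[1] else NA_real_,
                      numeric(1))
      passes_interval(q[1], first, tol)
    },
    first_peak_entry = { # scalar query vs candidate's first listed maximum
      first <- vapply(ev, function(p) if (length(p)) p[1] else NA_real_,
                      numeric(1))
      passes_interval(q, first, tol)
    },
    peak_list = vapply(ev, function(p) passes_uv_peaks(q, p, tol), logical(1)),
    stop("unknown stage kind: ", def$kind)
  )
}

#' Run the tolerance-filter cascade for a band against a database view
#'
#' Applies the view's stage sequence in order; each stage keeps only the
#' candidates whose library value lies within the stage tolerance of the
#' band's measured value. Stages for which the band carries no measurement
#' are skipped with a warning. The returned trace records, per stage, the
#' attribute compared, the tolerance, the surviving candidate codes and
#' their count; survivor sets are nested by construction.
#'
#' @param band A [band_observation()].
#' @param view An [select_view()] result, optionally restricted to a recorded
#'   candidate subset.
#' @param thresholds An [hptlc_thresholds()] object.
#' @param stages Stage names to apply, in order (default: the view's full
#'   [stage_sequence()]). Passing a suffix of the sequence lets a cascade
#'   resume from a recorded earlier stage, e.g. from a plate run's Rf
#'   survivor list when the run's Rf values differ from the reference run's.
#' @return A data frame of class `filter_trace` with columns `stage`,
#'   `threshold`, `n` and `survivors` (comma-separated codes); the final
#'   survivor codes are in `attr(, "final")` and via [final_matches()].
#' @export
run_cascade <- function(band, view, thresholds = hptlc_thresholds(),
                        stages = stage_sequence(view$label)) {
  if (!inherits(band, "band_observation")) {
    stop("band must be a band_observation", call. = FALSE)
  }
  if (!inherits(view, "hptlc_view")) stop("view must be an hptlc_view", call. = FALSE)
  if (nrow(view$entries) == 0) stop("view has no candidate entries", call. = FALSE)
  full <- stage_sequence(view$label)
  bad <- setdiff(stages, full)
  if (length(bad) > 0) {
    stop("stage(s) not in view ", view$label, "'s sequence: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if ("rf" %in% stages && is.null(.band_value(band, "rf"))) {
    stop("band has no Rf value; the primary filter cannot run", call. = FALSE)
  }
  defs <- .stage_defs()
  entries <- view$entries
  keep <- rep(TRUE, nrow(entries))
  rows <- list()
  for (st in stages) {
    def <- defs[defs$stage == st, ]
    q <- .band_value(band, def$band_field)
    if (is.null(q)) {
      warning("band has no value for stage '", st, "'; stage skipped",
              call. = FALSE)
      next
    }
    pass <- .apply_stage(def, band, entries, thresholds)
    keep <- keep & pass
    rows[[length(rows) + 1L]] <- data.frame(
      stage = st,
      threshold = if (def$kind == "peak_list") NA_real_ else .stage_tol(def, thresholds),
      n = sum(keep),
      survivors = paste(entries$code[keep], collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) stop("no stage could be applied", call. = FALSE)
  trace <- do.call(rbind, rows)
  attr(trace, "final") <- entries$code[keep]
  attr(trace, "view") <- view$label
  class(trace) <- c("filter_trace", "data.frame")
  trace
}

#' Final surviving candidate codes of a cascade
#'
#' @param trace A `filter_trace` from [run_cascade()].
#' @return Integer vector of candidate codes.
#' @export
final_matches <- function(trace) {
  stopifnot(inherits(trace, "filter_trace"))
  attr(trace, "final")
}

#' @export
print.filter_trace <- function(x, ...) {
  cat("Cascade trace (view ", attr(x, "view"), "):\n", sep = "")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-14s (tol %s): %3d candidate(s)\n", x$stage[i],
                ifelse(is.na(x$threshold[i]), "peak count",
                       format(x$threshold[i])), x$n[i]))
  }
  fin <- attr(x, "final")
  cat("  potential matches:",
      if (length(fin)) paste(fin, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Write a cascade trace as a delimited table
#'
#' One row per stage: stage name, threshold, survivor count and
#' comma-separated survivor codes.
#'
#' @param trace A `filter_trace`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  write.table(as.data.frame(trace), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
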