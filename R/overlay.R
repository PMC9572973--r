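# Spectral overlay scoring: clip both spectra to a comparison window,
# normalise each to its windowed maximum, interpolate the reference onto the
# unknown's wavelength grid, then score with Pearson correlation and the
# share of points falling inside a fixed absorbance band.

#' Construct a spectrum
#'
#' @param wavelength Strictly increasing wavelengths in nm (>= 2 samples).
#' @param intensity Finite intensities in AU, same length.
#' @param modality `"UV-Vis"` or `"fluorescence"`.
#' @param state Derivatisation state: `"pre"`, `"NP-PEG"` or `"VSA"`.
#' @return A list of class `spectrum`.
#' @export
band_spectrum <- function(wavelength, intensity,
                     modality = c("UV-Vis", "fluorescence"),
                     state = c("pre", "NP-PEG", "VSA")) {
  modality <- match.arg(modality)
  state <- match.arg(state)
  if (length(wavelength) != length(intensity)) {
    stop("wavelength and intensity lengths differ", call. = FALSE)
  }
  if (length(wavelength) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(!is.finite(wavelength)) || any(!is.finite(intensity))) {
    stop("samples must be finite", call. = FALSE)
  }
  if (is.unsorted(wavelength, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  structure(list(wavelength = as.numeric(wavelength),
                 intensity = as.numeric(intensity),
                 modality = modality, state = state),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("%s spectrum (%s): %d samples, %.0f-%.0f nm\n", x$modality,
              x$state, length(x$wavelength), min(x$wavelength),
              max(x$wavelength)))
  invisible(x)
}

#' Read a densitometer spectrum export
#'
#' Parses a two-column delimited file (wavelength nm, intensity AU),
#' comma- or tab-separated, with an optional single header line. Rows are
#' sorted by wavelength; duplicate wavelengths and non-numeric rows are
#' rejected with the offending line number.
#'
#' @param source File path.
#' @inheritParams band_spectrum
#' @return A `spectrum`.
#' @export
read_spectrum <- function(source, modality = c("UV-Vis", "fluorescence"),
                          state = c("pre", "NP-PEG", "VSA")) {
  lines <- readLines(source, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty spectrum file: ", source, call. = FALSE)
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  parse_row <- function(l) suppressWarnings(as.numeric(strsplit(l, sep)[[1]][1:2]))
  first <- parse_row(lines[[1]])
  start <- if (any(is.na(first))) 2L else 1L # tolerate one header line
  if (length(lines) - start + 1L < 2L) {
    stop("spectrum file needs at least 2 data rows: ", source, call. = FALSE)
  }
  vals <- lapply(seq.int(start, length(lines)), function(i) {
    v <- parse_row(lines[[i]])
    if (any(is.na(v))) {
      stop(sprintf("non-numeric spectrum row at line %d of %s", i, source),
           call. = FALSE)
    }
    v
  })
  m <- do.call(rbind, vals)
  if (anyDuplicated(m[, 1])) {
    stop("duplicate wavelength in ", source, ": ",
         m[duplicated(m[, 1]), 1][1], " nm", call. = FALSE)
  }
  o <- order(m[, 1])
  band_spectrum(m[o, 1], m[o, 2], modality = modality, state = state)
}

#' Write a spectrum as a two-column CSV
#'
#' @param s A `spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  writeLines(sprintf("%.17g,%.17g", s$wavelength, s$intensity), path)
  invisible(path)
}

#' Default comparison windows per spectrum kind
#'
#' UV-Vis before derivatisation and after NP-PEG: 250-500 nm (mobile-phase
#' solvents interfere below 250 nm). UV-Vis after VSA: 230-600 nm.
#' Fluorescence: 210-270 nm, the emission region carrying the discriminating
#' structure. All windows are configurable wherever they are consumed.
#'
#' @return Named list of `c(low, high)` pairs: `uv_pre`, `uv_np`, `uv_vs`,
#'   `fl`.
#' @export
default_windows <- function() {
  list(uv_pre = c(250, 500), uv_np = c(250, 500), uv_vs = c(230, 600),
       fl = c(210, 270))
}

#' Restrict a spectrum to a comparison window
#'
#' Keeps samples with wavelength in `[low, high]`, inclusive. Fails if fewer
#' than 2 samples fall inside the window.
#'
#' @param s A `spectrum`.
#' @param window Numeric `c(low, high)`, low < high, in nm.
#' @return The clipped `spectrum`.
#' @export
clip_spectrum <- function(s, window) {
  stopifnot(inherits(s, "spectrum"), length(window) == 2)
  if (window[1] >= window[2]) stop("window must satisfy low < high", call. = FALSE)
  keep <- s$wavelength >= window[1] & s$wavelength <= window[2]
  if (sum(keep) < 2) {
    stop(sprintf("window %g-%g nm overlaps the sampled range by < 2 samples",
                 window[1], window[2]), call. = FALSE)
  }
  band_spectrum(s$wavelength[keep], s$intensity[keep], s$modality, s$state)
}

#' Normalise a spectrum to its maximum
#'
#' Divides every intensity by the maximum intensity so the maximum becomes
#' exactly 1. Apply after clipping: the reference point is the windowed
#' maximum, not the global one. Idempotent.
#'
#' @param s A `spectrum`.
#' @return The normalised `spectrum`.
#' @export
normalise_spectrum <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  m <- max(s$intensity)
  if (m <= 0) stop("cannot normalise: maximum intensity is not positive",
                   call. = FALSE)
  band_spectrum(s$wavelength, s$intensity / m, s$modality, s$state)
}

#' Align a reference spectrum onto an unknown's wavelength grid
#'
#' Linearly interpolates the standard's intensities at the unknown's
#' wavelengths, restricted to the overlap of the two sampled ranges.
#'
#' @param unknown,standard `spectrum` objects.
#' @return Data frame with columns `wavelength`, `unknown`, `standard`.
#' @export
align_spectra <- function(unknown, standard) {
  stopifnot(inherits(unknown, "spectrum"), inherits(standard, "spectrum"))
  lo <- max(min(unknown$wavelength), min(standard$wavelength))
  hi <- min(max(unknown$wavelength), max(standard$wavelength))
  keep <- unknown$wavelength >= lo & unknown$wavelength <= hi
  if (sum(keep) < 2) {
    stop("spectra overlap at fewer than 2 of the unknown's samples",
         call. = FALSE)
  }
  wl <- unknown$wavelength[keep]
  std <- approx(standard$wavelength, standard$intensity, xout = wl,
                method = "linear", ties = "ordered")$y
  data.frame(wavelength = wl, unknown = unknown$intensity[keep],
             standard = std)
}

#' Score the overlay of an unknown band spectrum against a standard
#'
#' Both spectra are clipped to the comparison window and normalised to their
#' windowed maxima; the standard is interpolated onto the unknown's grid.
#' Two statistics are reported: the Pearson correlation of the paired
#' normalised intensities, and the percentage of the unknown's points whose
#' normalised intensity lies within plus/minus `band` absorbance units of the
#' standard's at the same wavelength.
#'
#' @param unknown,standard `spectrum` objects.
#' @param window Comparison window `c(low, high)` in nm (default: the
#'   [default_windows()] entry for the standard's modality and state).
#' @param band Half-width of the acceptance band on normalised absorbance
#'   (default 0.125 AU).
#' @param candidate Optional candidate code carried into the result.
#' @return A list of class `overlay_result`: `candidate`, `state`,
#'   `pearson_r`, `percent_within`, `n_points`, `window`.
#' @export
score_overlay <- function(unknown, standard, window = NULL, band = 0.125,
                          candidate = NA) {
  if (is.null(window)) {
    window <- if (standard$modality == "fluorescence") {
      default_windows()$fl
    } else {
      switch(standard$state, pre = default_windows()$uv_pre,
             `NP-PEG` = default_windows()$uv_np, VSA = default_windows()$uv_vs)
    }
  }
  u <- normalise_spectrum(clip_spectrum(unknown, window))
  s <- normalise_spectrum(clip_spectrum(standard, window))
  pairs <- align_spectra(u, s)
  if (stats::sd(pairs$unknown) == 0 || stats::sd(pairs$standard) == 0) {
    stop("correlation undefined for a constant spectrum", call. = FALSE)
  }
  r <- cor(pairs$unknown, pairs$standard, method = "pearson")
  within <- abs(pairs$unknown - pairs$standard) <= band
  structure(list(candidate = candidate, state = standard$state,
                 pearson_r = r,
                 percent_within = 100 * mean(within),
                 n_points = nrow(pairs), window = window),
            class = "overlay_result")
}

#' @export
print.overlay_result <- function(x, ...) {
  cat(sprintf(
    "overlay vs candidate %s (%s, %g-%g nm): r = %.3f, %.1f%% within band (n = %d)\n",
    x$candidate, x$state, x$window[1], x$window[2], x$pearson_r,
    x$percent_within, x$n_points))
  invisible(x)
}

#' Decision rules for selecting among shortlisted candidates
#'
#' @param band Half-width of the absorbance acceptance band (default 0.125 AU).
#' @param corr_diff Minimum top-1 vs top-2 correlation gap that separates
#'   candidates (default 0.100; the gap must be strictly greater).
#' @param pct_diff Minimum top-1 vs top-2 percent-within gap, in percentage
#'   points (default 10; strictly greater).
#' @param sequence Order in which spectrum states are consulted. Default:
#'   UV-Vis pre-derivatisation, UV-Vis post-NP-PEG, UV-Vis post-VSA, then the
#'   fluorescence states, which are consulted only when the UV-Vis overlays
#'   fail to separate the candidates.
#' @param floors Optional named vector `c(r_min = , pct_min = )`: absolute
#'   minima a winning candidate must meet on its decisive state. The default
#'   (`r_min` 0.8, `pct_min` 50) rejects bands whose best match still overlays
#'   poorly; set to `NULL` to accept any separated winner.
#' @return A list of class `decision_config`.
#' @export
decision_config <- function(band = 0.125, corr_diff = 0.100, pct_diff = 10,
                            sequence = c("uv_pre", "uv_np", "uv_vs",
                                         "fl_pre", "fl_post"),
                            floors = c(r_min = 0.8, pct_min = 50)) {
  if (band <= 0 || corr_diff < 0 || pct_diff < 0) {
    stop("band must be > 0 and gap thresholds >= 0", call. = FALSE)
  }
  structure(list(band = band, corr_diff = corr_diff, pct_diff = pct_diff,
                 sequence = sequence, floors = floors),
            class = "decision_config")
}

.meets_floors <- function(r, pct, floors) {
  is.null(floors) ||
    (r >= floors[["r_min"]] && pct >= floors[["pct_min"]])
}

#' Decide among candidates from overlay scores
#'
#' Walks the configured spectrum-state sequence. At each state with scores
#' for >= 2 candidates, the candidates separate if the top-1 vs top-2 Pearson
#' correlation gap exceeds `corr_diff`, or - failing that - the top-1 vs
#' top-2 percent-within gap exceeds `pct_diff` (correlation is consulted
#' first, percent as the tiebreak). The winner must additionally meet the
#' absolute floors, if configured, on the decisive state; otherwise the band
#' is declared unmatched. With a single candidate the floors alone decide.
#' If no state separates the candidates, the full set is returned as
#' ambiguous - unless floors are set and no candidate ever met them, in
#' which case the result is no-match.
#'
#' @param scores Data frame with columns `candidate`, `state`, `pearson_r`,
#'   `percent_within` (one row per candidate per scored state), e.g. rows of
#'   [score_overlay()] results.
#' @param config A [decision_config()].
#' @return A list of class `overlay_decision`: `verdict` (`"match"`,
#'   `"ambiguous"` or `"none"`), `candidate` (for a match), `state` (the
#'   decisive state), `candidates` (the ambiguous set, if any), `scores`.
#' @export
decide_scores <- function(scores, config = decision_config()) {
  req <- c("candidate", "state", "pearson_r", "percent_within")
  if (!all(req %in% names(scores)) || nrow(scores) == 0) {
    stop("scores must have rows and columns candidate, state, pearson_r, percent_within",
         call. = FALSE)
  }
  states <- intersect(config$sequence, unique(scores$state))
  if (length(states) == 0) stop("no scored state is in the decision sequence",
                                call. = FALSE)
  any_floor_met <- FALSE
  result <- function(verdict, candidate = NA, state = NA, candidates = NULL) {
    structure(list(verdict = verdict, candidate = candidate, state = state,
                   candidates = candidates, scores = scores),
              class = "overlay_decision")
  }
  for (st in states) {
    sub <- scores[scores$state == st, ]
    if (is.null(config$floors)) {
      any_floor_met <- TRUE
    } else {
      any_floor_met <- any_floor_met ||
        any(sub$pearson_r >= config$floors[["r_min"]] &
            sub$percent_within >= config$floors[["pct_min"]])
    }
    if (nrow(sub) == 1) {
      if (.meets_floors(sub$pearson_r, sub$percent_within, config$floors)) {
        return(result("match", sub$candidate, st))
      }
      next
    }
    by_r <- sub[order(-sub$pearson_r), ]
    by_p <- sub[order(-sub$percent_within), ]
    winner <- NULL
    if (by_r$pearson_r[1] - by_r$pearson_r[2] > config$corr_diff) {
      winner <- by_r[1, ]
    } else if (by_p$percent_within[1] - by_p$percent_within[2] > config$pct_diff) {
      winner <- by_p[1, ]
    }
    if (!is.null(winner)) {
      if (.meets_floors(winner$pearson_r, winner$percent_within, config$floors)) {
        return(result("match", winner$candidate, st))
      }
      return(result("none", state = st))
    }
  }
  if (!any_floor_met) return(result("none"))
  result("ambiguous", candidates = sort(unique(scores$candidate)))
}

#' @export
print.overlay_decision <- function(x, ...) {
  switch(x$verdict,
    match = cat("Decision: matched candidate", x$candidate,
                "on state", x$state, "\n"),
    ambiguous = cat("Decision: ambiguous between",
                    paste(x$candidates, collapse = ", "), "\n"),
    none = cat("Decision: no match\n"))
  invisible(x)
}

#' Score and decide a full overlay comparison
#'
#' Convenience wrapper: scores every candidate's spectra against the
#' unknown's, state by state, then applies [decide_scores()].
#'
#' @param unknown_spectra Named list of the unknown band's `spectrum`
#'   objects, names from the decision sequence (`uv_pre`, `uv_np`, `uv_vs`,
#'   `fl_pre`, `fl_post`).
#' @param candidate_spectra Named list (one element per candidate code) of
#'   named spectrum lists with the same state names.
#' @param config A [decision_config()].
#' @param windows Named list of comparison windows overriding
#'   [default_windows()] (names `uv_pre`, `uv_np`, `uv_vs`, `fl`).
#' @return An `overlay_decision`; the per-comparison scores are in
#'   `$scores`.
#' @export
decide_overlays <- function(unknown_spectra, candidate_spectra,
                            config = decision_config(), windows = NULL) {
  if (length(unknown_spectra) == 0 || length(candidate_spectra) == 0) {
    stop("need at least one unknown spectrum and one candidate", call. = FALSE)
  }
  win <- modifyList(default_windows(), if (is.null(windows)) list() else windows)
  state_window <- function(st) {
    switch(st, uv_pre = win$uv_pre, uv_np = win$uv_np, uv_vs = win$uv_vs,
           fl_pre = win$fl, fl_post = win$fl, stop("unknown state: ", st))
  }
  rows <- list()
  for (cand in names(candidate_spectra)) {
    for (st in intersect(config$sequence, names(candidate_spectra[[cand]]))) {
      if (is.null(unknown_spectra[[st]])) next
      sc <- score_overlay(unknown_spectra[[st]],
                          candidate_spectra[[cand]][[st]],
                          window = state_window(st), band = config$band,
                          candidate = cand)
      rows[[length(rows) + 1L]] <- data.frame(
        candidate = cand, state = st, pearson_r = sc$pearson_r,
        percent_within = sc$percent_within, n_points = sc$n_points,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no comparable spectra", call. = FALSE)
  scores <- do.call(rbind, rows)
  # decide on the spectrum-state labels, not the modality/state slots
  decide_scores(scores, config)
}
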