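# Combining cascade results across derivatisations and mobile phases.

#' Consolidate matches across the two derivatisations of one mobile phase
#'
#' Within a mobile phase the same plate chemistry is interrogated twice (once
#' per derivatisation reagent), so a credible identity must survive both
#' cascades: the consolidated set is the strict intersection. Commutative and
#' idempotent.
#'
#' @param matches_A,matches_B Candidate code (or name) sets from the two
#'   derivatisation views of the same mobile phase.
#' @return The intersection, sorted.
#' @export
consolidate_pair <- function(matches_A, matches_B) {
  sort(intersect(unique(matches_A), unique(matches_B)))
}

#' Cross-mobile-phase identification report
#'
#' Compounds identified in both mobile-phase database sets are
#' "double-identified"; compounds found in only one set are retained as
#' single identifications rather than discarded, because a band that is well
#' resolved in one solvent system may co-migrate with others in the second,
#' making its identification there impossible.
#'
#' @param result_MPA,result_MPB Identified compound sets (codes or names)
#'   from the MPA and MPB database sets.
#' @return A list of class `consolidated_matches`: `double_identified`,
#'   `single_identified`, plus the two input sets.
#' @export
cross_solvent_report <- function(result_MPA, result_MPB) {
  a <- unique(result_MPA)
  b <- unique(result_MPB)
  both <- sort(intersect(a, b))
  single <- sort(union(setdiff(a, b), setdiff(b, a)))
  structure(list(double_identified = both, single_identified = single,
                 mpa = sort(a), mpb = sort(b)),
            class = "consolidated_matches")
}

#' @export
print.consolidated_matches <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = ", ") else "(none)"
  cat("Double-identified (both mobile phases):", fmt(x$double_identified), "\n")
  cat("Single identifications:               ", fmt(x$single_identified), "\n")
  invisible(x)
}

#' Final identification report for a set of consolidated matches
#'
#' Joins consolidated candidate codes back to the library for a
#' human-readable report, optionally attaching overlay verdicts.
#'
#' @param codes Integer candidate codes.
#' @param library An `hptlc_library`.
#' @param views Character note of which views matched (recycled).
#' @return Data frame with columns `code`, `name`, `compound_class`, `views`.
#' @export
identification_report <- function(codes, library, views = "") {
  idx <- match(codes, library$code)
  if (anyNA(idx)) {
    stop("codes not in library: ",
         paste(codes[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  data.frame(code = codes, name = library$name[idx],
             compound_class = library$compound_class[idx],
             views = views, stringsAsFactors = FALSE)
}
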