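#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the ranked candidate table of a report
#'
#' @param x An `npsid_report`.
#' @param ... Unused.
#' @return One row per candidate formula: rank, scores, database hits
#'   (collapsed to a `|`-separated string).
#' @method tidy npsid_report
#' @export
tidy.npsid_report <- function(x, ...) {
  x$candidates |>
    transmute(
      rank = .data$rank,
      formula = .data$formula,
      nominal_mass = .data$nominal_mass,
      rdbe = .data$rdbe,
      isotope_score = .data$isotope_score,
      fragment_coverage = .data$fragment_coverage,
      db_hits = map_chr(.data$db_hits, paste, collapse = "|"),
      score = .data$score
    )
}

#' One-row summary of a report
#'
#' @param x An `npsid_report`.
#' @param ... Unused.
#' @return A one-row tibble: precursor m/z, neutral target mass, excluded
#'   elements, candidate count, top formula and its score and hits.
#' @method glance npsid_report
#' @export
glance.npsid_report <- function(x, ...) {
  n <- nrow(x$candidates)
  tibble(
    precursor_mz = x$precursor$mz,
    best_fragmentor = x$precursor$best_fragmentor,
    target_mass = x$constraints$target_mass,
    excluded_elements = paste(
      x$exclusions$element[x$exclusions$excluded], collapse = "|"),
    n_candidates = n,
    top_formula = if (n) x$candidates$formula[1] else NA_character_,
    top_score = if (n) x$candidates$score[1] else NA_real_,
    top_db_hits = if (n) paste(x$candidates$db_hits[[1]], collapse = "|")
                  else NA_character_
  )
}
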