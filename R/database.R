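#' Load a compound table for formula-level database correspondence
#'
#' The packaged table is a small curated list of new psychoactive substances
#' and common drugs of abuse (tryptamines, benzofurans, phenethylamines,
#' amphetamines, cathinones, piperazines, arylcyclohexylamines, opioids,
#' cannabinoids), frozen inside the package so identifications are
#' reproducible. Isomers deliberately share one formula (e.g. AMT and 5-IT,
#' both C11H14N2): a formula-level hit therefore reports an isomer ambiguity
#' set, which is as far as mass spectrometry alone can go.
#'
#' @param path Optional path to a user CSV in the same shape (`name`,
#'   `synonyms` |-separated, `formula`, `class`); default: packaged table.
#' @return A tibble with columns `name`, `synonyms`, `formula` (canonical
#'   Hill string), `class` and `nominal_mass`.
#' @examples
#' compound_db() |> dplyr::filter(class == "tryptamine")
#' @export
compound_db <- function(path = NULL) {
  if (is.null(path) && !is.null(the$db)) return(the$db)
  src <- path %||% system.file("extdata", "nps_compounds.csv",
                               package = "npsid", mustWork = TRUE)
  tab <- readr::read_csv(src, comment = "#", show_col_types = FALSE,
                         progress = FALSE) |>
    mutate(
      formula = map_chr(.data$formula, function(f) render_formula(parse_formula(f))),
      nominal_mass = nominal_mass(.data$formula)
    )
  if (anyNA(tab$name) || any(duplicated(paste(tab$name, tab$formula)))) {
    abort("compound table must have unique (name, formula) pairs")
  }
  if (is.null(path)) the$db <- tab
  tab
}

#' Look up compounds matching a neutral formula
#'
#' Canonical Hill-string comparison against the compound table; isomers all
#' match, so the result is the ambiguity set the formula resolves to.
#'
#' @param db A compound table from [compound_db()].
#' @param f Neutral formula (string or [chem_formula()]).
#' @return Matching rows, ordered alphabetically by name.
#' @examples
#' lookup_formula(compound_db(), "C11H14N2") # AMT and 5-IT
#' @export
lookup_formula <- function(db, f) {
  key <- render_formula(as_chem_formula(f))
  hits <- db[db$formula == key, , drop = FALSE]
  hits[order(hits$name), ]
}
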