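#' Stable-isotope table for the supported element set
#'
#' Returns the packaged table of stable isotopes (standard masses and natural
#' abundances) for the elements handled by the package:
#' H, C, N, O, F, S, Cl, Br, I. The most abundant ("principal") isotope of
#' each element defines its nominal (integer) and monoisotopic mass
#' contribution; the `valence_class` column records the classical MS
#' classification by the offset of the second-most-abundant heavy isotope
#' (`A` = monoisotopic elements, `A+1` = dominant +1 line, `A+2` = dominant
#' +2 line, the class that makes S/Cl/Br detectable from the M+2 peak).
#'
#' @return A tibble with columns `symbol`, `mass_number`, `exact_mass`,
#'   `abundance`, `principal` (logical), `offset` (mass-number offset from
#'   the element's lightest isotope) and `valence_class`.
#' @examples
#' element_table()
#' @export
element_table <- function() {
  if (!is.null(the$elements)) {
    return(the$elements)
  }
  path <- system.file("extdata", "element_isotopes.csv", package = "npsid",
                      mustWork = TRUE)
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  cls <- c(H = "A+1", C = "A+1", N = "A+1", O = "A+2", F = "A",
           S = "A+2", Cl = "A+2", Br = "A+2", I = "A")
  tab <- raw |>
    group_by(.data$symbol) |>
    mutate(
      principal = .data$abundance == max(.data$abundance),
      offset = .data$mass_number - min(.data$mass_number)
    ) |>
    ungroup() |>
    mutate(valence_class = unname(cls[.data$symbol]))
  the$elements <- tab
  tab
}

#' @rdname element_table
#' @export
supported_elements <- function() {
  unique(element_table()$symbol)
}

# named vector helpers, cached ------------------------------------------------

element_nominal_masses <- function() {
  if (is.null(the$nominal)) {
    tab <- filter(element_table(), .data$principal)
    the$nominal <- setNames(as.numeric(tab$mass_number), tab$symbol)
  }
  the$nominal
}

element_exact_masses <- function() {
  if (is.null(the$exact)) {
    tab <- filter(element_table(), .data$principal)
    the$exact <- setNames(tab$exact_mass, tab$symbol)
  }
  the$exact
}

# single-atom isotope distribution over integer offsets from the lightest
# isotope, as a numeric vector p[offset + 1]
element_offset_dist <- function(symbol) {
  if (is.null(the$offset_dists)) {
    tab <- element_table()
    the$offset_dists <- lapply(split(tab, tab$symbol), function(d) {
      p <- numeric(max(d$offset) + 1)
      p[d$offset + 1] <- d$abundance
      p / sum(p)
    })
  }
  the$offset_dists[[symbol]]
}

# minimal expected (M+2)/(M+0) contribution of one atom of an A+2 element
single_atom_m2_ratio <- function(symbol) {
  p <- element_offset_dist(symbol)
  if (length(p) < 3) return(0)
  p[3] / p[1]
}

ELECTRON_MASS <- 0.000548579909
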