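#' Packaged neutral-loss table
#'
#' Small curated table of common neutral losses observed in even-electron
#' fragmentation of protonated small molecules (water, ammonia, methylamine,
#' carbon monoxide, hydrogen cyanide, methyl radical, ethylene), with the
#' structural feature each is diagnostic of. Users can supply their own
#' table in the same shape (columns `name`, `formula`, `diagnostic_of`,
#' `radical`).
#'
#' @return A tibble with an added `nominal_mass` column.
#' @examples
#' packaged_loss_table()
#' @export
packaged_loss_table <- function() {
  if (!is.null(the$losses)) return(the$losses)
  path <- system.file("extdata", "neutral_losses.csv", package = "npsid",
                      mustWork = TRUE)
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE) |>
    mutate(nominal_mass = nominal_mass(.data$formula))
  the$losses <- tab
  tab
}

#' Match a precursor-fragment mass difference to named neutral losses
#'
#' @param precursor_mz,fragment_mz Integer m/z of the precursor and fragment
#'   ions; the fragment may not be heavier than the precursor.
#' @param loss_table A neutral-loss table (default: packaged).
#' @return The rows of `loss_table` whose nominal mass equals
#'   `precursor_mz - fragment_mz`; zero rows when none match.
#' @examples
#' neutral_loss(175, 158) # ammonia, diagnostic of a primary amine
#' @export
neutral_loss <- function(precursor_mz, fragment_mz,
                         loss_table = packaged_loss_table()) {
  if (fragment_mz > precursor_mz) {
    abort("fragment m/z exceeds precursor m/z")
  }
  delta <- round(precursor_mz) - round(fragment_mz)
  filter(loss_table, .data$nominal_mass == delta)
}

#' Explain fragments as subformulas of a candidate precursor
#'
#' For each fragment, enumerates every singly charged cation composition
#' whose element counts fit inside the protonated precursor (the neutral's
#' counts plus one hydrogen for the ionizing proton - no further hydrogen
#' rearrangement is allowed), whose nominal mass matches the fragment m/z
#' within the tolerance, and whose RDBE is at least 0.5 (ruling out
#' chemically impossible cations). Mass differences from the precursor that
#' equal a neutral loss applicable to the precursor are annotated, and the
#' aromatic diagnostic ions phenyl (77, C6H5+), tropylium (91, C7H7+) and
#' phenylvinyl (103, C8H7+) are labelled.
#'
#' @param precursor Neutral candidate formula (string or [chem_formula()]).
#' @param fragments Tibble of fragment peaks with columns `mz` and
#'   optionally `intensity`.
#' @param tolerance Mass tolerance in Da (default 0.5, unit resolution).
#' @param loss_table Neutral-loss table (default: packaged).
#' @return A tibble with one row per (fragment, explanation): `fragment_mz`,
#'   `ion_formula` (`NA` when no subformula exists), `loss_name`,
#'   `loss_formula`, `diagnostic_label`. Fragments with no explanation keep a
#'   single all-`NA` row.
#' @examples
#' assign_subformulas("C11H14N2", tibble::tibble(mz = c(77, 91, 103, 158)))
#' @export
assign_subformulas <- function(precursor, fragments, tolerance = 0.5,
                               loss_table = packaged_loss_table()) {
  if (is.null(fragments) || !nrow(fragments)) {
    abort("`fragments` must contain at least one peak")
  }
  ctx <- subformula_context(precursor, loss_table)

  diagnostic <- c(`77` = "phenyl", `91` = "tropylium", `103` = "phenylvinyl")
  canonical <- c(`77` = "C6H5+", `91` = "C7H7+", `103` = "C8H7+")

  out <- map(seq_len(nrow(fragments)), function(i) {
    fmz <- fragments$mz[i]
    if (fmz > ctx$prot_mz + tolerance) {
      return(tibble(fragment_mz = fmz, ion_formula = NA_character_,
                    loss_name = NA_character_, loss_formula = NA_character_,
                    diagnostic_label = NA_character_))
    }
    H <- round(fmz - ctx$mass_other)
    ok <- H >= 0 & H <= ctx$prot[["H"]] &
      abs(ctx$mass_other + H - fmz) <= tolerance &
      ctx$rdbe_base - H / 2 >= 0.5
    rows <- which(ok)
    # neutral losses from the protonated molecule applicable to this precursor
    loss <- ctx$losses[ctx$losses$nominal_mass == round(ctx$prot_mz) - round(fmz), ,
                       drop = FALSE]
    if (!length(rows)) {
      return(tibble(fragment_mz = fmz, ion_formula = NA_character_,
                    loss_name = if (nrow(loss)) loss$name[1] else NA_character_,
                    loss_formula = if (nrow(loss)) loss$formula[1] else NA_character_,
                    diagnostic_label = NA_character_))
    }
    ions <- map_chr(rows, function(r) ctx$render_ion(r, H[r]))
    # annotate the loss on the complement ion (protonated molecule - loss)
    loss_of_ion <- rep(NA_integer_, length(ions))
    if (nrow(loss)) {
      for (j in seq_len(nrow(loss))) {
        compl <- ctx$prot - formula_counts(loss$formula[j])
        target_ion <- render_formula(chem_formula(compl[compl > 0], charge = 1L))
        loss_of_ion[ions == target_ion] <- j
      }
    }
    key <- as.character(round(fmz))
    canon <- if (key %in% names(canonical)) canonical[[key]] else NA_character_
    tibble(
      fragment_mz = fmz,
      ion_formula = ions,
      loss_name = ifelse(is.na(loss_of_ion), NA_character_,
                         loss$name[loss_of_ion]),
      loss_formula = ifelse(is.na(loss_of_ion), NA_character_,
                            loss$formula[loss_of_ion]),
      diagnostic_label = ifelse(!is.na(canon) & ions == canon,
                                unname(diagnostic[key]), NA_character_)
    )
  })
  bind_rows(out)
}

# precomputed search state shared by assign_subformulas() and the fast
# coverage path: the subformula count grid of the protonated precursor, its
# partial masses and RDBE bases, and the applicable neutral losses
subformula_context <- function(precursor, loss_table) {
  prec <- as_chem_formula(precursor)
  if (formula_charge(prec) != 0) {
    abort("`precursor` must be the neutral formula")
  }
  prot <- formula_counts(prec)
  prot[["H"]] <- prot[["H"]] + 1L # ionizing proton
  prot_mz <- sum(element_nominal_masses() * prot)

  others <- setdiff(names(prot)[prot > 0], "H")
  ranges <- lapply(others, function(el) 0:prot[[el]])
  names(ranges) <- others
  grid <- if (length(others)) {
    as.matrix(expand.grid(ranges, KEEP.OUT.ATTRS = FALSE))
  } else {
    matrix(numeric(), nrow = 1, ncol = 0)
  }
  nom <- element_nominal_masses()
  mass_other <- if (length(others)) as.numeric(grid %*% nom[others]) else 0
  colget <- function(el) if (el %in% others) grid[, el] else 0
  # cation RDBE = base - H/2; the hydrogen part is filled in per fragment
  rdbe_base <- colget("C") + colget("N") / 2 + 1 -
    (colget("F") + colget("Cl") + colget("Br") + colget("I")) / 2
  applicable <- map_lgl(loss_table$formula,
                        function(lf) all(formula_counts(lf) <= prot))
  hill <- hill_order(c(others, "H"))
  render_ion <- function(r, h) {
    cnt <- c(grid[r, ], H = h)[hill]
    cnt <- cnt[cnt > 0]
    paste0(paste0(names(cnt), ifelse(cnt == 1, "", cnt), collapse = ""), "+")
  }
  list(prot = prot, prot_mz = prot_mz, grid = grid, mass_other = mass_other,
       rdbe_base = rdbe_base, losses = loss_table[applicable, , drop = FALSE],
       render_ion = render_ion)
}

# intensity-weighted coverage without materializing assignment rows;
# agrees with explanation_coverage(assign_subformulas(...), ...) by sharing
# subformula_context()
candidate_coverage <- function(precursor, fragments, tolerance = 0.5,
                               loss_table = packaged_loss_table()) {
  ctx <- subformula_context(precursor, loss_table)
  weights <- if ("intensity" %in% names(fragments)) {
    fragments$intensity
  } else {
    rep(1, nrow(fragments))
  }
  explained <- map_lgl(fragments$mz, function(fmz) {
    if (fmz > ctx$prot_mz + tolerance) return(FALSE)
    H <- round(fmz - ctx$mass_other)
    if (any(H >= 0 & H <= ctx$prot[["H"]] &
              abs(ctx$mass_other + H - fmz) <= tolerance &
              ctx$rdbe_base - H / 2 >= 0.5)) {
      return(TRUE)
    }
    (round(ctx$prot_mz) - round(fmz)) %in% ctx$losses$nominal_mass
  })
  sum(weights[explained]) / sum(weights)
}

#' Intensity-weighted fragment-explanation coverage
#'
#' Fraction of total fragment signal carrying at least one explanation (a
#' subformula of the candidate or a recognized neutral loss). Coverage 1
#' means the candidate accounts for every observed product ion.
#'
#' @param assignments Output of [assign_subformulas()].
#' @param fragments The fragment peak tibble the assignments were computed
#'   from (`mz`, optional `intensity`; equal weights assumed when absent).
#' @return A fraction in `[0, 1]`.
#' @export
explanation_coverage <- function(assignments, fragments) {
  if (is.null(fragments) || !nrow(fragments)) {
    abort("`fragments` must contain at least one peak")
  }
  weights <- if ("intensity" %in% names(fragments)) {
    fragments$intensity
  } else {
    rep(1, nrow(fragments))
  }
  explained <- map_lgl(fragments$mz, function(m) {
    hit <- assignments$fragment_mz == m
    any(hit) && any(!is.na(assignments$ion_formula[hit]) |
                      !is.na(assignments$loss_name[hit]))
  })
  sum(weights[explained]) / sum(weights)
}
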