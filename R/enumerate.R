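#' Constraints for molecular-formula enumeration
#'
#' Bundles everything the enumerator needs: the target neutral mass (integer
#' in nominal mode, a float plus tolerance in exact mode), per-element count
#' bounds, the nitrogen-count parity demanded by the nitrogen rule, RDBE
#' bounds, and the set of elements excluded by isotope-pattern evidence.
#'
#' @param target_mass Neutral target mass in Da.
#' @param bounds Named list mapping element symbols to `c(min, max)` counts,
#'   or a compact string such as `"C=8:15,H=7:20,N=2:4,O=0:2,F=0:1"`.
#'   Elements not mentioned are fixed at zero.
#' @param n_parity `"even"`, `"odd"` or `"any"`.
#' @param min_rdbe,max_rdbe RDBE bounds for the neutral (default 0 and `Inf`).
#' @param excluded_elements Character vector of element symbols forced to
#'   zero (their bounds are overridden to `c(0, 0)`).
#' @param mode `"nominal"` (integer-mass matching) or `"exact"`
#'   (monoisotopic within `tolerance`).
#' @param tolerance Mass tolerance for exact mode, in Da (default 0.005), or
#'   a string like `"5ppm"`.
#' @return An `enum_constraints` object.
#' @examples
#' enum_constraints(174, "C=8:15,H=7:20,N=2:4,O=0:2,F=0:1",
#'                  n_parity = "even", min_rdbe = 4)
#' @export
enum_constraints <- function(target_mass, bounds, n_parity = "any",
                             min_rdbe = 0, max_rdbe = Inf,
                             excluded_elements = character(),
                             mode = c("nominal", "exact"),
                             tolerance = 0.005) {
  mode <- match.arg(mode)
  bounds <- parse_bounds(bounds)
  bad <- setdiff(names(bounds), supported_elements())
  if (length(bad)) {
    abort(sprintf("unsupported element(s) in bounds: %s",
                  paste(bad, collapse = ", ")))
  }
  for (el in names(bounds)) {
    b <- bounds[[el]]
    if (length(b) != 2 || b[1] > b[2] || b[1] < 0) {
      abort(sprintf("invalid bounds for %s: need 0 <= min <= max", el))
    }
  }
  for (el in excluded_elements) bounds[[el]] <- c(0, 0)
  if (!n_parity %in% c("even", "odd", "any")) {
    abort('n_parity must be "even", "odd" or "any"')
  }
  structure(
    list(target_mass = target_mass, bounds = bounds, n_parity = n_parity,
         min_rdbe = min_rdbe, max_rdbe = max_rdbe,
         excluded_elements = sort(unique(excluded_elements)),
         mode = mode, tolerance = tolerance),
    class = "enum_constraints"
  )
}

#' @export
print.enum_constraints <- function(x, ...) {
  b <- map_chr(names(x$bounds), function(el) {
    sprintf("%s %d:%d", el, x$bounds[[el]][1], x$bounds[[el]][2])
  })
  cat("<enum_constraints>\n")
  cat("  target mass:", x$target_mass, "Da (", x$mode, "mode )\n")
  cat("  bounds:", paste(b, collapse = ", "), "\n")
  cat("  N parity:", x$n_parity, " RDBE in [", x$min_rdbe, ",",
      x$max_rdbe, "]\n")
  if (length(x$excluded_elements)) {
    cat("  excluded:", paste(x$excluded_elements, collapse = ", "), "\n")
  }
  invisible(x)
}

# "C=8:15,H=7:20" -> list(C = c(8, 15), H = c(7, 20))
parse_bounds <- function(bounds) {
  if (is.list(bounds)) return(bounds)
  if (!is.character(bounds) || length(bounds) != 1) {
    abort("bounds must be a named list or a 'El=min:max,...' string")
  }
  parts <- strsplit(bounds, ",", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    m <- regmatches(p, regexec("^\\s*([A-Z][a-z]?)\\s*=\\s*([0-9]+):([0-9]+)\\s*$", p))[[1]]
    if (length(m) != 4) {
      abort(sprintf("invalid bound '%s'; expected e.g. 'C=8:15'", p))
    }
    out[[m[2]]] <- c(as.integer(m[3]), as.integer(m[4]))
  }
  out
}

tolerance_da <- function(constraints) {
  tol <- constraints$tolerance
  if (is.character(tol)) {
    if (grepl("ppm$", tol)) {
      return(as.numeric(sub("ppm$", "", tol)) * 1e-6 * constraints$target_mass)
    }
    tol <- as.numeric(tol)
  }
  tol
}

#' Derive enumeration constraints from the assembled evidence
#'
#' Turns the outputs of the earlier pipeline stages into an
#' [enum_constraints()] object: the neutral target mass is the precursor m/z
#' minus 1 (protonation); the presence of any of the aromatic marker ions
#' m/z 77 (phenyl), 91 (tropylium) or 103 (phenylvinyl) among the fragments
#' raises the minimum RDBE to 4 (one benzene ring), and the phenylvinyl
#' marker additionally implies at least 8 carbons and 7 hydrogens; the
#' nitrogen rule fixes the nitrogen-count parity; elements excluded by the
#' isotope-pattern analysis get zero bounds; iodine is excluded when the mass
#' budget `target - 127` cannot accommodate the minimum carbon count at
#' 12 Da per carbon; a nitrogen-containing neutral loss from the precursor
#' (e.g. ammonia, -17 Da) raises the minimum nitrogen count to 1, rounded up
#' to the required parity. All remaining bounds come from the configuration.
#'
#' @param precursor A precursor call from [select_precursor()], or a single
#'   numeric precursor m/z.
#' @param fragments Tibble of product-ion peaks (`mz`, `intensity`), or NULL.
#' @param exclusions Output of [exclude_a2_elements()], or NULL.
#' @param config A run configuration from [default_config()]/[load_config()].
#' @param loss_table Neutral-loss table (default: packaged).
#' @return An `enum_constraints` object; the evidence rules that fired are
#'   recorded in its `"rules"` attribute.
#' @export
derive_constraints <- function(precursor, fragments = NULL, exclusions = NULL,
                               config = default_config(),
                               loss_table = packaged_loss_table()) {
  pre_mz <- if (is.data.frame(precursor)) precursor$mz[1] else precursor[1]
  if (is.null(pre_mz) || is.na(pre_mz)) {
    abort("no precursor m/z; supply one explicitly (e.g. precursor = 175)")
  }
  target <- round(pre_mz) - 1
  bounds <- config$bounds
  rules <- list()
  note <- function(rule, outcome) {
    rules[[length(rules) + 1L]] <<- tibble(rule = rule, outcome = outcome)
  }

  frag_mz <- if (!is.null(fragments) && nrow(fragments)) {
    round(fragments$mz)
  } else {
    numeric()
  }

  min_rdbe <- config$min_rdbe %||% 0
  markers <- intersect(c(77, 91, 103), frag_mz)
  if (length(markers)) {
    min_rdbe <- max(min_rdbe, 4)
    note("aromatic marker ions",
         sprintf("fragments at %s indicate a phenyl ring: RDBE >= 4",
                 paste(markers, collapse = "/")))
  } else {
    note("aromatic marker ions", "none of 77/91/103 present; RDBE floor unchanged")
  }
  raise_min <- function(el, new_min) {
    b <- bounds[[el]] %||% c(0, 0)
    bounds[[el]] <<- c(max(b[1], new_min), max(b[2], max(b[1], new_min)))
  }
  if (103 %in% frag_mz) {
    raise_min("C", 8)
    raise_min("H", 7)
    note("phenylvinyl marker", "fragment at 103 (C8H7+): C >= 8 and H >= 7")
  }

  n_par <- nitrogen_parity(target)
  note("nitrogen rule", sprintf("neutral mass %d is %s: N count must be %s",
                                target, if (target %% 2 == 0) "even" else "odd",
                                n_par))

  # nitrogen-containing neutral loss from the precursor implies N >= 1
  if (length(frag_mz)) {
    losses <- (round(pre_mz) - frag_mz)
    n_losses <- loss_table |>
      filter(map_lgl(.data$formula, function(f) {
        formula_counts(f)[["N"]] > 0
      }))
    hit <- intersect(losses, n_losses$nominal_mass)
    if (length(hit)) {
      n_min <- 1
      if (n_par == "even") n_min <- 2
      raise_min("N", n_min)
      note("nitrogenous neutral loss",
           sprintf("loss of %s Da matches a nitrogen-containing neutral: N >= %d",
                   paste(hit, collapse = "/"), n_min))
    }
  }

  excluded <- character()
  if (!is.null(exclusions) && nrow(exclusions)) {
    excluded <- exclusions$element[exclusions$excluded]
    if (length(excluded)) {
      note("A+2 isotope exclusion",
           sprintf("measured M+2 too low for %s", paste(excluded, collapse = ", ")))
    }
  }

  c_min <- (bounds[["C"]] %||% c(0, 0))[1]
  if (target - 127 < 12 * c_min) {
    excluded <- union(excluded, "I")
    note("iodine mass budget",
         sprintf("target %d minus 127 leaves < %d Da for C>=%d; I excluded",
                 target, 12 * c_min, c_min))
  }

  out <- enum_constraints(
    target_mass = if (identical(config$mode, "exact")) pre_mz - 1 else target,
    bounds = bounds, n_parity = n_par, min_rdbe = min_rdbe,
    max_rdbe = config$max_rdbe %||% Inf, excluded_elements = excluded,
    mode = config$mode %||% "nominal", tolerance = config$tolerance %||% 0.005
  )
  attr(out, "rules") <- bind_rows(rules)
  out
}

#' Enumerate all molecular formulas consistent with the constraints
#'
#' Iterates over the count grid of all elements except hydrogen and solves
#' the hydrogen count by mass closure (`H = target - sum of other nominal
#' masses`), which is exact at unit resolution; candidates failing the H
#' bounds, the nitrogen parity or the RDBE window are rejected. In exact
#' mode the hydrogen count is recovered by rounding the residual mass and
#' candidates must match the monoisotopic target within the tolerance.
#'
#' @param constraints An [enum_constraints()] object.
#' @return A tibble of neutral candidates: `formula` (Hill string), element
#'   count columns, `nominal_mass` (and `monoisotopic_mass` in exact mode)
#'   and `rdbe`, sorted by descending RDBE then formula; deterministic.
#' @examples
#' cons <- enum_constraints(174, "C=8:15,H=7:20,N=2:4,O=0:2,F=0:1",
#'                          n_parity = "even", min_rdbe = 4)
#' enumerate_formulas(cons)
#' @export
enumerate_formulas <- function(constraints) {
  stopifnot(inherits(constraints, "enum_constraints"))
  b <- constraints$bounds
  if (!length(b) || all(map_dbl(b, 2) == 0)) {
    return(empty_candidates())
  }
  if (any(!is.finite(unlist(b)))) {
    abort("unbounded search space: every element needs a finite upper bound")
  }
  others <- setdiff(names(b)[map_dbl(b, 2) > 0], "H")
  ranges <- lapply(others, function(el) seq(b[[el]][1], b[[el]][2]))
  names(ranges) <- others
  grid <- if (length(ranges)) {
    as_tibble(expand.grid(ranges, KEEP.OUT.ATTRS = FALSE))
  } else {
    tibble(.rows = 1)
  }

  nom <- element_nominal_masses()
  mass_other <- if (length(others)) {
    as.numeric(as.matrix(grid) %*% nom[others])
  } else {
    rep(0, nrow(grid))
  }
  hb <- b[["H"]] %||% c(0, 0)

  if (constraints$mode == "nominal") {
    H <- round(constraints$target_mass) - mass_other
    keep <- H >= hb[1] & H <= hb[2]
  } else {
    exact <- element_exact_masses()
    mono_other <- if (length(others)) {
      as.numeric(as.matrix(grid) %*% exact[others])
    } else {
      rep(0, nrow(grid))
    }
    tol <- tolerance_da(constraints)
    H <- round((constraints$target_mass - mono_other) / exact[["H"]])
    mono <- mono_other + H * exact[["H"]]
    keep <- H >= hb[1] & H <= hb[2] &
      abs(mono - constraints$target_mass) <= tol
  }

  grid <- grid[keep, , drop = FALSE]
  H <- H[keep]
  finish_candidates(grid, H, constraints)
}

#' Brute-force enumeration oracle
#'
#' Exhaustive nested iteration over every element-count tuple (hydrogen
#' included) with each constraint re-checked one by one. Exists as an
#' independent cross-check for [enumerate_formulas()]; refuses grids larger
#' than 1e7 cells.
#'
#' @inheritParams enumerate_formulas
#' @return Same shape as [enumerate_formulas()].
#' @export
brute_force_enumerate <- function(constraints) {
  stopifnot(inherits(constraints, "enum_constraints"))
  b <- constraints$bounds
  active <- names(b)[map_dbl(b, 2) > 0]
  if (!length(active)) return(empty_candidates())
  sizes <- map_dbl(active, function(el) b[[el]][2] - b[[el]][1] + 1)
  if (prod(sizes) > 1e7) abort("search space exceeds 1e7 tuples")
  ranges <- lapply(active, function(el) seq(b[[el]][1], b[[el]][2]))
  names(ranges) <- active
  grid <- as_tibble(expand.grid(ranges, KEEP.OUT.ATTRS = FALSE))

  counts_of <- function(i) {
    cnt <- unlist(grid[i, ])
    cnt[cnt > 0]
  }
  keep <- map_lgl(seq_len(nrow(grid)), function(i) {
    cnt <- counts_of(i)
    if (!length(cnt)) return(FALSE)
    f <- chem_formula(cnt)
    ok_mass <- if (constraints$mode == "nominal") {
      nominal_mass(f) == round(constraints$target_mass)
    } else {
      abs(monoisotopic_mass(f) - constraints$target_mass) <=
        tolerance_da(constraints)
    }
    n <- formula_counts(f)[["N"]]
    ok_par <- switch(constraints$n_parity,
                     even = n %% 2 == 0, odd = n %% 2 == 1, TRUE)
    r <- rdbe(f)
    ok_mass && ok_par && r >= constraints$min_rdbe && r <= constraints$max_rdbe
  })
  grid <- grid[keep, , drop = FALSE]
  H <- if ("H" %in% names(grid)) grid$H else rep(0, nrow(grid))
  grid <- grid[setdiff(names(grid), "H")]
  finish_candidates(grid, H, constraints)
}

empty_candidates <- function() {
  tibble(formula = character(), nominal_mass = numeric(), rdbe = numeric())
}

# assemble, filter on parity + rdbe, order
finish_candidates <- function(grid, H, constraints) {
  if (!nrow(grid)) return(empty_candidates())
  col0 <- function(el) {
    if (el %in% names(grid)) grid[[el]] else rep(0, nrow(grid))
  }
  C <- col0("C"); N <- col0("N")
  X <- col0("F") + col0("Cl") + col0("Br") + col0("I")
  r <- rdbe_counts(C, H, N, X)
  keep <- switch(constraints$n_parity,
                 even = N %% 2 == 0, odd = N %% 2 == 1,
                 rep(TRUE, nrow(grid))) &
    r >= constraints$min_rdbe & r <= constraints$max_rdbe &
    (H + rowSums(as.matrix(grid)) > 0)
  grid <- grid[keep, , drop = FALSE]
  if (!nrow(grid)) return(empty_candidates())
  H <- H[keep]; r <- r[keep]
  counts_tbl <- grid |> mutate(H = H)
  formulas <- map_chr(seq_len(nrow(counts_tbl)), function(i) {
    cnt <- unlist(counts_tbl[i, ])
    render_formula(chem_formula(cnt[cnt > 0]))
  })
  out <- bind_cols(
    tibble(formula = formulas),
    counts_tbl,
    tibble(rdbe = r)
  )
  out$nominal_mass <- nominal_mass(out$formula)
  if (constraints$mode == "exact") {
    out$monoisotopic_mass <- monoisotopic_mass(out$formula)
  }
  out |>
    distinct(.data$formula, .keep_all = TRUE) |>
    arrange(desc(.data$rdbe), .data$formula)
}

#' Re-check enumerated candidates against their constraints
#'
#' Post-hoc audit: every candidate is re-validated one by one (mass match,
#' element bounds, exclusions, nitrogen parity, RDBE window).
#'
#' @param candidates Output of [enumerate_formulas()].
#' @param constraints The [enum_constraints()] they were produced from.
#' @return Logical vector, one entry per candidate.
#' @export
audit_candidates <- function(candidates, constraints) {
  map_lgl(candidates$formula, function(fs) {
    f <- parse_formula(fs)
    cnt <- formula_counts(f)
    ok_bounds <- all(map_lgl(supported_elements(), function(el) {
      bd <- constraints$bounds[[el]] %||% c(0, 0)
      cnt[[el]] >= bd[1] && cnt[[el]] <= bd[2]
    }))
    ok_excl <- all(cnt[constraints$excluded_elements] == 0)
    ok_mass <- if (constraints$mode == "nominal") {
      nominal_mass(f) == round(constraints$target_mass)
    } else {
      abs(monoisotopic_mass(f) - constraints$target_mass) <=
        tolerance_da(constraints)
    }
    ok_par <- switch(constraints$n_parity,
                     even = cnt[["N"]] %% 2 == 0,
                     odd = cnt[["N"]] %% 2 == 1, TRUE)
    r <- rdbe(f)
    ok_bounds && ok_excl && ok_mass && ok_par &&
      r >= constraints$min_rdbe && r <= constraints$max_rdbe
  })
}
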