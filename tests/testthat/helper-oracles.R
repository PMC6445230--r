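# Independent oracles, deliberately naive: each re-derives a quantity by
# exhaustive enumeration so the package's faster implementations can be
# checked against them.

# exhaustive isotopologue expansion: explicit product over every isotope
# assignment of every atom, aggregated by integer offset from the lightest
# isotopologue; tractable only for a handful of atoms
oracle_isotope_pattern <- function(formula) {
  tab <- element_table()
  f <- parse_formula(if (is.character(formula)) formula else
    render_formula(formula))
  atoms <- rep(names(unclass(f)), unclass(f))
  choices <- lapply(atoms, function(sym) {
    d <- tab[tab$symbol == sym, ]
    list(offset = d$offset, prob = d$abundance)
  })
  idx <- expand.grid(lapply(choices, function(ch) seq_along(ch$offset)))
  probs <- rep(1, nrow(idx))
  offs <- rep(0, nrow(idx))
  for (a in seq_along(choices)) {
    probs <- probs * choices[[a]]$prob[idx[[a]]]
    offs <- offs + choices[[a]]$offset[idx[[a]]]
  }
  agg <- tapply(probs, offs, sum)
  tibble::tibble(offset = as.integer(names(agg)),
                 abundance = as.numeric(agg) / max(agg))
}

# brute-force subformula search: every count tuple inside the protonated
# precursor (hydrogen included), filtered by mass and cation RDBE >= 0.5
oracle_subformula_ions <- function(precursor, fragment_mz, tolerance = 0.5) {
  prot <- sapply(supported_elements(), function(el) 0)
  f <- parse_formula(precursor)
  for (el in names(unclass(f))) prot[el] <- unclass(f)[[el]]
  prot["H"] <- prot["H"] + 1
  active <- names(prot)[prot > 0]
  grid <- expand.grid(lapply(prot[active], function(n) 0:n))
  names(grid) <- active
  out <- character()
  for (i in seq_len(nrow(grid))) {
    cnt <- unlist(grid[i, ])
    cnt <- cnt[cnt > 0]
    if (!length(cnt)) next
    ion <- chem_formula(cnt, charge = 1L)
    if (abs(nominal_mass(ion) - fragment_mz) <= tolerance &&
        rdbe(ion) >= 0.5) {
      out <- c(out, render_formula(ion))
    }
  }
  sort(out)
}

# random formula over a given element subset (uniform counts, at least one
# atom); callers control the RNG seed
random_formula <- function(elements = c("C", "H", "N", "O"),
                           max_count = 12) {
  repeat {
    cnt <- sapply(elements, function(el) sample(0:max_count, 1))
    if (sum(cnt) > 0) break
  }
  chem_formula(cnt[cnt > 0])
}

# random bounded enumeration instance small enough for the brute-force path
random_constraints <- function() {
  bounds <- list(C = c(0, sample(4:9, 1)), H = c(0, sample(6:14, 1)),
                 N = c(0, sample(0:3, 1)), O = c(0, sample(0:3, 1)))
  if (sample(c(TRUE, FALSE), 1)) bounds$Cl <- c(0, sample(0:2, 1))
  enum_constraints(
    target_mass = sample(30:130, 1),
    bounds = bounds,
    n_parity = sample(c("even", "odd", "any"), 1),
    min_rdbe = sample(c(0, 0, 1, 4), 1)
  )
}
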