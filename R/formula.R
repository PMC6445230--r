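#' Molecular formulas at unit and exact resolution
#'
#' A `chem_formula` is a named integer vector of element counts with a
#' `charge` attribute (0 for neutrals, +1 for even-electron cations such as
#' protonated molecules). Formulas are the unit of all mass arithmetic in the
#' package; they render to and parse from Hill-notation strings
#' (C first, then H, then remaining elements alphabetically) with an optional
#' trailing `+`/`-` charge sign, e.g. `"C11H14N2"` or `"C6H5+"`.
#'
#' @param counts Named non-negative integer vector of element counts. Only
#'   elements in [supported_elements()] are accepted.
#' @param charge Integer charge (default 0).
#' @return A `chem_formula` object.
#' @examples
#' chem_formula(c(C = 11, H = 14, N = 2))
#' parse_formula("C6H5+")
#' @export
chem_formula <- function(counts = integer(), charge = 0L) {
  counts <- counts[counts != 0]
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      abort("element counts must be named")
    }
    bad <- setdiff(names(counts), supported_elements())
    if (length(bad)) {
      abort(sprintf("unsupported element symbol(s): %s",
                    paste(bad, collapse = ", ")))
    }
    if (any(counts < 0)) abort("element counts must be non-negative")
    counts <- setNames(as.integer(counts), names(counts))
    counts <- counts[hill_order(names(counts))]
  }
  structure(counts, charge = as.integer(charge), class = "chem_formula")
}

hill_order <- function(symbols) {
  if ("C" %in% symbols) {
    first <- intersect(c("C", "H"), symbols)
    c(first, sort(setdiff(symbols, first)))
  } else {
    sort(symbols)
  }
}

#' Parse a Hill-notation formula string
#'
#' @param text A single formula string, e.g. `"C11H14N2"`, `"C6H5+"`.
#'   Bare element symbols have an implicit count of 1.
#' @return A [chem_formula()].
#' @examples
#' parse_formula("C11H14N2")
#' nominal_mass("C6H5+")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(text)) {
    abort("`text` must be a single non-empty formula string")
  }
  body <- text
  charge <- 0L
  last <- substr(body, nchar(body), nchar(body))
  if (last %in% c("+", "-")) {
    charge <- if (last == "+") 1L else -1L
    body <- substr(body, 1, nchar(body) - 1)
    if (!nzchar(body)) abort("formula has a charge sign but no elements")
  }
  counts <- integer()
  pos <- 1L
  n <- nchar(body)
  while (pos <= n) {
    rest <- substr(body, pos, n)
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (!length(m) || !nzchar(m[2])) {
      abort(sprintf("malformed formula '%s': cannot parse at position %d",
                    text, pos))
    }
    sym <- m[2]
    if (!sym %in% supported_elements()) {
      # a two-letter guess may shadow a valid one-letter symbol (e.g. "Ho" in
      # "HoW"): retry with one letter before failing
      if (nchar(sym) == 2 && substr(sym, 1, 1) %in% supported_elements()) {
        sym <- substr(sym, 1, 1)
        m[3] <- ""
        m[1] <- sym
      } else {
        abort(sprintf("unknown element symbol '%s' in formula '%s'", m[2], text))
      }
    }
    cnt <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + cnt
    pos <- pos + nchar(m[1])
  }
  if (!length(counts)) abort(sprintf("empty formula '%s'", text))
  chem_formula(counts, charge)
}

#' Render a formula in Hill notation
#'
#' @param f A [chem_formula()] or formula string.
#' @return A single string; a trailing `+` or `-` marks charge.
#' @export
render_formula <- function(f) {
  f <- as_chem_formula(f)
  counts <- unclass(f)
  body <- paste0(names(counts), ifelse(counts == 1, "", counts),
                 collapse = "")
  ch <- attr(f, "charge") %||% 0L
  sign <- if (ch == 0) "" else {
    mag <- if (abs(ch) > 1) abs(ch) else ""
    paste0(mag, if (ch > 0) "+" else "-")
  }
  paste0(body, sign)
}

#' @rdname chem_formula
#' @param x Object to coerce: a formula string or a `chem_formula`.
#' @export
as_chem_formula <- function(x) {
  if (inherits(x, "chem_formula")) return(x)
  if (is.character(x) && length(x) == 1) return(parse_formula(x))
  abort("cannot coerce to chem_formula; supply a string or chem_formula")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", render_formula(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.chem_formula <- function(x, ...) render_formula(x)

#' @export
`==.chem_formula` <- function(e1, e2) {
  e1 <- as_chem_formula(e1); e2 <- as_chem_formula(e2)
  identical(formula_counts(e1), formula_counts(e2)) &&
    identical(attr(e1, "charge"), attr(e2, "charge"))
}

# full count vector over the supported element set (zeros filled in)
formula_counts <- function(f) {
  f <- as_chem_formula(f)
  out <- setNames(integer(length(supported_elements())), supported_elements())
  out[names(unclass(f))] <- unclass(f)
  out
}

formula_charge <- function(f) attr(as_chem_formula(f), "charge") %||% 0L

with_each_formula <- function(x, fun) {
  if (inherits(x, "chem_formula")) return(fun(x))
  if (is.list(x)) return(map_dbl(x, function(f) fun(as_chem_formula(f))))
  if (is.character(x)) return(map_dbl(x, function(s) fun(parse_formula(s))))
  abort("expected a chem_formula, a formula string, or a list/vector thereof")
}

#' Nominal (integer) mass of a formula
#'
#' Sum over elements of count times the integer mass number of the element's
#' most abundant isotope (C=12, H=1, N=14, O=16, F=19, S=32, Cl=35, Br=79,
#' I=127). Charge does not alter the nominal mass: the electron mass is far
#' below unit resolution.
#'
#' @param f A formula string, `chem_formula`, or vector/list of them.
#' @return Numeric vector of integer masses in Da.
#' @examples
#' nominal_mass("C11H14N2") # 174
#' nominal_mass("C6H5+")    # 77
#' @export
nominal_mass <- function(f) {
  masses <- element_nominal_masses()
  with_each_formula(f, function(ff) {
    cnt <- unclass(ff)
    sum(masses[names(cnt)] * cnt)
  })
}

#' Monoisotopic (exact) mass of a formula
#'
#' Sum of count times the exact mass of each element's most abundant isotope;
#' for charged species the electron mass (0.000549 Da per charge) is
#' subtracted, so the value is the m/z of the singly charged ion.
#'
#' @inheritParams nominal_mass
#' @return Numeric vector of masses in Da.
#' @examples
#' monoisotopic_mass("C11H14N2") # 174.1157
#' @export
monoisotopic_mass <- function(f) {
  masses <- element_exact_masses()
  with_each_formula(f, function(ff) {
    cnt <- unclass(ff)
    sum(masses[names(cnt)] * cnt) - formula_charge(ff) * ELECTRON_MASS
  })
}

#' Ring-plus-double-bond equivalents (degrees of unsaturation)
#'
#' RDBE = C - (H + F + Cl + Br + I)/2 + N/2 + 1, evaluated on the counts as
#' given. The value can be half-integer for cation compositions (e.g. C6H5+
#' has RDBE 4.5); a benzene ring contributes 4.
#'
#' @inheritParams nominal_mass
#' @return Numeric vector (possibly half-integer).
#' @examples
#' rdbe("C6H6")     # 4, one phenyl ring
#' rdbe("C11H14N2") # 6
#' @export
rdbe <- function(f) {
  with_each_formula(f, function(ff) {
    cnt <- formula_counts(ff)
    rdbe_counts(cnt[["C"]], cnt[["H"]], cnt[["N"]],
                cnt[["F"]] + cnt[["Cl"]] + cnt[["Br"]] + cnt[["I"]])
  })
}

# vectorized core used by the enumerators
rdbe_counts <- function(C, H, N, X) C - (H + X) / 2 + N / 2 + 1
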