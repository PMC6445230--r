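#' Simulate a unit-resolution isotope pattern
#'
#' Computes the isotopologue distribution of a formula by per-element
#' multinomial expansion (n-fold convolution of the single-atom isotope
#' distribution) convolved across elements, binned to integer mass offsets
#' from the lightest isotopologue, pruned below a relative-abundance
#' threshold and renormalized so the most abundant line is 1.
#'
#' @param f Formula string or [chem_formula()].
#' @param prune_threshold Lines below this fraction of the base line are
#'   dropped (default 1e-6).
#' @return A tibble with columns `offset` (integer Da above the monoisotopic
#'   line) and `abundance` (base line = 1).
#' @examples
#' simulate_pattern("Br")          # the 79/81 doublet, ratio ~0.973
#' simulate_pattern("C11H15N2+")   # protonated AMT cluster
#' @export
simulate_pattern <- function(f, prune_threshold = 1e-6) {
  if (prune_threshold <= 0 || prune_threshold >= 1) {
    abort("prune_threshold must be in (0, 1)")
  }
  f <- as_chem_formula(f)
  cnt <- unclass(f)
  dist <- 1
  for (sym in names(cnt)) {
    single <- element_offset_dist(sym)
    elem <- convolve_power(single, cnt[[sym]])
    dist <- convolve_dists(dist, elem)
  }
  dist <- dist / max(dist)
  keep <- dist >= prune_threshold
  tibble(offset = which(keep) - 1L, abundance = dist[keep] / max(dist[keep]))
}

convolve_dists <- function(a, b) {
  if (length(a) == 1) return(a * b)
  if (length(b) == 1) return(a * b)
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    if (a[i] > 0) {
      idx <- i:(i + length(b) - 1)
      out[idx] <- out[idx] + a[i] * b
    }
  }
  out
}

# n-fold self-convolution by binary exponentiation
convolve_power <- function(p, n) {
  result <- 1
  base <- p
  while (n > 0) {
    if (n %% 2 == 1) result <- convolve_dists(result, base)
    base <- convolve_dists(base, base)
    n <- n %/% 2
  }
  result
}

#' Exclude A+2 elements from a measured isotope cluster
#'
#' The A+2 elements S, Cl and Br each place a strong line two mass units
#' above the principal isotope (single-atom (M+2)/(M+0) contributions of
#' about 0.045, 0.32 and 0.97 respectively). An element is excluded when the
#' measured (M+2)/(M+0) ratio falls below half of its minimal single-atom
#' contribution; the factor of one half tolerates the substantial intensity
#' error of unit-resolution quadrupole measurements while still separating,
#' for example, a measured 0.7% M+2 from sulfur's ~4.5%.
#'
#' @param cluster Numeric vector of measured MH+0, MH+1, MH+2 intensities,
#'   normalized so MH+0 = 100. A missing third entry is treated as 0 with a
#'   warning.
#' @return A tibble with one row per A+2 element: `element`, `excluded`,
#'   `measured_ratio`, `threshold_ratio`, `rationale`.
#' @examples
#' exclude_a2_elements(c(100, 9.8, 0.7)) # S, Cl, Br all absent
#' @export
exclude_a2_elements <- function(cluster) {
  if (length(cluster) < 1 || abs(cluster[1] - 100) > 1e-6) {
    abort("cluster must be normalized so that MH+0 = 100")
  }
  if (length(cluster) < 3) {
    warn("no MH+2 intensity supplied; treating it as 0")
    cluster <- c(cluster, rep(0, 3 - length(cluster)))
  }
  if (any(cluster < 0)) abort("cluster intensities must be non-negative")
  measured <- cluster[3] / cluster[1]
  map(c("S", "Cl", "Br"), function(el) {
    contrib <- single_atom_m2_ratio(el)
    thr <- 0.5 * contrib
    tibble(
      element = el,
      excluded = measured < thr,
      measured_ratio = measured,
      threshold_ratio = thr,
      rationale = sprintf(
        "one %s atom would contribute (M+2)/(M+0) >= %.3f; measured %.4f is %s half of that",
        el, contrib, measured, if (measured < thr) "below" else "not below")
    )
  }) |> bind_rows()
}

#' Required nitrogen-count parity from the nitrogen rule
#'
#' For compositions over C, H, N, O, F, S, Cl, Br and I, an even nominal
#' molecular mass of the neutral implies an even number of nitrogen atoms and
#' an odd mass an odd number.
#'
#' @param neutral_nominal_mass Positive integer nominal mass of the neutral
#'   molecule in Da.
#' @return `"even"` or `"odd"`.
#' @examples
#' nitrogen_parity(174) # "even"
#' nitrogen_parity(189) # "odd"
#' @export
nitrogen_parity <- function(neutral_nominal_mass) {
  if (neutral_nominal_mass <= 0) abort("mass must be positive")
  if (round(neutral_nominal_mass) %% 2 == 0) "even" else "odd"
}

#' Score a formula's isotope pattern against a measured cluster
#'
#' Cosine (normalized dot-product) similarity between the simulated and
#' measured MH+0..+2 intensity vectors; 1 means identical cluster shape.
#'
#' @param f Formula of the ion (typically the protonated candidate, e.g.
#'   `"C11H15N2+"`).
#' @param cluster Measured MH+0, MH+1, MH+2 intensities (any common scale).
#' @return A score in `[0, 1]`.
#' @export
isotope_fit_score <- function(f, cluster) {
  if (length(cluster) < 3) cluster <- c(cluster, rep(0, 3 - length(cluster)))
  pat <- simulate_pattern(f)
  sim <- map_dbl(0:2, function(o) {
    v <- pat$abundance[pat$offset == o]
    if (length(v)) v else 0
  })
  meas <- as.numeric(cluster[1:3])
  denom <- sqrt(sum(sim^2)) * sqrt(sum(meas^2))
  if (denom == 0) return(0)
  min(1, sum(sim * meas) / denom)
}
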