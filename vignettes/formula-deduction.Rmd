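---
title: "Unmasking an unknown: formula deduction from unit-resolution LC-MS/MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deducing molecular formulas from unit-resolution LC-MS/MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npsid)
library(dplyr)
```

## The problem

When a seized powder contains a designer drug with no reference standard and
no library spectrum, a laboratory with a triple-quadrupole LC-MS/MS (unit
resolution, no accurate mass) can still pin down the molecular formula by
stacking weak constraints until only a handful of compositions survive.
`npsid` encodes that procedure. This vignette explains the model behind each
stage, the tunable parameters and their defaults, the numerical choices, and
what the synthetic benchmark does and does not demonstrate.

## Stage models and assumptions

**Precursor determination.** Electrospray sources fragment labile analytes
before mass analysis; the extent grows with the fragmentor voltage. Scanning
a ladder (default 110/90/70/40 eV) and tracking each integer-binned ion
across it, the protonated molecule is the *highest-m/z* ion whose abundance
profile peaks *at or below the median scanned voltage*; in-source fragments
peak at the top of the ladder. Two non-obvious choices:

* The rule is "argmax voltage at or below the median", not "most abundant at
  the lowest voltage": below an instrument-dependent optimum, overall ion
  transmission also falls, so the genuine precursor typically peaks at an
  interior voltage (70 eV in the packaged case).
* Profile ties resolve to the lower voltage, and candidates with identical
  profiles resolve to the higher m/z — in-source fragments are always
  lighter than their precursor. Isotope satellites (a peak 1-2 Da above a
  stronger peak) are not independent ions and are removed from candidacy.

The rule assumes singly protonated, even-electron species; adducts
([M+Na]⁺, dimers) and multiple charging are out of scope, and a high-mass
adduct with a monotone survival profile would fool it — the casework remedy
is the `precursor` override of `run_pipeline()`.

**A+2 element exclusion.** One atom of S, Cl or Br contributes at least
0.045, 0.320 or 0.973 to the (M+2)/(M+0) ratio (from the packaged isotope
table). An element is excluded when the measured ratio is below **one half**
of its single-atom contribution. The factor 0.5 is this package's
operationalization of "excluded by the isotopic pattern": quadrupole
intensity ratios are poor (tens of percent error), so the gate must tolerate
a halved M+2 while still separating a sub-1% measured ratio from sulfur's
4.5%. The same logic never *confirms* an element - a strong M+2 only leaves
the element's bounds open.

**Why M+1 is not used to estimate the carbon count.** In the packaged case
the measured M+1 (9.8%) sits well below the theoretical 12.6% for eleven
carbons; single-quadrupole-step intensity ratios at low analyte levels are
simply not reliable enough, so carbon bounds come from fragments instead.

**Nitrogen rule and RDBE.** For C/H/N/O/halogen compositions an even neutral
nominal mass implies an even nitrogen count, odd implies odd. Ring plus
double-bond equivalents are computed as RDBE = C − (H+F+Cl+Br+I)/2 + N/2 + 1
on the counts as written, so even-electron cations get half-integers (C6H5⁺
→ 4.5). Aromatic marker fragments at m/z 77/91/103 force RDBE ≥ 4 (one
benzene ring); the phenylvinyl marker (103, C8H7⁺) additionally forces
C ≥ 8 and H ≥ 7. A nitrogen-containing neutral loss from the precursor
(ammonia −17, methylamine −31) forces N ≥ 1, rounded up to the parity the
nitrogen rule demands. Iodine is excluded arithmetically whenever
`target − 127` cannot pay for the minimum carbon count at 12 Da per carbon.

**Enumeration.** Nominal mode iterates over the count grid of all elements
except hydrogen and solves H by mass closure — exact at integer resolution
and linear in the grid rather than exponential. Exact mode recovers H by
rounding the monoisotopic residual and applies a Da or ppm tolerance.
`brute_force_enumerate()` re-derives the same sets by exhaustive nested
iteration and exists purely as an oracle; the two are checked for set
equality on random instances in the test suite. Candidate order is
deterministic: descending RDBE, then Hill string.

**Fragment annotation.** A fragment is explained by any cation composition
element-wise inside the protonated precursor (neutral + 1 H; no further
hydrogen rearrangement, which keeps the search honest at unit resolution)
whose nominal mass matches within 0.5 Da and whose cation RDBE is ≥ 0.5
(rejecting impossible cations like CH₉⁺). Precursor-fragment mass
differences are matched against a small packaged loss table (H₂O 18, NH₃ 17,
CH₅N 31, CO 28, HCN 27, CH₃ 15 — flagged as a radical loss — and C₂H₄ 28).
Note one deliberate departure from a printed source value: the tropylium ion
at m/z 91 is modelled as C7H7⁺ (nominal 91); the occasionally seen "C7H6⁺"
is mass-inconsistent (90) and is treated as a typographical slip. Likewise
iodine's mass is the standard 126.90 Da, not the rounded "129" sometimes
quoted.

**Ranking.** Composite score `0.3·isotope fit + 0.5·coverage + 0.2·db hit`.
Fragment evidence dominates because it is what actually discriminates
same-mass candidates; the isotope cluster mostly works through the hard
exclusions; a database hit is a bonus and its absence never eliminates a
candidate (new substances are absent by definition). Ties break by
|RDBE − 6| (drug-like aromatic unsaturation) and then Hill string, making
reports byte-reproducible. With no MS2 data the coverage term is dropped and
the remaining weights renormalized — the report is flagged accordingly.

## Tunable parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| fragmentor ladder | 110/90/70/40 | eV | typical ESI survey ladder |
| collision energies | 10/20/30/40 | eV | standard CID series |
| element bounds (`focused`) | C 8:15, H 7:20, N 2:4, O 0:2, F 0:1, S/Cl/Br/I 0:1 | counts | drug-like aromatic amine space; S/Cl/Br/I left for the evidence to strike |
| element bounds (`screen`) | C 0:30, H 0:40, N 0:5, O 0:6, F 0:2, S 0:2, Cl 0:3, Br 0:2, I 0:1 | counts | assumption-light screening |
| A+2 exclusion gate | 0.5 × single-atom M+2 | fraction | tolerates ±50% intensity error |
| subformula tolerance | 0.5 | Da | unit resolution |
| exact-mode tolerance | 0.005 Da or ppm string | Da/ppm | HRMS use |
| prune threshold | 1e-6 | fraction of base | keeps patterns exact to well past measurable lines |
| ranking weights | 0.3 / 0.5 / 0.2 | — | see above |
| noise σ | 0.05 | lognormal | ~5% multiplicative intensity scatter, the level at which measured M+1 ratios plausibly drift as observed on real quadrupoles |
| survival midpoint / width | 80 / 15 | eV | puts the precursor optimum at an interior ladder voltage |
| transmission knee | 60 | eV | transmission falls linearly below it |
| CE midpoint / width | 22 / 8 | eV | precursor survival decays over the CID series |

The upper element bounds are configuration, not code: no algorithm derives
"feasible atom ratios" from first principles, so the bounds ship as editable
presets (`default_config()`, `load_config()`).

## The synthetic generator: what it emulates and what it does not

`simulate_ms1()`/`simulate_ms2()` produce unit-resolution peak tables with
isotope clusters from the package's own pattern model, logistic
survival × linear transmission in the fragmentor voltage, logistic survival
in the collision energy, and multiplicative lognormal intensity noise on a
common cross-scan scale. The benchmark (`make_benchmark()`) samples
compounds from the packaged table and builds each compound's fragment
template generically from its formula (applicable neutral losses plus
aromatic marker ions).

Deliberately *not* modelled: chromatographic background and co-eluting
matrix ions, detector saturation, m/z calibration error, adducts, and —
most importantly — fragmentation chemistry beyond generic losses. Passing
the benchmark therefore shows that the deduction logic is internally
consistent and robust to intensity noise; it does **not** show that real
unknowns always present the clean evidence the generator provides. The
logistic parameters are simulation knobs, not measured claims. One
structural property of the packaged table also matters for interpretation:
it was curated so distinct formulas never share a nominal mass (isomers
share a formula instead), so a database hit at the correct mass is
unambiguous; against a large external database, same-mass hits for
different formulas would have to be separated by the isotope and fragment
scores alone.

Benchmark sizes were chosen to exercise every stage while keeping the
default test run quick: 20 compounds per benchmark at σ = 0 and σ = 0.05,
100 noise realizations for the precursor-recovery property, 100 random
instances for the enumeration oracle, all ≤ 5-atom formulas (2001
compositions) for the isotope oracle.

## Degenerate inputs and edge policies

* Empty spectra parse with a warning; all-zero intensity spectra cannot be
  normalized and error.
* A failed precursor call yields an `NA` call; the pipeline then requires an
  explicit `precursor =` value.
* A missing MH+2 intensity is treated as zero with a warning (exclusion
  proceeds).
* Unit binning merges co-rounding peaks by summing intensities.
* Contradictory enumeration bounds return an empty candidate tibble, and an
  empty candidate list still produces a valid report marked "no candidates".
* Unknown configuration keys fail fast with the closest valid key suggested.

## Limitations

Formula-level identification only: isomers are reported as an ambiguity set,
and resolving them requires orthogonal evidence (in practice, NMR). The
even-electron assumption excludes radical cations and electron-ionization
spectra. mzML/vendor formats are out of scope — the I/O layer reads the
package's CSV dialect and a minimal MSP record. GC-MS library matching and
anything downstream of formula assignment (structure elucidation,
pharmacology, legal status) are outside the package's remit.
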