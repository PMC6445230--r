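# npsid

Molecular-formula deduction for unknown small molecules — typically new
psychoactive substances (NPS) — from **unit-resolution LC–MS/MS data acquired
without a reference standard**.

New designer drugs reach the market faster than reference materials and
spectral libraries do. A forensic toxicology laboratory equipped with a
triple-quadrupole instrument (integer resolution, no accurate mass) can still
deduce the molecular formula of a seized unknown by combining a handful of
classical mass-spectrometric arguments. `npsid` implements that chain of
reasoning as a reusable, tested pipeline:

1. **Precursor determination** — the protonated molecule [M+H]⁺ is
   recognized across MS1 scans acquired at decreasing in-source fragmentor
   voltages as the high-m/z ion whose abundance peaks at a low voltage,
   while in-source fragments peak at the top of the ladder.
2. **Isotope-pattern element exclusion** — the measured MH+0/+1/+2 cluster
   is compared with the minimal M+2 contribution of one atom of each A+2
   element; S, Cl and Br are excluded when the measured (M+2)/(M+0) ratio
   falls below half of that single-atom contribution.
3. **Nitrogen rule and RDBE constraints** — an even neutral nominal mass
   forces an even nitrogen count (and odd, odd); aromatic marker fragments
   (phenyl 77, tropylium 91, phenylvinyl 103) force at least one benzene
   ring's worth of unsaturation, RDBE = C − (H+X)/2 + N/2 + 1 ≥ 4, and
   minimum C and H counts.
4. **Constrained formula enumeration** — all neutral formulas matching the
   target nominal mass within per-element bounds, solved exactly by mass
   closure over the hydrogen count (an exact-mass mode with Da/ppm
   tolerance is available for HRMS data).
5. **Fragment and neutral-loss annotation** — every product ion is explained
   as a cation subformula of the protonated candidate (counts ≤ precursor +
   1 H, cation RDBE ≥ 0.5) and/or as a named neutral loss (NH₃ −17,
   diagnostic of a primary amine; H₂O; CH₅N; …).
6. **Ranking and database correspondence** — candidates are scored by
   `0.3·isotope fit + 0.5·fragment coverage + 0.2·database hit` against a
   packaged, versioned table of ~40 NPS and common drugs; isomers sharing a
   formula are reported as an ambiguity set (formula-level identification is
   as far as MS alone can go — distinguishing isomers needs NMR).

A synthetic-data module simulates complete acquisitions (fragmentor ladders,
collision-energy series, isotope clusters, lognormal intensity noise) so the
whole pipeline is testable end to end without instrument data.

## Worked example: the unknown grey/red powder

The package ships a reconstruction of a real casework acquisition: four MS1
scans (fragmentor 110/90/70/40 eV) and four product-ion scans (CE
10/20/30/40 eV) of an unknown compound.

```r
library(npsid)

ex <- amt_example()
report <- run_pipeline(ex$ms1, ex$ms2)
report
#> <npsid_report>
#>   precursor [M+H]+ m/z 175 (best fragmentor 70 eV)
#>   cluster MH+0/+1/+2: 100.0 / 9.80 / 0.70
#>   excluded elements: S, Cl, Br
#>   4 candidate formula(s)
#>    1. C11H14N2     score 1.000  [5-IT, AMT]
#>    2. C10H10N2O    score 0.800
#>    3. C10H7FN2     score 0.800
#>    4. C9H10N4      score 0.800
```

Reading the report: the [M+H]⁺ was called at m/z 175 (neutral mass 174),
its isotope cluster excluded S/Cl/Br, the fragments 77/91/103/158 forced a
phenyl ring (RDBE ≥ 4), C ≥ 8, H ≥ 7 and an even nitrogen count ≥ 2, and
enumeration inside the C₈₋₁₅H₇₋₂₀N₂₋₄O₀₋₂F₀₋₁ space left exactly four
formulas. All four explain every fragment; the decisive margin is the
database correspondence of C₁₁H₁₄N₂ with the tryptamines AMT and 5-IT — an
isomer pair the mass spectrometer cannot separate. `report$applied_rules`
lists every rule with its outcome; `write_report()` saves a text + JSON
report.

Individual stages are ordinary functions on tibbles:

```r
exclude_a2_elements(c(100, 9.8, 0.7))      # S, Cl, Br all excluded
nitrogen_parity(174)                       # "even"
enumerate_formulas(enum_constraints(
  174, "C=8:15,H=7:20,N=2:4,O=0:2,F=0:1",
  n_parity = "even", min_rdbe = 4))        # the four candidates
assign_subformulas("C11H14N2", tibble::tibble(mz = c(77, 91, 103, 158)))
```

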