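Package: npsid
Title: Formula Deduction for Unknown Psychoactive Substances from
    Unit-Resolution LC-MS/MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to deduce the molecular formula of an unknown small
    molecule (typically a new psychoactive substance) from unit-resolution
    triple-quadrupole LC-MS/MS data acquired without a reference standard.
    Implements precursor determination from in-source fragmentation profiles
    across fragmentor voltages, isotope-pattern simulation and A+2 element
    (S, Cl, Br) exclusion, the nitrogen rule and ring-plus-double-bond
    equivalent constraints, constrained molecular-formula enumeration at
    nominal or exact mass, tandem-MS fragment and neutral-loss annotation,
    and candidate ranking against a packaged compound table. Includes a
    synthetic-spectrum generator emulating fragmentor- and collision-energy
    dependent acquisitions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    stats,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
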