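test_that("neutral losses resolve by exact mass difference", {
  nh3 <- neutral_loss(175, 158)
  expect_equal(nh3$name, "ammonia")
  expect_equal(nh3$nominal_mass, 17)
  expect_match(nh3$diagnostic_of, "primary amine")

  ch5n <- neutral_loss(190, 159)
  expect_equal(ch5n$formula, "CH5N")
  expect_equal(ch5n$nominal_mass, 31)

  expect_equal(nrow(neutral_loss(175, 175)), 0)
  expect_error(neutral_loss(158, 175), "exceeds")
})

test_that("diagnostic aromatic ions are assigned and labelled", {
  frags <- tibble(mz = c(77, 91, 103, 158))
  asg <- assign_subformulas("C11H14N2", frags)
  expect_true(all(c("C6H5+", "C7H7+", "C8H7+") %in% asg$ion_formula))
  lab <- asg[!is.na(asg$diagnostic_label), ]
  expect_equal(lab$diagnostic_label[lab$ion_formula == "C6H5+"], "phenyl")
  expect_equal(lab$diagnostic_label[lab$ion_formula == "C7H7+"], "tropylium")
  expect_equal(lab$diagnostic_label[lab$ion_formula == "C8H7+"], "phenylvinyl")
  # ammonia loss lands on the complement ion of the protonated molecule
  row158 <- asg[asg$fragment_mz == 158 & !is.na(asg$loss_name), ]
  expect_equal(row158$ion_formula, "C11H12N+")
  expect_equal(row158$loss_name, "ammonia")
})

test_that("benzofuran fragments are explained by mass closure", {
  asg <- assign_subformulas("C12H15NO", tibble(mz = c(159, 131)))
  expect_true("C11H11O+" %in% asg$ion_formula[asg$fragment_mz == 159])
  expect_true("C9H7O+" %in% asg$ion_formula[asg$fragment_mz == 131])
})

test_that("fragments heavier than the precursor get no assignment", {
  asg <- assign_subformulas("C2H6", tibble(mz = 77))
  expect_equal(nrow(asg), 1)
  expect_true(is.na(asg$ion_formula))
})

test_that("every assignment re-validates against the precursor", {
  prot <- formula_counts(parse_formula("C12H15NO"))
  prot[["H"]] <- prot[["H"]] + 1L
  asg <- assign_subformulas("C12H15NO", tibble(mz = c(58, 91, 131, 159, 173)))
  real <- asg[!is.na(asg$ion_formula), ]
  for (i in seq_len(nrow(real))) {
    ion <- parse_formula(real$ion_formula[i])
    expect_true(all(formula_counts(ion) <= prot))
    expect_equal(nominal_mass(ion), round(real$fragment_mz[i]))
    expect_gte(rdbe(ion), 0.5)
  }
})

test_that("assignments agree with the brute-force subformula oracle", {
  set.seed(47)
  precursors <- c("C6H5N", "C9H10O2", "C8H11N", "C5H9NO2")
  for (p in precursors) {
    masses <- sort(sample(30:(nominal_mass(p) + 1), 4))
    asg <- assign_subformulas(p, tibble(mz = masses))
    for (m in masses) {
      got <- sort(asg$ion_formula[asg$fragment_mz == m & !is.na(asg$ion_formula)])
      expect_identical(got, oracle_subformula_ions(p, m),
                       label = sprintf("%s @ %d", p, m))
    }
  }
})

test_that("coverage is intensity-weighted and oracle-consistent", {
  frags <- tibble(mz = c(77, 91, 103, 158), intensity = c(1, 1, 1, 1))
  asg <- assign_subformulas("C11H14N2", frags)
  expect_equal(explanation_coverage(asg, frags), 1)

  # the competing mass-174 candidates: coverage must equal what the
  # brute-force subformula oracle implies, explanation by explanation
  for (cand in c("C9H10N4", "C10H10N2O", "C10H7FN2")) {
    asg_c <- assign_subformulas(cand, frags)
    cov <- explanation_coverage(asg_c, frags)
    oracle_cov <- mean(sapply(frags$mz, function(m) {
      length(oracle_subformula_ions(cand, m)) > 0
    }))
    expect_equal(cov, oracle_cov, label = cand)
    expect_equal(cov, npsid:::candidate_coverage(cand, frags), label = cand)
  }

  # unexplainable signal lowers the weighted fraction proportionally
  frags2 <- tibble(mz = c(158, 300), intensity = c(75, 25))
  asg2 <- assign_subformulas("C11H14N2", frags2)
  expect_equal(explanation_coverage(asg2, frags2), 0.75)
  expect_error(explanation_coverage(asg2, frags2[0, ]), "at least one peak")
})

test_that("coverage never decreases when the loss table grows", {
  frags <- tibble(mz = c(158, 144), intensity = c(60, 40))
  small <- packaged_loss_table()[1, ] # water only
  full <- packaged_loss_table()
  cov_small <- explanation_coverage(
    assign_subformulas("C11H14N2", frags, loss_table = small), frags)
  cov_full <- explanation_coverage(
    assign_subformulas("C11H14N2", frags, loss_table = full), frags)
  expect_gte(cov_full, cov_small)
})
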