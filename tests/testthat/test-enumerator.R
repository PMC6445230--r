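amt_constraints <- function(min_rdbe = 4) {
  enum_constraints(174, "C=8:15,H=7:20,N=2:4,O=0:2,F=0:1",
                   n_parity = "even", min_rdbe = min_rdbe)
}

test_that("the mass-174 instance yields exactly four drug-like formulas", {
  out <- enumerate_formulas(amt_constraints())
  expect_setequal(out$formula,
                  c("C10H7FN2", "C9H10N4", "C10H10N2O", "C11H14N2"))
  expect_true(all(out$nominal_mass == 174))
  expect_true(all(out$rdbe >= 4))
  expect_true(all(audit_candidates(out, amt_constraints())))
})

test_that("relaxing the aromatic RDBE floor admits saturated compositions", {
  relaxed <- enumerate_formulas(amt_constraints(min_rdbe = 0))
  expect_true("C8H18N2O2" %in% relaxed$formula)
  strict <- enumerate_formulas(amt_constraints())
  expect_false("C8H18N2O2" %in% strict$formula)
})

test_that("small closed-form instances behave", {
  benzene <- enumerate_formulas(enum_constraints(78, list(C = c(0, 6), H = c(0, 6))))
  expect_equal(benzene$formula, "C6H6")

  none <- enumerate_formulas(enum_constraints(50, list(C = c(10, 12), H = c(0, 5))))
  expect_equal(nrow(none), 0)
})

test_that("unbounded search spaces are refused", {
  expect_error(
    enumerate_formulas(enum_constraints(100, list(C = c(0, Inf), H = c(0, 20)))),
    "unbounded")
})

test_that("enumeration equals the brute-force oracle on random instances", {
  set.seed(41)
  for (i in 1:100) {
    cons <- random_constraints()
    expect_setequal(enumerate_formulas(cons)$formula,
                    brute_force_enumerate(cons)$formula)
  }
})

test_that("candidate order is deterministic and sorted by unsaturation", {
  a <- enumerate_formulas(amt_constraints())
  b <- enumerate_formulas(amt_constraints())
  expect_identical(a, b)
  expect_true(all(diff(a$rdbe) <= 0))
})

test_that("exact-mass mode recovers the formula within tolerance", {
  cons <- enum_constraints(174.1157, "C=8:15,H=7:20,N=2:4,O=0:2,F=0:1",
                           n_parity = "even", min_rdbe = 4,
                           mode = "exact", tolerance = 0.005)
  out <- enumerate_formulas(cons)
  expect_equal(out$formula, "C11H14N2")
  expect_equal(out$monoisotopic_mass, 174.1157, tolerance = 1e-3)
  cons_ppm <- enum_constraints(174.1157, "C=8:15,H=7:20,N=2:4,O=0:2,F=0:1",
                               mode = "exact", tolerance = "5ppm")
  expect_true("C11H14N2" %in% enumerate_formulas(cons_ppm)$formula)
})

test_that("evidence-derived constraints reproduce the printed search space", {
  frags <- tibble(mz = c(77, 91, 103, 158), intensity = c(40, 50, 35, 100))
  excl <- exclude_a2_elements(c(100, 9.8, 0.7))
  cons <- derive_constraints(175, frags, excl, config = default_config())
  expect_equal(cons$target_mass, 174)
  expect_equal(cons$bounds$C, c(8, 15))
  expect_equal(cons$bounds$H, c(7, 20))
  expect_equal(cons$bounds$N, c(2, 4))
  expect_equal(cons$bounds$O, c(0, 2))
  expect_equal(cons$bounds$F, c(0, 1))
  expect_equal(cons$n_parity, "even")
  expect_equal(cons$min_rdbe, 4)
  expect_setequal(cons$excluded_elements, c("S", "Cl", "Br", "I"))
  expect_true(all(unlist(cons$bounds[c("S", "Cl", "Br", "I")]) == 0))

  # the pipeline reproduces the four printed formulas from this evidence
  expect_setequal(enumerate_formulas(cons)$formula,
                  c("C10H7FN2", "C9H10N4", "C10H10N2O", "C11H14N2"))
})

test_that("aromatic constraints stay off without marker ions", {
  cons <- derive_constraints(175, tibble(mz = 158, intensity = 100),
                             exclusions = NULL,
                             config = default_config("screen"))
  expect_equal(cons$min_rdbe, 0)
  expect_equal(cons$bounds$C, c(0, 30))
})

test_that("iodine is excluded when the mass budget cannot fit it", {
  cons <- derive_constraints(121, tibble(mz = 103, intensity = 1),
                             exclusions = NULL, config = default_config())
  # 120 - 127 < 12 * 8: no room for iodine beside the required carbons
  expect_true("I" %in% cons$excluded_elements)
})

test_that("a missing precursor demands explicit input", {
  expect_error(derive_constraints(NA_real_, NULL, NULL), "precursor")
})
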