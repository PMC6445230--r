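test_that("single-element patterns match natural abundance ratios", {
  br <- simulate_pattern("Br")
  expect_equal(br$offset, c(0L, 2L))
  expect_equal(br$abundance[2], 0.973, tolerance = 1e-3)

  c1 <- simulate_pattern("C")
  expect_lt(abs(c1$abundance[c1$offset == 1] - 0.0108), 2e-4)

  h <- simulate_pattern("H", prune_threshold = 1e-3)
  expect_equal(h$offset, 0L) # deuterium pruned
})

test_that("a one-bromine drug cation shows the near-equal M/M+2 doublet", {
  pat <- simulate_pattern(chem_formula(c(C = 10, H = 13, Br = 1, N = 1, O = 3),
                                       charge = 1L))
  r <- pat$abundance[pat$offset == 2] / pat$abundance[pat$offset == 0]
  expect_gte(r, 0.95)
  expect_lte(r, 1.10)
})

test_that("patterns agree with exhaustive isotopologue expansion", {
  set.seed(7)
  for (i in 1:60) {
    f <- random_formula(sample(supported_elements(), 3), 2)
    if (sum(unclass(f)) > 5) next
    pat <- simulate_pattern(f, prune_threshold = 1e-12)
    oracle <- oracle_isotope_pattern(f)
    merged <- dplyr::full_join(pat, oracle, by = "offset",
                               suffix = c("_pkg", "_oracle"))
    merged[is.na(merged)] <- 0
    expect_lt(max(abs(merged$abundance_pkg - merged$abundance_oracle)), 1e-9)
  }
})

test_that("element order inside the formula string is irrelevant", {
  expect_equal(simulate_pattern("C7H9N"), simulate_pattern("NH9C7"))
})

test_that("pruning discards at most threshold x n_lines of total abundance", {
  set.seed(13)
  for (i in 1:20) {
    f <- random_formula(c("C", "H", "N", "O", "S", "Cl"), 8)
    full <- simulate_pattern(f, prune_threshold = 1e-15)
    t <- 10^sample(-6:-2, 1)
    pruned <- simulate_pattern(f, prune_threshold = t)
    lost <- sum(full$abundance) - sum(pruned$abundance)
    expect_lte(lost, t * nrow(full) + 1e-12)
  }
})

test_that("the printed cluster excludes S, Cl and Br; strong M+2 excludes nothing", {
  ex <- exclude_a2_elements(c(100, 9.8, 0.7))
  expect_equal(ex$element, c("S", "Cl", "Br"))
  expect_true(all(ex$excluded))
  expect_equal(ex$measured_ratio, rep(0.007, 3))

  none <- exclude_a2_elements(c(100, 11, 97))
  expect_false(any(none$excluded))

  all_gone <- exclude_a2_elements(c(100, 0, 0))
  expect_true(all(all_gone$excluded))
})

test_that("a missing M+2 entry is a warning, not an error", {
  expect_warning(ex <- exclude_a2_elements(c(100, 9.8)), "MH\\+2")
  expect_true(all(ex$excluded))
})

test_that("elements actually present are never excluded on simulated clusters", {
  set.seed(17)
  for (i in 1:200) {
    heavy <- sample(c("S", "Cl", "Br"), 1)
    cnt <- c(C = sample(1:15, 1), H = sample(1:20, 1))
    cnt[heavy] <- sample(1:2, 1)
    pat <- simulate_pattern(chem_formula(cnt, charge = 1L))
    cluster <- sapply(0:2, function(o) {
      v <- pat$abundance[pat$offset == o]
      if (length(v)) v else 0
    })
    cluster <- cluster / cluster[1] * 100
    # multiplicative noise at the generator's default level
    cluster[2:3] <- cluster[2:3] * exp(rnorm(2, 0, 0.05))
    ex <- exclude_a2_elements(c(100, cluster[2:3]))
    expect_false(ex$excluded[ex$element == heavy])
  }
})

test_that("the nitrogen rule maps mass parity to nitrogen parity", {
  expect_equal(nitrogen_parity(174), "even")
  expect_equal(nitrogen_parity(189), "odd") # one-nitrogen benzofuran amine
  expect_equal(nitrogen_parity(18), "even")
  expect_error(nitrogen_parity(0), "positive")
})

test_that("isotope fit score separates halogenated from CHN compositions", {
  pat <- simulate_pattern("C11H15N2+")
  self_cluster <- sapply(0:2, function(o) {
    v <- pat$abundance[pat$offset == o]
    if (length(v)) v else 0
  })
  expect_equal(isotope_fit_score("C11H15N2+", self_cluster), 1, tolerance = 1e-9)
  expect_gt(isotope_fit_score("C11H15N2+", c(100, 9.8, 0.7)), 0.99)
  expect_lt(isotope_fit_score(
    chem_formula(c(C = 10, H = 13, Br = 1, N = 1, O = 3), charge = 1L),
    c(100, 9.8, 0.7)), 0.8)
})
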