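test_that("the packaged compound table loads, validates and round-trips", {
  db <- compound_db()
  expect_gt(nrow(db), 30)
  expect_true(all(nominal_mass(db$formula) > 0))
  expect_false(any(duplicated(paste(db$name, db$formula))))
  # one neutral formula per nominal mass (isomers share the formula), so a
  # formula-level hit is never ambiguous across masses
  by_mass <- db |> distinct(nominal_mass, formula) |> count(nominal_mass)
  expect_true(all(by_mass$n == 1))

  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(db |> select(name, synonyms, formula, class), path)
  back <- compound_db(path)
  expect_equal(back$name, db$name)
  expect_equal(back$formula, db$formula)
})

test_that("formula lookup returns the isomer ambiguity set alphabetically", {
  hits <- lookup_formula(compound_db(), "C11H14N2")
  expect_true(all(c("AMT", "5-IT") %in% hits$name))
  expect_equal(hits$name, sort(hits$name))

  expect_equal(lookup_formula(compound_db(), "C12H15NO")$name, "5-MAPB")
  expect_equal(nrow(lookup_formula(compound_db(), "CH4")), 0)
})

fake_candidates <- function() {
  tibble(
    formula = c("C11H14N2", "C9H10N4"),
    rdbe = c(6, 7),
    nominal_mass = c(174, 174),
    isotope_score = c(0.99, 0.95),
    fragment_coverage = c(1, 0.6),
    db_hits = list(c("AMT", "5-IT"), character())
  )
}

test_that("composite ranking is deterministic and weight-monotone", {
  r <- rank_candidates(fake_candidates())
  expect_equal(r$formula[1], "C11H14N2")
  expect_equal(r$rank, c(1L, 2L))
  expect_equal(r$score[1], 0.3 * 0.99 + 0.5 * 1 + 0.2 * 1)

  # raising any single component raises the composite
  base <- fake_candidates()
  for (col in c("isotope_score", "fragment_coverage")) {
    bumped <- base
    bumped[[col]][2] <- bumped[[col]][2] + 0.2
    expect_gt(rank_candidates(bumped)$score[rank_candidates(bumped)$formula == "C9H10N4"],
              r$score[r$formula == "C9H10N4"])
  }

  expect_warning(rank_candidates(fake_candidates(), weights = c(1, 1, 1)),
                 "normalizing")
})

test_that("score ties break by drug-like RDBE then Hill string", {
  tied <- tibble(
    formula = c("C9H10N4", "C10H10N2O"),
    rdbe = c(7, 7),
    nominal_mass = c(174, 174),
    isotope_score = c(0.9, 0.9),
    fragment_coverage = c(1, 1),
    db_hits = list(character(), character())
  )
  r <- rank_candidates(tied)
  expect_equal(r$formula, c("C10H10N2O", "C9H10N4")) # Hill order
  single <- rank_candidates(tied[1, ])
  expect_equal(single$rank, 1L)
})

test_that("the packaged unknown-powder case resolves to the tryptamine isomer set", {
  ex <- amt_example()
  rep <- run_pipeline(ex$ms1, ex$ms2)
  expect_setequal(rep$candidates$formula,
                  c("C10H7FN2", "C9H10N4", "C10H10N2O", "C11H14N2"))
  expect_equal(rep$candidates$formula[1], "C11H14N2")
  expect_setequal(rep$candidates$db_hits[[1]], c("AMT", "5-IT"))
  expect_equal(rep$cluster, c(100, 9.8, 0.7), tolerance = 1e-6)
  expect_true(all(c("precursor_selection", "isotope_exclusion", "enumeration",
                    "ranking") %in% rep$applied_rules$stage))
})

test_that("reports are reproducible and round-trip through their JSON block", {
  ex <- amt_example()
  rep <- run_pipeline(ex$ms1, ex$ms2)
  p1 <- withr::local_tempfile(fileext = ".txt")
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_report(rep, p1)
  write_report(run_pipeline(ex$ms1, ex$ms2), p2)
  expect_identical(readLines(p1), readLines(p2))

  back <- read_report(p1)
  expect_equal(back$candidates$formula, rep$candidates$formula)
  expect_equal(back$precursor$mz, 175)
  expect_false(back$no_candidates)
})

test_that("tidy and glance summarize the report", {
  ex <- amt_example()
  rep <- run_pipeline(ex$ms1, ex$ms2)
  td <- tidy(rep)
  expect_equal(td$rank, 1:4)
  expect_equal(td$formula[1], "C11H14N2")
  expect_true(grepl("AMT", td$db_hits[1]))
  g <- glance(rep)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_candidates, 4L)
  expect_equal(g$top_formula, "C11H14N2")
})

test_that("without product-ion data the ranking degrades to isotope evidence", {
  ex <- amt_example()
  rep <- run_pipeline(ex$ms1, ms2 = NULL)
  expect_true(all(is.na(rep$candidates$fragment_coverage)))
  expect_gt(nrow(rep$candidates), 0)
  expect_true(any(grepl("no fragment evidence", rep$applied_rules$outcome)))
})

test_that("plot helpers return ggplot objects", {
  ex <- amt_example()
  expect_s3_class(plot_spectrum(ex$ms1), "ggplot")
  expect_s3_class(plot_precursor_profile(select_precursor(ex$ms1)), "ggplot")
  rep <- run_pipeline(ex$ms1, ex$ms2)
  expect_s3_class(autoplot(rep), "ggplot")
})
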