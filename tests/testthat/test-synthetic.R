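test_that("simulations are exactly reproducible for a fixed seed", {
  cfg <- sim_config("C11H14N2", seed = 42)
  expect_identical(simulate_ms1(cfg), simulate_ms1(cfg))
  expect_identical(simulate_ms2(cfg), simulate_ms2(cfg))
  other <- sim_config("C11H14N2", seed = 43)
  expect_false(identical(simulate_ms1(cfg), simulate_ms1(other)))
})

test_that("noiseless scans follow the closed-form survival model", {
  cfg <- sim_config("C11H14N2", seed = 1, noise_sigma = 0)
  ms1 <- simulate_ms1(cfg)
  for (v in cfg$fragmentor_voltages) {
    s <- 1 / (1 + exp((v - cfg$survival_midpoint) / cfg$survival_width))
    tr <- min(1, v / cfg$transmission_knee)
    got <- ms1$intensity[ms1$fragmentor_voltage == v & ms1$mz == 175]
    expect_equal(got, 100 * s * tr, tolerance = 1e-9)
  }
  # the precursor is maximal at an interior voltage of the ladder
  prof <- ms1 |> filter(mz == 175) |> arrange(fragmentor_voltage)
  expect_equal(prof$fragmentor_voltage[which.max(prof$intensity)], 70)
  # isotope ratio matches the simulated pattern exactly at sigma = 0
  pat <- simulate_pattern("C11H15N2+")
  r_theory <- pat$abundance[pat$offset == 1]
  scan70 <- ms1 |> filter(fragmentor_voltage == 70)
  expect_equal(scan70$intensity[scan70$mz == 176] /
                 scan70$intensity[scan70$mz == 175],
               r_theory, tolerance = 1e-9)
})

test_that("the aromatic amine template produces the four diagnostic fragments", {
  tmpl <- tibble(kind = c("ion", "ion", "ion", "loss"),
                 value = c("C6H5+", "C7H7+", "C8H7+", "ammonia"),
                 intensity = c(40, 55, 35, 100))
  cfg <- sim_config("C11H14N2", fragment_template = tmpl, seed = 2,
                    noise_sigma = 0)
  ms2 <- simulate_ms2(cfg)
  ce40 <- ms2 |> filter(collision_energy == 40, intensity > 1)
  expect_true(all(c(77, 91, 103, 158) %in% ce40$mz))
  # precursor survival falls with collision energy
  surv <- ms2 |> filter(mz == 175) |> arrange(collision_energy)
  expect_true(all(diff(surv$intensity) < 0))
})

test_that("a brominated precursor keeps its doublet through simulation", {
  cfg <- sim_config("bk-2C-B", seed = 9, noise_sigma = 0.05)
  ms2 <- simulate_ms2(cfg)
  ce10 <- ms2 |> filter(collision_energy == 10)
  r <- ce10$intensity[ce10$mz == 276] / ce10$intensity[ce10$mz == 274]
  # 81Br/79Br abundance ratio within 3 sigma of the multiplicative noise
  expect_equal(r, 0.9728, tolerance = 3 * sqrt(2) * 0.05)
})

test_that("isotope ratios converge to theory over replicates at default noise", {
  pat <- simulate_pattern("C11H15N2+")
  r_theory <- pat$abundance[pat$offset == 1]
  ratios <- sapply(1:100, function(i) {
    cfg <- sim_config("C11H14N2", seed = 5000 + i, noise_sigma = 0.05)
    s <- simulate_ms1(cfg) |> filter(fragmentor_voltage == 70)
    s$intensity[s$mz == 176] / s$intensity[s$mz == 175]
  })
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - r_theory), 3 * se + 1e-4)
})

test_that("an empty template yields precursor-only spectra", {
  tmpl <- tibble(kind = character(), value = character(),
                 intensity = numeric())
  cfg <- sim_config("C11H14N2", fragment_template = tmpl, seed = 3,
                    noise_sigma = 0)
  ms1 <- simulate_ms1(cfg)
  expect_true(all(ms1$mz >= 175))
})

test_that("inapplicable template losses fail naming the entry", {
  tmpl <- tibble(kind = "loss", value = "water", intensity = 50)
  cfg <- sim_config("C9H13N", fragment_template = tmpl, seed = 1)
  expect_error(simulate_ms2(cfg), "water")
})

test_that("benchmarks are labelled, deterministic and fully processable", {
  b1 <- make_benchmark(4, seed = 7, noise_sigma = 0)
  b2 <- make_benchmark(4, seed = 7, noise_sigma = 0)
  expect_identical(b1$manifest, b2$manifest)
  expect_identical(b1$cases[[2]]$ms2, b2$cases[[2]]$ms2)
  expect_equal(nrow(b1$manifest), 4)
  expect_equal(b1$manifest$formula, sapply(b1$cases, `[[`, "formula"))

  dir <- withr::local_tempdir()
  make_benchmark(2, seed = 8, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_length(list.files(dir, pattern = "ms[12]\\.csv$"), 4)
  back <- read_peaklist(file.path(dir, "case01_ms1.csv"))
  expect_gt(nrow(back), 0)

  for (cs in b1$cases[1:2]) {
    rep <- run_pipeline(cs$ms1, cs$ms2, config = default_config("screen"))
    expect_gt(nrow(rep$candidates), 0)
  }
})
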