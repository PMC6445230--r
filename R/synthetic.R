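#' Configuration for synthetic triple-quadrupole acquisitions
#'
#' Describes one simulated compound acquisition: MS1 scans across a ladder of
#' fragmentor voltages and MS2 product-ion scans across collision energies,
#' at unit resolution with multiplicative lognormal intensity noise.
#'
#' The in-source behaviour is modelled as a logistic precursor survival in
#' the fragmentor voltage (midpoint `survival_midpoint`, scale
#' `survival_width`) multiplied by an ion-transmission factor that falls
#' linearly below `transmission_knee`; the product peaks at an interior
#' voltage, reproducing the practical observation that the protonated
#' molecule is best seen neither at the highest nor the lowest fragmentor
#' setting. Collision-cell survival follows the same logistic form in the
#' collision energy.
#'
#' @param compound A neutral formula string, or a compound name present in
#'   [compound_db()].
#' @param fragmentor_voltages MS1 fragmentor ladder in eV (default
#'   `c(110, 90, 70, 40)`).
#' @param collision_energies MS2 collision energies in eV (default
#'   `c(10, 20, 30, 40)`).
#' @param fragment_template Tibble with columns `kind` (`"ion"` or
#'   `"loss"`), `value` (ion formula with `+`, or a loss name from the loss
#'   table) and `intensity` (relative, at full fragmentation). Default: a
#'   generic template derived from the formula (see Details).
#' @param survival_midpoint,survival_width Logistic parameters for in-source
#'   survival (eV); defaults 80 and 15.
#' @param transmission_knee Voltage below which overall transmission falls
#'   linearly (default 60 eV).
#' @param ce_midpoint,ce_width Logistic parameters for collision-cell
#'   survival (eV); defaults 22 and 8.
#' @param noise_sigma Lognormal sigma of multiplicative intensity noise
#'   (default 0.05; 0 gives the exact closed-form spectra).
#' @param seed Integer seed; a fixed seed yields identical output.
#' @details The generic template applies, in order and when the elements
#'   allow it: loss of ammonia (primary amine), water, methylamine and
#'   carbon monoxide, plus the aromatic diagnostic ions tropylium (91),
#'   phenyl (77) and phenylvinyl (103) for formulas with RDBE >= 4.
#' @return A `sim_config` list.
#' @examples
#' sim_config("C11H14N2", seed = 1)
#' @export
sim_config <- function(compound,
                       fragmentor_voltages = c(110, 90, 70, 40),
                       collision_energies = c(10, 20, 30, 40),
                       fragment_template = NULL,
                       survival_midpoint = 80, survival_width = 15,
                       transmission_knee = 60,
                       ce_midpoint = 22, ce_width = 8,
                       noise_sigma = 0.05, seed = 1L) {
  name <- compound
  if (!grepl("^[A-Z]", compound) ||
      inherits(try(parse_formula(compound), silent = TRUE), "try-error")) {
    hit <- filter(compound_db(), .data$name == compound)
    if (!nrow(hit)) {
      abort(sprintf("'%s' is neither a formula nor a packaged compound name",
                    compound))
    }
    compound <- hit$formula[1]
  }
  if (anyDuplicated(fragmentor_voltages) || anyDuplicated(collision_energies)) {
    abort("voltages and collision energies must be distinct")
  }
  template <- fragment_template %||% default_fragment_template(compound)
  if (!all(c("kind", "value", "intensity") %in% names(template)) ||
      any(template$intensity <= 0)) {
    abort("fragment_template needs kind/value/intensity columns with positive intensities")
  }
  structure(
    list(compound = compound, label = name,
         fragmentor_voltages = fragmentor_voltages,
         collision_energies = collision_energies,
         fragment_template = template,
         survival_midpoint = survival_midpoint,
         survival_width = survival_width,
         transmission_knee = transmission_knee,
         ce_midpoint = ce_midpoint, ce_width = ce_width,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_fragment_template <- function(compound) {
  f <- as_chem_formula(compound)
  cnt <- formula_counts(f)
  prot <- cnt
  prot[["H"]] <- prot[["H"]] + 1L
  r <- rdbe(f)
  rows <- list()
  add <- function(kind, value, intensity) {
    rows[[length(rows) + 1L]] <<- tibble(kind = kind, value = value,
                                         intensity = intensity)
  }
  if (prot[["N"]] >= 1 && prot[["H"]] >= 3) add("loss", "ammonia", 100)
  if (prot[["O"]] >= 1 && prot[["H"]] >= 2) add("loss", "water", 80)
  if (prot[["N"]] >= 1 && prot[["C"]] >= 1 && prot[["H"]] >= 5) {
    add("loss", "methylamine", 45)
  }
  if (prot[["O"]] >= 1 && prot[["C"]] >= 1) add("loss", "carbon monoxide", 30)
  if (r >= 4) {
    if (prot[["C"]] >= 7 && prot[["H"]] >= 7) add("ion", "C7H7+", 55)
    if (prot[["C"]] >= 6 && prot[["H"]] >= 5) add("ion", "C6H5+", 40)
    if (prot[["C"]] >= 8 && prot[["H"]] >= 7) add("ion", "C8H7+", 35)
  }
  if (!length(rows)) add("loss", "methyl radical", 40)
  bind_rows(rows)
}

# resolve template entries to ion formulas (charge +1)
resolve_template <- function(config, loss_table = packaged_loss_table()) {
  prot <- formula_counts(as_chem_formula(config$compound))
  prot[["H"]] <- prot[["H"]] + 1L
  pmap(config$fragment_template, function(kind, value, intensity) {
    ion <- if (kind == "ion") {
      formula_counts(as_chem_formula(value))
    } else {
      entry <- filter(loss_table, .data$name == value)
      if (!nrow(entry)) {
        abort(sprintf("template loss '%s' not in the loss table", value))
      }
      res <- prot - formula_counts(entry$formula[1])
      if (any(res < 0)) {
        abort(sprintf(
          "template entry '%s' not applicable to %s (element deficit)",
          value, config$compound))
      }
      res
    }
    list(formula = chem_formula(ion[ion > 0], charge = 1L),
         intensity = intensity)
  })
}

logistic_survival <- function(x, midpoint, width) {
  1 / (1 + exp((x - midpoint) / width))
}

transmission_factor <- function(v, knee) pmin(1, v / knee)

# cluster of an ion as (mz, intensity) rows scaled to `scale`
ion_cluster <- function(ion_formula, scale, prune = 1e-4) {
  pat <- simulate_pattern(ion_formula, prune_threshold = prune)
  tibble(mz = nominal_mass(ion_formula) + pat$offset,
         intensity = pat$abundance * scale)
}

assemble_scan <- function(peaks, sigma, scan_type, label,
                          fragmentor_voltage = NA, collision_energy = NA) {
  d <- peaks |>
    group_by(.data$mz) |>
    summarise(intensity = sum(.data$intensity), .groups = "drop")
  if (sigma > 0) {
    d$intensity <- d$intensity * exp(rnorm(nrow(d), 0, sigma))
  }
  # absolute scale is kept so that abundance is comparable across scans
  spectrum_tbl(d$mz, d$intensity,
               scan_type = scan_type, fragmentor_voltage = fragmentor_voltage,
               collision_energy = collision_energy, label = label)
}

#' Simulate MS1 scans across the fragmentor ladder
#'
#' Per voltage, the protonated molecule's isotope cluster is scaled by
#' survival x transmission and the template fragments (with their own
#' isotope clusters) by (1 - survival) x transmission; multiplicative
#' lognormal noise is applied. Intensities stay on one common scale across
#' the ladder so that precursor abundance is comparable between voltages.
#'
#' @param config A [sim_config()].
#' @param loss_table Neutral-loss table used to resolve template losses.
#' @return A spectrum tibble of one MS1 scan per voltage.
#' @export
simulate_ms1 <- function(config, loss_table = packaged_loss_table()) {
  stopifnot(inherits(config, "sim_config"))
  prot <- formula_counts(as_chem_formula(config$compound))
  prot[["H"]] <- prot[["H"]] + 1L
  prot_f <- chem_formula(prot[prot > 0], charge = 1L)
  frags <- resolve_template(config, loss_table)
  tmpl_max <- if (length(frags)) max(map_dbl(frags, "intensity")) else 1

  withr::with_seed(config$seed, {
    map(config$fragmentor_voltages, function(v) {
      s <- logistic_survival(v, config$survival_midpoint, config$survival_width)
      tr <- transmission_factor(v, config$transmission_knee)
      peaks <- bind_rows(
        ion_cluster(prot_f, 100 * s * tr),
        map(frags, function(fr) {
          ion_cluster(fr$formula, 100 * fr$intensity / tmpl_max * (1 - s) * tr)
        })
      )
      assemble_scan(peaks, config$noise_sigma, "MS1",
                    label = sprintf("%s MS1 F%g", config$label, v),
                    fragmentor_voltage = v)
    }) |> bind_rows()
  })
}

#' Simulate MS2 product-ion scans across collision energies
#'
#' Per collision energy, the surviving precursor cluster is scaled by the
#' collision-cell logistic survival and the template fragments by its
#' complement; noise and normalization as in [simulate_ms1()].
#'
#' @inheritParams simulate_ms1
#' @return A spectrum tibble of one MS2 scan per collision energy.
#' @export
simulate_ms2 <- function(config, loss_table = packaged_loss_table()) {
  stopifnot(inherits(config, "sim_config"))
  prot <- formula_counts(as_chem_formula(config$compound))
  prot[["H"]] <- prot[["H"]] + 1L
  prot_f <- chem_formula(prot[prot > 0], charge = 1L)
  frags <- resolve_template(config, loss_table)
  tmpl_max <- if (length(frags)) max(map_dbl(frags, "intensity")) else 1

  withr::with_seed(config$seed + 1L, {
    map(config$collision_energies, function(ce) {
      s <- logistic_survival(ce, config$ce_midpoint, config$ce_width)
      peaks <- bind_rows(
        ion_cluster(prot_f, 100 * s),
        map(frags, function(fr) {
          ion_cluster(fr$formula, 100 * fr$intensity / tmpl_max * (1 - s))
        })
      )
      assemble_scan(peaks, config$noise_sigma, "MS2",
                    label = sprintf("%s MS2 CE%g", config$label, ce),
                    collision_energy = ce)
    }) |> bind_rows()
  })
}

#' Generate a labelled benchmark of synthetic cases
#'
#' Samples compounds from the compound table, simulates a full MS1 + MS2
#' acquisition for each, and returns the cases together with their
#' ground-truth formulas; optionally writes everything to a directory of CSV
#' peak lists plus a JSON manifest. The same seed reproduces the identical
#' bundle.
#'
#' @param n_cases Number of cases (compounds are sampled without
#'   replacement; at most `nrow(db)`).
#' @param seed Integer seed.
#' @param noise_sigma Lognormal intensity-noise sigma for all cases.
#' @param db Compound table to sample from.
#' @param dir Optional output directory.
#' @return A list with `cases` (each: `name`, `formula`, `ms1`, `ms2`,
#'   `config`) and `manifest` (a tibble).
#' @export
make_benchmark <- function(n_cases, seed = 1L, noise_sigma = 0.05,
                           db = compound_db(), dir = NULL) {
  if (n_cases < 1) abort("n_cases must be >= 1")
  if (n_cases > nrow(db)) {
    abort(sprintf("n_cases exceeds the %d compounds available", nrow(db)))
  }
  picks <- withr::with_seed(seed, sample(nrow(db), n_cases))
  cases <- imap(picks, function(row, i) {
    rec <- db[row, ]
    cfg <- sim_config(rec$formula[1],
                      noise_sigma = noise_sigma,
                      seed = as.integer((as.numeric(seed) * 1009 + i * 7919) %%
                                          2000000000))
    cfg$label <- rec$name[1]
    list(name = rec$name[1], formula = rec$formula[1],
         ms1 = simulate_ms1(cfg), ms2 = simulate_ms2(cfg), config = cfg)
  })
  manifest <- tibble(
    case = seq_along(cases),
    name = map_chr(cases, "name"),
    formula = map_chr(cases, "formula"),
    nominal_mass = nominal_mass(map_chr(cases, "formula")),
    seed = map_int(cases, function(cs) cs$config$seed),
    noise_sigma = noise_sigma
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(cases)) {
      write_peaklist(cases[[i]]$ms1,
                     file.path(dir, sprintf("case%02d_ms1.csv", i)))
      write_peaklist(cases[[i]]$ms2,
                     file.path(dir, sprintf("case%02d_ms2.csv", i)))
    }
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  list(cases = cases, manifest = manifest)
}
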