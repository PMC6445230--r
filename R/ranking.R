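#' Rank candidate formulas by composite evidence score
#'
#' Composite score per candidate:
#' `w_iso * isotope_score + w_cov * fragment_coverage + w_db * has_db_hit`.
#' The default weights (0.3, 0.5, 0.2) put most weight on fragment evidence,
#' with the isotope cluster serving mainly for element exclusion and a
#' database hit acting as a bonus only - absence from the table never
#' eliminates a candidate, since genuinely new substances are absent by
#' definition. Components that are `NA` for every candidate (e.g. coverage
#' when no product-ion data exist) are dropped and the remaining weights
#' renormalized. Ties break by smaller `|rdbe - 6|` (drug-like aromatic
#' unsaturation) and then by Hill string, so the ordering is deterministic.
#'
#' @param candidates Tibble with columns `formula`, `rdbe`, `isotope_score`,
#'   `fragment_coverage` and `db_hits` (list-column of compound names).
#' @param weights Length-3 numeric (isotope, coverage, database); normalized
#'   with a warning when the sum is not 1.
#' @return The candidates with `score` and `rank` columns, sorted by rank.
#' @export
rank_candidates <- function(candidates,
                            weights = c(isotope = 0.3, coverage = 0.5,
                                        database = 0.2)) {
  if (!nrow(candidates)) {
    return(mutate(candidates, score = numeric(0), rank = integer(0)))
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    warn("ranking weights do not sum to 1; normalizing")
    weights <- weights / sum(weights)
  }
  comp <- tibble(
    isotope = candidates$isotope_score,
    coverage = candidates$fragment_coverage,
    database = as.numeric(map_int(candidates$db_hits, length) > 0)
  )
  use <- map_lgl(comp, function(col) !all(is.na(col)))
  w <- weights[use]
  w <- w / sum(w)
  score_mat <- as.matrix(comp[, use, drop = FALSE])
  score_mat[is.na(score_mat)] <- 0
  candidates |>
    mutate(score = as.numeric(score_mat %*% w)) |>
    arrange(desc(.data$score), abs(.data$rdbe - 6), .data$formula) |>
    mutate(rank = row_number())
}

#' Run the full deduction pipeline on one unknown
#'
#' Orchestrates the stages in the order an analyst works through them on a
#' unit-resolution triple quadrupole: (1) call the protonated molecule from
#' the MS1 scans acquired at decreasing fragmentor voltages; (2) read its
#' MH+0/+1/+2 isotope cluster and exclude A+2 elements; (3) apply the
#' nitrogen rule and derive element/RDBE constraints from the product-ion
#' evidence; (4) enumerate all formulas consistent with the constraints;
#' (5) score each candidate by isotope-cluster fit and fragment-explanation
#' coverage; (6) resolve candidates against the compound table and rank.
#' Every applied rule is logged in the report.
#'
#' @param ms1 Spectrum tibble of MS1 scans at several fragmentor voltages.
#' @param ms2 Spectrum tibble of MS2 product-ion scans (may be `NULL`;
#'   candidates are then ranked without fragment evidence).
#' @param config Run configuration (see [default_config()]).
#' @param db Compound table (default: packaged).
#' @param loss_table Neutral-loss table (default: packaged).
#' @param precursor Optional user-supplied precursor m/z, used when the
#'   automatic call fails.
#' @return An `npsid_report` object; see [tidy.npsid_report()],
#'   [glance.npsid_report()], [write_report()].
#' @examples
#' cfg <- sim_config("C11H14N2", seed = 1, noise_sigma = 0)
#' rep <- run_pipeline(simulate_ms1(cfg), simulate_ms2(cfg),
#'                     config = default_config("screen"))
#' head(tidy(rep))
#' @export
run_pipeline <- function(ms1, ms2 = NULL, config = default_config(),
                         db = compound_db(), loss_table = packaged_loss_table(),
                         precursor = NULL) {
  rules <- list()
  note <- function(stage, rule, outcome) {
    rules[[length(rules) + 1L]] <<- tibble(stage = stage, rule = rule,
                                          outcome = outcome)
  }

  # stage 1: precursor -------------------------------------------------------
  call <- select_precursor(ms1)
  if (is.na(call$mz) && !is.null(precursor)) {
    call <- tibble(mz = round(precursor), best_fragmentor = NA_real_,
                   profile = list(tibble(fragmentor_voltage = numeric(),
                                         intensity = numeric())))
    note("precursor_selection", "user-supplied precursor",
         sprintf("automatic call failed; using m/z %d", call$mz))
  } else if (is.na(call$mz)) {
    abort("precursor_selection: no precursor called and none supplied")
  } else {
    note("precursor_selection", "low-fragmentor survival",
         sprintf("[M+H]+ called at m/z %d (maximal at %g eV)",
                 call$mz, call$best_fragmentor))
  }

  # stage 2: isotope cluster and A+2 exclusion -------------------------------
  binned <- normalize_to_base_peak(bin_unit_resolution(ms1))
  ref_scan <- if (!is.na(call$best_fragmentor)) {
    filter(binned, .data$fragmentor_voltage == call$best_fragmentor)
  } else {
    filter(binned, .data$fragmentor_voltage == max(.data$fragmentor_voltage))
  }
  cl_int <- map_dbl(call$mz + 0:2, function(m) {
    v <- ref_scan$intensity[ref_scan$mz == m]
    if (length(v)) v[1] else 0
  })
  if (cl_int[1] <= 0) abort("isotope_cluster: precursor absent from reference scan")
  cluster <- cl_int / cl_int[1] * 100
  exclusions <- exclude_a2_elements(cluster)
  note("isotope_exclusion", "A+2 (M+2)/(M+0) threshold",
       sprintf("cluster (%.1f, %.2f, %.2f): excluded {%s}",
               cluster[1], cluster[2], cluster[3],
               paste(exclusions$element[exclusions$excluded], collapse = ", ")))

  # stage 3: fragment evidence ----------------------------------------------
  fragments <- NULL
  if (!is.null(ms2) && nrow(ms2)) {
    merged <- ms2 |>
      bin_unit_resolution() |>
      group_by(mz = .data$mz) |>
      summarise(intensity = max(.data$intensity), .groups = "drop")
    # strip isotope satellites, the precursor cluster and sub-1% noise
    sat <- map_lgl(seq_len(nrow(merged)), function(i) {
      any(merged$mz %in% (merged$mz[i] - 1:2) &
            merged$intensity > merged$intensity[i])
    })
    fragments <- merged |>
      filter(!sat, .data$mz < call$mz - 0.5,
             .data$intensity >= 0.01 * max(.data$intensity)) |>
      mutate(intensity = .data$intensity / max(.data$intensity) * 100)
    if (!nrow(fragments)) fragments <- NULL
  }
  if (is.null(fragments)) {
    note("fragment_evidence", "product-ion assembly",
         "no fragment evidence; candidates ranked without coverage")
  } else {
    note("fragment_evidence", "product-ion assembly",
         sprintf("%d fragment peaks at m/z %s", nrow(fragments),
                 paste(fragments$mz, collapse = "/")))
  }

  # stage 4: constraints and enumeration -------------------------------------
  constraints <- derive_constraints(call, fragments, exclusions,
                                    config = config, loss_table = loss_table)
  crules <- attr(constraints, "rules")
  for (i in seq_len(nrow(crules))) {
    note("constraint_derivation", crules$rule[i], crules$outcome[i])
  }
  candidates <- enumerate_formulas(constraints)
  note("enumeration", "constrained formula enumeration",
       sprintf("%d candidate formula(s) at neutral mass %s",
               nrow(candidates), format(constraints$target_mass)))

  # stage 5: per-candidate evidence scores ------------------------------------
  if (nrow(candidates)) {
    candidates <- candidates |>
      mutate(
        isotope_score = map_dbl(.data$formula, function(fs) {
          prot <- formula_counts(parse_formula(fs))
          prot[["H"]] <- prot[["H"]] + 1L
          isotope_fit_score(chem_formula(prot[prot > 0], charge = 1L), cluster)
        }),
        fragment_coverage = if (is.null(fragments)) NA_real_ else {
          map_dbl(.data$formula, function(fs) {
            candidate_coverage(fs, fragments, loss_table = loss_table)
          })
        },
        db_hits = map(.data$formula, function(fs) lookup_formula(db, fs)$name)
      )
  } else {
    candidates <- candidates |>
      mutate(isotope_score = numeric(0), fragment_coverage = numeric(0),
             db_hits = list())
  }

  # stage 6: ranking ----------------------------------------------------------
  ranked <- rank_candidates(candidates, config$weights)
  if (nrow(ranked)) {
    top_hits <- ranked$db_hits[[1]]
    note("ranking", "composite score",
         sprintf("top candidate %s (score %.3f)%s", ranked$formula[1],
                 ranked$score[1],
                 if (length(top_hits)) {
                   sprintf("; database correspondence: %s",
                           paste(top_hits, collapse = ", "))
                 } else {
                   "; no database correspondence"
                 }))
  } else {
    note("ranking", "composite score", "no candidates to rank")
  }

  structure(
    list(
      precursor = call, cluster = cluster, exclusions = exclusions,
      constraints = constraints, candidates = ranked,
      applied_rules = bind_rows(rules),
      provenance = list(
        package = "npsid",
        version = as.character(utils::packageVersion("npsid")),
        seed = config$seed,
        inputs = unique(c(ms1$spectrum, if (!is.null(ms2)) ms2$spectrum))
      )
    ),
    class = "npsid_report"
  )
}

#' @export
print.npsid_report <- function(x, ...) {
  cat("<npsid_report>\n")
  cat(sprintf("  precursor [M+H]+ m/z %s (best fragmentor %s eV)\n",
              format(x$precursor$mz), format(x$precursor$best_fragmentor)))
  cat(sprintf("  cluster MH+0/+1/+2: %.1f / %.2f / %.2f\n",
              x$cluster[1], x$cluster[2], x$cluster[3]))
  excl <- x$exclusions$element[x$exclusions$excluded]
  cat("  excluded elements:",
      if (length(excl)) paste(excl, collapse = ", ") else "none", "\n")
  n <- nrow(x$candidates)
  cat(sprintf("  %d candidate formula(s)\n", n))
  if (n) {
    top <- head(x$candidates, 5)
    for (i in seq_len(nrow(top))) {
      hits <- top$db_hits[[i]]
      cat(sprintf("   %d. %-12s score %.3f%s\n", top$rank[i], top$formula[i],
                  top$score[i],
                  if (length(hits)) paste0("  [", paste(hits, collapse = ", "), "]")
                  else ""))
    }
  } else {
    cat("   (no candidates)\n")
  }
  invisible(x)
}

#' Write an identification report
#'
#' Writes a human-readable summary followed by a machine-readable JSON block
#' (candidates, scores, applied rules, provenance) delimited by a
#' `"===== JSON ====="` marker line, so the same file serves the analyst and
#' downstream tooling. [read_report()] restores the JSON block.
#'
#' @param report An `npsid_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "npsid_report"))
  txt <- utils::capture.output(print(report))
  rules <- report$applied_rules
  txt <- c(txt, "", "Applied rules:",
           sprintf("  [%s] %s: %s", rules$stage, rules$rule, rules$outcome))
  cands <- report$candidates |>
    mutate(db_hits = map_chr(.data$db_hits, paste, collapse = "|"))
  payload <- list(
    precursor = list(mz = report$precursor$mz,
                     best_fragmentor = report$precursor$best_fragmentor),
    cluster = report$cluster,
    excluded_elements = report$exclusions$element[report$exclusions$excluded],
    target_mass = report$constraints$target_mass,
    no_candidates = nrow(cands) == 0,
    candidates = cands,
    applied_rules = rules,
    provenance = report$provenance
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
  writeLines(c(txt, "", "===== JSON =====", json), path)
  invisible(path)
}

#' Read back the machine-readable block of a written report
#'
#' @param path Path written by [write_report()].
#' @return A list with the parsed JSON payload; `$candidates` is a tibble in
#'   the written ranking order.
#' @export
read_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  mark <- which(lines == "===== JSON =====")
  if (!length(mark)) abort("no JSON block found in report file")
  payload <- jsonlite::fromJSON(paste(lines[(mark + 1):length(lines)],
                                      collapse = "\n"))
  if (!is.null(payload$candidates) && length(payload$candidates)) {
    payload$candidates <- as_tibble(payload$candidates)
  }
  payload
}
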