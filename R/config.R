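#' Run configuration
#'
#' A validated list of the knobs shared across the pipeline. Two presets are
#' provided. `"focused"` (the default) reproduces the search space a
#' forensic analyst would set up once the evidence points at a small
#' drug-like aromatic amine: nominal-mass mode with element bounds
#' C 8:15, H 7:20, N 2:4, O 0:2, F 0:1 and single allowances for S/Cl/Br/I
#' that the isotope-evidence stage can strike out. `"screen"` is a wider,
#' assumption-light space (C 0:30, H 0:40, N 0:5, O 0:6, F 0:2, S 0:2,
#' Cl 0:3, Br 0:2, I 0:1) for unknowns with no prior; expect larger
#' candidate lists.
#'
#' @param preset `"focused"` or `"screen"`.
#' @param ... Named overrides of individual keys (see Details).
#' @details Valid keys: `mode` (`"nominal"`/`"exact"`), `tolerance` (Da, or
#'   `"5ppm"`), `bounds` (named list or `"C=8:15,..."` string), `min_rdbe`,
#'   `max_rdbe`, `weights` (length-3: isotope, coverage, database),
#'   `loss_table_path` / `db_path` (`"packaged"` or a file path), `seed`
#'   (integer), `log_level`. Unknown keys are rejected with a suggestion.
#' @return A `run_config` list.
#' @examples
#' default_config()
#' default_config("screen", seed = 7)
#' @export
default_config <- function(preset = c("focused", "screen"), ...) {
  preset <- match.arg(preset)
  bounds <- if (preset == "focused") {
    list(C = c(8, 15), H = c(7, 20), N = c(2, 4), O = c(0, 2), F = c(0, 1),
         S = c(0, 1), Cl = c(0, 1), Br = c(0, 1), I = c(0, 1))
  } else {
    list(C = c(0, 30), H = c(0, 40), N = c(0, 5), O = c(0, 6), F = c(0, 2),
         S = c(0, 2), Cl = c(0, 3), Br = c(0, 2), I = c(0, 1))
  }
  cfg <- list(
    mode = "nominal",
    tolerance = 0.005,
    bounds = bounds,
    min_rdbe = 0,
    max_rdbe = Inf,
    weights = c(isotope = 0.3, coverage = 0.5, database = 0.2),
    loss_table_path = "packaged",
    db_path = "packaged",
    seed = 1L,
    log_level = "INFO"
  )
  validate_config(modify_config(cfg, list(...)))
}

#' Load a run configuration from a JSON file
#'
#' Reads a JSON object of configuration keys, applies it over the defaults
#' and validates the result; unknown keys are rejected with the closest
#' valid key suggested.
#'
#' @param path Path to a JSON file, or `NULL` for pure defaults.
#' @param preset Base preset to override (see [default_config()]).
#' @return A validated `run_config` list.
#' @export
load_config <- function(path = NULL, preset = "focused") {
  cfg <- default_config(preset)
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(user$bounds) && is.list(user$bounds)) {
    user$bounds <- lapply(user$bounds, as.numeric)
  }
  if (!is.null(user$weights)) {
    user$weights <- setNames(as.numeric(user$weights),
                             c("isotope", "coverage", "database"))
  }
  validate_config(modify_config(cfg, user))
}

modify_config <- function(cfg, changes) {
  if (!length(changes)) return(cfg)
  valid <- names(cfg)
  for (key in names(changes)) {
    if (!key %in% valid) {
      near <- valid[which.min(adist(key, valid))]
      abort(sprintf(
        "unknown configuration key '%s' (did you mean '%s'?). Valid keys: %s",
        key, near, paste(valid, collapse = ", ")))
    }
    cfg[[key]] <- changes[[key]]
  }
  cfg
}

validate_config <- function(cfg) {
  if (!cfg$mode %in% c("nominal", "exact")) {
    abort('config: mode must be "nominal" or "exact"')
  }
  cfg$bounds <- parse_bounds(cfg$bounds)
  for (el in names(cfg$bounds)) {
    b <- cfg$bounds[[el]]
    if (length(b) != 2 || b[1] > b[2] || b[1] < 0) {
      abort(sprintf(
        "config: invalid bounds for %s; expected c(min, max), e.g. C = c(8, 15)",
        el))
    }
  }
  if (length(cfg$weights) != 3 || any(cfg$weights < 0)) {
    abort("config: weights must be 3 non-negative numbers (isotope, coverage, database)")
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("run_config", "list"))
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  b <- map_chr(names(x$bounds), function(el) {
    sprintf("%s=%d:%d", el, x$bounds[[el]][1], x$bounds[[el]][2])
  })
  cat("  mode:", x$mode, " tolerance:", format(x$tolerance), "\n")
  cat("  bounds:", paste(b, collapse = ","), "\n")
  cat("  weights:", paste(sprintf("%s=%.2f", names(x$weights), x$weights),
                          collapse = " "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
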