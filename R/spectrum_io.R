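#' Build a peak-table spectrum
#'
#' Spectra are plain tibbles with one row per peak and the acquisition
#' metadata repeated along the rows, so that a set of scans is a single tidy
#' table that pipes through dplyr verbs. Columns: `spectrum` (label),
#' `scan_type` (`"MS1"` or `"MS2"`), `polarity`, `fragmentor_voltage` (eV,
#' `NA` when not applicable), `collision_energy` (eV, `NA` for MS1), `mz`,
#' `intensity`.
#'
#' @param mz,intensity Numeric vectors of equal length; `mz > 0`,
#'   `intensity >= 0`.
#' @param scan_type `"MS1"` or `"MS2"`.
#' @param fragmentor_voltage,collision_energy Acquisition energies in eV.
#' @param polarity `"positive"` or `"negative"`.
#' @param label Free-text spectrum label.
#' @return A tibble sorted by ascending `mz`.
#' @examples
#' spectrum_tbl(c(175, 176, 177), c(100, 9.8, 0.7),
#'              scan_type = "MS1", fragmentor_voltage = 70)
#' @export
spectrum_tbl <- function(mz, intensity, scan_type = "MS1",
                         fragmentor_voltage = NA_real_,
                         collision_energy = NA_real_,
                         polarity = "positive", label = "spectrum") {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) && (any(mz <= 0) || any(intensity < 0))) {
    abort("peaks must have mz > 0 and intensity >= 0")
  }
  if (!scan_type %in% c("MS1", "MS2")) abort("scan_type must be MS1 or MS2")
  tibble(
    spectrum = label, scan_type = scan_type, polarity = polarity,
    fragmentor_voltage = as.numeric(fragmentor_voltage),
    collision_energy = as.numeric(collision_energy),
    mz = as.numeric(mz), intensity = as.numeric(intensity)
  ) |> arrange(.data$mz)
}

spectrum_cols <- c("spectrum", "scan_type", "polarity", "fragmentor_voltage",
                   "collision_energy", "mz", "intensity")

check_spectra <- function(df) {
  missing <- setdiff(spectrum_cols, names(df))
  if (length(missing)) {
    abort(sprintf("not a spectrum table; missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Read peak lists with acquisition metadata
#'
#' Two plain-text formats are supported. `"csv"`: one or more blocks of
#' `#`-prefixed `key=value` header lines (keys `scan_type`, `polarity`,
#' `fragmentor_voltage`, `collision_energy`, `label`) followed by `mz,intensity`
#' rows (an optional `mz,intensity` column-header row is tolerated); a new
#' header block after data rows starts a new spectrum. `"msp"`: minimal
#' MSP-like records (`Name:`, `Comment:` with `key=value` pairs,
#' `Num Peaks:`, then whitespace-separated `mz intensity` lines).
#'
#' @param source Path to a file, or a character vector of lines.
#' @param format `"csv"` or `"msp"`.
#' @return A spectrum tibble (see [spectrum_tbl()]); several spectra are
#'   stacked and distinguished by the `spectrum` column.
#' @export
read_peaklist <- function(source, format = c("csv", "msp")) {
  format <- match.arg(format)
  lines <- if (length(source) == 1 && !grepl("\n", source) &&
               file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (is.character(source)) {
    unlist(strsplit(source, "\n", fixed = TRUE))
  } else {
    abort("`source` must be a readable file path or character lines")
  }
  if (format == "csv") parse_peaklist_csv(lines) else parse_peaklist_msp(lines)
}

parse_peaklist_csv <- function(lines) {
  blocks <- list()
  meta <- list()
  mz <- numeric(); int <- numeric()
  in_data <- FALSE
  n_spec <- 0L

  flush <- function() {
    n_spec <<- n_spec + 1L
    if (!length(mz)) warn(sprintf("empty spectrum '%s' (no peaks)",
                                  meta$label %||% paste0("spectrum", n_spec)))
    blocks[[n_spec]] <<- spectrum_tbl(
      mz, int,
      scan_type = meta$scan_type %||% "MS1",
      fragmentor_voltage = as.numeric(meta$fragmentor_voltage %||% NA),
      collision_energy = as.numeric(meta$collision_energy %||% NA),
      polarity = meta$polarity %||% "positive",
      label = meta$label %||% paste0("spectrum", n_spec)
    )
    meta <<- list(); mz <<- numeric(); int <<- numeric(); in_data <<- FALSE
  }

  started <- FALSE
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    if (startsWith(line, "#")) {
      if (in_data) flush()
      started <- TRUE
      kv <- trimws(sub("^#+", "", line))
      if (grepl("=", kv, fixed = TRUE)) {
        key <- trimws(sub("=.*$", "", kv))
        val <- trimws(sub("^[^=]*=", "", kv))
        meta[[key]] <- val
      }
      next
    }
    fields <- trimws(strsplit(line, ",", fixed = TRUE)[[1]])
    if (length(fields) < 2) {
      abort(sprintf("line %d: expected 'mz,intensity', got '%s'", i, line))
    }
    if (identical(tolower(fields[1]), "mz")) next # column header row
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (any(is.na(vals))) {
      abort(sprintf("line %d: non-numeric mz/intensity in '%s'", i, line))
    }
    started <- TRUE
    in_data <- TRUE
    mz <- c(mz, vals[1]); int <- c(int, vals[2])
  }
  if (started || !n_spec) flush()
  bind_rows(blocks)
}

parse_peaklist_msp <- function(lines) {
  blocks <- list()
  meta <- list(); mz <- numeric(); int <- numeric()
  flush <- function() {
    if (!length(meta) && !length(mz)) return(invisible())
    if (!length(mz)) warn(sprintf("empty spectrum '%s' (no peaks)",
                                  meta$label %||% "unnamed"))
    blocks[[length(blocks) + 1L]] <<- spectrum_tbl(
      mz, int,
      scan_type = meta$scan_type %||% "MS1",
      fragmentor_voltage = as.numeric(meta$fragmentor_voltage %||% NA),
      collision_energy = as.numeric(meta$collision_energy %||% NA),
      polarity = meta$polarity %||% "positive",
      label = meta$label %||% "unnamed"
    )
    meta <<- list(); mz <<- numeric(); int <<- numeric()
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    if (grepl("^Name:", line, ignore.case = TRUE)) {
      flush()
      meta$label <- trimws(sub("^Name:", "", line, ignore.case = TRUE))
    } else if (grepl("^Comment:", line, ignore.case = TRUE)) {
      body <- trimws(sub("^Comment:", "", line, ignore.case = TRUE))
      for (kv in strsplit(body, "[[:space:]]+")[[1]]) {
        if (grepl("=", kv, fixed = TRUE)) {
          meta[[sub("=.*$", "", kv)]] <- sub("^[^=]*=", "", kv)
        }
      }
    } else if (grepl("^Num ?Peaks:", line, ignore.case = TRUE)) {
      next
    } else {
      fields <- strsplit(line, "[[:space:],;]+")[[1]]
      vals <- suppressWarnings(as.numeric(fields[1:2]))
      if (any(is.na(vals))) {
        abort(sprintf("line %d: non-numeric peak line '%s'", i, line))
      }
      mz <- c(mz, vals[1]); int <- c(int, vals[2])
    }
  }
  flush()
  bind_rows(blocks)
}

#' Write peak lists
#'
#' Inverse of [read_peaklist()]; metadata fields round-trip and peak values
#' are written with enough digits to reproduce them to 6 significant figures.
#'
#' @param spectra A spectrum tibble.
#' @param path Output file path.
#' @param format `"csv"` or `"msp"`.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(spectra, path, format = c("csv", "msp")) {
  format <- match.arg(format)
  check_spectra(spectra)
  out <- character()
  for (lab in unique(spectra$spectrum)) {
    s <- filter(spectra, .data$spectrum == lab)
    m <- s[1, ]
    if (format == "csv") {
      hdr <- c(
        sprintf("# label=%s", lab),
        sprintf("# scan_type=%s", m$scan_type),
        sprintf("# polarity=%s", m$polarity),
        if (!is.na(m$fragmentor_voltage))
          sprintf("# fragmentor_voltage=%g", m$fragmentor_voltage),
        if (!is.na(m$collision_energy))
          sprintf("# collision_energy=%g", m$collision_energy)
      )
      body <- c("mz,intensity",
                sprintf("%.10g,%.10g", s$mz, s$intensity))
      out <- c(out, hdr, body, "")
    } else {
      cm <- paste0(
        "scan_type=", m$scan_type, " polarity=", m$polarity,
        if (!is.na(m$fragmentor_voltage))
          paste0(" fragmentor_voltage=", m$fragmentor_voltage),
        if (!is.na(m$collision_energy))
          paste0(" collision_energy=", m$collision_energy)
      )
      out <- c(out,
               paste0("Name: ", lab),
               paste0("Comment: ", cm),
               paste0("Num Peaks: ", nrow(s)),
               sprintf("%.10g %.10g", s$mz, s$intensity),
               "")
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Normalize spectra to base peak 100
#'
#' Scales each spectrum so its most intense peak is 100; relative ratios are
#' preserved and the operation is idempotent.
#'
#' @param spectra A spectrum tibble (one or more spectra).
#' @return The rescaled tibble.
#' @examples
#' s <- spectrum_tbl(c(274, 276), c(80, 78))
#' normalize_to_base_peak(s)
#' @export
normalize_to_base_peak <- function(spectra) {
  check_spectra(spectra)
  if (!nrow(spectra)) return(spectra)
  spectra |>
    group_by(.data$spectrum) |>
    group_modify(function(d, key) {
      top <- max(d$intensity)
      if (top <= 0) {
        abort(sprintf("spectrum '%s' has no positive intensity", key$spectrum))
      }
      mutate(d, intensity = .data$intensity / top * 100)
    }) |>
    ungroup() |>
    select(all_of(spectrum_cols)) |>
    arrange(.data$spectrum, .data$mz)
}

#' Bin peaks to unit (integer) m/z resolution
#'
#' Merges peaks whose m/z round to the same integer, summing intensities, as
#' appropriate for integer-resolution triple-quadrupole data.
#'
#' @param spectra A spectrum tibble.
#' @return The binned tibble with integer `mz`.
#' @export
bin_unit_resolution <- function(spectra) {
  check_spectra(spectra)
  spectra |>
    mutate(mz = round(.data$mz)) |>
    group_by(across(all_of(setdiff(spectrum_cols, "intensity")))) |>
    summarise(intensity = sum(.data$intensity), .groups = "drop") |>
    select(all_of(spectrum_cols)) |>
    arrange(.data$spectrum, .data$mz)
}
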