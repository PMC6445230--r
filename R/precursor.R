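#' Call the protonated molecule from MS1 scans at several fragmentor voltages
#'
#' In-source fragmentation depletes the precursor ion at high fragmentor
#' voltage, so the protonated molecule is recognized as the ion whose relative
#' intensity is maximal at a low voltage, while in-source fragments peak at
#' the top of the scanned range. Scans are binned to integer m/z on their
#' common intensity scale; candidate ions are the peaks present in the
#' lowest-voltage scan, with isotope satellites (a peak 1 or 2 Da above a
#' stronger peak) removed. The call is the highest-m/z candidate whose
#' intensity across voltages peaks at or below the median scanned voltage
#' (ties in the profile resolve to the lower voltage; candidates with
#' identical profiles resolve to the higher m/z, since in-source fragments
#' are always lighter than their precursor).
#'
#' @param scans A spectrum tibble of at least two MS1 scans with distinct
#'   `fragmentor_voltage` values and a common polarity.
#' @return A one-row tibble: `mz` (integer Da; `NA` if no candidate survives
#'   the selection rule), `best_fragmentor` (eV) and `profile`, a list-column
#'   holding the called ion's voltage/relative-intensity table.
#' @examples
#' # a synthetic acquisition where 175 peaks at 70 eV
#' cfg <- sim_config("C11H14N2", seed = 1, noise_sigma = 0)
#' select_precursor(simulate_ms1(cfg))
#' @export
select_precursor <- function(scans) {
  check_spectra(scans)
  scans <- filter(scans, .data$scan_type == "MS1")
  volts <- scans |> distinct(.data$spectrum, .data$fragmentor_voltage)
  if (nrow(volts) < 2 || anyNA(volts$fragmentor_voltage)) {
    abort("need >= 2 MS1 scans, each with a fragmentor_voltage")
  }
  if (length(unique(scans$polarity)) != 1) {
    abort("all scans must share one polarity")
  }
  # bin only: the cross-scan abundance comparison needs the common scale
  binned <- bin_unit_resolution(scans)

  med_v <- median(volts$fragmentor_voltage)
  low_v <- min(volts$fragmentor_voltage)
  low_scan <- filter(binned, .data$fragmentor_voltage == low_v)

  # candidates: peaks in the lowest-voltage scan, minus isotope satellites
  is_satellite <- map_lgl(seq_len(nrow(low_scan)), function(i) {
    m <- low_scan$mz[i]
    any(low_scan$mz %in% c(m - 1, m - 2) &
          low_scan$intensity > low_scan$intensity[i])
  })
  cand_mz <- sort(low_scan$mz[!is_satellite], decreasing = TRUE)

  profile_of <- function(m) {
    binned |>
      filter(.data$mz == m) |>
      right_join(volts, by = c("spectrum", "fragmentor_voltage")) |>
      transmute(fragmentor_voltage = .data$fragmentor_voltage,
                intensity = coalesce(.data$intensity, 0)) |>
      mutate(intensity = .data$intensity / max(.data$intensity) * 100) |>
      arrange(.data$fragmentor_voltage)
  }

  for (m in cand_mz) {
    prof <- profile_of(m)
    # argmax voltage, ties resolved to the lower voltage
    best_v <- prof$fragmentor_voltage[which.max(prof$intensity)]
    if (best_v <= med_v) {
      return(tibble(mz = m, best_fragmentor = best_v, profile = list(prof)))
    }
  }
  inform("no ion peaks at low fragmentor voltage; no precursor called")
  tibble(mz = NA_real_, best_fragmentor = NA_real_,
         profile = list(tibble(fragmentor_voltage = numeric(),
                               intensity = numeric())))
}
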