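#' Packaged worked example: the unknown tryptamine case
#'
#' A synthetic reconstruction of a real casework acquisition on an unknown
#' grey/red seized powder: four MS1 scans across the 110/90/70/40 eV
#' fragmentor ladder in which the protonated molecule at m/z 175 is most
#' abundant at 70 eV and carries the measured isotope cluster
#' 175 (100%) / 176 (9.8%) / 177 (0.7%), and four product-ion scans whose
#' diagnostic fragments are m/z 77, 91, 103 and 158. Only the cluster ratios
#' and the fragment list are measured values; the scan-to-scan intensity
#' scaling is an emulation (the files are labelled `synthetic`).
#'
#' @return A list with spectrum tibbles `ms1` and `ms2`.
#' @examples
#' ex <- amt_example()
#' select_precursor(ex$ms1)
#' @export
amt_example <- function() {
  dir <- system.file("extdata", "amt", package = "npsid", mustWork = TRUE)
  list(
    ms1 = read_peaklist(file.path(dir, "amt_ms1_synthetic.csv")),
    ms2 = read_peaklist(file.path(dir, "amt_ms2_synthetic.csv"))
  )
}
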