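extdata_path <- function(file) {
  system.file("extdata", file, package = "mcdamage", mustWork = TRUE)
}

#' Packaged reference tables for the ultrasoft X-ray study design
#'
#' Published per-category damage-yield tables at 21%, 2% and 0.1% O2 for the
#' five radiation qualities, the measured and simulated DSB yields with their
#' RBE values, the aggregate repair-outcome probabilities, and the
#' induction/conversion RBE summary. These serve as calibration targets and
#' static comparison columns in reports; they are never recomputed.
#'
#' Note: the carbon K-shell rows of the yield tables are internally
#' inconsistent (their constituent columns do not sum to the printed totals,
#' although the totals columns are mutually consistent); [read_damage_spectra()]
#' flags this. Calibration for carbon should target the totals columns.
#'
#' @return Named list of tibbles: `yields` (all three oxygen levels bound
#'   together), `dsb` (measured/simulated DSB yields and RBEs), `repair`
#'   (aggregate outcome probabilities), `conversion` (induction and
#'   enzymatic-DSB yields and RBEs).
#' @export
#' @examples
#' ref <- reference_tables()
#' ref$dsb
reference_tables <- function() {
  yields <- dplyr::bind_rows(
    read_damage_spectra(extdata_path("yields_21pct.tsv"), validate = FALSE),
    read_damage_spectra(extdata_path("yields_2pct.tsv"), validate = FALSE),
    read_damage_spectra(extdata_path("yields_0p1pct.tsv"), validate = FALSE)
  )
  rd <- function(f) readr::read_tsv(extdata_path(f), show_col_types = FALSE,
                                    progress = FALSE)
  list(
    yields = yields,
    dsb = rd("dsb_reference.tsv"),
    repair = rd("repair_reference.tsv"),
    conversion = rd("conversion_reference.tsv")
  )
}

#' Quality labels of the reference study design, lowest energy last
#'
#' @return Character vector of the five quality labels; the Co-60 reference
#'   quality is `"Co-60"`.
#' @export
reference_quality_labels <- function() {
  c("Titanium K-shell", "Aluminum K-shell", "Copper L-shell",
    "Carbon K-shell", "Co-60")
}
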