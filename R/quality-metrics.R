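#' Relative biological effectiveness from yield ratios
#'
#' Because DSB induction is linear in absorbed dose over the relevant range,
#' the RBE of a test radiation against a reference reduces to the ratio of
#' their DSB yields per unit dose: `RBE = sigma_test / sigma_ref`.
#'
#' @param sigma_test Yield(s) of the test radiation (per Gy per Gbp).
#' @param sigma_ref Yield of the reference radiation (> 0).
#' @return Dimensionless RBE (vectorized over `sigma_test`).
#' @export
#' @examples
#' rbe(21.2, 8.1)  # carbon K-shell vs Co-60
rbe <- function(sigma_test, sigma_ref) {
  if (any(sigma_ref <= 0)) abort("reference yield must be positive")
  sigma_test / sigma_ref
}

#' Hypoxia reduction factor
#'
#' Ratio of the yield under aerobic conditions (21% O2) to the yield under
#' hypoxia, for the same endpoint and radiation quality.
#'
#' @param sigma_aerobic Aerobic yield(s).
#' @param sigma_hypoxic Hypoxic yield(s) (> 0).
#' @return Dimensionless HRF (vectorized).
#' @export
#' @examples
#' hrf(8.1, 3.5)  # Co-60, 21% vs 0.1% O2
hrf <- function(sigma_aerobic, sigma_hypoxic) {
  if (any(sigma_hypoxic <= 0)) abort("hypoxic yield must be positive")
  sigma_aerobic / sigma_hypoxic
}

#' Percent reduction of a yield under hypoxia
#'
#' @param y_aerobic Aerobic yield (> 0).
#' @param y_hypoxic Hypoxic yield.
#' @return Percent reduction `100 (1 - y_hypoxic / y_aerobic)`; report layers
#'   round it to the nearest integer percent.
#' @export
#' @examples
#' reduction_percent(21.2, 15.5)  # ~27%
reduction_percent <- function(y_aerobic, y_hypoxic) {
  if (any(y_aerobic <= 0)) abort("aerobic yield must be positive")
  100 * (1 - y_hypoxic / y_aerobic)
}

#' Dose-weighted average of an energy-resolved quantity
#'
#' Averages an energy-resolved yield (optionally multiplied by an
#' energy-resolved probability) over a secondary-electron fluence spectrum
#' with the dose-weighting kernel `Phi(E) LET(E)`:
#' `<Y> = Int Y(E) p(E) Phi(E) LET(E) dE / Int Phi(E) LET(E) dE`.
#' For a line spectrum the integrals collapse to weighted sums over the
#' lines. Density spectra are integrated by the trapezoidal rule on the
#' union of the two energy grids in log energy, with log-linear
#' interpolation of the sparser function. The result is invariant to
#' rescaling the fluence by any positive constant.
#'
#' @param yields Tibble with `energy_eV`, a value column, and optionally a
#'   probability column.
#' @param fluence A fluence spectrum (line or density type).
#' @param model A [stopping_power_model()].
#' @param value_col Name of the value column (default `"yield"`).
#' @param prob_col Optional name of the probability column; when NULL the
#'   probability is taken as 1.
#' @return The dose-weighted average (scalar).
#' @export
dose_weighted_average <- function(yields, fluence,
                                  model = stopping_power_model(),
                                  value_col = "yield", prob_col = NULL) {
  if (!"energy_eV" %in% names(yields) || !value_col %in% names(yields)) {
    abort("`yields` needs columns energy_eV and the value column")
  }
  y_interp <- function(e) {
    if (nrow(yields) == 1) return(rep(yields[[value_col]], length(e)))
    approx(log(yields$energy_eV), yields[[value_col]], xout = log(e),
           rule = 2)$y
  }
  p_interp <- function(e) {
    if (is.null(prob_col)) return(rep(1, length(e)))
    if (nrow(yields) == 1) return(rep(yields[[prob_col]], length(e)))
    approx(log(yields$energy_eV), yields[[prob_col]], xout = log(e),
           rule = 2)$y
  }
  if (is_line_spectrum(fluence)) {
    e <- fluence$energy_eV
    w <- fluence$fluence * let_electron(e, model)
    return(sum(w * y_interp(e) * p_interp(e)) / sum(w))
  }
  lo <- max(min(fluence$energy_eV), min(yields$energy_eV))
  hi <- min(max(fluence$energy_eV), max(yields$energy_eV))
  if (nrow(yields) == 1) {
    lo <- min(fluence$energy_eV)
    hi <- max(fluence$energy_eV)
  }
  if (!(hi > lo)) abort("fluence and yield energy grids do not overlap")
  e <- sort(unique(c(fluence$energy_eV, yields$energy_eV)))
  e <- e[e >= lo & e <= hi]
  phi <- approx(log(fluence$energy_eV), fluence$fluence, xout = log(e),
                rule = 2)$y
  w <- phi * let_electron(e, model)
  num <- trapz(e, w * y_interp(e) * p_interp(e))
  den <- trapz(e, w)
  num / den
}

#' Dose-weighted mean LET of a fluence spectrum
#'
#' `<LET> = Int Phi LET^2 dE / Int Phi LET dE`, a scalar radiation-quality
#' descriptor of a secondary-electron spectrum.
#'
#' @param fluence A fluence spectrum.
#' @param model A [stopping_power_model()].
#' @return Mean LET in eV/nm.
#' @export
dose_mean_let <- function(fluence, model = stopping_power_model()) {
  e <- fluence$energy_eV
  lets <- tibble(energy_eV = e, yield = let_electron(e, model))
  dose_weighted_average(lets, fluence, model)
}

#' Report rounding conventions
#'
#' Yields are reported to 1 decimal, outcome probabilities to 3 decimals,
#' RBE and HRF values to 1 decimal, and percent reductions to the nearest
#' integer. Internal computation is always full precision; reports show both.
#'
#' @param x Numeric vector.
#' @return Rounded vector.
#' @name report-rounding
NULL

#' @rdname report-rounding
#' @export
round_yield <- function(x) round(x, 1)

#' @rdname report-rounding
#' @export
round_probability <- function(x) round(x, 3)

#' @rdname report-rounding
#' @export
round_ratio <- function(x) round(x, 1)

#' @rdname report-rounding
#' @export
round_percent <- function(x) round(x, 0)

#' Assemble the standard report tables
#'
#' Builds the six-table report of a multi-quality run: per-category induction
#' yields at each oxygen level, the DSB summary with RBE against the
#' reference quality (with measured reference values attached as static
#' comparison columns), aggregate repair-outcome probabilities, enzymatic
#' DSB-conversion yields with their RBEs, HRF values, and consistency /
#' discrepancy notes. Full-precision and rounded columns are both included.
#'
#' @param spectra Damage-spectrum tibble covering every quality at every
#'   oxygen level run (must include 21%).
#' @param outcomes Tibble with `label`, `p_correct`, `p_mutation`,
#'   `p_conversion` (aggregate, one row per quality), or NULL to skip the
#'   repair tables.
#' @param reference_label Reference quality for RBE (default `"Co-60"`).
#' @param reference Packaged comparison tables (default [reference_tables()];
#'   pass NULL to omit comparison columns).
#' @return Named list of tibbles: `induction`, `dsb_summary`, `repair`,
#'   `conversion`, `hrf`, `notes`.
#' @export
build_report <- function(spectra, outcomes = NULL,
                         reference_label = "Co-60",
                         reference = reference_tables()) {
  if (!reference_label %in% spectra$label) {
    abort(paste0("missing reference quality '", reference_label,
                 "' in spectra"))
  }
  o2_levels <- sort(unique(spectra$oxygen_percent), decreasing = TRUE)
  if (!21 %in% o2_levels) abort("spectra must include the 21% O2 level")

  induction <- dplyr::arrange(spectra, dplyr::desc(.data$oxygen_percent),
                              .data$label)

  # DSB summary with RBE per oxygen level (reference at the same level)
  dsb_summary <- spectra |>
    dplyr::group_by(.data$oxygen_percent) |>
    dplyr::group_modify(function(df, key) {
      ref_dsb <- df$total_DSB[df$label == reference_label]
      tibble(label = df$label, total_DSB = df$total_DSB,
             rbe_dsb = rbe(df$total_DSB, ref_dsb),
             rbe_dsb_rounded = round_ratio(rbe(df$total_DSB, ref_dsb)))
    }) |>
    dplyr::ungroup()
  if (!is.null(reference)) {
    dsb_summary <- dplyr::left_join(
      dsb_summary,
      reference$dsb[, c("label", "measured_dsb", "measured_rbe")],
      by = "label"
    )
  }

  # HRF per quality and hypoxic level
  hrf_tab <- hrf_from_tables(spectra)
  hrf_tab <- hrf_tab[hrf_tab$o2_percent != 21, ]
  hrf_tab$hrf_rounded <- round_ratio(hrf_tab$hrf)
  hrf_tab$reduction_pct <- round_percent(100 * (1 - 1 / hrf_tab$hrf))

  repair <- NULL
  conversion <- NULL
  if (!is.null(outcomes)) {
    repair <- outcomes
    repair$p_correct_rounded <- round_probability(repair$p_correct)
    repair$p_mutation_rounded <- round_probability(repair$p_mutation)
    repair$p_conversion_rounded <- round_probability(repair$p_conversion)
    aero <- spectra[spectra$oxygen_percent == 21, ]
    conv <- dplyr::left_join(
      aero[, c("label", "total_DSB", "total_damage")],
      outcomes[, c("label", "p_conversion")], by = "label"
    )
    conv$dsb_conversion <- enzymatic_dsb_yield(conv$total_damage,
                                               conv$p_conversion)
    ref_ind <- conv$total_DSB[conv$label == reference_label]
    ref_conv <- conv$dsb_conversion[conv$label == reference_label]
    conversion <- tibble(
      label = conv$label,
      dsb_induction = conv$total_DSB,
      dsb_conversion = conv$dsb_conversion,
      rbe_induction = rbe(conv$total_DSB, ref_ind),
      rbe_conversion = rbe(conv$dsb_conversion, ref_conv),
      rbe_induction_rounded = round_ratio(rbe(conv$total_DSB, ref_ind)),
      rbe_conversion_rounded = round_ratio(rbe(conv$dsb_conversion,
                                               ref_conv))
    )
  }

  chk <- check_spectrum_totals(spectra)
  notes <- chk[!chk$consistent, ]
  list(induction = induction, dsb_summary = dsb_summary, repair = repair,
       conversion = conversion, hrf = hrf_tab, notes = notes)
}
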