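#' The seven-category clustered DNA damage taxonomy
#'
#' Clustered DNA lesions are graded by the strand-break content of the
#' cluster: base damage only (`BD`), a single strand break (`SSB`), two or
#' more breaks on one strand (`SSBp`), breaks on both strands that are too
#' far apart (more than the pairing gap, canonically 10 bp) to sever the
#' duplex (`twoSSB`), one opposite-strand break pair within the gap (`DSB`),
#' a DSB with at least one additional break (`DSBp`), and two or more DSBs
#' in one cluster (`DSBpp`).
#'
#' @return Character vector of the seven category codes, in canonical order.
#' @export
#' @examples
#' damage_categories()
damage_categories <- function() {
  c("BD", "SSB", "SSBp", "twoSSB", "DSB", "DSBp", "DSBpp")
}

# column names of the serialized table layout (external TSV interface)
tsv_category_names <- function() {
  c("BD", "SSB", "SSBp", "2SSB", "DSB", "DSBp", "DSBpp")
}

spectrum_columns <- function() {
  c("label", "oxygen_percent", damage_categories(),
    "total_SSB", "total_DSB", "total_damage")
}

#' Build a damage spectrum row from per-category yields
#'
#' A damage spectrum is a one-row-per-quality tibble of per-category damage
#' yields in lesions (clusters) per Gy per Gbp, with the three conventional
#' totals: `total_SSB = SSB + SSBp + twoSSB`, `total_DSB = DSB + DSBp +
#' DSBpp`, and `total_damage = BD + total_SSB + total_DSB`.
#'
#' @param label Radiation-quality label.
#' @param yields Named numeric vector with one non-negative entry per
#'   category in [damage_categories()].
#' @param oxygen_percent Oxygen concentration in percent O2 (default 21,
#'   aerobic).
#' @return A one-row tibble in the damage-spectrum layout.
#' @export
#' @examples
#' damage_spectrum("Co-60", c(
#'   BD = 424.4, SSB = 178.6, SSBp = 8.0, twoSSB = 1.0,
#'   DSB = 7.1, DSBp = 1.0, DSBpp = 0.1
#' ))
damage_spectrum <- function(label, yields, oxygen_percent = 21) {
  cats <- damage_categories()
  if (!all(cats %in% names(yields))) {
    abort(paste0(
      "`yields` must be named with all of: ", paste(cats, collapse = ", ")
    ))
  }
  yields <- yields[cats]
  if (any(!is.finite(yields)) || any(yields < 0)) {
    abort("all category yields must be finite and non-negative")
  }
  out <- tibble(label = label, oxygen_percent = oxygen_percent)
  for (cc in cats) out[[cc]] <- unname(yields[[cc]])
  recompute_totals(out)
}

#' Recompute the totals columns of a damage spectrum
#'
#' @param spectrum A tibble with the seven category yield columns.
#' @return The tibble with `total_SSB`, `total_DSB` and `total_damage`
#'   recomputed from the constituent columns.
#' @export
recompute_totals <- function(spectrum) {
  spectrum$total_SSB <- spectrum$SSB + spectrum$SSBp + spectrum$twoSSB
  spectrum$total_DSB <- spectrum$DSB + spectrum$DSBp + spectrum$DSBpp
  spectrum$total_damage <-
    spectrum$BD + spectrum$total_SSB + spectrum$total_DSB
  spectrum
}

#' Check totals consistency of a damage-spectrum table
#'
#' Published yield tables occasionally print totals that do not equal the sum
#' of their constituent columns (rounding upstream of the table, or totals
#' taken from a different run). This check flags such rows without failing.
#'
#' @param spectrum Damage-spectrum tibble (any number of rows).
#' @param tol Relative tolerance on each of the three totals (default 0.005).
#' @param abs_tol Absolute tolerance (default 0.2, the worst-case discrepancy
#'   when three constituents and the total are each printed to one decimal).
#' @return A tibble with one row per input row: `label`, `oxygen_percent`,
#'   logical `consistent`, and the relative error of each total.
#' @export
check_spectrum_totals <- function(spectrum, tol = 0.005, abs_tol = 0.2) {
  ref <- recompute_totals(spectrum)
  rel <- function(x, y) ifelse(y == 0, as.numeric(x != 0), abs(x - y) / y)
  ok <- function(x, y) abs(x - y) <= pmax(abs_tol, tol * abs(y))
  out <- tibble(
    label = spectrum$label,
    oxygen_percent = spectrum$oxygen_percent,
    rel_total_SSB = rel(spectrum$total_SSB, ref$total_SSB),
    rel_total_DSB = rel(spectrum$total_DSB, ref$total_DSB),
    rel_total_damage = rel(spectrum$total_damage, ref$total_damage)
  )
  out$consistent <- ok(spectrum$total_SSB, ref$total_SSB) &
    ok(spectrum$total_DSB, ref$total_DSB) &
    ok(spectrum$total_damage, ref$total_damage)
  out[, c("label", "oxygen_percent", "consistent",
          "rel_total_SSB", "rel_total_DSB", "rel_total_damage")]
}

#' Read a damage-spectrum table from TSV
#'
#' Expects the tab-separated layout `label, oxygen_percent, BD, SSB, SSBp,
#' 2SSB, DSB, DSBp, DSBpp, total_SSB, total_DSB, total_damage` (yields per Gy
#' per Gbp). Rows whose printed totals disagree with the sum of their
#' constituent columns raise a warning, not an error.
#'
#' @param path Path to a TSV file.
#' @param validate Warn on totals-inconsistent rows (default TRUE).
#' @return A damage-spectrum tibble (zero rows for an empty file).
#' @export
read_damage_spectra <- function(path, validate = TRUE) {
  if (file.size(path) == 0) {
    out <- tibble(label = character(), oxygen_percent = numeric())
    for (cc in c(damage_categories(), "total_SSB", "total_DSB",
                 "total_damage")) {
      out[[cc]] <- numeric()
    }
    return(out)
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  expected <- c("label", "oxygen_percent", tsv_category_names(),
                "total_SSB", "total_DSB", "total_damage")
  missing <- setdiff(expected, names(df))
  if (length(missing) > 0) {
    abort(paste0("malformed damage-spectrum TSV '", path,
                 "': missing columns ", paste(missing, collapse = ", ")))
  }
  names(df)[names(df) == "2SSB"] <- "twoSSB"
  df <- as_tibble(df)[, spectrum_columns()]
  bad <- which(!vapply(
    df[, c(damage_categories(), "total_SSB", "total_DSB", "total_damage")],
    is.numeric, logical(1)
  ))
  if (length(bad) > 0) {
    abort(paste0("malformed damage-spectrum TSV '", path,
                 "': non-numeric yield column(s)"))
  }
  if (validate && nrow(df) > 0) {
    chk <- check_spectrum_totals(df)
    if (any(!chk$consistent)) {
      bad_lab <- paste(chk$label[!chk$consistent], collapse = ", ")
      warn(paste0(
        "totals-inconsistent rows in '", path, "': ", bad_lab,
        " (printed totals do not equal the sum of constituent columns)"
      ))
    }
  }
  df
}

#' @rdname read_damage_spectra
#' @export
load_yield_table <- read_damage_spectra

#' Write a damage-spectrum table to TSV
#'
#' Inverse of [read_damage_spectra()]; round-trips exactly.
#'
#' @param spectrum Damage-spectrum tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_damage_spectra <- function(spectrum, path) {
  out <- spectrum[, spectrum_columns()]
  names(out)[names(out) == "twoSSB"] <- "2SSB"
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
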