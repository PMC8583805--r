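ELECTRON_REST_EV <- 511e3  # electron rest energy, eV
LOW_ENERGY_COEF <- c(4376, -19803, 129622)  # sub-keV LET fit coefficients
LET_CROSSOVER_EV <- 1000
LET_CUTOFF_EV <- 50  # electrons are not followed below this energy

#' Electron stopping-power model for liquid water
#'
#' Below 1 keV the unrestricted LET (collision stopping power) of electrons
#' in liquid water follows the closed-form fit
#' `LET(eV/nm) = (4376 ln T - 19803) / T + 129622 / T^2` with `T` in eV;
#' at and above 1 keV it is log-log interpolated from a tabulated
#' high-energy stopping-power curve. The packaged default table is a
#' constructed (synthetic) approximation to standard liquid-water collision
#' stopping-power compilations, spanning 1 keV to 10 MeV; supply your own
#' two-column TSV (`energy_eV`, `let_eV_per_nm`) to override it.
#'
#' @param high_energy_table Optional tibble or TSV path with columns
#'   `energy_eV` and `let_eV_per_nm` covering energies >= 1 keV.
#' @return List of class `"stopping_power_model"`.
#' @export
#' @examples
#' m <- stopping_power_model()
#' let_electron(c(100, 1000, 1e6), m)
stopping_power_model <- function(high_energy_table = NULL) {
  if (is.null(high_energy_table)) {
    path <- system.file("extdata", "water_stopping_power_synthetic.tsv",
                        package = "mcdamage", mustWork = TRUE)
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else if (is.character(high_energy_table)) {
    tab <- readr::read_tsv(high_energy_table, show_col_types = FALSE,
                           progress = FALSE)
  } else {
    tab <- as_tibble(high_energy_table)
  }
  if (!all(c("energy_eV", "let_eV_per_nm") %in% names(tab))) {
    abort("stopping-power table needs columns energy_eV, let_eV_per_nm")
  }
  tab <- tab[order(tab$energy_eV), ]
  if (any(tab$let_eV_per_nm <= 0) || tab$energy_eV[1] > LET_CROSSOVER_EV) {
    abort("table must be positive and start at or below 1 keV")
  }
  structure(
    list(low_energy_coefficients = LOW_ENERGY_COEF,
         crossover_energy = LET_CROSSOVER_EV,
         high_energy_table = tab),
    class = "stopping_power_model"
  )
}

#' Closed-form sub-keV electron LET in liquid water
#'
#' Direct evaluation of the low-energy fit
#' `LET(eV/nm) = (4376 ln T - 19803) / T + 129622 / T^2` (`T` in eV),
#' without the table switch applied by [let_electron()] at 1 keV.
#'
#' @param T_eV Electron kinetic energy in eV.
#' @return LET in eV/nm.
#' @export
#' @examples
#' let_low_energy(c(100, 1000))
let_low_energy <- function(T_eV) {
  a <- LOW_ENERGY_COEF
  (a[1] * log(T_eV) + a[2]) / T_eV + a[3] / T_eV^2
}

#' Unrestricted LET of an electron in liquid water
#'
#' @param T_eV Electron kinetic energy (or energies) in eV; must be >= 50 eV
#'   (the transport cut-off) and within the table span above 1 keV.
#' @param model A [stopping_power_model()].
#' @return LET in eV/nm.
#' @export
let_electron <- function(T_eV, model = stopping_power_model()) {
  if (any(T_eV < LET_CUTOFF_EV)) {
    abort("electron energy below the 50 eV transport cut-off")
  }
  tab <- model$high_energy_table
  if (any(T_eV > max(tab$energy_eV))) {
    abort("electron energy above the stopping-power table span")
  }
  out <- numeric(length(T_eV))
  lo <- T_eV < model$crossover_energy
  out[lo] <- let_low_energy(T_eV[lo])
  if (any(!lo)) {
    out[!lo] <- exp(approx(log(tab$energy_eV), log(tab$let_eV_per_nm),
                           xout = log(T_eV[!lo]), rule = 1)$y)
  }
  out
}

#' Relative gap between the sub-keV fit and the table at the crossover
#'
#' The low-energy fit and the tabulated stopping power come from different
#' sources and do not join smoothly at 1 keV; the relative gap is reported so
#' it can be monitored (it should stay below 25%).
#'
#' @param model A [stopping_power_model()].
#' @return Relative gap (dimensionless).
#' @export
let_crossover_gap <- function(model = stopping_power_model()) {
  fit <- let_low_energy(model$crossover_energy)
  tab <- exp(approx(log(model$high_energy_table$energy_eV),
                    log(model$high_energy_table$let_eV_per_nm),
                    xout = log(model$crossover_energy), rule = 1)$y)
  abs(fit - tab) / tab
}

#' Define a photon source as a set of emission lines
#'
#' @param label Quality label.
#' @param energies_eV Photon line energies in eV.
#' @param weights Relative line weights (default equal); normalized
#'   internally.
#' @return List of class `"photon_source"` with a `lines` tibble.
#' @export
#' @examples
#' photon_source("Co-60", c(1.17e6, 1.33e6))
photon_source <- function(label, energies_eV, weights = NULL) {
  if (length(energies_eV) == 0 || any(energies_eV <= 0)) {
    abort("line energies must be positive")
  }
  if (is.null(weights)) weights <- rep(1, length(energies_eV))
  if (length(weights) != length(energies_eV) || any(weights <= 0)) {
    abort("weights must be positive, one per line")
  }
  structure(
    list(label = label,
         lines = tibble(energy_eV = energies_eV,
                        weight = weights / sum(weights))),
    class = "photon_source"
  )
}

#' The five radiation qualities of the ultrasoft X-ray study design
#'
#' Four characteristic X-ray lines (titanium K-shell 4.55 keV, aluminium
#' K-shell 1.49 keV, copper L-shell 0.96 keV, carbon K-shell 0.28 keV) and
#' the Co-60 gamma pair (1.17 + 1.33 MeV) used as the reference quality.
#'
#' @return Named list of [photon_source()] objects.
#' @export
standard_photon_sources <- function() {
  list(
    `Titanium K-shell` = photon_source("Titanium K-shell", 4550),
    `Aluminum K-shell` = photon_source("Aluminum K-shell", 1490),
    `Copper L-shell` = photon_source("Copper L-shell", 960),
    `Carbon K-shell` = photon_source("Carbon K-shell", 280),
    `Co-60` = photon_source("Co-60", c(1.17e6, 1.33e6))
  )
}

new_fluence_spectrum <- function(energy_eV, fluence, label, type) {
  out <- tibble(energy_eV = energy_eV, fluence = fluence)
  attr(out, "label") <- label
  attr(out, "spectrum_type") <- type  # "line" or "density"
  out
}

#' Is a fluence spectrum a discrete line spectrum?
#'
#' @param spectrum A fluence spectrum tibble.
#' @return TRUE for line spectra, FALSE for densities.
#' @export
is_line_spectrum <- function(spectrum) {
  identical(attr(spectrum, "spectrum_type"), "line")
}

#' Photoelectron fluence of an ultrasoft X-ray source
#'
#' Ultrasoft photons interact almost exclusively by the photoelectric
#' effect and the photoelectron carries nearly the whole photon energy, so
#' each photon line is mapped to a monoenergetic electron line at the photon
#' energy (binding energy neglected), with its weight preserved.
#'
#' @param source A [photon_source()] with all lines below 20 keV.
#' @return A line-type fluence spectrum (tibble `energy_eV`, `fluence`).
#' @export
#' @examples
#' photoelectron_fluence(photon_source("Carbon K-shell", 280))
photoelectron_fluence <- function(source) {
  if (any(source$lines$energy_eV >= 20e3)) {
    abort("photoelectron line mapping is restricted to lines below 20 keV")
  }
  new_fluence_spectrum(source$lines$energy_eV, source$lines$weight,
                       source$label, "line")
}

# Klein-Nishina electron energy distribution (unnormalized), photon energy
# e_gamma and electron kinetic energy t, both in eV.
kn_electron_density <- function(t, e_gamma) {
  eps <- e_gamma / ELECTRON_REST_EV
  t_max <- e_gamma * 2 * eps / (1 + 2 * eps)
  s <- t / e_gamma
  d <- ifelse(
    t < 0 | t > t_max, 0,
    2 + s^2 / (eps^2 * (1 - s)^2) + (s / (1 - s)) * (s - 2 / eps)
  )
  pmax(d, 0)
}

#' Compton edge of a photon line
#'
#' Maximum Compton-electron energy `T_max = E 2 eps / (1 + 2 eps)` with
#' `eps = E / (511 keV)`.
#'
#' @param e_gamma Photon energy in eV.
#' @return Edge energy in eV.
#' @export
compton_edge <- function(e_gamma) {
  eps <- e_gamma / ELECTRON_REST_EV
  e_gamma * 2 * eps / (1 + 2 * eps)
}

#' Compton electron fluence of a high-energy photon source
#'
#' Single-scatter Klein-Nishina electron energy distribution per line,
#' normalized to the line weight and summed over lines, on a logarithmic
#' energy grid from 50 eV to the highest Compton edge.
#'
#' @param source A [photon_source()] with all lines at or above 100 keV.
#' @param n_bins Number of logarithmic grid points (default 200).
#' @return A density-type fluence spectrum.
#' @export
#' @examples
#' compton_electron_fluence(photon_source("Co-60", c(1.17e6, 1.33e6)))
compton_electron_fluence <- function(source, n_bins = 200) {
  if (any(source$lines$energy_eV < 100e3)) {
    abort("Compton sampling expects photon lines >= 100 keV")
  }
  t_top <- max(compton_edge(source$lines$energy_eV))
  grid <- exp(seq(log(LET_CUTOFF_EV), log(t_top), length.out = n_bins))
  fl <- numeric(n_bins)
  for (i in seq_len(nrow(source$lines))) {
    d <- kn_electron_density(grid, source$lines$energy_eV[i])
    z <- trapz(grid, d)
    fl <- fl + source$lines$weight[i] * d / z
  }
  new_fluence_spectrum(grid, fl, source$label, "density")
}

# trapezoidal rule
trapz <- function(x, y) {
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Continuous-slowing-down equilibrium fluence
#'
#' For a source spectrum of electrons set in motion, the equilibrium track
#' fluence under the continuous-slowing-down approximation is
#' `phi(E) = Q(E) / LET(E)`, where `Q(E)` is the total source weight of
#' electrons starting above `E`. Line and density source spectra are both
#' accepted; sources superpose linearly.
#'
#' @param initial Source fluence spectrum (line or density type).
#' @param model A [stopping_power_model()].
#' @param grid Output energy grid in eV (default: 200-point log grid from
#'   50 eV to the maximum source energy).
#' @return A density-type fluence spectrum on `grid`.
#' @export
slowing_down_fluence <- function(initial, model = stopping_power_model(),
                                 grid = NULL) {
  e_max <- max(initial$energy_eV)
  if (is.null(grid)) {
    grid <- exp(seq(log(LET_CUTOFF_EV), log(e_max), length.out = 200))
    grid[1] <- LET_CUTOFF_EV
    grid[length(grid)] <- e_max
  }
  if (any(grid < LET_CUTOFF_EV) || any(grid > e_max * (1 + 1e-12))) {
    abort("grid must lie within [50 eV, max source energy]")
  }
  if (is_line_spectrum(initial)) {
    q <- vapply(grid, function(e) {
      sum(initial$fluence[initial$energy_eV >= e])
    }, numeric(1))
  } else {
    x <- initial$energy_eV
    y <- initial$fluence
    q <- vapply(grid, function(e) {
      if (e >= max(x)) return(0)
      xs <- sort(unique(c(e, x[x > e])))
      ys <- approx(x, y, xout = xs, rule = 2)$y
      trapz(xs, ys)
    }, numeric(1))
  }
  new_fluence_spectrum(grid, q / let_electron(grid, model),
                       attr(initial, "label"), "density")
}

#' Read / write fluence spectra as two-column TSV
#'
#' Columns `energy_eV` and `fluence`. Values round-trip exactly. The label
#' and spectrum type (`line` or `density`) are not serialized; supply them
#' on read.
#'
#' @param spectrum A fluence spectrum tibble.
#' @param path File path.
#' @param label,type Label and spectrum type to attach on read.
#' @return The spectrum (read) or `path` invisibly (write).
#' @export
write_fluence_spectrum <- function(spectrum, path) {
  readr::write_tsv(spectrum[, c("energy_eV", "fluence")], path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_fluence_spectrum
#' @export
read_fluence_spectrum <- function(path, label = "spectrum",
                                  type = c("density", "line")) {
  type <- match.arg(type)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("energy_eV", "fluence") %in% names(df))) {
    abort("fluence TSV needs columns energy_eV, fluence")
  }
  if (any(df$fluence < 0)) abort("fluence must be non-negative")
  new_fluence_spectrum(df$energy_eV, df$fluence, label, type)
}
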