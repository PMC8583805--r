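#' Hill-type oxygen response of damage yields
#'
#' The yield of each damage category scales with oxygen concentration as a
#' Hill curve: `s_min + (1 - s_min) * o2^h / (o2^h + k^h)`, where `s_min` is
#' the hypoxic floor (relative yield at 0% O2), `k` the half-effect
#' concentration in %O2, and `h` the Hill exponent. The curve plateaus at
#' `s_min` under severe hypoxia and approaches 1 under aerobic conditions
#' (21% O2) when `k << 21`. For the base-damage category the floor may
#' exceed 1 (capped at 1.1): base-damage yields of low-energy qualities can
#' rise slightly under hypoxia.
#'
#' @param s_min Hypoxic floor, scalar or named per-category vector; in
#'   (0, 1] (BD: (0, 1.1]).
#' @param half_effect_k Half-effect oxygen concentration in %O2 (> 0),
#'   scalar or per-category.
#' @param hill_exponent Hill exponent (> 0), scalar or per-category.
#' @return A tibble of class `"oxygen_response"` with one row per category:
#'   `category`, `s_min`, `half_effect_k`, `hill_exponent`.
#' @export
#' @examples
#' oxygen_response(s_min = 0.45, half_effect_k = 1.2, hill_exponent = 1)
oxygen_response <- function(s_min, half_effect_k, hill_exponent) {
  cats <- damage_categories()
  expand <- function(x, what) {
    if (length(x) == 1) {
      setNames(rep(as.numeric(x), length(cats)), cats)
    } else {
      if (!all(cats %in% names(x))) {
        abort(paste0("per-category `", what, "` must name all categories"))
      }
      x[cats]
    }
  }
  s <- expand(s_min, "s_min")
  k <- expand(half_effect_k, "half_effect_k")
  h <- expand(hill_exponent, "hill_exponent")
  cap <- ifelse(cats == "BD", 1.1, 1)
  if (any(s <= 0) || any(s > cap + 1e-12)) {
    abort("s_min must lie in (0, 1] ((0, 1.1] for BD)")
  }
  if (any(k <= 0) || any(h <= 0)) {
    abort("half_effect_k and hill_exponent must be positive")
  }
  out <- tibble(category = cats, s_min = unname(s),
                half_effect_k = unname(k), hill_exponent = unname(h))
  class(out) <- c("oxygen_response", class(out))
  out
}

#' Relative yield at a given oxygen concentration
#'
#' Evaluates the raw Hill scale for one category (see [oxygen_response()]),
#' clamped so it never exceeds `max(1, s_min)`.
#'
#' @param o2_percent Oxygen concentration(s) in %O2 (>= 0).
#' @param category One category code.
#' @param params An [oxygen_response()].
#' @return Relative yield(s) in (0, max(1, s_min)].
#' @export
#' @examples
#' r <- oxygen_response(0.4, 1.5, 1)
#' oxygen_scale(0, "DSB", r)    # the floor
#' oxygen_scale(1.5, "DSB", r)  # half effect: s + (1 - s) / 2
oxygen_scale <- function(o2_percent, category, params) {
  if (any(o2_percent < 0)) abort("oxygen concentration must be >= 0")
  row <- params[params$category == category, ]
  if (nrow(row) != 1) abort(paste("unknown category:", category))
  s <- row$s_min
  h <- row$hill_exponent
  k <- row$half_effect_k
  hill <- ifelse(o2_percent == 0, 0,
                 o2_percent^h / (o2_percent^h + k^h))
  pmin(s + (1 - s) * hill, max(1, s))
}

#' Scale an aerobic damage spectrum to another oxygen concentration
#'
#' Each category yield of a 21% O2 spectrum is multiplied by its oxygen
#' scale, normalized to the scale at 21% so that `apply_oxygen(x, 21, r)` is
#' exactly the identity; totals are recomputed.
#'
#' @param spectrum_21 Damage-spectrum tibble tagged `oxygen_percent == 21`.
#' @param o2_percent Target oxygen concentration in %O2.
#' @param params An [oxygen_response()].
#' @return The scaled damage-spectrum tibble, tagged with `o2_percent`.
#' @export
apply_oxygen <- function(spectrum_21, o2_percent, params) {
  if (any(spectrum_21$oxygen_percent != 21)) {
    abort("`spectrum_21` must be tagged oxygen_percent = 21")
  }
  out <- spectrum_21
  for (cc in damage_categories()) {
    sc <- oxygen_scale(o2_percent, cc, params) /
      oxygen_scale(21, cc, params)
    out[[cc]] <- out[[cc]] * sc
  }
  out$oxygen_percent <- o2_percent
  recompute_totals(out)
}

#' Fit the oxygen response from spectra at several oxygen levels
#'
#' Least-squares fit, per category, of the normalized Hill scale to the
#' relative yields `y(o2) / y(21)`, with a penalty constraining the curve to
#' be flat (within 2%) below 0.1% O2. At least three oxygen levels including
#' 21% are required; three levels determine the floor well but leave
#' (`half_effect_k`, `hill_exponent`) weakly identified (the plateau penalty
#' regularizes them); five or more levels identify all three parameters.
#'
#' @param spectra Damage-spectrum tibble: one quality, >= 3 distinct
#'   `oxygen_percent` values including 21.
#' @param plateau_tol Allowed relative change of the scale between 0.001 and
#'   0.05 %O2 (default 0.02).
#' @return An object of class `"oxygen_fit"`: the fitted [oxygen_response()]
#'   plus per-category residuals. Use [tidy()] / [glance()].
#' @export
calibrate_oxygen <- function(spectra, plateau_tol = 0.02) {
  if (length(unique(spectra$label)) != 1) {
    abort("`spectra` must contain a single radiation quality")
  }
  o2 <- spectra$oxygen_percent
  if (length(unique(o2)) < 3 || !(21 %in% o2)) {
    abort("need spectra at >= 3 oxygen levels including 21%")
  }
  base <- spectra[match(21, o2), ]
  cats <- damage_categories()
  fit_one <- function(cc) {
    y21 <- base[[cc]]
    rel <- spectra[[cc]] / ifelse(y21 > 0, y21, 1)
    cap <- if (cc == "BD") 1.1 else 1
    if (y21 == 0 || all(abs(rel - 1) < 1e-12)) {
      return(c(s_min = 1, half_effect_k = 1, hill_exponent = 1, sse = 0))
    }
    norm_scale <- function(o, s, k, h) {
      hill <- ifelse(o == 0, 0, o^h / (o^h + k^h))
      raw <- pmin(s + (1 - s) * hill, max(1, s))
      raw21 <- min(s + (1 - s) * 21^h / (21^h + k^h), max(1, s))
      raw / raw21
    }
    obj <- function(p) {
      s <- p[1]; k <- exp(p[2]); h <- exp(p[3])
      if (s <= 0.01 || s > cap || k < 0.05 || k > 15 || h < 0.2 || h > 6) {
        return(1e6)
      }
      pred <- norm_scale(o2, s, k, h)
      plateau <- abs(norm_scale(0.05, s, k, h) /
                       norm_scale(0.001, s, k, h) - 1)
      sum((pred - rel)^2) + 100 * max(0, plateau - plateau_tol)^2
    }
    best <- NULL
    for (s0 in c(min(rel), 0.5)) {
      for (k0 in c(0.5, 2)) {
        o <- optim(c(max(0.02, min(s0, cap)), log(k0), log(1)), obj,
                   control = list(maxit = 500, reltol = 1e-10))
        if (is.null(best) || o$value < best$value) best <- o
      }
    }
    c(s_min = best$par[1], half_effect_k = exp(best$par[2]),
      hill_exponent = exp(best$par[3]), sse = best$value)
  }
  fits <- t(vapply(cats, fit_one, numeric(4)))
  response <- oxygen_response(
    s_min = setNames(fits[, "s_min"], cats),
    half_effect_k = setNames(fits[, "half_effect_k"], cats),
    hill_exponent = setNames(fits[, "hill_exponent"], cats)
  )
  fitted_rel <- vapply(cats, function(cc) {
    oxygen_scale(o2, cc, response) / oxygen_scale(21, cc, response)
  }, numeric(length(o2)))
  structure(
    list(response = response, label = spectra$label[1],
         oxygen_percent = o2,
         sse = setNames(fits[, "sse"], cats),
         fitted_rel = fitted_rel),
    class = "oxygen_fit"
  )
}

#' @export
print.oxygen_fit <- function(x, ...) {
  cat("<oxygen_fit>", x$label, "\n")
  print(as.data.frame(x$response), row.names = FALSE)
  invisible(x)
}

#' @rdname calibrate_oxygen
#' @param x An `"oxygen_fit"` object.
#' @param ... Unused.
#' @export
tidy.oxygen_fit <- function(x, ...) {
  out <- as_tibble(x$response)
  out$sse <- unname(x$sse[out$category])
  out
}

#' @rdname calibrate_oxygen
#' @export
glance.oxygen_fit <- function(x, ...) {
  tibble(label = x$label, n_levels = length(unique(x$oxygen_percent)),
         total_sse = sum(x$sse))
}

#' Hypoxia-reduction-factor curve from a fitted oxygen response
#'
#' The hypoxia reduction factor (HRF) is the aerobic (21% O2) total DSB yield
#' divided by the yield at a given oxygen concentration. The curve is
#' computed by scaling the aerobic spectrum with [apply_oxygen()] at each
#' concentration.
#'
#' @param spectrum_21 Aerobic damage spectrum (one row).
#' @param params An [oxygen_response()] or `"oxygen_fit"`.
#' @param o2_percent Oxygen grid in %O2 (default log-spaced 0.001-21).
#' @param endpoint Column the HRF is computed for (default `"total_DSB"`).
#' @return Tibble with `o2_percent` and `hrf`.
#' @export
hrf_curve <- function(spectrum_21, params,
                      o2_percent = 10^seq(-3, log10(21), length.out = 60),
                      endpoint = "total_DSB") {
  if (inherits(params, "oxygen_fit")) params <- params$response
  # recompute the aerobic endpoint through the same scaling path, so the
  # curve is exactly 1 at 21% even when the input row carries printed
  # totals that differ from the sum of its constituent columns
  y21 <- apply_oxygen(spectrum_21, 21, params)[[endpoint]]
  hrf_vals <- vapply(o2_percent, function(o) {
    y <- apply_oxygen(spectrum_21, o, params)[[endpoint]]
    y21 / y
  }, numeric(1))
  tibble(o2_percent = o2_percent, hrf = hrf_vals)
}

#' Table-derived hypoxia reduction factors
#'
#' HRFs computed directly from tabulated yields at the oxygen levels present,
#' without any curve fit: `y(21) / y(o2)` per quality and level.
#'
#' @param spectra Damage-spectrum tibble with rows at 21% and at least one
#'   other oxygen level.
#' @param endpoint Column to form the ratio on (default `"total_DSB"`).
#' @return Tibble with `label`, `o2_percent`, `hrf`.
#' @export
hrf_from_tables <- function(spectra, endpoint = "total_DSB") {
  spectra |>
    dplyr::group_by(.data$label) |>
    dplyr::group_modify(function(df, key) {
      base <- df[[endpoint]][df$oxygen_percent == 21]
      if (length(base) != 1) {
        abort("each quality needs exactly one 21% O2 row")
      }
      tibble(o2_percent = df$oxygen_percent,
             hrf = base / df[[endpoint]])
    }) |>
    dplyr::ungroup()
}

#' Write an HRF curve as two-column TSV
#'
#' @param curve Tibble with `o2_percent` and `hrf` (from [hrf_curve()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hrf_curve <- function(curve, path) {
  readr::write_tsv(curve[, c("o2_percent", "hrf")], path, progress = FALSE)
  invisible(path)
}
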