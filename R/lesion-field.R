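#' Configuration of the stochastic lesion-induction model
#'
#' One "damage site" is the set of elementary lesions deposited by a single
#' local energy-deposition event on a DNA segment. Sites occur at `site_rate`
#' per Gy per Gbp; each carries `1 + Poisson(lesion_multiplicity)` lesions,
#' each lesion is a strand break with probability `sb_fraction` (otherwise a
#' base damage), lies on either strand with probability 1/2, and its
#' base-pair position is uniform over `segment_length`. Two lesions never
#' share a (position, strand) slot: collisions are re-drawn.
#'
#' @param site_rate Damage sites per Gy per Gbp (> 0).
#' @param lesion_multiplicity Mean number of extra lesions per site beyond
#'   the first (the Poisson mean; >= 0).
#' @param sb_fraction Probability that a lesion is a strand break, in [0, 1].
#' @param segment_length Base pairs over which one site's lesions scatter
#'   (>= `cluster_gap`).
#' @param cluster_gap Chaining distance in base pairs for clustering and DSB
#'   pairing (default 10).
#' @return A validated list of class `"induction_config"`.
#' @export
#' @examples
#' induction_config(site_rate = 500, lesion_multiplicity = 1.3,
#'                  sb_fraction = 0.17, segment_length = 27)
induction_config <- function(site_rate, lesion_multiplicity, sb_fraction,
                             segment_length = 25, cluster_gap = 10) {
  ok <- is.numeric(site_rate) && length(site_rate) == 1 && site_rate > 0 &&
    is.numeric(lesion_multiplicity) && lesion_multiplicity >= 0 &&
    is.numeric(sb_fraction) && sb_fraction >= 0 && sb_fraction <= 1 &&
    is.numeric(segment_length) && is.numeric(cluster_gap) &&
    cluster_gap >= 1 && segment_length >= cluster_gap
  if (!ok) {
    abort(paste(
      "invalid induction configuration: need site_rate > 0,",
      "lesion_multiplicity >= 0, sb_fraction in [0, 1],",
      "segment_length >= cluster_gap >= 1"
    ))
  }
  structure(
    list(
      site_rate = site_rate,
      lesion_multiplicity = lesion_multiplicity,
      sb_fraction = sb_fraction,
      segment_length = as.integer(round(segment_length)),
      cluster_gap = as.integer(round(cluster_gap))
    ),
    class = "induction_config"
  )
}

#' @export
print.induction_config <- function(x, ...) {
  cat("<induction_config>\n")
  cat(sprintf("  site_rate:           %.4g sites / Gy / Gbp\n", x$site_rate))
  cat(sprintf("  lesion_multiplicity: %.4g (count = 1 + Poisson)\n",
              x$lesion_multiplicity))
  cat(sprintf("  sb_fraction:         %.4g\n", x$sb_fraction))
  cat(sprintf("  segment_length:      %d bp\n", x$segment_length))
  cat(sprintf("  cluster_gap:         %d bp\n", x$cluster_gap))
  invisible(x)
}

#' Sample the lesions of one or more damage sites
#'
#' @param config An [induction_config()].
#' @param n_sites Number of independent sites to draw.
#' @param seed Optional integer seed (sets the R RNG).
#' @return A tibble with columns `site`, `position` (0-based bp offset),
#'   `strand` (0/1) and `kind` (`"strand_break"` or `"base_damage"`), one row
#'   per lesion.
#' @export
#' @examples
#' cfg <- induction_config(500, 2, 0.5, 25)
#' sample_site(cfg, n_sites = 3, seed = 1)
sample_site <- function(config, n_sites = 1, seed = NULL) {
  stopifnot(inherits(config, "induction_config"))
  if (!is.null(seed)) set.seed(seed)
  L <- config$segment_length
  k <- 1L + rpois(n_sites, config$lesion_multiplicity)
  k <- pmin(k, L)  # cannot exceed distinct slots on one strand
  site <- rep.int(seq_len(n_sites), k)
  m <- length(site)
  strand <- as.integer(runif(m) < 0.5)
  kind <- ifelse(runif(m) < config$sb_fraction, "strand_break",
                 "base_damage")
  position <- as.integer(floor(runif(m) * L))
  # redraw (position, strand) collisions within a site until all distinct;
  # k <= L guarantees termination even with every lesion on one strand
  repeat {
    key <- (site * 2 + strand) * L + position
    dup <- duplicated(key)
    if (!any(dup)) break
    position[dup] <- as.integer(floor(runif(sum(dup)) * L))
  }
  tibble(site = site, position = position, strand = strand, kind = kind)
}

#' Chain lesions into damage clusters
#'
#' Two lesions belong to the same cluster if they are connected by a chain of
#' lesions whose consecutive base-pair gaps are all `<= gap`; strand and kind
#' are ignored for chaining. The output is a partition of the input, with
#' clusters numbered by leftmost position.
#'
#' @param lesions Tibble with at least `position`; `strand`/`kind` carried
#'   through.
#' @param gap Chaining distance in base pairs (default 10).
#' @return The input rows sorted by position with a `cluster` integer column
#'   added. Empty input gives an empty tibble with a `cluster` column.
#' @export
#' @examples
#' cluster_lesions(tibble::tibble(
#'   position = c(0, 8, 16), strand = c(0, 1, 0),
#'   kind = "strand_break"
#' ))
cluster_lesions <- function(lesions, gap = 10) {
  if (nrow(lesions) == 0) {
    lesions$cluster <- integer()
    return(lesions)
  }
  lesions <- dplyr::arrange(lesions, .data$position)
  gaps <- diff(lesions$position)
  lesions$cluster <- cumsum(c(1L, as.integer(gaps > gap)))
  lesions
}

#' Classify one damage cluster
#'
#' Strand breaks on opposite strands within `gap` base pairs pair into a DSB;
#' the classifier counts the maximum number of disjoint such pairings
#' (greedily, left to right, which is equivalent to maximum matching for
#' breaks on a line) and applies the rules in precedence order: two or more
#' pairings give `DSBpp`; one pairing with an extra break gives `DSBp`; one
#' pairing gives `DSB`; unpaired breaks on both strands give `twoSSB`; two or
#' more breaks on a single strand give `SSBp`; one break gives `SSB`; no
#' break gives `BD`.
#'
#' @param lesions Tibble with `position`, `strand`, `kind` (one cluster).
#' @param gap Pairing distance in base pairs (default 10).
#' @return A single category code (see [damage_categories()]).
#' @export
#' @examples
#' classify_cluster(tibble::tibble(
#'   position = c(3, 7), strand = c(0, 1), kind = "strand_break"
#' ))
classify_cluster <- function(lesions, gap = 10) {
  if (nrow(lesions) == 0) {
    abort("cannot classify an empty cluster")
  }
  code <- cpp_classify_cluster(
    as.integer(lesions$position), as.integer(lesions$strand),
    as.integer(lesions$kind == "strand_break"), as.integer(gap)
  )
  damage_categories()[code + 1L]
}

#' Cluster and classify a lesion field
#'
#' Convenience wrapper: [cluster_lesions()] then [classify_cluster()] per
#' cluster (per site when a `site` column is present).
#'
#' @param lesions Tibble with `position`, `strand`, `kind` and optionally
#'   `site`.
#' @param gap Chaining/pairing distance in base pairs (default 10).
#' @return Tibble with one row per cluster: `site` (if given), `cluster`,
#'   `n_lesions`, `category`.
#' @export
classify_lesions <- function(lesions, gap = 10) {
  if (!"site" %in% names(lesions)) lesions$site <- 1L
  lesions |>
    dplyr::group_by(.data$site) |>
    dplyr::group_modify(function(df, key) {
      df <- cluster_lesions(df, gap = gap)
      df |>
        dplyr::group_by(.data$cluster) |>
        dplyr::summarise(
          n_lesions = dplyr::n(),
          category = classify_cluster(dplyr::pick(dplyr::everything()),
                                      gap = gap),
          .groups = "drop"
        )
    }) |>
    dplyr::ungroup()
}

#' Simulate a per-Gy-per-Gbp damage spectrum
#'
#' Draws `n_sites` damage sites, chains and classifies every cluster, and
#' scales the per-category cluster counts by `site_rate / n_sites` to yields
#' per Gy per Gbp. Totals satisfy the spectrum identities exactly. Monte
#' Carlo standard errors (binomial, on cluster counts) are attached as the
#' `"mc_se"` attribute, together with `"n_sites"` and `"n_clusters"`.
#'
#' @param config An [induction_config()].
#' @param n_sites Number of sites to simulate (>= 1).
#' @param label Radiation-quality label for the output row.
#' @param oxygen_percent Oxygen concentration tag (default 21).
#' @param seed Optional integer seed.
#' @return One-row damage-spectrum tibble (see [damage_spectrum()]).
#' @export
#' @examples
#' cfg <- induction_config(480, 1.3, 0.17, 27)
#' simulate_damage_spectrum(cfg, n_sites = 1e4, label = "demo", seed = 1)
simulate_damage_spectrum <- function(config, n_sites, label = "simulated",
                                     oxygen_percent = 21, seed = NULL) {
  stopifnot(inherits(config, "induction_config"))
  if (!is.numeric(n_sites) || n_sites < 1) {
    abort("`n_sites` must be a positive integer")
  }
  if (!is.null(seed)) set.seed(seed)
  raw <- cpp_sim_damage(
    as.integer(n_sites), config$lesion_multiplicity, config$sb_fraction,
    config$segment_length, config$cluster_gap
  )
  counts <- raw[1:7]
  n_clusters <- raw[8]
  scale <- config$site_rate / n_sites
  yields <- setNames(counts * scale, damage_categories())
  out <- damage_spectrum(label, yields, oxygen_percent = oxygen_percent)
  phat <- counts / n_clusters
  se <- sqrt(pmax(phat * (1 - phat) * n_clusters, 0)) * scale
  attr(out, "mc_se") <- setNames(se, damage_categories())
  attr(out, "n_sites") <- n_sites
  attr(out, "n_clusters") <- n_clusters
  out
}

# CRN objective shared by calibrate_induction(): weighted sum of squared
# relative errors of the simulated columns against the target columns.
induction_objective <- function(par, target_vals, columns, weights, n_sites,
                                seed, cluster_gap, fixed_L) {
  site_rate <- exp(par[["log_site_rate"]])
  lambda <- exp(par[["log_lambda"]])
  f <- stats::plogis(par[["logit_f"]])
  L <- if (is.null(fixed_L)) {
    max(11L, min(200L, as.integer(round(exp(par[["log_L"]])))))
  } else {
    fixed_L
  }
  set.seed(seed)
  raw <- cpp_sim_damage(as.integer(n_sites), lambda, f, L,
                        as.integer(cluster_gap))
  yields <- setNames(raw[1:7] * site_rate / n_sites, damage_categories())
  row <- damage_spectrum("cal", yields)
  sim_vals <- vapply(columns, function(cc) row[[cc]], numeric(1))
  rel <- (sim_vals - target_vals) / ifelse(target_vals > 0, target_vals, 1)
  sum(weights * rel^2)
}

#' Calibrate the induction model against a target damage spectrum
#'
#' Inverts a printed (or simulated) per-category yield table into induction
#' parameters by derivative-free optimization (Nelder-Mead) of a weighted sum
#' of squared relative errors, using common random numbers: every objective
#' evaluation re-seeds the simulator with the same seed, so the objective is
#' a deterministic function of the parameters.
#'
#' @param target One-row damage-spectrum tibble (all seven category yields),
#'   e.g. from [read_damage_spectra()].
#' @param bounds Named list overriding the default search bounds; entries
#'   `site_rate`, `lesion_multiplicity`, `sb_fraction`, `segment_length`,
#'   each a length-2 numeric (lower, upper).
#' @param n_sites Sites per objective evaluation (default 2e5).
#' @param seed Integer seed for the common random numbers (default 1).
#' @param columns Target columns for the fit. Default: the seven categories.
#'   Use e.g. `c("BD", "total_SSB", "total_DSB", "total_damage")` for tables
#'   whose constituent columns are internally inconsistent.
#' @param weights Non-negative weights, one per entry of `columns`
#'   (default equal).
#' @param calibrate_segment Also optimize `segment_length` (default TRUE).
#'   When FALSE, `segment_length` is fixed at the value of `init`.
#' @param init Optional [induction_config()] used as the starting point.
#' @param maxit Nelder-Mead iteration cap per restart (default 300).
#' @param restarts Number of Nelder-Mead restarts from the previous optimum
#'   (default 2).
#' @return An object of class `"induction_fit"`: the fitted
#'   [induction_config()] plus residuals per target column and optimizer
#'   diagnostics. Use [tidy()] / [glance()] to extract them.
#' @export
calibrate_induction <- function(target, bounds = NULL, n_sites = 2e5,
                                seed = 1, columns = damage_categories(),
                                weights = NULL, calibrate_segment = TRUE,
                                init = NULL, maxit = 300, restarts = 2) {
  if (nrow(target) != 1) abort("`target` must be a one-row damage spectrum")
  missing_cols <- setdiff(columns, names(target))
  if (length(missing_cols) > 0) {
    abort(paste("target lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  target_vals <- vapply(columns, function(cc) target[[cc]], numeric(1))
  if (is.null(weights)) weights <- rep(1, length(columns))
  if (length(weights) != length(columns) || any(weights < 0)) {
    abort("`weights` must be non-negative, one per target column")
  }
  b <- list(site_rate = c(1, 5000), lesion_multiplicity = c(1e-4, 8),
            sb_fraction = c(1e-4, 0.999), segment_length = c(11, 200))
  if (!is.null(bounds)) b <- modifyList(b, bounds)
  if (is.null(init)) {
    # moment-style start: total damage sets the scale; break share sets f
    td <- if ("total_damage" %in% names(target)) target$total_damage else
      sum(target_vals)
    f0 <- min(0.9, max(0.05, (target$SSB %||% 0.3 * td) / td))
    init <- induction_config(site_rate = 0.8 * td, lesion_multiplicity = 1,
                             sb_fraction = f0, segment_length = 25,
                             cluster_gap = target_gap_default(target))
  }
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  par <- c(
    log_site_rate = log(clamp(init$site_rate, b$site_rate[1], b$site_rate[2])),
    log_lambda = log(clamp(init$lesion_multiplicity,
                           b$lesion_multiplicity[1], b$lesion_multiplicity[2])),
    logit_f = stats::qlogis(clamp(init$sb_fraction, b$sb_fraction[1],
                                  b$sb_fraction[2]))
  )
  fixed_L <- NULL
  if (calibrate_segment) {
    par <- c(par, log_L = log(clamp(init$segment_length,
                                    b$segment_length[1], b$segment_length[2])))
  } else {
    fixed_L <- init$segment_length
  }
  cluster_gap <- init$cluster_gap
  fn_at <- function(ns) {
    function(p) {
      names(p) <- names(par)
      # box penalty keeps Nelder-Mead inside the user bounds
      vals <- c(exp(p[["log_site_rate"]]), exp(p[["log_lambda"]]),
                stats::plogis(p[["logit_f"]]))
      lims <- rbind(b$site_rate, b$lesion_multiplicity, b$sb_fraction)
      if (calibrate_segment) {
        vals <- c(vals, exp(p[["log_L"]]))
        lims <- rbind(lims, b$segment_length)
      }
      pen <- sum(pmax(0, lims[, 1] - vals)^2 + pmax(0, vals - lims[, 2])^2)
      if (pen > 0) return(1e6 * (1 + pen))
      induction_objective(p, target_vals, columns, weights, ns, seed,
                          cluster_gap, fixed_L)
    }
  }
  fn <- fn_at(n_sites)
  # multi-start screening at reduced cost: the objective surface has local
  # minima trading lesion multiplicity against strand-break fraction, so a
  # single Nelder-Mead start is unreliable
  starts <- list(par)
  for (l0 in c(0.3, 1, 2.5)) {
    for (f0 in c(0.2, 0.5, 0.8)) {
      s <- par
      s[["log_lambda"]] <- log(l0)
      s[["logit_f"]] <- stats::qlogis(f0)
      starts[[length(starts) + 1]] <- s
    }
  }
  ns_screen <- max(2e4, ceiling(n_sites / 10))
  fn_screen <- fn_at(ns_screen)
  screened <- lapply(starts, function(s) {
    optim(s, fn_screen, method = "Nelder-Mead",
          control = list(maxit = ceiling(maxit / 2), reltol = 1e-6))
  })
  best <- screened[[which.min(vapply(screened, `[[`, numeric(1), "value"))]]
  opt <- list(par = best$par, value = fn(best$par), convergence = 1L)
  names(opt$par) <- names(par)
  for (r in seq_len(max(1, restarts))) {
    opt <- optim(opt$par, fn, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-8))
    names(opt$par) <- names(par)
  }
  cfg <- induction_config(
    site_rate = exp(opt$par[["log_site_rate"]]),
    lesion_multiplicity = exp(opt$par[["log_lambda"]]),
    sb_fraction = stats::plogis(opt$par[["logit_f"]]),
    segment_length = if (is.null(fixed_L)) {
      max(11L, min(200L, as.integer(round(exp(opt$par[["log_L"]])))))
    } else fixed_L,
    cluster_gap = cluster_gap
  )
  fitted <- simulate_damage_spectrum(cfg, n_sites = n_sites,
                                     label = target$label[1], seed = seed)
  fitted_vals <- vapply(columns, function(cc) fitted[[cc]], numeric(1))
  residuals <- tibble(
    column = columns,
    target = target_vals,
    fitted = fitted_vals,
    rel_error = (fitted_vals - target_vals) /
      ifelse(target_vals > 0, target_vals, 1)
  )
  if (!is.finite(opt$value)) {
    abort(paste("induction calibration failed to converge; residuals:",
                paste(sprintf("%s %.3f", residuals$column,
                              residuals$rel_error), collapse = ", ")))
  }
  structure(
    list(config = cfg, residuals = residuals, objective = opt$value,
         convergence = opt$convergence, n_sites = n_sites, seed = seed,
         target = target),
    class = "induction_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

target_gap_default <- function(target) {
  g <- attr(target, "cluster_gap")
  if (is.null(g)) 10L else as.integer(g)
}

#' @export
print.induction_fit <- function(x, ...) {
  cat("<induction_fit>  objective =", format(x$objective, digits = 4), "\n")
  print(x$config)
  cat("residuals (relative):\n")
  print(as.data.frame(x$residuals), row.names = FALSE)
  invisible(x)
}

#' @rdname calibrate_induction
#' @param x An `"induction_fit"` object.
#' @param ... Unused.
#' @export
tidy.induction_fit <- function(x, ...) {
  x$residuals
}

#' @rdname calibrate_induction
#' @export
glance.induction_fit <- function(x, ...) {
  tibble(
    objective = x$objective,
    max_abs_rel_error = max(abs(x$residuals$rel_error)),
    convergence = x$convergence,
    n_sites = x$n_sites,
    site_rate = x$config$site_rate,
    lesion_multiplicity = x$config$lesion_multiplicity,
    sb_fraction = x$config$sb_fraction,
    segment_length = x$config$segment_length
  )
}

#' Exhaustively verify the cluster classifier against a brute-force oracle
#'
#' Compares the production classification path (chain clustering plus greedy
#' left-to-right break pairing) against an independent oracle (union-find
#' clustering plus enumerated maximum matching) over every configuration of
#' up to `max_lesions` lesions on a window of `window` base pairs, both
#' strands and both lesion kinds.
#'
#' @param window Window size in base pairs (default 30).
#' @param max_lesions Maximum lesions per configuration (default 4).
#' @param gap DSB pairing / chaining distance in bp (default 10).
#' @return List with `n_checked`, `n_mismatch` and, when any mismatch
#'   exists, the first mismatching configuration.
#' @export
verify_classifier <- function(window = 30, max_lesions = 4, gap = 10) {
  if (window < 1 || max_lesions < 1) {
    abort("window and max_lesions must be positive")
  }
  cpp_exhaustive_classifier_check(as.integer(window),
                                  as.integer(max_lesions),
                                  as.integer(gap))
}
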