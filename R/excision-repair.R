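#' Excision-repair pathway codes
#'
#' Short-patch base excision repair replaces a single nucleotide; long-patch
#' BER resynthesizes a 2-13 nucleotide patch; the combined BER/NER pathways
#' route base damage through nucleotide excision repair (a two-sided patch of
#' the same 2-13 nt length) while strand breaks take the BER mode.
#'
#' @return Character vector of the four pathway codes.
#' @export
repair_pathways <- function() {
  c("SP_BER", "LP_BER", "NER_SP_BER", "NER_LP_BER")
}

#' Repair outcome codes
#'
#' @return Character vector: correct repair, mutation, DSB conversion.
#' @export
repair_outcomes <- function() {
  c("correct_repair", "mutation", "dsb_conversion")
}

#' Parameters of the excision-repair state machine
#'
#' Defaults follow the standard Monte Carlo excision-repair parameter set:
#' an 8 bp inhibition distance (a repair intermediate within this distance of
#' an opposite-strand break converts the cluster into a DSB), equal chance of
#' starting from a strand-break lesion when both kinds remain, polymerase
#' error 1e-4 for short-patch BER and 1e-6 for long-patch BER and NER, and
#' probability 0.75 of an incorrect insertion opposite a damaged or lost
#' base. Long-patch/NER excision removes 2-13 nucleotides.
#'
#' @param inhibition_distance Base pairs (>= 1, default 8).
#' @param p_first_strand_break Probability of selecting a strand-break lesion
#'   first when both kinds remain (default 0.5).
#' @param err_sp Polymerase error for SP BER (default 1e-4).
#' @param err_lp_ner Polymerase error for LP BER and NER (default 1e-6).
#' @param p_misinsert_damaged Probability of incorrect insertion opposite a
#'   damaged base in the template span (default 0.75).
#' @param p_misinsert_lost Probability of incorrect insertion opposite a lost
#'   base (default 0.75; retained for interface completeness - the two-kind
#'   lesion model produces no abasic template sites).
#' @param lp_patch_min,lp_patch_max Long-patch size bounds in nucleotides
#'   (defaults 2 and 13).
#' @return Validated list of class `"repair_params"`.
#' @export
repair_params <- function(inhibition_distance = 8,
                          p_first_strand_break = 0.5,
                          err_sp = 1e-4, err_lp_ner = 1e-6,
                          p_misinsert_damaged = 0.75,
                          p_misinsert_lost = 0.75,
                          lp_patch_min = 2, lp_patch_max = 13) {
  probs <- c(p_first_strand_break, err_sp, err_lp_ner, p_misinsert_damaged,
             p_misinsert_lost)
  if (any(probs < 0) || any(probs > 1)) {
    abort("all repair probabilities must lie in [0, 1]")
  }
  if (inhibition_distance < 1 || lp_patch_min > lp_patch_max ||
      lp_patch_min < 1) {
    abort(paste("need inhibition_distance >= 1 and",
                "1 <= lp_patch_min <= lp_patch_max"))
  }
  structure(
    list(inhibition_distance = as.integer(inhibition_distance),
         p_first_strand_break = p_first_strand_break,
         err_sp = err_sp, err_lp_ner = err_lp_ner,
         p_misinsert_damaged = p_misinsert_damaged,
         p_misinsert_lost = p_misinsert_lost,
         lp_patch_min = as.integer(lp_patch_min),
         lp_patch_max = as.integer(lp_patch_max)),
    class = "repair_params"
  )
}

assert_repairable <- function(lesions, gap = 10) {
  category <- classify_cluster(lesions, gap = gap)
  if (category %in% c("DSB", "DSBp", "DSBpp")) {
    abort(paste0(
      "cluster already contains a DSB (category ", category,
      "); excision repair operates on non-DSB clustered damage only"
    ))
  }
  category
}

repair_mc_counts <- function(lesions, pathway, params, n_trials) {
  path_code <- match(pathway, repair_pathways()) - 1L
  if (is.na(path_code)) {
    abort(paste("unknown pathway:", pathway, "- see repair_pathways()"))
  }
  cpp_repair_mc(
    as.integer(lesions$position), as.integer(lesions$strand),
    as.integer(lesions$kind == "strand_break"),
    path_code, as.integer(n_trials),
    params$inhibition_distance, params$p_first_strand_break,
    params$err_sp, params$err_lp_ner, params$p_misinsert_damaged,
    params$lp_patch_min, params$lp_patch_max
  )
}

#' Simulate the excision repair of one non-DSB cluster
#'
#' Runs the repair state machine once: lesions are selected one at a time
#' (strand breaks preferred with probability `p_first_strand_break` when both
#' kinds remain), excised (SP: 1 nt 3' patch; LP: 2-13 nt 3' patch; NER: 2-13
#' nt two-sided patch, used for base damage in the combined pathways), which
#' opens a transient single-strand gap. Same-strand lesions inside the patch
#' are co-excised. If an unrepaired opposite-strand break lies within the
#' inhibition distance of the gap, the cluster converts into a DSB and the
#' run terminates. Otherwise the gap is filled: a mis-insertion is committed
#' with probability `p_misinsert_damaged` when the template span holds a
#' damaged base, or with the pathway polymerase error. After all lesions are
#' processed, any committed mis-insertion yields a mutation; otherwise the
#' repair is correct.
#'
#' @param lesions Tibble with `position`, `strand`, `kind`; must classify as
#'   BD, SSB, SSBp or twoSSB.
#' @param pathway One of [repair_pathways()].
#' @param params A [repair_params()].
#' @param seed Optional integer seed.
#' @param check_category Enforce the non-DSB precondition (default TRUE).
#'   Disable only to probe the state machine itself on arbitrary lesion sets.
#' @return A single outcome code (see [repair_outcomes()]).
#' @export
#' @examples
#' les <- tibble::tibble(position = 5, strand = 0, kind = "base_damage")
#' repair_cluster(les, "SP_BER", seed = 1)
repair_cluster <- function(lesions, pathway, params = repair_params(),
                           seed = NULL, check_category = TRUE) {
  if (check_category) assert_repairable(lesions)
  if (!is.null(seed)) set.seed(seed)
  counts <- repair_mc_counts(lesions, pathway, params, 1L)
  repair_outcomes()[which(counts == 1)]
}

#' Monte Carlo repair-outcome probabilities for one cluster
#'
#' Repeats [repair_cluster()] `n_trials` times; the three outcome
#' probabilities share one denominator, so they sum to 1 exactly. Binomial
#' standard errors are attached as the `"mc_se"` attribute.
#'
#' @inheritParams repair_cluster
#' @param n_trials Number of independent repair simulations (>= 1).
#' @return One-row tibble: `pathway`, `p_correct`, `p_mutation`,
#'   `p_conversion`, `n_trials`.
#' @export
outcome_probabilities <- function(lesions, pathway, params = repair_params(),
                                  n_trials = 1e4, seed = NULL,
                                  check_category = TRUE) {
  if (n_trials < 1) abort("`n_trials` must be >= 1")
  if (check_category) assert_repairable(lesions)
  if (!is.null(seed)) set.seed(seed)
  counts <- repair_mc_counts(lesions, pathway, params, n_trials)
  p <- counts / n_trials
  out <- tibble(pathway = pathway, p_correct = p[1], p_mutation = p[2],
                p_conversion = p[3], n_trials = as.integer(n_trials))
  attr(out, "mc_se") <- setNames(sqrt(p * (1 - p) / n_trials),
                                 c("p_correct", "p_mutation", "p_conversion"))
  out
}

#' Yield-weighted aggregate repair-outcome probabilities
#'
#' Averages per-category outcome probabilities over all damage categories,
#' weighted by category yield relative to total damage. Clusters that already
#' contain a DSB are not run through excision repair; the caller supplies
#' their rows as the outcome of their accompanying base damage, or (1, 0, 0)
#' when there is none (see [category_outcome_probabilities()], which builds
#' the per-category table that way).
#'
#' @param spectrum One-row damage spectrum.
#' @param per_category Tibble with `category`, `p_correct`, `p_mutation`,
#'   `p_conversion`, covering every category with non-zero yield. Categories
#'   whose probabilities are `NA` (no clusters of that category were sampled
#'   in the Monte Carlo pool) are dropped with a warning and the weights are
#'   renormalized over the observed categories; this is a negligible
#'   approximation when the missing categories carry a tiny yield fraction.
#' @return One-row tibble with the aggregate `p_correct`, `p_mutation`,
#'   `p_conversion` and the `label` of the spectrum.
#' @export
aggregate_outcomes <- function(spectrum, per_category) {
  if (nrow(spectrum) != 1) abort("`spectrum` must be a one-row spectrum")
  yields <- vapply(damage_categories(), function(cc) spectrum[[cc]],
                   numeric(1))
  active <- names(yields)[yields > 0]
  missing_cat <- setdiff(active, per_category$category)
  if (length(missing_cat) > 0) {
    abort(paste("per-category outcomes missing for:",
                paste(missing_cat, collapse = ", ")))
  }
  idx <- match(active, per_category$category)
  have <- !is.na(per_category$p_correct[idx])
  if (!all(have)) {
    dropped <- active[!have]
    warn(paste0(
      "no sampled clusters for categor", if (sum(!have) == 1) "y " else
        "ies ", paste(dropped, collapse = ", "),
      " (yield fraction ", format(sum(yields[dropped]) / sum(yields),
                                  digits = 3),
      "); renormalizing over observed categories"
    ))
    active <- active[have]
    idx <- idx[have]
  }
  w <- yields[active] / sum(yields[active])
  tibble(
    label = spectrum$label,
    p_correct = sum(w * per_category$p_correct[idx]),
    p_mutation = sum(w * per_category$p_mutation[idx]),
    p_conversion = sum(w * per_category$p_conversion[idx])
  )
}

#' Per-category outcome probabilities from simulated clusters
#'
#' Samples damage sites from an induction configuration, pools the resulting
#' clusters by category, and Monte Carlo estimates the repair-outcome
#' probabilities of each category as the average over its sampled clusters.
#' Non-DSB categories are repaired as-is; DSB-containing clusters contribute
#' the outcome of their base-damage-only sub-cluster, or exactly
#' (1, 0, 0) when the cluster holds no base damage.
#'
#' @param config An [induction_config()].
#' @param pathway One of [repair_pathways()].
#' @param params A [repair_params()].
#' @param n_sites Sites to sample for the cluster pool (default 2e4).
#' @param n_trials Repair trials per sampled cluster (default 200).
#' @param max_clusters_per_category Cap on clusters repaired per category
#'   (default 500).
#' @param seed Optional integer seed.
#' @return Tibble with one row per category: `category`, `p_correct`,
#'   `p_mutation`, `p_conversion`, `n_clusters`, `n_trials_total`.
#' @export
category_outcome_probabilities <- function(config, pathway,
                                           params = repair_params(),
                                           n_sites = 2e4, n_trials = 200,
                                           max_clusters_per_category = 500,
                                           seed = NULL) {
  path_code <- match(pathway, repair_pathways()) - 1L
  if (is.na(path_code)) {
    abort(paste("unknown pathway:", pathway, "- see repair_pathways()"))
  }
  if (!is.null(seed)) set.seed(seed)
  lesions <- sample_site(config, n_sites = n_sites)
  gap <- config$cluster_gap
  lesions <- dplyr::arrange(lesions, .data$site, .data$position)
  n <- nrow(lesions)
  pos <- as.integer(lesions$position)
  strand <- as.integer(lesions$strand)
  sb <- as.integer(lesions$kind == "strand_break")
  new_cluster <- c(TRUE, lesions$site[-1] != lesions$site[-n] |
                     diff(pos) > gap)
  idx_by_cluster <- split(seq_len(n), cumsum(new_cluster))
  cat_code <- vapply(idx_by_cluster, function(ii) {
    cpp_classify_cluster(pos[ii], strand[ii], sb[ii], as.integer(gap))
  }, integer(1))
  dsb_cats <- c("DSB", "DSBp", "DSBpp")
  cats <- damage_categories()
  rows <- lapply(seq_along(cats), function(ci) {
    cc <- cats[ci]
    groups <- idx_by_cluster[cat_code == ci - 1L]
    if (length(groups) == 0) {
      return(tibble(category = cc, p_correct = NA_real_,
                    p_mutation = NA_real_, p_conversion = NA_real_,
                    n_clusters = 0L, n_trials_total = 0L))
    }
    if (length(groups) > max_clusters_per_category) {
      groups <- groups[sample.int(length(groups),
                                  max_clusters_per_category)]
    }
    counts <- c(0, 0, 0)
    trials <- 0L
    for (ii in groups) {
      if (cc %in% dsb_cats) {
        ii <- ii[sb[ii] == 0L]
        if (length(ii) == 0) {
          counts <- counts + c(n_trials, 0, 0)
          trials <- trials + n_trials
          next
        }
      }
      counts <- counts + cpp_repair_mc(
        pos[ii], strand[ii], sb[ii], path_code, as.integer(n_trials),
        params$inhibition_distance, params$p_first_strand_break,
        params$err_sp, params$err_lp_ner, params$p_misinsert_damaged,
        params$lp_patch_min, params$lp_patch_max
      )
      trials <- trials + n_trials
    }
    p <- counts / trials
    tibble(category = cc, p_correct = p[1], p_mutation = p[2],
           p_conversion = p[3], n_clusters = length(groups),
           n_trials_total = trials)
  })
  dplyr::bind_rows(rows)
}

#' Enzymatic DSB yield
#'
#' The yield of DSBs created by excision repair of non-DSB clustered damage:
#' total damage yield multiplied by the aggregate DSB-conversion probability.
#'
#' @param total_damage Total damage yield per Gy per Gbp (>= 0).
#' @param p_conversion Aggregate DSB-conversion probability (>= 0).
#' @return Enzymatic DSB yield per Gy per Gbp (vectorized).
#' @export
#' @examples
#' enzymatic_dsb_yield(552.8, 0.017)
enzymatic_dsb_yield <- function(total_damage, p_conversion) {
  if (any(total_damage < 0) || any(p_conversion < 0)) {
    abort("inputs must be non-negative")
  }
  total_damage * p_conversion
}

#' A standard battery of small non-DSB clusters
#'
#' Named 1-3 lesion clusters exercising the repair machine's branch points:
#' isolated lesions, same-strand break pairs, opposite-strand break pairs
#' beyond the pairing gap (twoSSB), and base damage flanked by an
#' opposite-strand break just outside the inhibition distance.
#'
#' @return Tibble with `name` and a `lesions` list-column.
#' @export
standard_cluster_battery <- function() {
  mk <- function(position, strand, kind) {
    tibble(position = position, strand = strand, kind = kind)
  }
  tibble(
    name = c("single_bd", "single_ssb", "bd_pair", "ssb_pair_same_strand",
             "bd_opposite_break_9bp", "twossb_chain",
             "ssbp_with_template_bd", "ssbp_triplet"),
    lesions = list(
      mk(5, 0, "base_damage"),
      mk(5, 0, "strand_break"),
      mk(c(2, 7), c(0, 1), c("base_damage", "base_damage")),
      mk(c(0, 4), c(0, 0), c("strand_break", "strand_break")),
      mk(c(9, 0), c(0, 1), c("base_damage", "strand_break")),
      mk(c(0, 6, 12), c(0, 1, 1),
         c("strand_break", "base_damage", "strand_break")),
      mk(c(0, 4, 7), c(0, 1, 0),
         c("strand_break", "base_damage", "strand_break")),
      mk(c(0, 5, 9), c(0, 0, 0),
         c("strand_break", "strand_break", "strand_break"))
    )
  )
}
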