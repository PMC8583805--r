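# Independent analytic oracle for the excision-repair state machine.
#
# Computes the exact outcome probabilities of a cluster by enumerating the
# machine's discrete branch tree (lesion-class selection, uniform lesion
# choice within the class, uniform patch length, deterministic NER patch
# split) and taking expectations in pure R. The recursion is Markov in the
# set of surviving lesions, so results are memoized on that set.
#
# Outcome algebra per step: let q be the step's mis-insertion probability
# and (c, m, v) the outcome distribution of the remaining process. A
# conversion anywhere dominates; otherwise any mis-insertion yields a
# mutation. Hence the step contributes
#   correct    = (1 - q) c
#   mutation   = (1 - q) m + q (c + m)
#   conversion = v
oracle_repair_probs <- function(position, strand, kind_break, pathway,
                                params = repair_params()) {
  position <- as.integer(position)
  strand <- as.integer(strand)
  kind_break <- as.integer(kind_break)
  n <- length(position)
  stopifnot(pathway %in% repair_pathways())
  memo <- new.env(parent = emptyenv())
  patch_lengths <- seq(params$lp_patch_min, params$lp_patch_max)

  recurse <- function(alive) {
    if (!any(alive)) return(c(1, 0, 0))
    key <- paste(which(alive), collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    brk <- which(alive & kind_break == 1L)
    bd <- which(alive & kind_break == 0L)
    if (length(brk) > 0 && length(bd) > 0) {
      sels <- c(brk, bd)
      sel_p <- c(rep(params$p_first_strand_break / length(brk),
                     length(brk)),
                 rep((1 - params$p_first_strand_break) / length(bd),
                     length(bd)))
    } else {
      sels <- c(brk, bd)
      sel_p <- rep(1 / length(sels), length(sels))
    }
    out <- c(0, 0, 0)
    for (si in seq_along(sels)) {
      sel <- sels[si]
      is_ner <- switch(pathway,
                       SP_BER = FALSE, LP_BER = FALSE,
                       NER_SP_BER = kind_break[sel] == 0L,
                       NER_LP_BER = kind_break[sel] == 0L)
      is_sp <- switch(pathway,
                      SP_BER = TRUE, LP_BER = FALSE,
                      NER_SP_BER = !is_ner, NER_LP_BER = FALSE)
      lens <- if (is_sp) 1L else patch_lengths
      for (L in lens) {
        p_branch <- sel_p[si] / length(lens)
        left <- if (is_ner) (L - 1L) %/% 2L else 0L
        a <- position[sel] - left
        b <- a + L - 1L
        new_alive <- alive
        new_alive[alive & strand == strand[sel] &
                    position >= a & position <= b] <- FALSE
        dist <- ifelse(position < a, a - position,
                       ifelse(position > b, position - b, 0L))
        converts <- any(new_alive & strand != strand[sel] &
                          kind_break == 1L &
                          dist <= params$inhibition_distance)
        if (converts) {
          out <- out + p_branch * c(0, 0, 1)
          next
        }
        damaged_template <- any(new_alive & strand != strand[sel] &
                                  kind_break == 0L &
                                  position >= a & position <= b)
        q <- if (damaged_template) params$p_misinsert_damaged else
          if (is_sp) params$err_sp else params$err_lp_ner
        sub <- recurse(new_alive)
        out <- out + p_branch * c((1 - q) * sub[1],
                                  (1 - q) * sub[2] + q * (sub[1] + sub[2]),
                                  sub[3])
      }
    }
    memo[[key]] <- out
    out
  }
  setNames(recurse(rep(TRUE, n)),
           c("p_correct", "p_mutation", "p_conversion"))
}

# Tibble-facing wrapper matching the production lesion layout.
oracle_repair_probs_df <- function(lesions, pathway,
                                   params = repair_params()) {
  oracle_repair_probs(lesions$position, lesions$strand,
                      as.integer(lesions$kind == "strand_break"),
                      pathway, params)
}

# All 1- and 2-lesion clusters (positions on a small window, both strands,
# both kinds), excluding DSB-forming pairs, as a list of lesion tibbles.
enumerate_small_clusters <- function(window = 12, gap = 10) {
  singles <- list()
  for (p in c(0L, 3L)) for (s in 0:1) for (kb in 0:1) {
    singles[[length(singles) + 1]] <- tibble::tibble(
      position = p, strand = s,
      kind = if (kb == 1) "strand_break" else "base_damage"
    )
  }
  pairs <- list()
  slots <- expand.grid(p = 0:(window - 1), s = 0:1, kb = 0:1)
  for (i in seq_len(nrow(slots) - 1)) {
    for (j in seq(i + 1, nrow(slots))) {
      a <- slots[i, ]
      b <- slots[j, ]
      if (a$p == b$p && a$s == b$s) next  # occupied slot
      les <- tibble::tibble(
        position = c(a$p, b$p), strand = c(a$s, b$s),
        kind = ifelse(c(a$kb, b$kb) == 1, "strand_break", "base_damage")
      )
      if (classify_cluster(les, gap = gap) %in% c("DSB", "DSBp", "DSBpp")) {
        next
      }
      pairs[[length(pairs) + 1]] <- les
    }
  }
  c(singles, pairs)
}
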