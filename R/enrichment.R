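# GSEA-style metabolite-set enrichment: Welch-t ranking between two diet
# groups, a weighted Kolmogorov-Smirnov running sum per set, and a
# sample-label permutation null (which preserves the inter-metabolite
# correlation structure of FIA data, unlike a metabolite-shuffling null).

#' Rank metabolites by a two-group statistic
#'
#' Per-ion Welch t computed on log10 intensities between two diet groups,
#' sorted descending; exact ties are broken by ion id so the ranking is
#' deterministic.
#'
#' @param matrix a \code{metabolite_matrix}.
#' @param cohort cohort data.frame.
#' @param group_a,group_b diet labels; positive scores mean higher in
#'   \code{group_a}.
#' @param stat ranking statistic; only \code{"welch_t"}.
#' @return data.frame \code{ion_id, score}, sorted by decreasing score.
#' @export
rank_metabolites <- function(matrix, cohort, group_a, group_b,
                             stat = "welch_t") {
  stopifnot(inherits(matrix, "metabolite_matrix"),
            identical(stat, "welch_t"))
  ids_a <- cohort$id[cohort$diet == group_a]
  ids_b <- cohort$id[cohort$diet == group_b]
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    stop_input("both groups need >= 2 participants")
  }
  lm10 <- log10(matrix$intensities[, cohort$id, drop = FALSE])
  score <- welch_t_rows(lm10, ids_a, ids_b)
  ord <- order(-score, rownames(lm10))
  data.frame(ion_id = rownames(lm10)[ord], score = score[ord],
             stringsAsFactors = FALSE)
}

#' Weighted running-sum enrichment score
#'
#' Classic GSEA statistic: walking down the ranking, the sum increases by
#' \code{|score|^weight_p / sum over members of |score|^weight_p} at each
#' set member and decreases by \code{1 / (N - N_members)} at each
#' non-member. ES is the running-sum value of maximal absolute deviation
#' from zero (signed); with \code{weight_p = 0} the final running-sum
#' value is exactly 0.
#'
#' @param ranked data.frame from [rank_metabolites()] (or any
#'   \code{ion_id, score} ranking).
#' @param set character vector of member ids (>= 1 member must appear in
#'   the ranking).
#' @param weight_p weighting exponent (0 = unweighted KS, 1 = classic).
#' @return list \code{es} (scalar in [-1, 1]) and \code{running} (the
#'   full running-sum trace).
#' @export
enrichment_score <- function(ranked, set, weight_p = 1) {
  hits <- ranked$ion_id %in% set
  n <- nrow(ranked)
  nm <- sum(hits)
  if (nm == 0) stop_input("no set members present in the ranking")
  if (nm == n) {
    w <- abs(ranked$score)^weight_p
    run <- cumsum(w / sum(w))
    return(list(es = 1, running = run))
  }
  inc <- numeric(n)
  w <- abs(ranked$score[hits])^weight_p
  if (sum(w) == 0) w <- rep(1, nm)  # all-zero scores: fall back to flat
  inc[hits] <- w / sum(w)
  inc[!hits] <- -1 / (n - nm)
  run <- cumsum(inc)
  # signed maximal deviation; an exact tie between the positive and
  # negative extremes resolves to the positive one
  hi <- max(run); lo <- min(run)
  es <- if (hi >= -lo - 1e-12) hi else lo
  list(es = es, running = run)
}

#' Metabolite-set enrichment with a sample-permutation null
#'
#' For each set: observed ES from the true group labels; a null
#' distribution from \code{n_perm} shuffles of the group labels (the
#' ranking is recomputed per shuffle, so the inter-ion correlation
#' structure is preserved under the null); two-sided
#' \code{p = (#\{|ES*| >= |ES|\} + 1) / (n_perm + 1)};
#' \code{NES = ES / mean(|null ES| of the same sign)}; Benjamini-Hochberg
#' across the retained sets. Sets with fewer than \code{min_size}
#' members in the matrix are skipped with a warning.
#'
#' @param matrix a \code{metabolite_matrix}.
#' @param cohort cohort data.frame.
#' @param sets named list (e.g. from [read_gmt()]).
#' @param group_a,group_b diet labels to compare.
#' @param n_perm permutation count (>= 1).
#' @param seed RNG seed.
#' @param weight_p running-sum weight (default 1).
#' @param min_size minimum members present (default 3).
#' @param null \code{"sample"} (label shuffling, default) or
#'   \code{"metabolite"} (shuffle which ions are called members; faster
#'   but anti-conservative under correlated ions).
#' @return data.frame \code{pathway, es, nes, p, q, n_members, n_perm}.
#' @export
pathway_permutation_test <- function(matrix, cohort, sets,
                                     group_a = "VGN", group_b = "OMN",
                                     n_perm = 999L, seed = NULL,
                                     weight_p = 1, min_size = 3L,
                                     null = c("sample", "metabolite")) {
  null <- match.arg(null)
  if (n_perm < 1) stop_input("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  keep <- cohort$diet %in% c(group_a, group_b)
  sub <- cohort[keep, , drop = FALSE]
  lm10 <- log10(matrix$intensities[, sub$id, drop = FALSE])
  ion_names <- rownames(lm10)

  present <- vapply(sets, function(s) sum(ion_names %in% s), 0L)
  skip <- present < min_size
  if (any(skip)) {
    warning(sprintf("skipping %d set(s) with < %d members present: %s",
                    sum(skip), min_size,
                    paste(names(sets)[skip], collapse = ", ")))
  }
  sets <- sets[!skip]
  if (!length(sets)) {
    return(data.frame(pathway = character(0), es = numeric(0),
                      nes = numeric(0), p = numeric(0), q = numeric(0),
                      n_members = integer(0), n_perm = integer(0)))
  }

  is_a <- sub$diet == group_a
  rank_and_score <- function(a_mask) {
    score <- welch_t_rows(lm10, which(a_mask), which(!a_mask))
    ord <- order(-score, ion_names)
    list(ids = ion_names[ord], score = score[ord])
  }
  es_of <- function(rk) {
    vapply(sets, function(s) {
      enrichment_score(data.frame(ion_id = rk$ids, score = rk$score,
                                  stringsAsFactors = FALSE),
                       s, weight_p)$es
    }, 0.0)
  }

  obs <- es_of(rank_and_score(is_a))
  null_es <- matrix(NA_real_, n_perm, length(sets))
  if (null == "sample") {
    n <- nrow(sub); na <- sum(is_a)
    for (b in seq_len(n_perm)) {
      mask <- logical(n)
      mask[sample.int(n, na)] <- TRUE
      null_es[b, ] <- es_of(rank_and_score(mask))
    }
  } else {
    rk <- rank_and_score(is_a)
    for (b in seq_len(n_perm)) {
      perm_ids <- sample(rk$ids)
      null_es[b, ] <- vapply(seq_along(sets), function(si) {
        enrichment_score(data.frame(ion_id = perm_ids, score = rk$score,
                                    stringsAsFactors = FALSE),
                         sets[[si]], weight_p)$es
      }, 0.0)
    }
  }

  p <- vapply(seq_along(sets), function(si) {
    (sum(abs(null_es[, si]) >= abs(obs[si]) - 1e-12) + 1) / (n_perm + 1)
  }, 0.0)
  nes <- vapply(seq_along(sets), function(si) {
    same <- null_es[, si][sign(null_es[, si]) == sign(obs[si])]
    denom <- mean(abs(same))
    if (!length(same) || !is.finite(denom) || denom == 0) return(NA_real_)
    obs[si] / denom
  }, 0.0)

  data.frame(pathway = names(sets), es = unname(obs), nes = nes,
             p = p, q = bh_adjust(p),
             n_members = unname(present[!skip]),
             n_perm = as.integer(n_perm),
             stringsAsFactors = FALSE, row.names = NULL)
}
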