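# Untargeted FIA-TOF-MS handling: accurate-mass putative annotation,
# isotopologue-correlation support, and fold changes versus the omnivore
# mean. Annotation is putative by design: accurate mass alone cannot
# distinguish isomers, so every compound within tolerance is retained.

# Most-abundant-isotope masses (Da); extensible via the `elements`
# argument of monoisotopic_mass().
ELEMENT_MASSES <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151,
  S = 31.97207069
)

PROTON_MASS <- 1.007276

#' Monoisotopic neutral mass of an elemental formula
#'
#' @param formula formula string over C, H, N, O, P, S (e.g.
#'   \code{"C6H12O6"}); the element-mass table is extensible.
#' @param elements named vector of isotope masses to use.
#' @return neutral monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("H2O")  # 18.0106
monoisotopic_mass <- function(formula, elements = ELEMENT_MASSES) {
  if (is.na(formula) || !nzchar(formula)) {
    stop_input("empty or missing formula")
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)
  toks <- regmatches(formula, m)[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(formula)) {
    stop_input("unparseable formula '%s'", formula)
  }
  mass <- 0
  for (tk in toks) {
    el <- sub("[0-9]*$", "", tk)
    cnt <- sub("^[A-Za-z]+", "", tk)
    cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (!el %in% names(elements)) {
      stop_input("unknown element '%s' in formula '%s'", el, formula)
    }
    mass <- mass + elements[[el]] * cnt
  }
  mass
}

#' Theoretical m/z of a formula in negative ionization mode
#'
#' Only the deprotonated species is modeled:
#' \code{[M-H]- m/z = monoisotopic mass - 1.007276}.
#'
#' @inheritParams monoisotopic_mass
#' @param mode ionization mode; only \code{"negative"} is implemented.
#' @return m/z in Th.
#' @export
#' @examples
#' mz_from_formula("C6H12O6")  # glucose [M-H]-, 179.0561
mz_from_formula <- function(formula, mode = "negative",
                            elements = ELEMENT_MASSES) {
  if (!identical(mode, "negative")) {
    stop_input("only negative mode ([M-H]-) is implemented")
  }
  monoisotopic_mass(formula, elements) - PROTON_MASS
}

#' Putative accurate-mass annotation of ion peaks
#'
#' Every ion is assigned ALL database compounds whose theoretical
#' \code{[M-H]-} m/z lies within \code{tol} of the observed m/z
#' (absolute tolerance, default 0.001 m/z). Isomers share a mass and are
#' all retained; candidate lists are sorted by |delta m/z|. Ions with no
#' match stay unannotated.
#'
#' @param matrix a \code{metabolite_matrix}.
#' @param compounds compound database data.frame (see
#'   [read_compound_db()]).
#' @param tol absolute m/z tolerance (> 0).
#' @return the matrix with \code{annotations} (named list ion ->
#'   data.frame \code{compound_id, theoretical_mz, delta_mz}) and the ion
#'   table's \code{annotation} column filled (semicolon-separated ids).
#' @export
annotate_peaks <- function(matrix, compounds, tol = 0.001) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  if (tol <= 0) stop_input("tol must be > 0")
  theo <- compound_mz(compounds)
  ord <- order(theo)
  theo_s <- theo[ord]
  ids_s <- compounds$compound_id[ord]
  ann <- vector("list", nrow(matrix$ions))
  names(ann) <- matrix$ions$ion_id
  eps <- 1e-9  # float guard so an exactly-at-tolerance match stays in
  for (i in seq_along(ann)) {
    mz <- matrix$ions$mz[i]
    lo <- findInterval(mz - tol - eps, theo_s) + 1L
    hi <- findInterval(mz + tol + eps, theo_s)
    if (hi >= lo) {
      k <- lo:hi
      d <- theo_s[k] - mz
      keep <- abs(d) <= tol + eps    # exact boundary: <= tol included
      k <- k[keep]; d <- d[keep]
      o <- order(abs(d), ids_s[k])
      ann[[i]] <- data.frame(compound_id = ids_s[k][o],
                             theoretical_mz = theo_s[k][o],
                             delta_mz = d[o], stringsAsFactors = FALSE)
    } else {
      ann[[i]] <- data.frame(compound_id = character(0),
                             theoretical_mz = numeric(0),
                             delta_mz = numeric(0))
    }
  }
  matrix$annotations <- ann
  matrix$ions$annotation <- vapply(ann, function(a)
    paste(a$compound_id, collapse = ";"), "")
  matrix
}

#' Isotopologue-correlation support for an ion annotation
#'
#' An annotation gains support when a companion peak sits one
#' 13C-12C spacing higher (\code{delta = 1.003355} m/z, within
#' \code{tol}) AND the two peaks' intensities correlate across
#' participants (Pearson r >= \code{r_min}), the behavior expected of an
#' M+1 isotopologue of the same compound.
#'
#' @param matrix a \code{metabolite_matrix} with >= 3 participants.
#' @param ion ion id to check.
#' @param delta isotopologue spacing in m/z.
#' @param tol m/z tolerance for the partner search.
#' @param r_min minimum Pearson correlation.
#' @return logical flag (TRUE = supported), with attribute
#'   \code{partner} naming the best-correlated partner ion if any.
#' @export
isotope_correlation_support <- function(matrix, ion, delta = 1.003355,
                                        tol = 0.001, r_min = 0.7) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  if (ncol(matrix$intensities) < 3) stop_input("need >= 3 participants")
  i <- match(ion, matrix$ions$ion_id)
  if (is.na(i)) stop_input("unknown ion '%s'", ion)
  target <- matrix$ions$mz[i] + delta
  partners <- which(abs(matrix$ions$mz - target) <= tol)
  partners <- setdiff(partners, i)
  if (!length(partners)) return(structure(FALSE, partner = NA_character_))
  r <- vapply(partners, function(j)
    stats::cor(matrix$intensities[i, ], matrix$intensities[j, ]), 0.0)
  best <- which.max(r)
  structure(any(r >= r_min),
            partner = matrix$ions$ion_id[partners[best]])
}

#' Replace zeros and missing intensities
#'
#' \code{strategy = "half_min"}: zeros/NA in an ion are replaced by half
#' the smallest positive intensity of that ion; order-preserving and the
#' standard pragmatic choice before log-transforming FIA data.
#'
#' @param matrix a \code{metabolite_matrix}.
#' @param strategy zero-handling strategy (only \code{"half_min"}).
#' @return the matrix with strictly positive intensities.
#' @export
handle_zeros <- function(matrix, strategy = "half_min") {
  stopifnot(inherits(matrix, "metabolite_matrix"),
            identical(strategy, "half_min"))
  m <- matrix$intensities
  bad <- is.na(m) | m <= 0
  if (!any(bad)) return(matrix)
  for (i in which(rowSums(bad) > 0)) {
    pos <- m[i, !bad[i, ]]
    if (!length(pos)) {
      stop_input("ion '%s' has no positive intensities", rownames(m)[i])
    }
    m[i, bad[i, ]] <- min(pos) / 2
  }
  matrix$intensities <- m
  matrix
}

#' Per-individual log2 fold changes versus the reference-group mean
#'
#' \code{fc(ion, participant) = log2(intensity / arithmetic mean of the
#' reference group's intensities for that ion)}; a participant sitting at
#' the reference mean maps to exactly 0, so the zero level of a fold-change
#' plot is the omnivore mean.
#'
#' @param matrix a \code{metabolite_matrix} (strictly positive; run
#'   [handle_zeros()] first if needed).
#' @param cohort cohort data.frame aligned with the matrix columns.
#' @param reference reference diet group (default "OMN").
#' @return matrix of log2 fold changes, ions x participants, with
#'   attribute \code{reference_mean} ("arithmetic").
#' @export
log2_fold_changes <- function(matrix, cohort, reference = "OMN") {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  ref_ids <- cohort$id[cohort$diet == reference]
  if (!length(ref_ids)) stop_input("reference group '%s' is empty", reference)
  m <- matrix$intensities[, cohort$id, drop = FALSE]
  if (any(is.na(m)) || any(m <= 0)) {
    stop_input("nonpositive intensities: apply handle_zeros() first")
  }
  ref_mean <- rowMeans(m[, ref_ids, drop = FALSE])
  fc <- log2(m / ref_mean)
  attr(fc, "reference") <- reference
  attr(fc, "reference_mean") <- "arithmetic"
  fc
}

#' Pooled metabolite-class comparison (box-plot summaries)
#'
#' Pools the per-individual fold changes of all member ions of a class
#' within each diet group (n = members x participants, e.g. 3 ions x 24
#' omnivores = 72) and returns box-plot statistics per class and group.
#' No single test is computed on the pooled values — a t-test on pooled
#' dependent metabolites would be invalid — instead each member ion gets
#' its own Welch test (each non-reference group vs the reference), with
#' Benjamini-Hochberg correction across the members of the class.
#'
#' @param fc fold-change matrix from [log2_fold_changes()].
#' @param ion_groups named list: class name -> member ion ids.
#' @param cohort cohort data.frame.
#' @param reference reference diet group for the member tests.
#' @return list with \code{box_stats} (class, diet, n, min, q1, median,
#'   q3, max) and \code{member_tests} (class, ion, comparison, t, df, p,
#'   q).
#' @export
pooled_class_comparison <- function(fc, ion_groups, cohort,
                                    reference = "OMN") {
  unknown <- setdiff(unlist(ion_groups), rownames(fc))
  if (length(unknown)) {
    stop_input("unknown ion in class definition: %s", unknown[1])
  }
  box <- list(); tests <- list()
  for (cls in names(ion_groups)) {
    memb <- ion_groups[[cls]]
    for (g in levels(factor(cohort$diet))) {
      ids <- cohort$id[cohort$diet == g]
      if (!length(ids)) next
      v <- as.numeric(fc[memb, ids, drop = FALSE])
      qs <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      box[[length(box) + 1L]] <- data.frame(
        class = cls, diet = g, n = length(v), min = qs[1], q1 = qs[2],
        median = qs[3], q3 = qs[4], max = qs[5], stringsAsFactors = FALSE)
    }
    ref_ids <- cohort$id[cohort$diet == reference]
    others <- setdiff(unique(as.character(cohort$diet)), reference)
    for (g in others) {
      ids <- cohort$id[cohort$diet == g]
      res <- lapply(memb, function(ion) {
        wt <- welch_t(fc[ion, ids], fc[ion, ref_ids])
        data.frame(class = cls, ion = ion,
                   comparison = paste0(g, "-", reference),
                   t = wt$t, df = wt$df, p = wt$p,
                   stringsAsFactors = FALSE)
      })
      res <- do.call(rbind, res)
      res$q <- bh_adjust(res$p)
      tests[[length(tests) + 1L]] <- res
    }
  }
  list(box_stats = do.call(rbind, box),
       member_tests = do.call(rbind, tests))
}
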