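# Hierarchical clustering of participants on the untargeted metabolome:
# log10 + autoscaling, agglomerative Ward linkage, a fixed-k cut, and
# diet-group composition summaries of the resulting clusters.

#' Standardize a metabolite matrix for clustering
#'
#' log10 transform, then per-ion centering and unit-variance scaling
#' (autoscaling), so that abundant ions do not dominate the distances.
#' Constant ions are dropped with a warning.
#'
#' @param matrix a \code{metabolite_matrix} (strictly positive).
#' @return numeric matrix, participants x ions, each retained column with
#'   mean 0 and SD 1.
#' @export
preprocess_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  if (ncol(matrix$intensities) < 2) stop_input("need >= 2 participants")
  if (any(matrix$intensities <= 0)) {
    stop_input("nonpositive intensities: apply handle_zeros() first")
  }
  x <- t(log10(matrix$intensities))   # participants x ions
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant ion(s)", sum(sds == 0)))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  scale(x, center = TRUE, scale = sds)
}

#' Agglomerative Ward clustering of participants
#'
#' Ward's minimum-variance criterion via the Lance-Williams recurrence.
#' The default convention (\code{distance = "squared_euclidean"}) applies
#' the recurrence to squared Euclidean distances — the classic Ward
#' objective, where each merge minimizes the increase in within-cluster
#' sum of squares. \code{distance = "euclidean"} instead feeds unsquared
#' distances to the same recurrence, a variant some software labels
#' "Ward on Euclidean distance"; the convention used is recorded on the
#' result.
#'
#' @param standardized participants x features matrix (e.g. from
#'   [preprocess_matrix()]).
#' @param distance "squared_euclidean" (classic Ward, default) or
#'   "euclidean".
#' @return an [stats::hclust] tree with attribute \code{distance}.
#' @export
ward_cluster <- function(standardized,
                         distance = c("squared_euclidean", "euclidean")) {
  distance <- match.arg(distance)
  if (nrow(standardized) < 2) stop_input("need >= 2 participants")
  if (any(!is.finite(standardized))) stop_input("non-finite values in input")
  d <- stats::dist(standardized)
  hc <- if (distance == "squared_euclidean") {
    stats::hclust(d^2, method = "ward.D")
  } else {
    stats::hclust(d, method = "ward.D")
  }
  attr(hc, "distance") <- distance
  hc
}

#' Cut a dendrogram into k clusters
#'
#' Cuts at the height yielding exactly \code{k} clusters and relabels the
#' clusters A, B, C, ... in order of first appearance along the
#' participant order.
#'
#' @param linkage an [stats::hclust] tree.
#' @param k number of clusters (1 <= k <= n).
#' @return a \code{cluster_assignment}: data.frame \code{id, cluster}
#'   with attributes \code{k} and \code{heights} (the merge heights).
#' @export
cut_clusters <- function(linkage, k = 4) {
  n <- length(linkage$labels %||% linkage$order)
  if (k < 1 || k > n) stop_input("k must be in [1, %d]", n)
  raw <- stats::cutree(linkage, k = k)
  first <- !duplicated(raw)
  relabel <- stats::setNames(LETTERS[seq_len(k)], raw[first])
  out <- data.frame(id = names(raw) %||% as.character(seq_along(raw)),
                    cluster = unname(relabel[as.character(raw)]),
                    stringsAsFactors = FALSE)
  structure(out, k = k, heights = linkage$height,
            class = c("cluster_assignment", "data.frame"))
}

#' Diet-group composition of clusters
#'
#' @param assignment a \code{cluster_assignment}.
#' @param cohort cohort data.frame covering all assigned participants.
#' @return list with \code{clusters} (per cluster: size, count and
#'   fraction of each diet group) and \code{groups} (per diet group: its
#'   modal cluster and the fraction of members there).
#' @export
cluster_composition <- function(assignment, cohort) {
  m <- match(assignment$id, cohort$id)
  if (any(is.na(m))) {
    stop_input("unknown participant '%s' in assignment",
               assignment$id[which(is.na(m))[1]])
  }
  diet <- as.character(cohort$diet[m])
  tab <- table(cluster = assignment$cluster, diet = diet)
  clusters <- do.call(rbind, lapply(rownames(tab), function(cl) {
    sz <- sum(tab[cl, ])
    data.frame(cluster = cl, size = sz,
               diet = colnames(tab),
               count = as.integer(tab[cl, ]),
               fraction = as.numeric(tab[cl, ]) / sz,
               stringsAsFactors = FALSE)
  }))
  groups <- do.call(rbind, lapply(colnames(tab), function(g) {
    cnt <- tab[, g]
    modal <- rownames(tab)[which.max(cnt)]
    data.frame(diet = g, modal_cluster = modal,
               modal_fraction = max(cnt) / sum(cnt),
               n = as.integer(sum(cnt)), stringsAsFactors = FALSE)
  }))
  list(clusters = clusters, groups = groups)
}

#' Export a dendrogram as a newick tree
#' @param linkage an [stats::hclust] tree.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_dendrogram <- function(linkage, path) {
  ape::write.tree(ape::as.phylo(linkage), file = path)
  invisible(path)
}
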