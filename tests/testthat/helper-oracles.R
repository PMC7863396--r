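# Independent brute-force oracles used across the suite. These stay
# deliberately naive (pairwise enumeration, O(m^2) definitions,
# step-by-step walks, exhaustive merge search) so that they check the
# implementation rather than share code with it.

# probability index by literal pairwise enumeration
pi_brute <- function(x, y) {
  gt <- 0; eq <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) gt <- gt + 1 else if (xi == yj) eq <- eq + 1
  }
  (gt + 0.5 * eq) / (length(x) * length(y))
}

# Benjamini-Hochberg straight from the step-up definition
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in seq_len(m)) {
      if (p[o[j]] >= p[o[i]]) cand <- min(cand, m * p[o[j]] / j)
    }
    q[o[i]] <- min(1, cand)
  }
  q
}

# Welch t from the textbook formulas
welch_brute <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# GSEA running sum, one explicit step at a time
es_brute <- function(ids, scores, set, weight_p) {
  n <- length(ids)
  hits <- ids %in% set
  nm <- sum(hits)
  denom <- sum(abs(scores[hits])^weight_p)
  run <- numeric(n); cur <- 0
  for (i in seq_len(n)) {
    if (hits[i]) {
      cur <- cur + if (denom > 0) abs(scores[i])^weight_p / denom else 1 / nm
    } else {
      cur <- cur - 1 / (n - nm)
    }
    run[i] <- cur
  }
  # signed maximal deviation, positive extreme wins exact ties
  if (max(run) >= -min(run) - 1e-12) max(run) else min(run)
}

# exhaustive greedy Ward: at each step merge the pair with the smallest
# increase in within-cluster sum of squares (ties: smallest pair index)
ward_brute <- function(X) {
  n <- nrow(X)
  members <- as.list(seq_len(n))
  active <- seq_len(n)
  merges <- list(); heights <- numeric(0)
  while (length(active) > 1) {
    best <- NULL; bestd <- Inf
    for (a in seq_along(active)) for (b in seq_len(a - 1)) {
      i <- active[b]; j <- active[a]
      ci <- colMeans(X[members[[i]], , drop = FALSE])
      cj <- colMeans(X[members[[j]], , drop = FALSE])
      ni <- length(members[[i]]); nj <- length(members[[j]])
      d <- ni * nj / (ni + nj) * sum((ci - cj)^2)
      if (d < bestd - 1e-12) { bestd <- d; best <- c(i, j) }
    }
    members[[best[1]]] <- c(members[[best[1]]], members[[best[2]]])
    active <- setdiff(active, best[2])
    merges[[length(merges) + 1]] <- sort(members[[best[1]]])
    heights <- c(heights, bestd)
  }
  list(merges = merges, heights = heights)
}

# the sequence of merged index sets implied by an hclust tree
hclust_partitions <- function(hc) {
  out <- list()
  for (k in seq_len(nrow(hc$merge))) {
    m <- hc$merge[k, ]
    get <- function(v) if (v < 0) -v else out[[v]]
    out[[k]] <- sort(c(get(m[1]), get(m[2])))
  }
  out
}

# brute-force accurate-mass matcher over every (ion, compound) pair
annotate_brute <- function(mz, compounds, tol) {
  theo <- compounds$monoisotopic_mass - 1.007276
  lapply(mz, function(m) {
    d <- theo - m
    keep <- which(abs(d) <= tol)
    o <- order(abs(d[keep]), compounds$compound_id[keep])
    compounds$compound_id[keep][o]
  })
}

# adjusted Rand index for partition-equivalence checks
rand_adjusted <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sn <- choose(sum(tab), 2)
  exp_ <- si * sj / sn
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# small deterministic cohort for unit tests
tiny_cohort <- function(sizes = c(OMN = 6, VGTR = 3, VGN = 3), seed = 99) {
  cfg <- sim_config(group_sizes = sizes, n_ions = 40,
                    pathway_spec = default_pathway_spec(40, 2, 10),
                    effect_table = data.frame(pathway = "pathway_01",
                                              log2_shift = 1,
                                              attenuation = 0.5),
                    seed = seed)
  list(config = cfg, cohort = simulate_cohort(cfg))
}
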