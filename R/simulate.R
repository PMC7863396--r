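#' Simulate a diet-group cohort
#'
#' Draws participant ids, diet-group labels, ages (i.i.d. uniform on the
#' configured range), sex (i.i.d. Bernoulli), and anthropometrics (height,
#' weight, mid-upper arm circumference generated from smooth age trends
#' with individual noise). Reproducible: the cohort substream of the
#' master seed is used, so adding later simulation stages never changes
#' the cohort.
#'
#' @param config a [sim_config()].
#' @return a data.frame of class \code{c("cohort","data.frame")} with
#'   columns \code{id, diet, age_years, sex, height_cm, weight_kg, muac_cm}.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(seed = 1))
#' table(coh$diet)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "cohort"))
  sizes <- config$group_sizes
  n <- sum(sizes)
  diet <- factor(rep(names(sizes), sizes), levels = DIET_LEVELS)
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- ifelse(stats::runif(n) < config$sex_balance, "F", "M")
  # smooth pediatric growth trends + individual variation; synthetic, not
  # a published reference
  height <- 70 + 7.5 * age - 0.15 * age^2 + stats::rnorm(n, 0, 4)
  weight <- 2.2 + 0.24 * height - 0.01 * age + stats::rnorm(n, 0, 1.2)
  weight <- pmax(weight, 6)
  muac <- 14.2 + 0.28 * age + stats::rnorm(n, 0, 0.9)
  out <- data.frame(
    id = sprintf("P%03d", seq_len(n)),
    diet = diet,
    age_years = age,
    sex = sex,
    height_cm = height,
    weight_kg = weight,
    muac_cm = muac,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cohort", "data.frame")
  out
}

#' Simulate an untargeted metabolome intensity matrix
#'
#' Log10 intensities are multivariate normal: a per-ion baseline mean,
#' exchangeable within-pathway correlation (a shared participant-level
#' pathway factor), an additive vegan group shift specified on the log2
#' scale (converted to log10), the vegetarian shift equal to the vegan
#' shift times the attenuation factor, and an optional age-confounding
#' slope. Intensities are returned on the linear scale (strictly
#' positive).
#'
#' @param cohort a cohort from [simulate_cohort()].
#' @param config a [sim_config()].
#' @param compounds optional compound database (see [read_compound_db()]);
#'   when supplied, the first ions take their m/z from database compounds
#'   (with sub-tolerance jitter), the rest are synthetic.
#' @return a \code{metabolite_matrix}: list with \code{intensities}
#'   (ions x participants), \code{ions} (data.frame \code{ion_id, mz,
#'   annotation}), and \code{pathways}.
#' @export
simulate_metabolome <- function(cohort, config, compounds = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!nrow(cohort)) stop_input("cohort is empty")
  set.seed(substream_seed(config$seed, "metabolome"))
  n_ions <- config$n_ions
  n <- nrow(cohort)
  ids <- ion_ids(n_ions)
  rho <- config$block_correlation
  sdl <- config$log10_sd
  log2_to_log10 <- log10(2)

  baseline <- stats::runif(n_ions, config$baseline_range[1],
                           config$baseline_range[2])
  # per-ion group shift on the log10 scale
  shift <- matrix(0, n_ions, 3, dimnames = list(ids, DIET_LEVELS))
  if (nrow(config$effect_table)) {
    for (r in seq_len(nrow(config$effect_table))) {
      memb <- config$pathway_spec[[config$effect_table$pathway[r]]]
      s10 <- config$effect_table$log2_shift[r] * log2_to_log10
      shift[memb, "VGN"] <- shift[memb, "VGN"] + s10
      shift[memb, "VGTR"] <- shift[memb, "VGTR"] +
        s10 * config$effect_table$attenuation[r]
    }
  }

  # exchangeable block correlation: z_ij = sqrt(rho) u_j + sqrt(1-rho) e_ij
  z <- matrix(stats::rnorm(n_ions * n), n_ions, n) * sqrt(1 - rho)
  rownames(z) <- ids
  for (p in names(config$pathway_spec)) {
    memb <- config$pathway_spec[[p]]
    if (length(memb) < 2) next
    u <- stats::rnorm(n)
    z[memb, ] <- z[memb, ] + rep(sqrt(rho) * u, each = length(memb))
  }
  # unassigned ions: no shared factor, restore unit variance
  assigned <- unique(unlist(config$pathway_spec))
  lone <- setdiff(ids, assigned)
  if (length(lone)) {
    z[lone, ] <- z[lone, ] / sqrt(1 - rho)
  }

  logI <- baseline + shift[, as.character(cohort$diet)] + sdl * z +
    config$age_slope * rep(cohort$age_years, each = n_ions)
  intens <- 10^logI
  dimnames(intens) <- list(ids, cohort$id)

  if (!is.null(compounds)) {
    theo <- compound_mz(compounds)
    k <- min(length(theo), n_ions)
    mz <- stats::runif(n_ions, 80, 1000)
    mz[seq_len(k)] <- theo[seq_len(k)] + stats::rnorm(k, 0, 2e-4)
  } else {
    mz <- stats::runif(n_ions, 80, 1000)
  }

  metabolite_matrix(
    intensities = intens,
    ions = data.frame(ion_id = ids, mz = mz, annotation = "",
                      stringsAsFactors = FALSE),
    pathways = config$pathway_spec
  )
}

#' Simulate the biomarker panel of a cohort
#'
#' Per-analyte Gaussian (or log-normal) draws with group-specific means;
#' draws above a configured detection limit are stored at the limit with
#' \code{censored = TRUE} (right-censoring, as for a transcobalamin-bound
#' B12 assay that measures only up to its linear limit).
#'
#' @param cohort a cohort from [simulate_cohort()].
#' @param config a [sim_config()] with a nonempty \code{biomarker_spec}.
#' @return a long data.frame \code{id, analyte, value, unit, censored}.
#' @export
simulate_biomarkers <- function(cohort, config) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$biomarker_spec
  if (!nrow(spec)) stop_input("biomarker_spec is empty")
  if (any(spec$sd < 0)) stop_input("negative SD in biomarker_spec")
  set.seed(substream_seed(config$seed, "biomarkers"))
  n <- nrow(cohort)
  out <- vector("list", nrow(spec))
  for (i in seq_len(nrow(spec))) {
    mu <- c(OMN = spec$mean_OMN[i], VGTR = spec$mean_VGTR[i],
            VGN = spec$mean_VGN[i])[as.character(cohort$diet)]
    raw <- stats::rnorm(n, mu, spec$sd[i])
    if (identical(spec$dist[i], "lognormal")) raw <- exp(raw)
    lim <- spec$censor_limit[i]
    cens <- is.finite(lim) & raw > lim
    raw[cens] <- lim
    out[[i]] <- data.frame(
      id = cohort$id, analyte = spec$analyte[i], value = raw,
      unit = spec$unit[i], censored = cens, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Construct a metabolite matrix container
#'
#' @param intensities numeric matrix, ions x participants, row names =
#'   ion ids, column names = participant ids; strictly positive.
#' @param ions data.frame with \code{ion_id}, \code{mz}, \code{annotation}.
#' @param pathways optional named list pathway -> ion ids.
#' @param annotations optional named list ion -> candidate data.frame.
#' @return an object of class \code{metabolite_matrix}.
#' @export
metabolite_matrix <- function(intensities, ions, pathways = NULL,
                              annotations = NULL) {
  stopifnot(is.matrix(intensities), nrow(intensities) == nrow(ions))
  if (any(ions$mz <= 0)) stop_input("m/z values must be positive")
  structure(
    list(intensities = intensities, ions = ions, pathways = pathways,
         annotations = annotations),
    class = "metabolite_matrix"
  )
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat("metabolite_matrix:", nrow(x$intensities), "ions x",
      ncol(x$intensities), "participants;",
      sum(nzchar(x$ions$annotation)), "annotated\n")
  invisible(x)
}
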