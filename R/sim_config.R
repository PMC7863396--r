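#' Default biomarker specification for the synthetic cohort
#'
#' Group-level means and standard deviations for the biomarker panel of a
#' small omnivore/vegetarian/vegan cohort. Values are synthetic but chosen
#' so that the generated panel reproduces the qualitative pattern of
#' published pediatric diet-group comparisons: vegan retinol-binding
#' protein (RBP) centred below the 1.17 umol/l insufficiency cut-off,
#' vegan total 25(OH)D around 60 nmol/l (sd 3.5, i.e. roughly 53-67),
#' vegan erythrocyte folate mostly above the 972 nmol/l upper reference
#' limit, and transcobalamin-bound B12 right-censored at the 128 pmol/l
#' assay limit with about two thirds of vegans censored.
#'
#' @return a data.frame with one row per analyte: \code{analyte},
#'   \code{unit}, \code{dist} ("normal" or "lognormal" — for lognormal the
#'   mean/sd columns are on the log scale), per-group means
#'   \code{mean_OMN}, \code{mean_VGTR}, \code{mean_VGN}, common \code{sd},
#'   and \code{censor_limit} (upper detection limit; \code{Inf} = none).
#' @export
default_biomarker_spec <- function() {
  data.frame(
    analyte = c("rbp", "transthyretin", "crp", "vitd_total",
                "folate_rbc", "b12", "zinc", "ferritin"),
    unit = c("umol/l", "umol/l", "mg/l", "nmol/l",
             "nmol/l", "pmol/l", "umol/l", "ug/l"),
    dist = c("normal", "normal", "lognormal", "normal",
             "normal", "normal", "normal", "lognormal"),
    mean_OMN  = c(1.45, 4.60, 0.0, 80, 600, 160, 13.0, 3.3),
    mean_VGTR = c(1.30, 4.30, 0.0, 70, 800, 155, 11.8, 3.2),
    mean_VGN  = c(0.95, 3.80, 0.0, 60, 1050, 140, 13.0, 3.2),
    sd = c(0.12, 0.40, 0.8, 3.5, 150, 25, 1.3, 0.5),
    censor_limit = c(Inf, Inf, Inf, Inf, Inf, 128, Inf, Inf),
    stringsAsFactors = FALSE
  )
}

#' Default pathway structure for the synthetic metabolome
#'
#' Assigns the first ions to equally sized pathway blocks; remaining ions
#' stay unassigned (background). Ion ids are zero-padded so that ordering
#' by id is stable.
#'
#' @param n_ions total number of ions.
#' @param n_pathways number of pathway blocks.
#' @param pathway_size ions per block.
#' @return named list: pathway name -> character vector of ion ids.
#' @export
default_pathway_spec <- function(n_ions = 872, n_pathways = 20,
                                 pathway_size = 20) {
  if (n_pathways * pathway_size > n_ions) {
    stop_input("pathways need %d ions but n_ions = %d",
               n_pathways * pathway_size, n_ions)
  }
  ids <- ion_ids(n_ions)
  stats::setNames(
    lapply(seq_len(n_pathways), function(p) {
      ids[((p - 1) * pathway_size + 1):(p * pathway_size)]
    }),
    sprintf("pathway_%02d", seq_len(n_pathways))
  )
}

ion_ids <- function(n) sprintf("ion_%04d", seq_len(n))

#' Build and validate a simulation configuration
#'
#' The configuration fixes the study conditions the generator emulates:
#' three diet groups of sizes 24/10/6, ages uniform on 1.42-7.07 years,
#' balanced sex, an 872-ion log-normal metabolome with within-pathway
#' exchangeable correlation, vegan effect sizes on the log2 scale with the
#' vegetarian effect attenuated towards the omnivore baseline, optional
#' age confounding, and a biomarker panel with group-level means and
#' right-censoring at a detection limit.
#'
#' @param group_sizes named integer vector: participants per diet group,
#'   names from \code{c("OMN","VGTR","VGN")}.
#' @param age_range numeric length 2, years (min < max).
#' @param sex_balance probability that a participant is female.
#' @param n_ions number of metabolite ions.
#' @param pathway_spec named list pathway -> ion ids.
#' @param effect_table data.frame with columns \code{pathway},
#'   \code{log2_shift} (vegan minus omnivore shift on the log2 scale) and
#'   \code{attenuation} (vegetarian shift = vegan shift x attenuation,
#'   in [0,1]).
#' @param block_correlation within-pathway exchangeable correlation of the
#'   log10 intensities, in [0, 1).
#' @param age_slope additive confounding slope on the log10-intensity
#'   scale, per year of age (0 = none).
#' @param log10_sd within-group standard deviation of log10 intensities.
#' @param baseline_range range of per-ion baseline log10 intensities.
#' @param biomarker_spec see [default_biomarker_spec()].
#' @param seed master seed, split into named substreams per stage.
#' @return an object of class \code{sim_config}.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$group_sizes
sim_config <- function(group_sizes = c(OMN = 24L, VGTR = 10L, VGN = 6L),
                       age_range = c(1.42, 7.07),
                       sex_balance = 0.5,
                       n_ions = 872L,
                       pathway_spec = default_pathway_spec(n_ions),
                       effect_table = data.frame(
                         pathway = c("pathway_01", "pathway_02"),
                         log2_shift = c(1, -1),
                         attenuation = c(0.5, 0.5)
                       ),
                       block_correlation = 0.3,
                       age_slope = 0,
                       log10_sd = 0.15,
                       baseline_range = c(4, 6),
                       biomarker_spec = default_biomarker_spec(),
                       seed = 1L) {
  if (is.null(names(group_sizes))) names(group_sizes) <- DIET_LEVELS
  if (!setequal(names(group_sizes), DIET_LEVELS)) {
    stop_input("invalid configuration field 'group_sizes': names must be %s",
               paste(DIET_LEVELS, collapse = ", "))
  }
  group_sizes <- group_sizes[DIET_LEVELS]
  if (any(group_sizes < 1)) {
    stop_input("invalid configuration field 'group_sizes': all sizes must be >= 1")
  }
  if (length(age_range) != 2L || !(age_range[1] < age_range[2])) {
    stop_input("invalid configuration field 'age_range': need min < max")
  }
  check_scalar(sex_balance, "sex_balance", 0, 1)
  check_scalar(n_ions, "n_ions", 1)
  check_scalar(block_correlation, "block_correlation", 0, 1 - 1e-12)
  check_scalar(age_slope, "age_slope")
  check_scalar(log10_sd, "log10_sd", 0)
  check_scalar(seed, "seed")
  if (!is.list(pathway_spec) || is.null(names(pathway_spec))) {
    stop_input("invalid configuration field 'pathway_spec': need a named list")
  }
  all_ids <- ion_ids(n_ions)
  for (p in names(pathway_spec)) {
    bad <- setdiff(pathway_spec[[p]], all_ids)
    if (length(bad)) {
      stop_input("invalid configuration field 'pathway_spec': pathway '%s' references unknown ions (%s)",
                 p, paste(utils::head(bad, 3), collapse = ", "))
    }
  }
  if (nrow(effect_table)) {
    need <- c("pathway", "log2_shift", "attenuation")
    if (!all(need %in% names(effect_table))) {
      stop_input("invalid configuration field 'effect_table': need columns %s",
                 paste(need, collapse = ", "))
    }
    unknown <- setdiff(effect_table$pathway, names(pathway_spec))
    if (length(unknown)) {
      stop_input("invalid configuration field 'effect_table': unknown pathway '%s'",
                 unknown[1])
    }
    if (any(effect_table$attenuation < 0 | effect_table$attenuation > 1)) {
      stop_input("invalid configuration field 'effect_table': attenuation must be in [0, 1]")
    }
  }
  if (nrow(biomarker_spec)) {
    need <- c("analyte", "unit", "dist", "mean_OMN", "mean_VGTR", "mean_VGN",
              "sd", "censor_limit")
    if (!all(need %in% names(biomarker_spec))) {
      stop_input("invalid configuration field 'biomarker_spec': need columns %s",
                 paste(need, collapse = ", "))
    }
    if (any(biomarker_spec$sd < 0)) {
      stop_input("invalid configuration field 'biomarker_spec': negative SD")
    }
  }
  structure(
    list(group_sizes = group_sizes, age_range = age_range,
         sex_balance = sex_balance, n_ions = as.integer(n_ions),
         pathway_spec = pathway_spec, effect_table = effect_table,
         block_correlation = block_correlation, age_slope = age_slope,
         log10_sd = log10_sd, baseline_range = baseline_range,
         biomarker_spec = biomarker_spec, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", sum(x$group_sizes), "participants (",
      paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
            collapse = ", "),
      "),", x$n_ions, "ions,", length(x$pathway_spec), "pathways, seed",
      x$seed, "\n")
  invisible(x)
}
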