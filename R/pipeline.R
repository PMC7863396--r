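# End-to-end orchestration: simulate -> zscore -> test -> annotate ->
# foldchange -> enrich -> cluster -> status, one config, one seed, all
# artifacts written with provenance headers and listed in a manifest.
# Every stochastic step draws from a named substream of the master seed,
# so a re-run with the same config and seed is bit-identical.

#' Build a pipeline run configuration
#'
#' @param out_dir run directory (created by [run_pipeline()]).
#' @param seed master seed for the whole run.
#' @param sim a [sim_config()]; defaults to the standard synthetic study
#'   conditions with the given seed.
#' @param stages character vector of stages to execute, in dependency
#'   order; any subset of the default.
#' @param n_perm permutations for the biomarker/anthropometry
#'   probability-index tests.
#' @param enrich_n_perm permutations for the metabolite-set enrichment.
#' @param k clusters for the dendrogram cut.
#' @param primary,secondary group comparisons, each "A-B".
#' @param rules_file YAML cut-off rule file (default: packaged rules).
#' @param lms_file LMS reference CSV (default: packaged synthetic table).
#' @param compounds_file compound mass database CSV (default: packaged
#'   synthetic database).
#' @return object of class \code{run_config}.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            sim = sim_config(seed = seed),
                            stages = c("simulate", "zscore", "test",
                                       "annotate", "foldchange", "enrich",
                                       "cluster", "status"),
                            n_perm = 47500L,
                            enrich_n_perm = 999L,
                            k = 4L,
                            primary = "VGN-OMN",
                            secondary = c("VGTR-OMN", "VGTR-VGN"),
                            rules_file = system.file(
                              "extdata", "status_rules.yaml",
                              package = "dietmetab"),
                            lms_file = system.file(
                              "extdata", "lms_synthetic.csv",
                              package = "dietmetab"),
                            compounds_file = system.file(
                              "extdata", "compounds_synthetic.csv",
                              package = "dietmetab")) {
  known <- c("simulate", "zscore", "test", "annotate", "foldchange",
             "enrich", "cluster", "status")
  bad <- setdiff(stages, known)
  if (length(bad)) stop_input("unknown stage '%s'", bad[1])
  comps <- c(primary, secondary)
  for (cp in comps) {
    gg <- strsplit(cp, "-", fixed = TRUE)[[1]]
    if (length(gg) != 2 || !all(gg %in% DIET_LEVELS)) {
      stop_input("comparison '%s' must be 'A-B' with labels from %s",
                 cp, paste(DIET_LEVELS, collapse = ", "))
    }
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
         stages = stages, n_perm = as.integer(n_perm),
         enrich_n_perm = as.integer(enrich_n_perm), k = as.integer(k),
         primary = primary, secondary = secondary,
         rules_file = rules_file, lms_file = lms_file,
         compounds_file = compounds_file),
    class = "run_config"
  )
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # strip the output path so the hash identifies the analysis, not where
  # it was written
  cfg <- config
  cfg$out_dir <- NULL
  cfg$rules_file <- basename(cfg$rules_file)
  cfg$lms_file <- basename(cfg$lms_file)
  cfg$compounds_file <- basename(cfg$compounds_file)
  saveRDS(cfg, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

# CSV with a machine-parseable provenance header block
write_result_csv <- function(df, path, config, extra = character(0)) {
  hdr <- c(
    sprintf("# dietmetab %s",
            as.character(utils::packageVersion("dietmetab"))),
    sprintf("# seed: %d", config$seed),
    sprintf("# config_hash: %s", config_hash(config)),
    sprintf("# %s", extra)[length(extra) > 0]
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

log_line <- function(log_path, ...) {
  msg <- sprintf(...)
  message(msg)
  cat(msg, "\n", file = log_path, append = TRUE, sep = "")
}

#' Run the full diet-group analysis pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic cohort
#' generated from the configured study conditions, writing every artifact
#' to the run directory with a provenance header (tool version, seed,
#' config hash) and a machine-readable \code{manifest.json}. Re-running
#' with the same config and seed reproduces all outputs bit-for-bit.
#' Benjamini-Hochberg correction is applied within each reported panel
#' (anthropometric z-scores; the biomarker panel; the enrichment set
#' collection), never globally across panels.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest (list with \code{files} and per-file
#'   md5 checksums).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  cat("", file = logf)
  files <- character(0)
  add <- function(path) files <<- c(files, path)
  stage_on <- function(s) s %in% config$stages

  run_stage <- function(name, fun) {
    log_line(logf, "[%s] start", name)
    tryCatch(fun(), error = function(e) {
      stop_input("stage '%s' failed: %s", name, conditionMessage(e))
    })
    log_line(logf, "[%s] done", name)
  }

  cohort <- NULL; biomarkers <- NULL; matrix <- NULL

  if (stage_on("simulate")) run_stage("simulate", function() {
    cohort <<- simulate_cohort(config$sim)
    biomarkers <<- simulate_biomarkers(cohort, config$sim)
    compounds <- read_compound_db(config$compounds_file)
    matrix <<- simulate_metabolome(cohort, config$sim,
                                   compounds = compounds)
    p <- write_fixture(cohort, biomarkers, matrix, config$out_dir)
    for (f in p) add(f)
  })

  if (stage_on("zscore")) run_stage("zscore", function() {
    lms <- read_lms(config$lms_file)
    cohort <<- cohort_zscores(cohort, lms)
    z <- cohort[, c("id", "diet", "age_years", "sex", "bmi",
                    "z_height", "z_bmi", "z_muac")]
    f <- file.path(config$out_dir, "zscores.csv")
    write_result_csv(z, f, config)
    add(f)
  })

  if (stage_on("test")) run_stage("test", function() {
    comps <- c(config$primary, config$secondary)
    panels <- list()
    if (!is.null(cohort$z_height)) {
      panels$anthropometry <- cohort[, c("z_height", "z_bmi", "z_muac")]
    }
    rules <- yaml::read_yaml(config$rules_file)
    res <- list()
    for (cp in comps) {
      gg <- strsplit(cp, "-", fixed = TRUE)[[1]]
      keep <- cohort$diet %in% gg
      # anthropometry panel
      for (panel in names(panels)) {
        for (outc in names(panels[[panel]])) {
          v <- panels[[panel]][[outc]][keep]
          tst <- perm_test(
            v, as.character(cohort$diet[keep]),
            age = cohort$age_years[keep], sex = cohort$sex[keep],
            n_perm = config$n_perm,
            seed = substream_seed(config$seed,
                                  paste0("test/", panel, "/", outc, "/", cp)),
            adjust = TRUE)
          res[[length(res) + 1L]] <- data.frame(
            panel = panel, outcome = outc, comparison = cp,
            pi = tst$statistic, p_raw = tst$p_raw, q = NA_real_,
            n_perm = tst$n_perm, mode = tst$mode,
            n1 = tst$n1, n2 = tst$n2, stringsAsFactors = FALSE)
        }
      }
      # biomarker panel: censored analytes are excluded from PI testing
      # (a point mass at the assay limit would dominate the statistic)
      for (an in unique(biomarkers$analyte)) {
        sub <- biomarkers[biomarkers$analyte == an, ]
        if (any(sub$censored)) next
        m <- match(cohort$id[keep], sub$id)
        v <- sub$value[m]
        tst <- perm_test(
          v, as.character(cohort$diet[keep]),
          age = cohort$age_years[keep], sex = cohort$sex[keep],
          n_perm = config$n_perm,
          seed = substream_seed(config$seed,
                                paste0("test/biomarkers/", an, "/", cp)),
          adjust = TRUE)
        res[[length(res) + 1L]] <- data.frame(
          panel = "biomarkers", outcome = an, comparison = cp,
          pi = tst$statistic, p_raw = tst$p_raw, q = NA_real_,
          n_perm = tst$n_perm, mode = tst$mode,
          n1 = tst$n1, n2 = tst$n2, stringsAsFactors = FALSE)
      }
    }
    res <- do.call(rbind, res)
    # BH within each panel (the family that is reported together)
    for (panel in unique(res$panel)) {
      sel <- res$panel == panel
      res$q[sel] <- bh_adjust(res$p_raw[sel])
    }
    f <- file.path(config$out_dir, "tests.csv")
    write_result_csv(res, f, config)
    add(f)
  })

  if (stage_on("annotate")) run_stage("annotate", function() {
    compounds <- read_compound_db(config$compounds_file)
    matrix <<- annotate_peaks(matrix, compounds, tol = 0.001)
    f <- file.path(config$out_dir, "ions_annotated.csv")
    write_result_csv(matrix$ions, f, config)
    add(f)
  })

  fc <- NULL
  if (stage_on("foldchange")) run_stage("foldchange", function() {
    fc <<- log2_fold_changes(handle_zeros(matrix), cohort,
                             reference = "OMN")
    tab <- data.frame(ion_id = rownames(fc), round(fc, 6),
                      check.names = FALSE, stringsAsFactors = FALSE)
    f <- file.path(config$out_dir, "foldchanges.tsv")
    utils::write.table(tab, f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    add(f)
  })

  if (stage_on("enrich")) run_stage("enrich", function() {
    gg <- strsplit(config$primary, "-", fixed = TRUE)[[1]]
    enr <- pathway_permutation_test(
      matrix, cohort, config$sim$pathway_spec,
      group_a = gg[1], group_b = gg[2],
      n_perm = config$enrich_n_perm,
      seed = substream_seed(config$seed, "enrich"))
    f <- file.path(config$out_dir, "enrichment.csv")
    write_result_csv(enr, f, config)
    add(f)
  })

  if (stage_on("cluster")) run_stage("cluster", function() {
    std <- preprocess_matrix(handle_zeros(matrix))
    hc <- ward_cluster(std)
    asg <- cut_clusters(hc, k = config$k)
    comp <- cluster_composition(asg, cohort)
    f1 <- file.path(config$out_dir, "clusters.csv")
    write_result_csv(as.data.frame(asg), f1, config,
                     extra = sprintf("distance: %s", attr(hc, "distance")))
    f2 <- file.path(config$out_dir, "cluster_composition.csv")
    write_result_csv(comp$clusters, f2, config)
    f3 <- file.path(config$out_dir, "dendrogram.nwk")
    write_dendrogram(hc, f3)
    add(f1); add(f2); add(f3)
  })

  if (stage_on("status")) run_stage("status", function() {
    rules <- yaml::read_yaml(config$rules_file)
    calls <- status_calls(biomarkers, rules)
    f <- file.path(config$out_dir, "status.csv")
    write_result_csv(calls, f, config)
    add(f)
    # censored-fraction summary for detection-limited analytes
    cens <- list()
    for (an in names(rules)) {
      lim <- rules[[an]]$detection_limit
      if (is.null(lim)) next
      sub <- biomarkers[biomarkers$analyte == an, ]
      m <- match(sub$id, cohort$id)
      for (g in DIET_LEVELS) {
        sel <- cohort$diet[m] == g
        cens[[length(cens) + 1L]] <- data.frame(
          analyte = an, diet = g, n = sum(sel),
          censored_fraction = censored_fraction(
            sub$value[sel], sub$censored[sel], lim),
          limit = lim, stringsAsFactors = FALSE)
      }
    }
    if (length(cens)) {
      f2 <- file.path(config$out_dir, "censored_fractions.csv")
      write_result_csv(do.call(rbind, cens), f2, config)
      add(f2)
    }
  })

  manifest <- list(
    tool = "dietmetab",
    version = as.character(utils::packageVersion("dietmetab")),
    seed = config$seed,
    config_hash = config_hash(config),
    stages = config$stages,
    files = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_line(logf, "run complete: %d artifacts", length(files))
  invisible(manifest)
}

#' Summarize a pipeline run directory
#'
#' Joins, per tested outcome: the probability index, raw and adjusted
#' p-values, and the per-diet-group "median [minimum - maximum]" summary
#' of the underlying values, plus non-sufficient status counts per group
#' where a cut-off rule applies.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return a data.frame report, one row per outcome x comparison.
#' @export
summarize_run <- function(run_dir) {
  man_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(man_path)) stop_input("no manifest.json in '%s'", run_dir)
  manifest <- jsonlite::read_json(man_path)
  have <- vapply(manifest$files, function(f) f$file, "")
  need <- c("tests.csv", "cohort.csv")
  if (!all(need %in% have)) {
    stop_input("incomplete manifest: missing %s",
               paste(setdiff(need, have), collapse = ", "))
  }
  tests <- utils::read.csv(file.path(run_dir, "tests.csv"),
                           comment.char = "#", stringsAsFactors = FALSE)
  cohort <- read_cohort(file.path(run_dir, "cohort.csv"))
  biom <- if ("biomarkers.csv" %in% have) {
    read_biomarkers(file.path(run_dir, "biomarkers.csv"))
  }
  zsc <- if ("zscores.csv" %in% have) {
    utils::read.csv(file.path(run_dir, "zscores.csv"), comment.char = "#",
                    stringsAsFactors = FALSE)
  }
  status <- if ("status.csv" %in% have) {
    utils::read.csv(file.path(run_dir, "status.csv"), comment.char = "#",
                    stringsAsFactors = FALSE)
  }

  fmt <- function(v) sprintf("%.3g [%.3g - %.3g]", stats::median(v),
                             min(v), max(v))
  group_summary <- function(outcome, panel) {
    vals <- if (panel == "biomarkers" && !is.null(biom)) {
      sub <- biom[biom$analyte == outcome, ]
      stats::setNames(sub$value[match(cohort$id, sub$id)], cohort$id)
    } else if (!is.null(zsc) && outcome %in% names(zsc)) {
      stats::setNames(zsc[[outcome]][match(cohort$id, zsc$id)], cohort$id)
    }
    if (is.null(vals)) return(rep(NA_character_, length(DIET_LEVELS)))
    vapply(DIET_LEVELS, function(g) fmt(vals[cohort$diet == g]), "")
  }

  rows <- lapply(seq_len(nrow(tests)), function(i) {
    gs <- group_summary(tests$outcome[i], tests$panel[i])
    df <- data.frame(tests[i, c("panel", "outcome", "comparison",
                                "pi", "p_raw", "q")],
                     stringsAsFactors = FALSE)
    for (g in DIET_LEVELS) df[[paste0("summary_", g)]] <- gs[[g]]
    if (!is.null(status)) {
      st <- status[status$analyte == tests$outcome[i], ]
      for (g in DIET_LEVELS) {
        ids <- cohort$id[cohort$diet == g]
        df[[paste0("flagged_", g)]] <- if (nrow(st)) {
          sum(st$status[st$id %in% ids] %in%
                c("deficient", "insufficient", "below", "above"))
        } else NA_integer_
      }
    }
    df
  })
  do.call(rbind, rows)
}
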