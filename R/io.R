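# Plain-text I/O for all pipeline formats. Readers skip leading '#'
# comment lines so run outputs can carry provenance headers.

#' Write cohort, biomarker, and metabolome fixtures to disk
#'
#' Emits the standard file set: \code{cohort.csv}, \code{biomarkers.csv},
#' \code{matrix.tsv} (first column \code{ion_id}, one column per
#' participant), \code{ions.csv}, and \code{pathways.gmt}. All files
#' round-trip losslessly through the package readers.
#'
#' @param cohort cohort data.frame.
#' @param biomarkers long biomarker data.frame (may be \code{NULL}).
#' @param matrix a \code{metabolite_matrix} (may be \code{NULL}).
#' @param dir destination directory (created if absent).
#' @return invisibly, a named character vector of the written paths.
#' @export
write_fixture <- function(cohort, biomarkers = NULL, matrix = NULL,
                          dir = ".") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cohort = file.path(dir, "cohort.csv"))
  write_cohort(cohort, paths[["cohort"]])
  if (!is.null(biomarkers)) {
    paths[["biomarkers"]] <- file.path(dir, "biomarkers.csv")
    write_biomarkers(biomarkers, paths[["biomarkers"]])
  }
  if (!is.null(matrix)) {
    paths[["matrix"]] <- file.path(dir, "matrix.tsv")
    paths[["ions"]] <- file.path(dir, "ions.csv")
    write_matrix(matrix, paths[["matrix"]], paths[["ions"]])
    if (!is.null(matrix$pathways)) {
      paths[["gmt"]] <- file.path(dir, "pathways.gmt")
      write_gmt(matrix$pathways, paths[["gmt"]])
    }
  }
  invisible(paths)
}

#' @rdname write_fixture
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a cohort CSV
#'
#' Expected columns: \code{id,diet,age_years,sex,height_cm,weight_kg,muac_cm}.
#' @param path file path.
#' @return a cohort data.frame.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("id", "diet", "age_years", "sex")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop_input("cohort file lacks columns: %s",
                               paste(miss, collapse = ", "))
  if (anyDuplicated(x$id)) stop_input("duplicate participant ids")
  x$diet <- factor(x$diet, levels = DIET_LEVELS)
  class(x) <- c("cohort", "data.frame")
  x
}

#' @rdname write_fixture
#' @export
write_biomarkers <- function(biomarkers, path) {
  utils::write.csv(biomarkers, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format biomarker CSV (\code{id,analyte,value,unit,censored})
#' @param path file path.
#' @return data.frame.
#' @export
read_biomarkers <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  x$censored <- as.logical(x$censored)
  x
}

#' @rdname write_fixture
#' @param ions_path path for the ion table CSV.
#' @export
write_matrix <- function(matrix, path, ions_path = NULL) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  tab <- data.frame(ion_id = rownames(matrix$intensities),
                    matrix$intensities, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(ions_path)) {
    utils::write.csv(matrix$ions, ions_path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' Read a metabolite intensity matrix (TSV) plus optional ion table (CSV)
#' @param path matrix TSV: first column \code{ion_id}, then one column per
#'   participant id.
#' @param ions_path optional ion table CSV (\code{ion_id,mz,annotation}).
#' @return a \code{metabolite_matrix}.
#' @export
read_matrix <- function(path, ions_path = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  if (!is.null(ions_path)) {
    ions <- utils::read.csv(ions_path, stringsAsFactors = FALSE,
                            comment.char = "#")
    if (!"annotation" %in% names(ions)) ions$annotation <- ""
    ions$annotation[is.na(ions$annotation)] <- ""
    ions <- ions[match(rownames(m), ions$ion_id), , drop = FALSE]
  } else {
    ions <- data.frame(ion_id = rownames(m), mz = NA_real_, annotation = "",
                       stringsAsFactors = FALSE)
  }
  metabolite_matrix(intensities = m, ions = ions)
}

#' Write metabolite sets in GMT format
#'
#' One line per set: \code{name <TAB> description <TAB> member ids...}.
#' @param sets named list: set name -> character vector of member ids.
#' @param path file path.
#' @param descriptions optional named character vector of descriptions.
#' @return invisibly, the path.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[nm] %||% "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT metabolite-set file
#' @param path file path.
#' @return named list: set name -> character vector of member ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop_input("malformed GMT line: '%s'",
                                  substr(ln, 1, 40))
    out[[f[1]]] <- unique(f[-(1:2)])
  }
  out
}

#' Read a compound mass database CSV
#'
#' Columns: \code{compound_id}, and \code{formula} and/or
#' \code{monoisotopic_mass} (Da), optional \code{name}. When both are
#' present the formula must parse to the stated mass within 1e-4 Da.
#' @param path file path.
#' @return validated data.frame with a \code{monoisotopic_mass} column.
#' @export
read_compound_db <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!"compound_id" %in% names(x)) stop_input("compound db lacks compound_id")
  if (!"monoisotopic_mass" %in% names(x)) x$monoisotopic_mass <- NA_real_
  if (!"formula" %in% names(x)) x$formula <- NA_character_
  need <- is.na(x$monoisotopic_mass)
  if (any(need & (is.na(x$formula) | !nzchar(x$formula)))) {
    stop_input("compound db: rows with neither formula nor mass")
  }
  x$monoisotopic_mass[need] <-
    vapply(x$formula[need], monoisotopic_mass, 0.0)
  both <- !need & !is.na(x$formula) & nzchar(x$formula)
  if (any(both)) {
    delta <- abs(vapply(x$formula[both], monoisotopic_mass, 0.0) -
                   x$monoisotopic_mass[both])
    if (any(delta > 1e-4)) {
      stop_input("compound db: formula/mass mismatch for %s",
                 x$compound_id[both][which.max(delta)])
    }
  }
  if (any(x$monoisotopic_mass <= 0)) stop_input("compound db: mass <= 0")
  x
}

# theoretical [M-H]- m/z for every compound in a db table
compound_mz <- function(compounds) {
  compounds$monoisotopic_mass - PROTON_MASS
}

#' Read an LMS growth-reference table CSV
#'
#' Columns: \code{measure,sex,age_years,L,M,S}. Within each (measure, sex)
#' the ages must be strictly increasing, M and S positive.
#' @param path file path.
#' @return an \code{lms_table} data.frame.
#' @export
read_lms <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  lms_table(x)
}

#' Validate an LMS table data.frame
#' @param x data.frame with columns \code{measure,sex,age_years,L,M,S}.
#' @return the validated table, class \code{c("lms_table","data.frame")}.
#' @export
lms_table <- function(x) {
  need <- c("measure", "sex", "age_years", "L", "M", "S")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop_input("LMS table lacks columns: %s",
                               paste(miss, collapse = ", "))
  if (any(x$M <= 0) || any(x$S <= 0)) stop_input("LMS table: M and S must be > 0")
  for (key in split(x, list(x$measure, x$sex), drop = TRUE)) {
    if (is.unsorted(key$age_years, strictly = TRUE)) {
      stop_input("LMS table: ages must be strictly increasing within (%s, %s)",
                 key$measure[1], key$sex[1])
    }
  }
  class(x) <- c("lms_table", "data.frame")
  x
}
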