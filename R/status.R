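# Micronutrient and metabolic status classification. Convention for all
# cut-offs: a boundary value belongs to the better category — pathology
# is "below the cut-off", so equality is non-pathological.

#' Vitamin A status from retinol-binding protein (RBP)
#'
#' Deficient below 0.83 umol/l, insufficient in [0.83, 1.17), sufficient
#' at and above 1.17 umol/l (method-validated serum RBP cut-offs).
#'
#' @param rbp RBP concentration(s), umol/l; nonnegative.
#' @param unit unit check; must be "umol/l" if supplied.
#' @param deficient_below,insufficient_below cut-offs, umol/l.
#' @return character vector: "deficient", "insufficient", "sufficient".
#' @export
#' @examples
#' classify_rbp(c(0.82, 1.00, 1.17))
classify_rbp <- function(rbp, unit = "umol/l",
                         deficient_below = 0.83,
                         insufficient_below = 1.17) {
  check_unit(unit, "umol/l", "RBP")
  if (any(rbp < 0)) stop_input("RBP must be nonnegative")
  ifelse(rbp < deficient_below, "deficient",
         ifelse(rbp < insufficient_below, "insufficient", "sufficient"))
}

#' Vitamin D status from total 25-hydroxyvitamin D
#'
#' Insufficient below 50 nmol/l (clinical cut-off), else sufficient.
#'
#' @param total_25ohd total 25(OH)D, nmol/l; nonnegative.
#' @param unit unit check; must be "nmol/l" if supplied.
#' @param insufficient_below cut-off, nmol/l.
#' @return character vector: "insufficient" or "sufficient".
#' @export
classify_vitamin_d <- function(total_25ohd, unit = "nmol/l",
                               insufficient_below = 50) {
  check_unit(unit, "nmol/l", "25(OH)D")
  if (any(total_25ohd < 0)) stop_input("25(OH)D must be nonnegative")
  ifelse(total_25ohd < insufficient_below, "insufficient", "sufficient")
}

#' Define an inflammation-aware vitamin A status model
#'
#' A linear model estimating retinol from RBP, transthyretin, and
#' C-reactive protein (CRP, entered through a configurable transform).
#' The published coefficient values live in the external validation
#' study and are NOT shipped with this package: the user must supply
#' them; an unconfigured model refuses to run.
#'
#' @param intercept,b_rbp,b_transthyretin,b_crp model coefficients.
#' @param crp_transform "log1p" (default: log(CRP + 1)) or "identity".
#' @param threshold estimated-retinol deficiency cut-off, umol/l
#'   (default 0.70, the conventional serum retinol cut-off).
#' @return object of class \code{vitamin_a_model}.
#' @export
vitamin_a_model <- function(intercept, b_rbp, b_transthyretin, b_crp,
                            crp_transform = c("log1p", "identity"),
                            threshold = 0.70) {
  coefs <- c(intercept, b_rbp, b_transthyretin, b_crp)
  if (length(coefs) != 4 || any(!is.finite(coefs))) {
    stop_input(paste(
      "vitamin A model is not configured: supply the published",
      "intercept and coefficients for RBP, transthyretin, and CRP",
      "from the validation study"))
  }
  if (threshold <= 0) stop_input("threshold must be > 0")
  structure(list(intercept = intercept, b_rbp = b_rbp,
                 b_transthyretin = b_transthyretin, b_crp = b_crp,
                 crp_transform = match.arg(crp_transform),
                 threshold = threshold),
            class = "vitamin_a_model")
}

#' Estimate retinol and vitamin A status from the regression model
#'
#' @param rbp RBP, umol/l.
#' @param transthyretin transthyretin, umol/l.
#' @param crp C-reactive protein, mg/l.
#' @param model a configured [vitamin_a_model()].
#' @return data.frame \code{estimate} (umol/l) and \code{status}
#'   ("deficient" if the estimate is below the model threshold,
#'   else "sufficient").
#' @export
vitamin_a_model_estimate <- function(rbp, transthyretin, crp, model) {
  if (!inherits(model, "vitamin_a_model")) {
    stop_input(paste(
      "vitamin A model is not configured: supply the published",
      "coefficients via vitamin_a_model()"))
  }
  if (any(rbp < 0) || any(transthyretin < 0) || any(crp < 0)) {
    stop_input("model inputs must be nonnegative")
  }
  crp_t <- switch(model$crp_transform,
                  log1p = log1p(crp),
                  identity = crp)
  est <- model$intercept + model$b_rbp * rbp +
    model$b_transthyretin * transthyretin + model$b_crp * crp_t
  data.frame(estimate = est,
             status = ifelse(est < model$threshold, "deficient",
                             "sufficient"),
             stringsAsFactors = FALSE)
}

#' Classify a value against a reference range
#'
#' @param value numeric value(s).
#' @param lo,hi reference limits (lo < hi); boundary values are
#'   \code{"within"}.
#' @return character vector: "below", "within", "above".
#' @export
#' @examples
#' flag_reference_range(c(100, 208, 1000), 208, 972)
flag_reference_range <- function(value, lo, hi) {
  if (lo >= hi) stop_input("reference range needs lo < hi")
  ifelse(value < lo, "below", ifelse(value > hi, "above", "within"))
}

#' Fraction of records censored at an upper detection limit
#'
#' For an assay measured only up to its linear limit: records flagged
#' censored sit at (i.e., above) the limit; uncensored values below the
#' limit stay in the denominator.
#'
#' @param values measured values (censored records stored at the limit).
#' @param censored logical flags.
#' @param limit the detection limit.
#' @return fraction in [0, 1].
#' @export
censored_fraction <- function(values, censored, limit) {
  stopifnot(length(values) == length(censored))
  if (any(censored & abs(values - limit) > 1e-9)) {
    stop_input("censored value not stored at the limit %g", limit)
  }
  if (!length(values)) return(NA_real_)
  mean(censored)
}

#' Taurine-to-glycine bile-acid conjugation ratio per participant
#'
#' \code{ratio = sum of taurine-conjugated / sum of glycine-conjugated}
#' bile-acid concentrations. A zero glycine denominator yields a
#' \code{not_evaluable} status, not an error.
#'
#' @param bile_table data.frame \code{id, conjugation, value} where
#'   \code{conjugation} is "taurine", "glycine", or "unconjugated".
#' @return data.frame \code{id, taurine, glycine, ratio, status}.
#' @export
conjugation_ratio <- function(bile_table) {
  need <- c("id", "conjugation", "value")
  if (!all(need %in% names(bile_table))) {
    stop_input("bile_table needs columns %s", paste(need, collapse = ", "))
  }
  ids <- unique(bile_table$id)
  out <- do.call(rbind, lapply(ids, function(p) {
    sub <- bile_table[bile_table$id == p, ]
    tau <- sum(sub$value[sub$conjugation == "taurine"])
    gly <- sum(sub$value[sub$conjugation == "glycine"])
    data.frame(id = p, taurine = tau, glycine = gly,
               ratio = if (gly > 0) tau / gly else NA_real_,
               status = if (gly > 0) "ok" else "not_evaluable",
               stringsAsFactors = FALSE)
  }))
  out
}

check_unit <- function(unit, expected, what) {
  if (!is.null(unit) && !identical(unit, expected)) {
    stop_input("%s unit mismatch: expected '%s', got '%s'",
               what, expected, unit)
  }
  invisible(TRUE)
}

#' Rule-based status calls for a biomarker panel
#'
#' Applies the cut-off rules (a YAML-friendly nested list, see
#' \code{system.file("extdata", "status_rules.yaml", package =
#' "dietmetab")}) to a long biomarker table. Censored records are called
#' "censored"; analytes without a rule are skipped.
#'
#' @param biomarkers long data.frame \code{id, analyte, value, unit,
#'   censored}.
#' @param rules named list of per-analyte rules: elements may contain
#'   \code{unit}, \code{deficient_below}, \code{insufficient_below},
#'   \code{reference_range}, \code{detection_limit}.
#' @return data.frame \code{id, analyte, value, unit, status, rule}.
#' @export
status_calls <- function(biomarkers, rules) {
  out <- list()
  for (an in intersect(names(rules), unique(biomarkers$analyte))) {
    rule <- rules[[an]]
    sub <- biomarkers[biomarkers$analyte == an, ]
    if (!is.null(rule$unit)) {
      bad <- setdiff(unique(sub$unit), rule$unit)
      if (length(bad)) {
        stop_input("%s unit mismatch: expected '%s', got '%s'",
                   an, rule$unit, bad[1])
      }
    }
    status <- rep(NA_character_, nrow(sub))
    rule_id <- rep(NA_character_, nrow(sub))
    if (!is.null(rule$deficient_below) || !is.null(rule$insufficient_below)) {
      def <- rule$deficient_below %||% -Inf
      ins <- rule$insufficient_below %||% def
      status <- ifelse(sub$value < def, "deficient",
                       ifelse(sub$value < ins, "insufficient",
                              "sufficient"))
      rule_id <- sprintf("cutoff<%s", ins)
    } else if (!is.null(rule$reference_range)) {
      rr <- rule$reference_range
      status <- flag_reference_range(sub$value, rr[[1]], rr[[2]])
      rule_id <- sprintf("range[%s,%s]", rr[[1]], rr[[2]])
    } else if (!is.null(rule$detection_limit)) {
      status <- ifelse(sub$censored, "censored", "measured")
      rule_id <- sprintf("limit=%s", rule$detection_limit)
    }
    cens <- !is.na(sub$censored) & sub$censored
    status[cens] <- "censored"
    out[[an]] <- data.frame(id = sub$id, analyte = an, value = sub$value,
                            unit = sub$unit, status = status,
                            rule = rule_id, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
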