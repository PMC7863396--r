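db_path <- system.file("extdata", "compounds_synthetic.csv",
                       package = "dietmetab")

test_that("monoisotopic masses come from the isotope table and are additive", {
  expect_lt(abs(monoisotopic_mass("H2O") -
                  (2 * 1.0078250319 + 15.9949146221)), 5e-4)
  expect_lt(abs(mz_from_formula("C6H12O6") - 179.0561), 5e-4)
  # additivity over concatenated formulas
  set.seed(1)
  for (i in 1:20) {
    a <- sprintf("C%dH%dN%d", sample(1:9, 1), sample(1:20, 1), sample(1:3, 1))
    b <- sprintf("O%dS%d", sample(1:6, 1), sample(1:2, 1))
    expect_equal(monoisotopic_mass(paste0(a, b)),
                 monoisotopic_mass(a) + monoisotopic_mass(b),
                 tolerance = 1e-12)
  }
  expect_error(monoisotopic_mass(""), "empty")
  expect_error(monoisotopic_mass("C6Xx2"), "unknown element")
  expect_error(mz_from_formula("C6H12O6", mode = "positive"), "negative")
})

mk_matrix <- function(mz, intens = NULL, ids = NULL) {
  n_ion <- length(mz)
  if (is.null(intens)) {
    intens <- matrix(rlnorm(n_ion * 5), n_ion, 5)
  }
  ids <- ids %||% sprintf("ion_%04d", seq_len(n_ion))
  rownames(intens) <- ids
  colnames(intens) <- sprintf("P%03d", seq_len(ncol(intens)))
  metabolite_matrix(intens,
                    data.frame(ion_id = ids, mz = mz, annotation = "",
                               stringsAsFactors = FALSE))
}

test_that("annotation keeps all isomers and respects the exact tolerance", {
  compounds <- read_compound_db(db_path)
  glu <- mz_from_formula("C6H12O6")
  set.seed(2)
  mm <- mk_matrix(c(glu, glu + 0.001, glu + 0.001 + 1e-6, 500))
  ann <- annotate_peaks(mm, compounds, tol = 0.001)
  # isomers (glucose/fructose) are both retained
  expect_setequal(ann$annotations[[1]]$compound_id,
                  c("cpd_glucose", "cpd_fructose"))
  # exactly tol away is still in; tol + 1e-6 is out
  expect_equal(nrow(ann$annotations[[2]]), 2)
  expect_equal(nrow(ann$annotations[[3]]), 0)
  expect_equal(ann$ions$annotation[4], "")
})

test_that("annotation equals a brute-force matcher and is monotone in tol", {
  compounds <- read_compound_db(db_path)
  set.seed(3)
  mz <- c(compounds$monoisotopic_mass[sample(nrow(compounds), 20)] -
            1.007276 + rnorm(20, 0, 8e-4),
          runif(20, 80, 1000))
  mm <- mk_matrix(mz)
  for (tol in c(2e-4, 1e-3, 5e-3)) {
    got <- annotate_peaks(mm, compounds, tol = tol)
    want <- annotate_brute(mz, compounds, tol)
    for (i in seq_along(mz)) {
      expect_identical(got$annotations[[i]]$compound_id, want[[i]],
                       label = sprintf("ion %d tol %g", i, tol))
    }
  }
  # shrinking tol never adds annotations
  wide <- annotate_peaks(mm, compounds, tol = 1e-3)
  narrow <- annotate_peaks(mm, compounds, tol = 2e-4)
  for (i in seq_along(mz)) {
    expect_true(all(narrow$annotations[[i]]$compound_id %in%
                      wide$annotations[[i]]$compound_id))
  }
})

test_that("isotopologue support needs both the mass spacing and correlation", {
  set.seed(4)
  base <- rlnorm(20, 5)
  intens <- rbind(base, base * 0.3, rlnorm(20, 5), rlnorm(20, 5))
  mm <- mk_matrix(c(200, 200 + 1.00336, 300 + 1.003355, 300),
                  intens = intens,
                  ids = c("mono", "iso", "noise_partner", "lonely"))
  # duplicated (scaled) intensity vector at +1.00336: r = 1
  expect_true(isotope_correlation_support(mm, "mono"))
  expect_equal(attr(isotope_correlation_support(mm, "mono"), "partner"),
               "iso")
  # partner at the right spacing but independent intensities
  expect_false(isotope_correlation_support(mm, "lonely", r_min = 0.7))
  # no partner ion at all
  expect_false(isotope_correlation_support(mm, "iso"))
})

test_that("zero handling replaces by half the ion minimum and preserves order", {
  intens <- matrix(c(0, 4, 8,
                     1, 2, 3), 2, 3, byrow = TRUE)
  mm <- mk_matrix(c(100, 200), intens = intens)
  fixed <- handle_zeros(mm)
  expect_equal(unname(fixed$intensities[1, ]), c(2, 4, 8))
  expect_equal(unname(fixed$intensities[2, ]), c(1, 2, 3))  # untouched
  # order preserved under random sparsity
  set.seed(5)
  intens2 <- matrix(rlnorm(200), 20, 10)
  intens2[sample(200, 30)] <- 0
  mm2 <- mk_matrix(runif(20, 80, 900), intens = intens2)
  out <- handle_zeros(mm2)
  expect_true(all(out$intensities > 0))
  for (i in 1:20) {
    pos <- intens2[i, ] > 0
    expect_equal(order(out$intensities[i, pos]), order(intens2[i, pos]))
    expect_true(all(out$intensities[i, !pos] < min(intens2[i, pos])))
  }
  bad <- mk_matrix(c(100, 200), intens = matrix(c(0, 0, 0, 1, 2, 3),
                                                2, 3, byrow = TRUE))
  expect_error(handle_zeros(bad), "ion_0001")
})

test_that("log2 fold changes are zero at the omnivore mean and match the formula", {
  tc <- tiny_cohort()
  mm <- simulate_metabolome(tc$cohort, tc$config)
  fc <- log2_fold_changes(mm, tc$cohort, reference = "OMN")
  ref_ids <- tc$cohort$id[tc$cohort$diet == "OMN"]
  ref_mean <- rowMeans(mm$intensities[, ref_ids])
  # direct-formula oracle
  expect_equal(fc, log2(mm$intensities / ref_mean),
               ignore_attr = TRUE, tolerance = 1e-12)
  # a participant at exactly the reference mean maps to 0, at 2x to +1
  m2 <- mm
  m2$intensities[1, 1] <- ref_mean[1]
  m2$intensities[2, 1] <- 2 * ref_mean[2]
  ref_ids_wo <- setdiff(ref_ids, colnames(m2$intensities)[1])
  fc2 <- log2_fold_changes(m2, tc$cohort)
  rm1 <- rowMeans(m2$intensities[, ref_ids])
  expect_equal(unname(fc2[1, 1]), unname(log2(m2$intensities[1, 1] / rm1[1])))
  # translation: scaling one ion shifts non-reference fold changes by log2(c)
  m3 <- mm
  m3$intensities[5, ] <- m3$intensities[5, ] * 8
  fc3 <- log2_fold_changes(m3, tc$cohort)
  expect_equal(fc3[5, ], fc[5, ], tolerance = 1e-12)  # ref mean scales too
  expect_error(log2_fold_changes(mm, tc$cohort, reference = "XXX"), "empty")
})

test_that("pooled class comparison pools n = members x participants", {
  cfg <- sim_config(n_ions = 12, pathway_spec = default_pathway_spec(12, 1, 4),
                    effect_table = data.frame(pathway = "pathway_01",
                                              log2_shift = 1,
                                              attenuation = 0.5),
                    seed = 31)
  coh <- simulate_cohort(cfg)       # 24 / 10 / 6
  mm <- simulate_metabolome(coh, cfg)
  fc <- log2_fold_changes(mm, coh)
  groups <- list(MCFA = rownames(fc)[1:3], LCFA = rownames(fc)[4:9])
  res <- pooled_class_comparison(fc, groups, coh)
  box <- res$box_stats
  expect_equal(box$n[box$class == "MCFA"][order(box$diet[box$class == "MCFA"])],
               c(3 * 24, 3 * 6, 3 * 10))  # OMN, VGN, VGTR alphabetical
  expect_equal(sort(box$n[box$class == "LCFA"]), sort(c(144, 36, 60)))
  # box statistics match a sort-based oracle
  v <- as.numeric(fc[groups$MCFA, coh$id[coh$diet == "OMN"]])
  sv <- sort(v)
  row <- box[box$class == "MCFA" & box$diet == "OMN", ]
  expect_equal(row$min, sv[1])
  expect_equal(row$max, sv[length(sv)])
  expect_equal(row$median, median(v))
  # single-ion class reduces to that ion's distribution
  res1 <- pooled_class_comparison(fc, list(one = rownames(fc)[10]), coh)
  row1 <- res1$box_stats[res1$box_stats$diet == "VGN", ]
  expect_equal(row1$n, 6)
  expect_equal(row1$median,
               median(fc[rownames(fc)[10], coh$id[coh$diet == "VGN"]]))
  # no pooled test is emitted: member-level Welch tests only, BH within class
  expect_true(all(res$member_tests$ion %in% unlist(groups)))
  expect_true(all(res$member_tests$q >= res$member_tests$p - 1e-15))
  expect_error(pooled_class_comparison(fc, list(bad = "nope"), coh),
               "unknown ion")
})
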