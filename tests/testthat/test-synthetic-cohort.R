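test_that("cohort has the configured structure and is seed-reproducible", {
  cfg <- sim_config(seed = 1)
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh), 40)
  expect_equal(as.integer(table(coh$diet)[c("OMN", "VGTR", "VGN")]),
               c(24L, 10L, 6L))
  expect_false(anyDuplicated(coh$id) > 0)

  small <- sim_config(group_sizes = c(OMN = 1, VGTR = 1, VGN = 1), seed = 5)
  expect_identical(simulate_cohort(small), simulate_cohort(small))

  # ages stay inside the configured range even over many draws
  big <- sim_config(group_sizes = c(OMN = 5000, VGTR = 2500, VGN = 2500),
                    seed = 2)
  ages <- simulate_cohort(big)$age_years
  expect_gte(min(ages), 1.42)
  expect_lte(max(ages), 7.07)
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(group_sizes = c(OMN = 0, VGTR = 1, VGN = 1)),
               "group_sizes")
  expect_error(sim_config(age_range = c(5, 2)), "age_range")
  expect_error(sim_config(block_correlation = 1.2), "block_correlation")
  expect_error(sim_config(effect_table = data.frame(
    pathway = "no_such", log2_shift = 1, attenuation = 0.5)),
    "unknown pathway")
  expect_error(sim_config(effect_table = data.frame(
    pathway = "pathway_01", log2_shift = 1, attenuation = 1.5)),
    "attenuation")
  spec <- default_biomarker_spec(); spec$sd[1] <- -1
  expect_error(sim_config(biomarker_spec = spec), "negative SD")
})

test_that("planted log2 shifts are recovered as group fold changes", {
  # Monte-Carlo check at n = 200/group over 3 seeds: a +1 vegan log2
  # shift with attenuation 0.5 must come back as VGN-OMN ~ 1.0 and
  # VGTR-OMN ~ 0.5 for pathway members
  for (seed in 1:3) {
    cfg <- sim_config(
      group_sizes = c(OMN = 200, VGTR = 200, VGN = 200),
      n_ions = 40, pathway_spec = default_pathway_spec(40, 2, 10),
      effect_table = data.frame(pathway = "pathway_01", log2_shift = 1,
                                attenuation = 0.5),
      seed = seed)
    coh <- simulate_cohort(cfg)
    mm <- simulate_metabolome(coh, cfg)
    l2 <- log2(mm$intensities)
    memb <- cfg$pathway_spec$pathway_01
    grp_mean <- function(g) rowMeans(l2[memb, coh$diet == g, drop = FALSE])
    fc_vgn <- mean(grp_mean("VGN") - grp_mean("OMN"))
    fc_vgtr <- mean(grp_mean("VGTR") - grp_mean("OMN"))
    expect_lt(abs(fc_vgn - 1), 0.1)
    expect_lt(abs(fc_vgtr - 0.5), 0.1)
    # non-members are unshifted
    rest <- setdiff(rownames(l2), memb)
    expect_lt(abs(mean(rowMeans(l2[rest, coh$diet == "VGN"]) -
                         rowMeans(l2[rest, coh$diet == "OMN"]))), 0.1)
  }
})

test_that("within-pathway correlation matches the configured block value", {
  cfg <- sim_config(
    group_sizes = c(OMN = 2000, VGTR = 2000, VGN = 1000),
    n_ions = 20, pathway_spec = default_pathway_spec(20, 1, 10),
    effect_table = data.frame(pathway = character(0),
                              log2_shift = numeric(0),
                              attenuation = numeric(0)),
    block_correlation = 0.3, seed = 3)
  coh <- simulate_cohort(cfg)
  mm <- simulate_metabolome(coh, cfg)
  l10 <- log10(mm$intensities)
  memb <- cfg$pathway_spec$pathway_01
  cors <- cor(t(l10[memb, ]))
  mean_r <- mean(cors[upper.tri(cors)])
  expect_lt(abs(mean_r - 0.30), 0.02)
  # unassigned ions are uncorrelated with the block
  lone <- setdiff(rownames(l10), memb)[1:5]
  cross <- cor(t(l10[memb, ]), t(l10[lone, ]))
  expect_lt(max(abs(cross)), 0.1)
})

test_that("biomarker censoring stores draws at the limit with the flag", {
  spec <- data.frame(analyte = "b12", unit = "pmol/l", dist = "normal",
                     mean_OMN = 500, mean_VGTR = 500, mean_VGN = 500,
                     sd = 10, censor_limit = 128,
                     stringsAsFactors = FALSE)
  cfg <- sim_config(biomarker_spec = spec, seed = 4)
  bm <- simulate_biomarkers(simulate_cohort(cfg), cfg)
  expect_true(all(bm$censored))           # mean far above the limit
  expect_true(all(bm$value == 128))

  spec$censor_limit <- Inf
  cfg2 <- sim_config(biomarker_spec = spec, seed = 4)
  bm2 <- simulate_biomarkers(simulate_cohort(cfg2), cfg2)
  expect_false(any(bm2$censored))
})

test_that("vegan 25(OH)D draws have the configured coverage", {
  # mean 60, sd 3.5 => ~95% of vegan draws inside [53, 67]
  spec <- data.frame(analyte = "vitd_total", unit = "nmol/l",
                     dist = "normal", mean_OMN = 80, mean_VGTR = 70,
                     mean_VGN = 60, sd = 3.5, censor_limit = Inf,
                     stringsAsFactors = FALSE)
  cfg <- sim_config(group_sizes = c(OMN = 10, VGTR = 10, VGN = 4000),
                    biomarker_spec = spec, seed = 6)
  coh <- simulate_cohort(cfg)
  bm <- simulate_biomarkers(coh, cfg)
  vgn <- bm$value[bm$id %in% coh$id[coh$diet == "VGN"]]
  cover <- mean(vgn >= 53 & vgn <= 67)
  expect_lt(abs(cover - 0.954), 0.02)
})

test_that("all three simulators are deterministic under one master seed", {
  cfg <- sim_config(n_ions = 30, pathway_spec = default_pathway_spec(30, 2, 10),
                    seed = 77)
  run <- function() {
    coh <- simulate_cohort(cfg)
    list(coh, simulate_biomarkers(coh, cfg), simulate_metabolome(coh, cfg))
  }
  expect_identical(run(), run())
})

test_that("per-ion tests are calibrated under the all-null generator", {
  # no effects, no age slope: Welch p-values across ions must be uniform
  cfg <- sim_config(
    n_ions = 1000, pathway_spec = default_pathway_spec(1000, 10, 20),
    effect_table = data.frame(pathway = character(0),
                              log2_shift = numeric(0),
                              attenuation = numeric(0)),
    seed = 8)
  coh <- simulate_cohort(cfg)
  mm <- simulate_metabolome(coh, cfg)
  l10 <- log10(mm$intensities)
  ids_v <- coh$id[coh$diet == "VGN"]; ids_o <- coh$id[coh$diet == "OMN"]
  p <- vapply(seq_len(nrow(l10)), function(i)
    t.test(l10[i, ids_v], l10[i, ids_o])$p.value, 0.0)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("fixture files round-trip losslessly", {
  tc <- tiny_cohort()
  coh <- tc$cohort
  bm <- simulate_biomarkers(coh, tc$config)
  mm <- simulate_metabolome(coh, tc$config)
  d1 <- withr::local_tempdir()
  p1 <- write_fixture(coh, bm, mm, d1)
  coh2 <- read_cohort(p1[["cohort"]])
  bm2 <- read_biomarkers(p1[["biomarkers"]])
  mm2 <- read_matrix(p1[["matrix"]], p1[["ions"]])
  gmt <- read_gmt(p1[["gmt"]])
  # write -> read -> write gives byte-identical files
  d2 <- withr::local_tempdir()
  mm2$pathways <- gmt
  p2 <- write_fixture(coh2, bm2, mm2, d2)
  for (k in names(p1)) {
    expect_identical(readLines(p2[[k]]), readLines(p1[[k]]),
                     label = paste("round-trip of", k))
  }
  expect_equal(dim(mm2$intensities), dim(mm$intensities))
  # empty biomarker table still writes a valid header-only file
  d3 <- withr::local_tempdir()
  p3 <- write_fixture(coh, bm[0, ], NULL, d3)
  expect_equal(nrow(read_biomarkers(p3[["biomarkers"]])), 0)
})
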