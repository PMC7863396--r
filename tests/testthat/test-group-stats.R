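test_that("probability index equals pairwise enumeration and is complementary", {
  expect_equal(probability_index(c(1, 2, 3), c(2, 4)), 0.25)
  expect_equal(probability_index(c(1, 2, 3), c(3, 2, 1)), 0.5)
  set.seed(1)
  for (i in 1:50) {
    x <- sample(1:6, sample(2:8, 1), replace = TRUE)  # ties likely
    y <- sample(1:6, sample(2:8, 1), replace = TRUE)
    expect_equal(probability_index(x, y), pi_brute(x, y))
    expect_equal(probability_index(x, y) + probability_index(y, x), 1)
  }
  expect_error(probability_index(numeric(0), 1), "nonempty")
})

test_that("PI equals Mann-Whitney U/(n1 n2) under the midrank tie convention", {
  set.seed(2)
  for (i in 1:20) {
    x <- sample(1:5, 10, replace = TRUE)
    y <- sample(1:5, 7, replace = TRUE)
    u <- suppressWarnings(wilcox.test(x, y)$statistic)
    expect_equal(probability_index(x, y), unname(u) / (10 * 7))
  }
})

test_that("residualization is a null-model OLS fit", {
  set.seed(3)
  age <- runif(20, 1, 7); sex <- sample(c("F", "M"), 20, TRUE)
  # outcome unrelated to covariates: residuals are centred values of the
  # projection complement; orthogonality is the defining property
  v <- rnorm(20)
  r <- residualize(v, age, sex)
  expect_lt(abs(sum(r)), 1e-8)
  expect_lt(abs(sum(r * age)), 1e-8)
  expect_lt(abs(sum(r * (as.numeric(factor(sex)) - 1))), 1e-8)
  # perfect fit leaves nothing
  expect_lt(max(abs(residualize(2 * age, age, sex))), 1e-10)
  # degenerate design is refused
  expect_error(residualize(v, rep(2, 20), rep("F", 20)), "rank-deficient")
  expect_error(residualize(v[1:3], age[1:3], sex[1:3]), ">= 4")
})

test_that("exhaustive permutation test reproduces the hand-enumerated example", {
  # values (1,2 | 3,4): T_obs = 0.5, attained by 2 of the 6 splits
  res <- perm_test(c(1, 2, 3, 4), rep(c("a", "b"), each = 2),
                   mode = "exhaustive")
  expect_equal(res$effect, 0.5)
  expect_equal(res$p_raw, 1 / 3)
  expect_equal(res$n_perm, choose(4, 2))

  tied <- perm_test(rep(1, 6), rep(c("a", "b"), each = 3),
                    mode = "exhaustive")
  expect_equal(tied$statistic, 0.5)
  expect_equal(tied$effect, 0)
  expect_equal(tied$p_raw, 1)
})

test_that("monte carlo p agrees with exhaustive p within Monte-Carlo error", {
  set.seed(4)
  for (i in 1:5) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    v <- rnorm(n1 + n2)
    g <- rep(c("a", "b"), c(n1, n2))
    pe <- perm_test(v, g, mode = "exhaustive")$p_raw
    pm <- perm_test(v, g, n_perm = 20000, seed = i)$p_raw
    se <- sqrt(pe * (1 - pe) / 20000)
    expect_lt(abs(pm - pe), 3 * se + 1e-4)
  }
})

test_that("exchanging the group roles flips PI and keeps p", {
  set.seed(5)
  v <- rnorm(12); g <- rep(c("a", "b"), c(7, 5))
  r1 <- perm_test(v, g, mode = "exhaustive")
  # present group b first so it takes the reference role
  ord <- order(g == "a")
  r2 <- perm_test(v[ord], g[ord], mode = "exhaustive")
  expect_equal(r1$statistic + r2$statistic, 1)
  expect_equal(r1$p_raw, r2$p_raw)
})

test_that("monte carlo p respects its granularity floor", {
  set.seed(6)
  v <- c(rnorm(10), rnorm(5) + 50)  # extreme separation
  g <- rep(c("a", "b"), c(10, 5))
  res <- perm_test(v, g, n_perm = 999, seed = 1)
  expect_gte(res$p_raw, 1 / 1000)
})

test_that("adjusted schemes accept covariates and agree on exchangeable data", {
  set.seed(7)
  age <- runif(24, 1, 7); sex <- sample(c("F", "M"), 24, TRUE)
  v <- rnorm(24)
  g <- rep(c("a", "b"), c(18, 6))
  for (scheme in c("freedman_lane", "residualize", "stratified")) {
    res <- perm_test(v, g, age = age, sex = sex, n_perm = 499, seed = 2,
                     adjust = TRUE, scheme = scheme)
    expect_true(res$adjusted)
    expect_gt(res$p_raw, 0.01)  # null data: no scheme finds an effect
  }
  expect_error(perm_test(v, g, adjust = TRUE), "requires age and sex")
  expect_error(perm_test(v, g, age = age, sex = sex, adjust = TRUE,
                         mode = "exhaustive"),
               "scheme = 'residualize'")
})

test_that("exhaustive mode refuses infeasible designs with guidance", {
  expect_error(perm_test(rnorm(40), rep(c("a", "b"), c(24, 16)),
                         mode = "exhaustive"),
               "monte_carlo")
  expect_error(perm_test(rnorm(6), rep(c("a", "b", "c"), 2)),
               "two group labels")
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(8)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_brute(p))
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("welch_t matches the textbook formulas and is antisymmetric", {
  w <- welch_t(c(1, 2, 3), c(2, 3, 4))
  o <- welch_brute(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$t, o$t, tolerance = 1e-10)
  expect_equal(w$df, o$df, tolerance = 1e-10)
  expect_equal(w$p, o$p, tolerance = 1e-10)

  same <- welch_t(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$t, 0); expect_equal(same$p, 1)

  set.seed(9)
  x <- rnorm(8); y <- rnorm(6, 1, 2)
  expect_equal(welch_t(x, y)$t, -welch_t(y, x)$t)
  expect_equal(welch_t(x, y)$p, welch_t(y, x)$p)
  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

test_that("Behrens-Fisher intervals are centred, nested, and match Welch form", {
  set.seed(10)
  x <- rnorm(10); y <- rnorm(8)
  ci <- behrens_fisher_ci(x, y)
  expect_equal(mean(ci), mean(x) - mean(y), tolerance = 1e-10)
  # widen monotonically with level
  w90 <- diff(behrens_fisher_ci(x, y, 0.90))
  w95 <- diff(behrens_fisher_ci(x, y, 0.95))
  w99 <- diff(behrens_fisher_ci(x, y, 0.99))
  expect_true(w90 < w95 && w95 < w99)
  # explicit Welch-Satterthwaite formula
  o <- welch_brute(x, y)
  half <- qt(0.975, o$df) * sqrt(var(x) / 10 + var(y) / 8)
  expect_equal(unname(ci), c(mean(x) - mean(y) - half,
                             mean(x) - mean(y) + half),
               tolerance = 1e-10)
  expect_error(behrens_fisher_ci(x, y, 1.2), "level")
})

test_that("Freedman-Lane stays calibrated where one-shot residualization is conservative", {
  # strong confounding: outcome tracks age and vegan ages sit 1.5 y higher
  set.seed(314)
  res <- replicate(500, {
    age <- c(runif(24, 1.42, 5.57), runif(6, 1.42, 5.57) + 1.5)
    sex <- sample(c("F", "M"), 30, TRUE)
    v <- age + rnorm(30, 0, 1.5)
    g <- rep(c("OMN", "VGN"), c(24, 6))
    c(fl = perm_test(v, g, age = age, sex = sex, n_perm = 399,
                     adjust = TRUE)$p_raw <= 0.05,
      os = perm_test(v, g, age = age, sex = sex, n_perm = 399,
                     adjust = TRUE, scheme = "residualize")$p_raw <= 0.05)
  })
  rate_fl <- mean(res["fl", ]); rate_os <- mean(res["os", ])
  expect_lt(rate_os, rate_fl)        # one-shot loses power to detect even noise
  expect_lt(rate_os, 0.04)           # markedly below nominal size
  expect_gt(rate_fl, 0.025)          # Freedman-Lane stays near nominal
  expect_lt(rate_fl, 0.08)
})
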