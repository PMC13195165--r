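# Per-arm regressions, exact binomial direction tests, one-way ANOVA
# and arm-vector correlations.

test_that("exact binomial tails match enumeration and tail-sum oracles", {
  # brute-force enumeration for small n
  for (n in c(5, 10, 15)) {
    for (k in c(0, 1, n %/% 2, n)) {
      st <- sign_binomial(k, n = n)
      expect_equal(st$p_value, binom_tail_enumeration(k, n),
                   tolerance = 1e-12)
    }
  }
  # exact tail sums at the 39-arm analysis scale
  for (k in c(39, 31, 29, 26, 20)) {
    st <- sign_binomial(k, n = 39)
    expect_equal(st$p_value, binom_tail_oracle(k, 39),
                 tolerance = 1e-12)
    expect_equal(st$p_hat, k / 39)
  }
})

test_that("binomial confidence bound conventions behave as documented", {
  st <- sign_binomial(39, n = 39)
  expect_equal(st$ci[["upper"]], 1)
  expect_equal(st$ci[["lower"]], 0.05^(1 / 39), tolerance = 1e-10)
  st31 <- sign_binomial(31, n = 39)
  expect_equal(round(st31$ci[["lower"]], 2), 0.66)
  st26 <- sign_binomial(26, n = 39)
  expect_equal(round(st26$ci[["lower"]], 2), 0.52)
  two <- sign_binomial(39, n = 39, ci_sided = "two")
  expect_lt(two$ci[["lower"]], st$ci[["lower"]])
  zero <- sign_binomial(0, n = 10)
  expect_equal(zero$ci[["lower"]], 0)
  expect_equal(zero$p_value, 1, tolerance = 1e-12)
})

test_that("per-arm OLS recovers a uniform simulated age effect", {
  cfg <- tiny_config(n = 600, seed = 37, age_slope_coupling = 0,
                     variance_fractions = c(individual = 0.08,
                                            arm = 0.09, age = 0.1))
  coh <- make_cohort(cfg)
  tab <- true_arm_table(coh, "analysis")
  true_slope <- coh$age_slopes[[1]]
  assoc <- per_arm_ols(tab, "age")
  expect_equal(nrow(assoc), 39L)
  expect_true(all(assoc$beta < 0))
  expect_equal(mean(assoc$beta), true_slope,
               tolerance = abs(true_slope) * 0.1)
  st <- sign_binomial(assoc, "negative")
  expect_equal(st$n_in_direction, 39L)
  expect_lt(st$p_value, 1e-10)
})

test_that("per-arm OLS guards: aliasing and unfittable arms", {
  tab <- true_arm_table(make_cohort(tiny_config(n = 30, seed = 39)),
                        "analysis")
  expect_error(per_arm_ols(tab, "age", adjusters = c("age", "sex")),
               "aliased")
  tiny <- tab[tab$sample_id %in% unique(tab$sample_id)[1:2], ]
  expect_warning(res <- per_arm_ols(tiny, "age",
                                    adjusters = c("sex", "bmi")),
                 "omitted")
})

test_that("noise-only exposures reject at the nominal rate", {
  set.seed(41)
  tab <- true_arm_table(make_cohort(tiny_config(n = 150, seed = 41)),
                        "analysis")
  ids <- unique(tab$sample_id)
  hits <- replicate(40, {
    tab$noise <- stats::rnorm(length(ids))[match(tab$sample_id, ids)]
    mean(per_arm_ols(tab, "noise")$p < 0.05)
  })
  expect_lt(abs(mean(hits) - 0.05), 0.03)
})

test_that("one-way ANOVA of arm: df, closed form, and null behavior", {
  tab <- true_arm_table(make_cohort(tiny_config(n = 80, seed = 43)),
                        "analysis")
  av <- arm_anova(tab)
  expect_equal(av$df1, 38L)
  expect_equal(av$df2, nrow(tab) - 39L)
  expect_gt(av$F, 1)
  expect_equal(length(av$means), 39L)

  # two-group case reduces to the squared t statistic
  two <- tab[tab$arm %in% c("1p", "9q"), ]
  av2 <- arm_anova(two)
  tt <- stats::t.test(cstl ~ arm, two, var.equal = TRUE)
  expect_equal(av2$F, unname(tt$statistic)^2, tolerance = 1e-10)

  # equal means: F near 1 in expectation
  set.seed(44)
  null_tab <- data.frame(arm = rep(sprintf("a%d", 1:10), each = 50),
                         cstl = stats::rnorm(500))
  fs <- replicate(30, {
    null_tab$cstl <- stats::rnorm(500)
    arm_anova(null_tab)$F
  })
  expect_lt(abs(mean(fs) - 1), 0.3)
})

test_that("ANOVA arm means reproduce the generator's arm ordering", {
  cfg <- tiny_config(n = 400, seed = 47)
  coh <- make_cohort(cfg)
  tab <- true_arm_table(coh, "analysis")
  av <- arm_anova(tab)
  rho <- stats::cor(av$means[analysis_arms()],
                    coh$arm_means[analysis_arms()],
                    method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("arm-vector correlations: identities and coupling detection", {
  x <- stats::setNames(seq(2000, 6000, length.out = 20),
                       analysis_arms()[1:20])
  expect_equal(arm_vector_correlation(x, 2 * x + 1)$estimate, 1,
               tolerance = 1e-12)
  y <- exp(x / 1000)
  sp <- arm_vector_correlation(x, y, method = "spearman")
  expect_equal(sp$estimate, 1, tolerance = 1e-12)
  expect_lt(arm_vector_correlation(x, y)$estimate, 1)
  expect_error(arm_vector_correlation(x[1:2], y[1:2]), "3 common")

  cfg <- tiny_config(n = 500, seed = 53, age_slope_coupling = 1)
  coh <- make_cohort(cfg)
  tab <- true_arm_table(coh, "analysis")
  assoc <- per_arm_ols(tab, "age")
  betas <- stats::setNames(abs(assoc$beta), assoc$arm)
  means <- tapply(tab$cstl, tab$arm, mean)
  ct <- arm_vector_correlation(betas, means)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p, 0.05)
})
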