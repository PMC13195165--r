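# Synthetic-cohort generator: variance structure, determinism, read
# emission and disease assignment.

test_that("cohort structure: 92 sites per individual, valid TLs", {
  coh <- make_cohort(tiny_config(n = 25, seed = 3))
  counts <- table(coh$sites$sample_id)
  expect_true(all(counts == 92))
  expect_true(all(coh$sites$tl_true > 0))
  expect_identical(sort(unique(coh$sites$arm)), sort(arm_labels()))
  # autosomal arms carry two alleles, sex arms one
  per_arm <- table(coh$sites$arm[coh$sites$sample_id ==
                                   coh$sites$sample_id[1]])
  expect_true(all(per_arm[setdiff(arm_labels(),
                                  sex_chromosome_arms())] == 2))
  expect_true(all(per_arm[sex_chromosome_arms()] == 1))
})

test_that("degenerate config: only residual variance", {
  cfg <- tiny_config(n = 200, seed = 5,
                     variance_fractions = c(individual = 0, arm = 0,
                                            batch = 0, age = 0, sex = 0,
                                            smoking = 0, bmi = 0,
                                            ancestry = 0))
  coh <- make_cohort(cfg)
  expect_true(all(coh$individuals$true_ind_effect == 0))
  tab <- true_arm_table(coh, "analysis")
  # residual carries the whole configured variance
  expect_equal(stats::var(tab$cstl), cfg$total_sd^2, tolerance = 0.02)
  # all arm means equal the grand mean
  expect_true(all(abs(coh$arm_means - cfg$grand_mean_tl) < 1e-8))
})

test_that("configured variance fractions are realized in-sample", {
  cfg <- tiny_config(n = 500, seed = 11,
                     variance_fractions = c(individual = 0.25))
  coh <- make_cohort(cfg)
  frac <- stats::var(coh$individuals$true_ind_effect) / cfg$total_sd^2
  expect_gte(frac, 0.20)
  expect_lte(frac, 0.30)
  # exact by construction at the generator's calibration
  expect_equal(frac, 0.25, tolerance = 1e-10)
})

test_that("invalid variance fractions are rejected", {
  expect_error(sim_config(variance_fractions = c(individual = 0.7,
                                                 arm = 0.5)),
               "configuration error")
  expect_error(sim_config(variance_fractions = c(individual = -0.1)),
               "configuration error")
  expect_error(sim_config(coverage_model = c(high = 0, mid = 4)),
               "coverage")
})

test_that("generation is deterministic given the seed", {
  c1 <- make_cohort(tiny_config(n = 40, seed = 77))
  c2 <- make_cohort(tiny_config(n = 40, seed = 77))
  expect_identical(c1$sites, c2$sites)
  expect_identical(c1$individuals, c2$individuals)
  r1 <- emit_reads(c1)
  r2 <- emit_reads(c2)
  expect_identical(r1, r2)
  c3 <- make_cohort(tiny_config(n = 40, seed = 78))
  expect_false(identical(c1$sites$tl_true, c3$sites$tl_true))
})

test_that("age-slope magnitude is monotone in arm mean when coupled", {
  cfg <- tiny_config(n = 10, seed = 1, age_slope_coupling = 1.5)
  coh <- make_cohort(cfg)
  ana <- analysis_arms()
  o <- order(coh$arm_means[ana])
  expect_true(all(diff(abs(coh$age_slopes[ana][o])) >= 0))
  expect_true(all(coh$age_slopes < 0))
  # uncoupled: identical slopes
  coh0 <- make_cohort(tiny_config(n = 10, seed = 1,
                                  age_slope_coupling = 0))
  expect_lt(diff(range(coh0$age_slopes)), 1e-9)
})

test_that("read emission follows the coverage and noise model", {
  cfg <- tiny_config(n = 60, seed = 13,
                     coverage_model = c(high = 30, mid = 30))
  coh <- make_cohort(cfg)
  reads <- emit_reads(coh)
  n_sites <- nrow(coh$sites)
  mean_reads <- nrow(reads) / n_sites
  se <- sqrt(30 / n_sites)
  expect_lt(abs(mean_reads - 30), 3 * se)
  expect_true(all(reads$read_tl_bp >= 0))
  expect_true(all(reads$read_len_bp >= reads$read_tl_bp))

  # noiseless limit: every read equals its site's true TL
  cfg0 <- tiny_config(n = 5, seed = 13, read_noise_sd = 0)
  coh0 <- make_cohort(cfg0)
  reads0 <- emit_reads(coh0)
  key <- paste(coh0$sites$sample_id, coh0$sites$arm, coh0$sites$allele)
  truth <- stats::setNames(coh0$sites$tl_true, key)
  expect_equal(unname(truth[paste(reads0$sample_id, reads0$arm,
                                  reads0$allele)]),
               reads0$read_tl_bp, tolerance = 1e-12)
})

test_that("near-zero coverage yields an empty read table", {
  cfg <- tiny_config(n = 3, seed = 2,
                     coverage_model = c(high = 1e-9, mid = 1e-9))
  reads <- emit_reads(make_cohort(cfg))
  expect_equal(nrow(reads), 0L)
})

test_that("depth matrix carries the configured low-rank batch structure", {
  coh <- make_cohort(tiny_config(n = 120, seed = 19))
  dep <- emit_depth_and_average_tl(coh, n_bins = 150, rank = 3,
                                   artifact_sd = 500,
                                   depth_noise_sd = 0.5)
  sv <- svd(scale(dep$depth, center = TRUE, scale = FALSE))$d
  # scree gap: top 3 singular values dominate the rest
  expect_gt(sv[3], 3 * sv[4])
  # artifact-free average TL tracks the true mean more closely
  dep0 <- emit_depth_and_average_tl(coh, n_bins = 150, rank = 3,
                                    artifact_sd = 0,
                                    depth_noise_sd = 0.5)
  r_clean <- stats::cor(dep0$average_tl$telseq_tl,
                        dep0$average_tl$true_mean_tl)
  r_cont <- stats::cor(dep$average_tl$telseq_tl,
                       dep$average_tl$true_mean_tl)
  expect_gt(r_clean, r_cont)
  # deterministic under a fixed seed
  dep2 <- emit_depth_and_average_tl(coh, n_bins = 150, rank = 3,
                                    artifact_sd = 500,
                                    depth_noise_sd = 0.5)
  expect_identical(dep$depth, dep2$depth)
})

test_that("disease assignment follows the logistic link", {
  coh <- make_cohort(tiny_config(n = 4000, seed = 23))
  # slope zero: prevalence matches the intercept
  coh1 <- assign_disease(coh, disease_params = list(
    D = list(metric = "mean_tl", or_per_kb = 1, prevalence = 0.3)))
  prev <- mean(coh1$individuals$D)
  expect_lt(abs(prev - 0.3), 3 * sqrt(0.3 * 0.7 / 4000))
  # intercept -> -Inf: no cases
  coh2 <- assign_disease(coh, disease_params = list(
    D = list(metric = "mean_tl", or_per_kb = 1, intercept = -1e6)))
  expect_equal(sum(coh2$individuals$D), 0L)
})
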