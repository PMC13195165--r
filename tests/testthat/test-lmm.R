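# The crossed random-effects LMM: oracle equivalence, classical closed
# forms, invariances and methods.

test_that("ML and REML objectives match the dense MVN oracle", {
  d <- make_crossed_data(n_ind = 15, n_arm = 6, seed = 3)
  for (reml in c(TRUE, FALSE)) {
    fit <- cstl_lmm(y ~ x, d, REML = reml)
    ll <- dense_loglik_oracle(fit, d, y ~ x, c("sample_id", "arm"))
    expect_equal(fit$logLik, ll, tolerance = 1e-6)
  }
})

test_that("sparse and dense code paths agree", {
  d <- make_crossed_data(n_ind = 40, n_arm = 8, seed = 9)
  fd <- cstl_lmm(y ~ x, d, REML = TRUE)
  fs <- cstl_lmm(y ~ x, d, REML = TRUE,
                 control = list(dense_cutoff = 1L))
  expect_equal(fd$logLik, fs$logLik, tolerance = 1e-8)
  expect_equal(fd$varcomp$variance, fs$varcomp$variance,
               tolerance = 1e-6)
  expect_equal(fd$beta, fs$beta, tolerance = 1e-8)
})

test_that("pure-noise data degenerates to ordinary least squares", {
  set.seed(11)
  d <- make_crossed_data(n_ind = 40, n_arm = 6, sd_ind = 0, sd_arm = 0,
                         sd_e = 1, seed = 11)
  fit <- cstl_lmm(y ~ x, d, REML = FALSE)
  ols <- stats::lm(y ~ x, d)
  expect_equal(unname(fit$beta), unname(stats::coef(ols)),
               tolerance = 1e-5)
  vc <- fit$varcomp
  expect_lt(vc$variance[vc$term == "sample_id"], 0.05)
  expect_lt(vc$variance[vc$term == "arm"], 0.05)
})

test_that("balanced one-way layout matches the ANOVA closed form", {
  set.seed(13)
  a <- 12; m <- 25
  d <- data.frame(g = factor(rep(sprintf("g%02d", 1:a), each = m)))
  d$y <- stats::rnorm(a, 0, 2)[as.integer(d$g)] + stats::rnorm(a * m)
  fit <- cstl_lmm(y ~ 1, d, random = "g", REML = TRUE)
  gm <- tapply(d$y, d$g, mean)
  msb <- m * stats::var(gm)
  msw <- sum((d$y - gm[as.integer(d$g)])^2) / (a * (m - 1))
  mom <- (msb - msw) / m  # method-of-moments between-group variance
  vc <- fit$varcomp
  expect_equal(vc$variance[vc$term == "g"], mom, tolerance = 1e-4)
  expect_equal(vc$variance[vc$term == "residual"], msw,
               tolerance = 1e-4)
})

test_that("fits are invariant to record order and level relabeling", {
  d <- make_crossed_data(n_ind = 25, n_arm = 5, seed = 17)
  fit <- cstl_lmm(y ~ x, d, REML = TRUE)
  set.seed(1)
  perm <- sample(nrow(d))
  fit2 <- cstl_lmm(y ~ x, d[perm, ], REML = TRUE)
  expect_equal(fit$logLik, fit2$logLik, tolerance = 1e-6)
  expect_equal(fit$varcomp$variance, fit2$varcomp$variance,
               tolerance = 1e-4)
  d3 <- d
  d3$sample_id <- factor(paste0("zz_", d3$sample_id))
  fit3 <- cstl_lmm(y ~ x, d3, REML = TRUE)
  expect_equal(fit$varcomp$variance, fit3$varcomp$variance,
               tolerance = 1e-6)
})

test_that("collinear fixed designs fail naming the aliased column", {
  d <- make_crossed_data(seed = 19)
  d$x2 <- 2 * d$x
  expect_error(cstl_lmm(y ~ x + x2, d), "aliased.*x2")
})

test_that("random-slope fits agree with lme4 at the optimum", {
  skip_if_not_installed("lme4")
  set.seed(23)
  n_ind <- 80; n_arm <- 10
  d <- expand.grid(sample_id = sprintf("i%03d", 1:n_ind),
                   arm = sprintf("a%02d", 1:n_arm))
  age_i <- stats::runif(n_ind, 20, 80)
  d$age <- age_i[as.integer(d$sample_id)]
  ac <- d$age - mean(d$age)
  d$y <- 40 - 0.3 * d$age +
    stats::rnorm(n_ind, 0, 2)[as.integer(d$sample_id)] +
    stats::rnorm(n_arm, 0, 2)[as.integer(d$arm)] +
    stats::rnorm(n_arm, 0, 0.1)[as.integer(d$arm)] * ac +
    stats::rnorm(nrow(d), 0, 2)
  fit <- cstl_lmm(y ~ age, d,
                  slope = list(factor = "arm", covariate = "age"),
                  REML = TRUE)
  d$age_c <- ac
  lf <- lme4::lmer(y ~ age + (1 | sample_id) + (1 + age_c | arm), d,
                   REML = TRUE,
                   control = lme4::lmerControl(calc.derivs = FALSE))
  expect_gte(fit$logLik, as.numeric(stats::logLik(lf)) - 1e-3)
  vc <- fit$varcomp
  vl <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(vc$variance[vc$term == "residual"],
               vl$vcov[is.na(vl$var1) & vl$grp == "Residual"],
               tolerance = 0.05)
})

test_that("intercept-only crossed fits agree with lme4", {
  skip_if_not_installed("lme4")
  d <- make_crossed_data(n_ind = 50, n_arm = 8, seed = 29)
  fit <- cstl_lmm(y ~ x, d, REML = TRUE)
  lf <- lme4::lmer(y ~ x + (1 | sample_id) + (1 | arm), d, REML = TRUE)
  expect_equal(fit$logLik, as.numeric(stats::logLik(lf)),
               tolerance = 1e-5)
  vl <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$varcomp$variance[1:2],
               vl$vcov[match(c("sample_id", "arm"), vl$grp)],
               tolerance = 1e-3)
  expect_equal(unname(fit$beta), unname(lme4::fixef(lf)),
               tolerance = 1e-5)
  expect_equal(unname(fit$se), unname(sqrt(diag(as.matrix(
    stats::vcov(lf))))), tolerance = 1e-3)
})

test_that("methods expose the fit: predict, simulate, residuals", {
  d <- make_crossed_data(n_ind = 20, n_arm = 5, seed = 31)
  fit <- cstl_lmm(y ~ x, d, REML = TRUE)
  expect_equal(fitted(fit) + residuals(fit), d$y, tolerance = 1e-10)
  expect_equal(predict(fit), fitted(fit))
  # predictions on known levels use the BLUPs; unseen levels drop to 0
  nd <- d[1:3, ]
  expect_equal(predict(fit, nd), fitted(fit)[1:3], tolerance = 1e-10)
  nd$sample_id <- "unseen"
  expect_equal(predict(fit, nd),
               as.vector(cbind(1, nd$x) %*% fit$beta) +
                 fit$ranef$arm[as.character(nd$arm)],
               tolerance = 1e-10, ignore_attr = TRUE)
  sims <- simulate(fit, nsim = 3, seed = 5)
  expect_equal(dim(sims), c(nrow(d), 3L))
  sims2 <- simulate(fit, nsim = 3, seed = 5)
  expect_identical(sims, sims2)
  # refitting a simulated response recovers variance components roughly
  d$ysim <- sims$sim_1
  refit <- cstl_lmm(ysim ~ x, d, REML = TRUE)
  expect_true(all(is.finite(refit$varcomp$variance)))
  out <- utils::capture.output(print(summary(fit)))
  expect_true(any(grepl("Variance components", out)))
})
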