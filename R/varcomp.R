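# Variance partitioning (PVE), likelihood-ratio tests and the covariate
# contribution / age-by-arm interaction analyses built on cstl_lmm.

#' Percent variance explained decomposition of a mixed-model fit
#'
#' The fixed-effects share is the sample variance of the fixed-effect
#' fitted values X beta-hat; each random intercept contributes its
#' estimated variance component, and the residual its variance. The
#' total is the sum of these, so shares add to one.
#'
#' @param fit A converged intercepts-only \code{\link{cstl_lmm}} fit.
#' @return Object of class \code{cstl_pve}: data.frame with
#'   \code{component}, \code{variance} (bp^2), \code{pve}.
#' @export
pve <- function(fit) {
  stopifnot(inherits(fit, "cstl_lmm"))
  if (!is.null(fit$slope))
    stop("pve is defined for random-intercept models")
  if (!fit$converged)
    warning("fit did not converge; PVE may be unreliable")
  v_fixed <- stats::var(fit$fitted_fixed)
  vc <- fit$varcomp
  v_rand <- vc$variance[vc$term != "residual"]
  names(v_rand) <- vc$term[vc$term != "residual"]
  total <- v_fixed + sum(v_rand) + fit$sigma2
  out <- data.frame(
    component = c("fixed", names(v_rand), "residual"),
    variance = c(v_fixed, unname(v_rand), fit$sigma2),
    stringsAsFactors = FALSE)
  out$pve <- out$variance / total
  class(out) <- c("cstl_pve", "data.frame")
  attr(out, "total_variance") <- total
  out
}

#' @export
print.cstl_pve <- function(x, ...) {
  cat("Variance decomposition (total",
      format(attr(x, "total_variance"), digits = 5), "bp^2):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-12s %11.1f  (%5.1f%%)\n", x$component[i],
                x$variance[i], 100 * x$pve[i]))
  invisible(x)
}

#' Likelihood-ratio test between nested mixed models
#'
#' The statistic is 2(logLik_full - logLik_reduced), clamped at zero,
#' referred to a chi-squared distribution with degrees of freedom equal
#' to the parameter-count difference. Both fits must use the same
#' criterion and records: fixed-effect comparisons should be between ML
#' fits; random-effect comparisons between REML fits with identical
#' fixed parts. P-values that underflow double precision are reported on
#' the log scale (\code{log10_p} is always exact).
#'
#' @param full,reduced \code{\link{cstl_lmm}} fits, reduced nested in
#'   full.
#' @return Object of class \code{cstl_lrt}: list with \code{chisq},
#'   \code{df}, \code{p}, \code{log10_p}.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "cstl_lmm"), inherits(reduced, "cstl_lmm"))
  if (!identical(full$criterion, reduced$criterion))
    stop("fits use different criteria (", full$criterion, " vs ",
         reduced$criterion, "); refit with a common criterion")
  if (full$n != reduced$n)
    stop("fits use different numbers of records; refit on common data")
  if (full$REML && !identical(full$fixed_names, reduced$fixed_names))
    stop("REML comparisons require identical fixed-effect parts; ",
         "use ML fits for fixed-effect tests")
  nested_fixed <- all(reduced$fixed_names %in% full$fixed_names)
  nested_random <- all(reduced$random %in% full$random) &&
    (is.null(reduced$slope) ||
       (!is.null(full$slope) && identical(reduced$slope, full$slope)))
  if (!nested_fixed || !nested_random)
    stop("models are not nested")
  df <- full$df_model - reduced$df_model
  if (df <= 0) stop("models are not nested (no parameter difference)")
  delta <- 2 * (full$logLik - reduced$logLik)
  if (delta < -1e-4)
    stop("full model has lower likelihood than reduced (", signif(delta, 3),
         "); refit required (check convergence)")
  chisq <- max(0, delta)
  log10_p <- stats::pchisq(chisq, df, lower.tail = FALSE,
                           log.p = TRUE) / log(10)
  out <- list(chisq = chisq, df = df,
              p = stats::pchisq(chisq, df, lower.tail = FALSE),
              log10_p = log10_p)
  class(out) <- "cstl_lrt"
  out
}

#' @export
print.cstl_lrt <- function(x, ...) {
  if (x$p < 1e-300) {
    cat(sprintf("LRT: chi2(%d) = %.1f, P < 1e-300 (log10 P = %.1f)\n",
                x$df, x$chisq, x$log10_p))
  } else {
    cat(sprintf("LRT: chi2(%d) = %.1f, P = %s\n", x$df, x$chisq,
                format(signif(x$p, 2))))
  }
  invisible(x)
}

#' Marginal contribution of a single covariate
#'
#' Compares two ML mixed models with the crossed random intercepts: one
#' with the single fixed-effect covariate and one with an intercept
#' only. The covariate's contribution is the marginal R-squared (the
#' fixed-effects PVE of the single-covariate model); significance comes
#' from the likelihood-ratio test of the pair.
#'
#' @param data Long arm table.
#' @param covariate Covariate column name.
#' @param response Response column name (default \code{"cstl"}).
#' @param random Grouping factors (default \code{c("sample_id", "arm")}).
#' @return list: \code{covariate}, \code{r2_marginal}, \code{chisq},
#'   \code{df}, \code{p}, \code{log10_p}, and the two fits.
#' @export
covariate_contribution <- function(data, covariate, response = "cstl",
                                   random = c("sample_id", "arm")) {
  f1 <- stats::as.formula(paste(response, "~", covariate))
  f0 <- stats::as.formula(paste(response, "~ 1"))
  fit1 <- cstl_lmm(f1, data, random = random, REML = FALSE)
  fit0 <- cstl_lmm(f0, data, random = random, REML = FALSE)
  test <- lrt(fit1, fit0)
  dec <- pve(fit1)
  list(covariate = covariate,
       r2_marginal = dec$pve[dec$component == "fixed"],
       chisq = test$chisq, df = test$df, p = test$p,
       log10_p = test$log10_p, fit = fit1, null_fit = fit0)
}

#' Test heterogeneity of a covariate's slope across chromosome arms
#'
#' Compares a model with crossed random intercepts to one that
#' additionally lets the covariate's slope vary by arm (random slope
#' variance plus slope-intercept covariance, hence 2 degrees of
#' freedom). Both fits use REML with identical fixed parts. Returns the
#' likelihood-ratio test and the predicted per-arm slopes (fixed slope
#' plus arm-level BLUP deviation).
#'
#' @param data Long arm table.
#' @param fixed Fixed-effects formula (must contain \code{covariate}).
#' @param covariate Covariate whose slope may vary by arm (default
#'   \code{"age"}).
#' @param random Grouping factors; the second is taken as the arm factor
#'   unless \code{arm_factor} is given.
#' @param arm_factor Name of the arm grouping factor.
#' @return list of class \code{cstl_interaction}: \code{chisq},
#'   \code{df} (= 2), \code{p}, \code{log10_p}, \code{slopes} (named
#'   per-arm predicted slopes), \code{boundary}, plus both fits.
#' @export
age_by_arm_interaction <- function(data, fixed = cstl ~ age,
                                   covariate = "age",
                                   random = c("sample_id", "arm"),
                                   arm_factor = "arm") {
  if (!(covariate %in% all.vars(fixed)))
    stop("fixed formula must include the slope covariate '", covariate,
         "'")
  reduced <- cstl_lmm(fixed, data, random = random, REML = TRUE)
  full <- cstl_lmm(fixed, data, random = random,
                   slope = list(factor = arm_factor,
                                covariate = covariate), REML = TRUE)
  test <- lrt(full, reduced)
  fixed_slope <- full$beta[[covariate]]
  re <- full$ranef[[arm_factor]]
  slopes <- fixed_slope + re[, "slope"]
  names(slopes) <- rownames(re)
  out <- list(chisq = test$chisq, df = test$df, p = test$p,
              log10_p = test$log10_p, slopes = slopes,
              boundary = full$boundary, fit = full, reduced = reduced)
  class(out) <- "cstl_interaction"
  out
}

#' @export
print.cstl_interaction <- function(x, ...) {
  cat("Covariate-by-arm slope heterogeneity\n")
  print(structure(x[c("chisq", "df", "p", "log10_p")],
                  class = "cstl_lrt"))
  cat(sprintf("  per-arm predicted slopes: %d arms, range [%.2f, %.2f]\n",
              length(x$slopes), min(x$slopes), max(x$slopes)))
  if (x$boundary)
    cat("  note: slope variance at the zero boundary\n")
  invisible(x)
}

#' Full variance decomposition with component tests
#'
#' Fits the full mixed model (all fixed covariates plus crossed random
#' intercepts) and reports the PVE of each component together with
#' likelihood-ratio tests: each random factor is tested by dropping it
#' from the REML fit; the combined fixed effects by dropping all
#' covariates from the ML fit; and each covariate's marginal
#' contribution by the single-covariate comparison.
#'
#' @param data Long arm table.
#' @param covariates Fixed-effect covariate names.
#' @param response Response column (default \code{"cstl"}).
#' @param random Grouping factors (default \code{c("sample_id", "arm")}).
#' @param batch_mode How to handle batch: \code{"fixed"} (a covariate),
#'   \code{"random"} (an extra crossed intercept factor),
#'   \code{"residualize"} (pre-adjust the response on batch and drop it
#'   from the model).
#' @return Object of class \code{cstl_decomposition}: data.frame with
#'   one row per component (\code{fixed_all}, each random factor, each
#'   covariate, \code{residual}): \code{pve}, \code{chisq}, \code{df},
#'   \code{p}. The full fit is attached as an attribute.
#' @export
variance_decomposition <- function(data, covariates = c("age", "sex",
                                                        "ancestry",
                                                        "smoking", "bmi",
                                                        "batch"),
                                   response = "cstl",
                                   random = c("sample_id", "arm"),
                                   batch_mode = c("fixed", "random",
                                                  "residualize")) {
  batch_mode <- match.arg(batch_mode)
  if (batch_mode == "residualize" && "batch" %in% covariates) {
    data <- residualize_on_batch(data, value = response)
    data[[response]] <- data$cstl_adj
    covariates <- setdiff(covariates, "batch")
  }
  if (batch_mode == "random" && "batch" %in% covariates) {
    covariates <- setdiff(covariates, "batch")
    random <- c(random, "batch")
  }
  ffull <- stats::as.formula(paste(response, "~",
                                   paste(covariates, collapse = " + ")))
  fnull <- stats::as.formula(paste(response, "~ 1"))

  fit_reml <- cstl_lmm(ffull, data, random = random, REML = TRUE)
  dec <- pve(fit_reml)

  rows <- list()
  # combined fixed effects: ML comparison
  fit_ml <- cstl_lmm(ffull, data, random = random, REML = FALSE)
  fit_ml0 <- cstl_lmm(fnull, data, random = random, REML = FALSE)
  t_fixed <- lrt(fit_ml, fit_ml0)
  rows[["fixed_all"]] <- data.frame(
    component = "fixed_all", pve = dec$pve[dec$component == "fixed"],
    chisq = t_fixed$chisq, df = t_fixed$df, p = t_fixed$p,
    log10_p = t_fixed$log10_p, stringsAsFactors = FALSE)
  # each random factor: REML comparison with identical fixed part
  for (g in random) {
    red <- cstl_lmm(ffull, data, random = setdiff(random, g),
                    REML = TRUE)
    tg <- lrt(fit_reml, red)
    rows[[g]] <- data.frame(component = g,
                            pve = dec$pve[dec$component == g],
                            chisq = tg$chisq, df = tg$df, p = tg$p,
                            log10_p = tg$log10_p,
                            stringsAsFactors = FALSE)
  }
  # single-covariate marginal contributions
  for (cv in covariates) {
    cc <- covariate_contribution(data, cv, response = response,
                                 random = random)
    rows[[cv]] <- data.frame(component = cv, pve = cc$r2_marginal,
                             chisq = cc$chisq, df = cc$df, p = cc$p,
                             log10_p = cc$log10_p,
                             stringsAsFactors = FALSE)
  }
  rows[["residual"]] <- data.frame(
    component = "residual", pve = dec$pve[dec$component == "residual"],
    chisq = NA_real_, df = NA_integer_, p = NA_real_,
    log10_p = NA_real_, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cstl_decomposition", "data.frame")
  attr(out, "fit") <- fit_reml
  attr(out, "batch_mode") <- batch_mode
  out
}
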