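# Per-arm association analyses and cross-arm meta-summaries: arm-wise
# regressions, exact one-sided binomial direction tests, one-way ANOVA
# of arm, and arm-level correlations.

#' Per-arm linear regression of csTL on an exposure
#'
#' Fits an ordinary least-squares model independently for each
#' chromosome arm, regressing csTL on the exposure with optional
#' adjusters, and returns the exposure coefficient (bp per exposure
#' unit) with its standard error and two-sided p-value. Arms with fewer
#' records than parameters are omitted with a warning. No multiple-
#' testing adjustment is applied across arms; p-values are per arm.
#'
#' @param arm_table Long arm table with \code{arm}, the exposure and
#'   adjusters.
#' @param exposure Exposure column name.
#' @param adjusters Character vector of adjustment covariates (must not
#'   contain the exposure).
#' @param response Response column (default \code{"cstl"}).
#' @return Object of class \code{arm_assoc}: data.frame with one row per
#'   arm: \code{arm}, \code{beta}, \code{se}, \code{p}, \code{n}.
#' @export
per_arm_ols <- function(arm_table, exposure, adjusters = character(0),
                        response = "cstl") {
  if (exposure %in% adjusters)
    stop("exposure '", exposure, "' is aliased with the adjuster set")
  rhs <- paste(c(exposure, adjusters), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  arms <- unique(as.character(arm_table$arm))
  rows <- lapply(arms, function(a) {
    sub <- droplevels(arm_table[as.character(arm_table$arm) == a, ,
                                drop = FALSE])
    fit <- try(stats::lm(fml, data = sub), silent = TRUE)
    if (inherits(fit, "try-error") || anyNA(stats::coef(fit)))
      return(NULL)
    sm <- summary(fit)$coefficients
    hit <- grep(paste0("^", exposure), rownames(sm), value = TRUE)[1]
    if (is.na(hit) || stats::df.residual(fit) < 1) return(NULL)
    data.frame(arm = a, beta = sm[hit, 1], se = sm[hit, 2],
               p = sm[hit, 4], n = stats::nobs(fit),
               stringsAsFactors = FALSE)
  })
  dropped <- arms[vapply(rows, is.null, logical(1))]
  if (length(dropped))
    warning("arm(s) omitted (too few records for the model): ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(arm = character(), beta = numeric(),
                      se = numeric(), p = numeric(), n = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "exposure") <- exposure
  attr(out, "adjusters") <- adjusters
  class(out) <- c("arm_assoc", "data.frame")
  out
}

#' Exact one-sided binomial test of association direction across arms
#'
#' Tests whether per-arm associations point in one direction more often
#' than chance: with k of n arms in the stated direction, the one-sided
#' exact P is the binomial tail sum over k..n at success probability
#' one half. The reported interval is an exact (Clopper-Pearson style)
#' lower confidence bound with upper bound fixed at 1, matching the
#' one-direction alternative; set \code{ci_sided = "two"} for the
#' two-sided-convention lower bound.
#'
#' @param x An \code{\link{per_arm_ols}} result, or the count of arms in
#'   the stated direction (then \code{n} is required).
#' @param direction \code{"negative"} or \code{"positive"}: the expected
#'   sign of the per-arm coefficients.
#' @param n Number of arms when \code{x} is a count.
#' @param conf_level Confidence level for the lower bound.
#' @param ci_sided \code{"one"} (default) or \code{"two"}.
#' @return Object of class \code{sign_test}: list with \code{n_arms},
#'   \code{n_in_direction}, \code{p_hat}, \code{ci} (lower, 1),
#'   \code{p_value}.
#' @examples
#' st <- sign_binomial(39, n = 39)
#' signif(st$p_value, 1)  # 2e-12
#' @export
sign_binomial <- function(x, direction = c("negative", "positive"),
                          n = NULL, conf_level = 0.95,
                          ci_sided = c("one", "two")) {
  direction <- match.arg(direction)
  ci_sided <- match.arg(ci_sided)
  if (inherits(x, "arm_assoc") || is.data.frame(x)) {
    sgn <- if (direction == "negative") x$beta < 0 else x$beta > 0
    k <- sum(sgn)
    n <- nrow(x)
  } else {
    k <- as.integer(x)
    if (is.null(n)) stop("n (number of arms) required for a count input")
  }
  if (n < 1L) stop("need at least one arm")
  p_value <- stats::binom.test(k, n, p = 0.5,
                               alternative = "greater")$p.value
  alpha <- 1 - conf_level
  a <- if (ci_sided == "one") alpha else alpha / 2
  lower <- if (k == 0L) 0 else stats::qbeta(a, k, n - k + 1)
  out <- list(n_arms = n, n_in_direction = k, p_hat = k / n,
              ci = c(lower = lower, upper = 1), p_value = p_value,
              direction = direction, ci_sided = ci_sided)
  class(out) <- "sign_test"
  out
}

#' @export
print.sign_test <- function(x, ...) {
  cat(sprintf(
    "Exact binomial direction test: %d of %d arms %s\n",
    x$n_in_direction, x$n_arms, x$direction))
  cat(sprintf("  p-hat = %.2g, CI = [%.2g, 1], one-sided P = %.1g\n",
              x$p_hat, x$ci[["lower"]], x$p_value))
  invisible(x)
}

#' One-way ANOVA of csTL on chromosome arm
#'
#' Fixed-effects one-way analysis of variance across arm labels; with
#' the 39 analysis arms the numerator degrees of freedom are 38. Per-arm
#' means are returned for ranking arms by mean csTL.
#'
#' @param arm_table Long arm table.
#' @param response Response column (default \code{"cstl"}).
#' @return list of class \code{arm_anova}: \code{F}, \code{df1},
#'   \code{df2}, \code{p}, \code{means} (named per-arm means).
#' @export
arm_anova <- function(arm_table, response = "cstl") {
  arm <- droplevels(as.factor(arm_table$arm))
  if (nlevels(arm) < 2L) stop("need at least 2 arms")
  y <- arm_table[[response]]
  fit <- stats::lm(y ~ arm)
  av <- stats::anova(fit)
  out <- list(F = av$`F value`[1], df1 = av$Df[1], df2 = av$Df[2],
              p = av$`Pr(>F)`[1],
              means = tapply(y, arm, mean))
  class(out) <- "arm_anova"
  out
}

#' @export
print.arm_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA of csTL on arm: F(%d, %d) = %.1f, P %s\n",
              x$df1, x$df2, x$F,
              if (x$p < 2.2e-16) "< 2.2e-16"
              else paste("=", format(signif(x$p, 2)))))
  rng <- range(x$means)
  cat(sprintf("  per-arm means: %d arms, %.0f-%.0f bp\n",
              length(x$means), rng[1], rng[2]))
  invisible(x)
}

#' Correlate two per-arm vectors
#'
#' Aligns the vectors on their common arm labels (inner join) and
#' computes a Pearson or Spearman correlation with its two-sided
#' p-value. Used for cross-platform comparisons of per-arm coefficients,
#' the arm-mean versus age-slope relation, and rank comparisons against
#' external arm-level orderings.
#'
#' @param x,y Named numeric vectors (names are arm labels).
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return list: \code{estimate}, \code{p}, \code{n}, \code{method}.
#' @export
arm_vector_correlation <- function(x, y, method = c("pearson",
                                                    "spearman")) {
  method <- match.arg(method)
  common <- intersect(names(x), names(y))
  if (length(common) < 3L)
    stop("need at least 3 common arms; found ", length(common))
  ct <- suppressWarnings(
    stats::cor.test(x[common], y[common], method = method,
                    alternative = "two.sided", exact = FALSE))
  list(estimate = unname(ct$estimate), p = ct$p.value,
       n = length(common), method = method)
}
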