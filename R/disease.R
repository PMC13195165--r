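# Disease association: logistic models of disease status on per-person
# TL metrics (mean TL, shortest TL) and on per-arm csTL, with odds
# ratios per 1 kb of telomere length.

#' Per-person TL metrics with outlier exclusion
#'
#' Converts mean and shortest TL to kb and excludes individuals whose
#' mean or shortest TL lies more than \code{sd_bound} standard
#' deviations from the cohort mean. Bounds are computed once on the
#' pre-exclusion cohort (single pass, not iterated).
#'
#' @param summaries \code{\link{sample_summaries}} table.
#' @param sd_bound SD multiple for exclusion (default 3).
#' @return data.frame: \code{sample_id}, \code{mean_tl_kb},
#'   \code{shortest_tl_kb}; the number of excluded individuals is in the
#'   \code{"n_excluded"} attribute.
#' @export
tl_metrics_with_exclusion <- function(summaries, sd_bound = 3) {
  m <- summaries$mean_tl / 1000
  s <- summaries$shortest_tl / 1000
  out_of <- function(x) {
    mu <- mean(x); sd_ <- stats::sd(x)
    if (!is.finite(sd_) || sd_ == 0) return(rep(FALSE, length(x)))
    abs(x - mu) > sd_bound * sd_
  }
  drop <- out_of(m) | out_of(s)
  out <- data.frame(sample_id = summaries$sample_id[!drop],
                    mean_tl_kb = m[!drop], shortest_tl_kb = s[!drop],
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Logistic regression of disease status on a TL metric
#'
#' Maximum-likelihood logistic fit of a binary outcome on a TL metric in
#' kb with optional adjusters; reports the odds ratio per 1 kb increase
#' with a Wald confidence interval. Complete or quasi-complete
#' separation is detected and raised as an error naming the covariate.
#'
#' @param data data.frame containing the outcome, metric and adjusters.
#' @param outcome Binary outcome column name (logical or 0/1).
#' @param metric TL metric column name (kb scale).
#' @param adjusters Adjustment covariate names.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class \code{disease_assoc}: list with \code{metric},
#'   \code{or}, \code{ci}, \code{p}, \code{beta}, \code{se},
#'   \code{n_cases}, \code{n_controls}.
#' @export
logistic_or <- function(data, outcome, metric,
                        adjusters = character(0), conf_level = 0.95) {
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  stopifnot(all(y %in% c(0, 1)))
  rhs <- paste(c(metric, adjusters), collapse = " + ")
  fml <- stats::as.formula(paste("y ~", rhs))
  dat <- cbind(data.frame(y = y), data[, c(metric, adjusters),
                                       drop = FALSE])
  fit <- suppressWarnings(stats::glm(fml, data = dat,
                                     family = stats::binomial()))
  co <- summary(fit)$coefficients
  big <- rownames(co)[abs(co[, 1]) > 15 & rownames(co) != "(Intercept)"]
  mu <- stats::fitted(fit)
  if (length(big) || any(mu < 1e-10) || any(mu > 1 - 1e-10))
    stop("separation detected in logistic model",
         if (length(big)) paste0(" (covariate: ",
                                 paste(big, collapse = ", "), ")"))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  b <- co[metric, 1]; se <- co[metric, 2]
  out <- list(metric = metric, or = exp(b),
              ci = c(lower = exp(b - z * se), upper = exp(b + z * se)),
              p = co[metric, 4], beta = b, se = se,
              n_cases = sum(y == 1), n_controls = sum(y == 0))
  class(out) <- "disease_assoc"
  out
}

#' @export
print.disease_assoc <- function(x, ...) {
  cat(sprintf(
    "Logistic association, %s: OR per 1 kb = %.2f, CI = [%.2f, %.2f], P = %.2g\n",
    x$metric, x$or, x$ci[["lower"]], x$ci[["upper"]], x$p))
  cat(sprintf("  %d cases / %d controls\n", x$n_cases, x$n_controls))
  invisible(x)
}

#' Per-arm disease association
#'
#' For each chromosome arm, fits a logistic model of disease status on
#' that arm's csTL (in kb) with adjusters; each person contributes only
#' to the arms they have estimates for. Arms with fewer than 10 cases
#' are flagged low-power but still reported. Optionally adds a pooled
#' cross-arm mixed-model association of csTL on disease status via
#' \code{\link{cstl_lmm}}.
#'
#' @param arm_table Long arm table with covariates and a disease flag
#'   column.
#' @param outcome Disease flag column name.
#' @param adjusters Adjustment covariate names.
#' @param pooled Also fit the pooled LMM (default FALSE).
#' @return data.frame with one row per arm: \code{arm}, \code{or},
#'   \code{ci_lower}, \code{ci_upper}, \code{p}, \code{n_cases},
#'   \code{low_power}; if \code{pooled}, the LMM fit is attached as the
#'   \code{"pooled_fit"} attribute (disease coefficient in bp).
#' @export
per_arm_disease <- function(arm_table, outcome,
                            adjusters = c("age", "sex", "bmi", "smoking",
                                          "ancestry", "batch"),
                            pooled = FALSE) {
  arm_table$cstl_kb <- arm_table$cstl / 1000
  arms <- unique(as.character(arm_table$arm))
  rows <- lapply(arms, function(a) {
    sub <- droplevels(arm_table[as.character(arm_table$arm) == a, ,
                                drop = FALSE])
    res <- try(logistic_or(sub, outcome, "cstl_kb", adjusters),
               silent = TRUE)
    if (inherits(res, "try-error")) {
      return(data.frame(arm = a, or = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, p = NA_real_,
                        n_cases = sum(sub[[outcome]] %in% c(TRUE, 1)),
                        low_power = TRUE, stringsAsFactors = FALSE))
    }
    data.frame(arm = a, or = res$or, ci_lower = res$ci[["lower"]],
               ci_upper = res$ci[["upper"]], p = res$p,
               n_cases = res$n_cases, low_power = res$n_cases < 10,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (pooled) {
    fml <- stats::as.formula(paste("cstl ~", paste(c(outcome, adjusters),
                                                   collapse = " + ")))
    attr(out, "pooled_fit") <- cstl_lmm(fml, arm_table, REML = TRUE)
  }
  out
}

#' Compose a cardiovascular disease flag from component conditions
#'
#' A CVD case is an individual with hypertension, ischemic heart
#' disease, or heart failure; the composite is the union of the flags,
#' so its prevalence is at least each component's.
#'
#' @param data data.frame with logical component columns.
#' @param components Component flag column names.
#' @return \code{data} with an added logical \code{CVD} column.
#' @export
compose_cvd <- function(data, components = c("hypertension",
                                             "ischemic_heart_disease",
                                             "heart_failure")) {
  present <- intersect(components, names(data))
  if (!length(present)) stop("no component flag columns found")
  flags <- as.matrix(data[, present, drop = FALSE])
  data$CVD <- rowSums(flags, na.rm = TRUE) > 0
  data
}
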