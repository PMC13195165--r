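# S3 methods for cstl_lmm objects.

#' @export
print.cstl_lmm <- function(x, ...) {
  cat("Crossed random-effects linear mixed model (", x$criterion, ")\n",
      sep = "")
  cat("  ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  records: %d, %s\n", x$n,
              paste(sprintf("%s: %d levels", names(x$n_levels),
                            x$n_levels), collapse = ", ")))
  vc <- x$varcomp
  cat("Variance components (bp^2):\n")
  for (i in seq_len(nrow(vc)))
    cat(sprintf("  %-12s %-10s %12.1f\n", vc$term[i], vc$component[i],
                vc$variance[i]))
  cat(sprintf("log-likelihood (%s): %.3f\n", x$criterion, x$logLik))
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  if (x$boundary) cat("note: a variance component is at the zero boundary\n")
  invisible(x)
}

#' @export
summary.cstl_lmm <- function(object, ...) {
  z <- object$beta / object$se
  coefs <- cbind(Estimate = object$beta, `Std. Error` = object$se,
                 `z value` = z,
                 `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(fit = object, coefficients = coefs)
  class(out) <- "summary.cstl_lmm"
  out
}

#' @export
print.summary.cstl_lmm <- function(x, ...) {
  print(x$fit)
  cat("\nFixed effects:\n")
  stats::printCoefmat(x$coefficients, digits = 4, signif.stars = FALSE)
  invisible(x)
}

#' @export
coef.cstl_lmm <- function(object, ...) object$beta

#' @export
vcov.cstl_lmm <- function(object, ...) object$vcov_beta

#' @export
logLik.cstl_lmm <- function(object, ...) {
  structure(object$logLik, df = object$df_model, nobs = object$n,
            class = "logLik")
}

#' @export
fitted.cstl_lmm <- function(object, ...) object$fitted

#' @export
residuals.cstl_lmm <- function(object, ...) object$residuals

#' Extract random-effect predictions (BLUPs)
#'
#' @param object A \code{cstl_lmm} fit.
#' @param ... Unused.
#' @return Named list, one element per grouping factor: a named vector of
#'   intercept predictions, or a levels x (intercept, slope) matrix for a
#'   factor with a random slope.
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @export
ranef.cstl_lmm <- function(object, ...) object$ranef

#' @export
predict.cstl_lmm <- function(object, newdata = NULL,
                             re.form = TRUE, ...) {
  if (is.null(newdata)) {
    return(if (isTRUE(re.form)) object$fitted else object$fitted_fixed)
  }
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
  X <- stats::model.matrix(tt, mf)
  pred <- as.vector(X %*% object$beta[colnames(X)])
  if (!isTRUE(re.form)) return(pred)
  for (g in object$random) {
    re <- object$ranef[[g]]
    lev <- as.character(newdata[[g]])
    if (is.matrix(re)) {
      m <- match(lev, rownames(re))
      contrib <- ifelse(is.na(m), 0, re[m, 1L])
      xcov <- newdata[[object$slope$covariate]] - object$slope_center
      contrib <- contrib + ifelse(is.na(m), 0, re[m, 2L]) * xcov
    } else {
      m <- match(lev, names(re))
      contrib <- ifelse(is.na(m), 0, re[m])
    }
    pred <- pred + contrib
  }
  pred
}

#' Simulate responses from a fitted csTL mixed model
#'
#' Draws new random effects and residuals at the fitted variance
#' components and returns simulated response vectors for the original
#' records.
#'
#' @param object A \code{cstl_lmm} fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return data.frame with \code{nsim} columns, \code{n} rows.
#' @export
simulate.cstl_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  vc <- object$varcomp
  with_seed(seed, {
    out <- replicate(nsim, {
      y <- object$fitted_fixed
      for (g in object$random) {
        re <- object$ranef[[g]]
        if (is.matrix(re)) {
          vi <- vc$variance[vc$term == g & vc$component == "intercept"]
          vs <- vc$variance[vc$term == g & vc$component == "slope"]
          cv <- vc$variance[vc$term == g & vc$component == "covariance"]
          Sg <- matrix(c(vi, cv, cv, vs), 2L)
          ev <- eigen(Sg, symmetric = TRUE)
          rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2L) %*%
            t(ev$vectors)
          bs <- matrix(stats::rnorm(2L * nrow(re)), ncol = 2L) %*% rt
          lev <- rownames(re)
          # reconstruct record-level contribution via stored design info
          idx <- match(object$ranef_index[[g]], lev)
          y <- y + bs[idx, 1L] + bs[idx, 2L] * object$ranef_x[[g]]
        } else {
          vi <- vc$variance[vc$term == g & vc$component == "intercept"]
          bs <- stats::rnorm(length(re), 0, sqrt(vi))
          idx <- match(object$ranef_index[[g]], names(re))
          y <- y + bs[idx]
        }
      }
      y + stats::rnorm(object$n, 0, sqrt(object$sigma2))
    })
    out <- as.data.frame(out)
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}
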