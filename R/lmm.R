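# Gaussian linear mixed models with crossed random effects, fit by
# profiled ML/REML. The variance parameters are relative covariance
# factors (Cholesky scale, relative to the residual SD), optimized by a
# quasi-Newton method with log-parameterization of the diagonal entries
# so non-negativity is enforced; beta and the residual variance are
# profiled out. The n x n covariance is never materialized: all algebra
# runs through the q x q penalized normal equations
#   A = Lambda' Z'Z Lambda + I
# with sparse (or small dense) Cholesky factorizations.

#' Fit a crossed random-effects linear mixed model for csTL
#'
#' Fits y ~ Normal(X beta, V) with
#' V = sigma2_1 Z1 Z1' + ... + sigma2_e I for crossed random intercepts
#' (typically individual and chromosome arm), optionally adding a random
#' slope on a covariate for one factor (slope variance plus
#' slope-intercept covariance). Estimation maximizes the profiled ML or
#' REML objective over the relative covariance parameters; beta is the
#' generalized least squares solution at the optimum.
#'
#' @param fixed Fixed-effects formula, e.g. \code{cstl ~ age + sex +
#'   ancestry + smoking + bmi + batch}. Categorical covariates use their
#'   factor reference levels (set these in the data; cohort tables from
#'   this package use AFR ancestry, female sex, never-smoker and the
#'   largest batch as references).
#' @param data Long data.frame, one row per individual x arm record.
#' @param random Character vector of grouping-factor column names for
#'   random intercepts (default \code{c("sample_id", "arm")}).
#' @param slope Optional random slope: \code{c(factor = "arm",
#'   covariate = "age")}; the factor must appear in \code{random}. The
#'   slope covariate is centered internally for numerical stability.
#' @param REML Use the restricted criterion (default TRUE). Fixed-effect
#'   model comparisons should use \code{REML = FALSE}.
#' @param control List: \code{dense_cutoff} (use dense algebra when the
#'   number of random-effect levels is at most this, default 500),
#'   \code{iter_max}, \code{rel_tol}.
#' @return Object of class \code{cstl_lmm} with components including
#'   \code{beta} (with standard errors in \code{se}), \code{varcomp}
#'   (variance components, bp^2), \code{sigma2} (residual variance),
#'   \code{logLik}, \code{converged}, \code{boundary}, \code{ranef}.
#' @seealso \code{\link{pve}}, \code{\link{lrt}},
#'   \code{\link{covariate_contribution}},
#'   \code{\link{age_by_arm_interaction}}
#' @export
cstl_lmm <- function(fixed, data, random = c("sample_id", "arm"),
                     slope = NULL, REML = TRUE, control = list()) {
  ctrl <- list(dense_cutoff = 500L, iter_max = 300L, rel_tol = 1e-10)
  ctrl[names(control)] <- control
  if (!is.null(slope)) {
    slope <- as.list(slope)
    stopifnot(!is.null(slope$factor), !is.null(slope$covariate))
    if (!(slope$factor %in% random))
      stop("slope factor must be one of the random factors")
  }
  stopifnot(length(random) >= 1L, all(random %in% names(data)))

  needed <- unique(c(all.vars(fixed), random,
                     if (!is.null(slope)) slope$covariate))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("column(s) not in data: ", paste(missing_cols, collapse = ", "))
  cc <- stats::complete.cases(data[, needed, drop = FALSE])
  dat <- data[cc, , drop = FALSE]

  mf <- stats::model.frame(fixed, dat)
  y <- unname(stats::model.response(mf))
  tm <- attr(mf, "terms")
  X <- stats::model.matrix(tm, mf)
  n <- length(y)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("collinear fixed-effect design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }

  # grouping structure
  groups <- lapply(dat[random], function(g) droplevels(as.factor(g)))
  names(groups) <- random
  if (any(vapply(groups, nlevels, 1L) < 2L))
    stop("each random factor needs at least 2 levels")

  blocks <- list()
  zi <- integer(0); zj <- integer(0); zx <- numeric(0)
  col0 <- 0L
  slope_x <- NULL
  for (g in random) {
    f <- groups[[g]]
    L <- nlevels(f)
    if (!is.null(slope) && identical(g, slope$factor)) {
      xcov <- dat[[slope$covariate]]
      slope_x <- xcov - mean(xcov)
      icol <- col0 + 2L * (as.integer(f) - 1L) + 1L
      zi <- c(zi, seq_len(n), seq_len(n))
      zj <- c(zj, icol, icol + 1L)
      zx <- c(zx, rep(1, n), slope_x)
      blocks[[g]] <- list(type = "intslope", factor = g,
                          levels = levels(f),
                          cols = col0 + seq_len(2L * L), npar = 3L)
      col0 <- col0 + 2L * L
    } else {
      zi <- c(zi, seq_len(n))
      zj <- c(zj, col0 + as.integer(f))
      zx <- c(zx, rep(1, n))
      blocks[[g]] <- list(type = "int", factor = g, levels = levels(f),
                          cols = col0 + seq_len(L), npar = 1L)
      col0 <- col0 + L
    }
  }
  q <- col0
  Z <- Matrix::sparseMatrix(i = zi, j = zj, x = zx, dims = c(n, q))

  dense <- q <= ctrl$dense_cutoff
  ZtZ <- Matrix::forceSymmetric(Matrix::crossprod(Z))
  ZtX <- Matrix::crossprod(Z, X)
  Zty <- as.vector(Matrix::crossprod(Z, y))
  XtX <- crossprod(X)
  Xty <- as.vector(crossprod(X, y))
  yty <- sum(y^2)
  pre <- list(ZtZ = if (dense) as.matrix(ZtZ) else ZtZ,
              ZtZsp = ZtZ, ZtX = as.matrix(ZtX), Zty = Zty,
              XtX = XtX, Xty = Xty, yty = yty,
              blocks = blocks, dense = dense, n = n, p = p, q = q,
              REML = REML, diag_only = is.null(slope))

  npar <- sum(vapply(blocks, function(b) b$npar, 1L))
  par0 <- numeric(npar)
  lower <- rep(-12, npar); upper <- rep(12, npar)
  k <- 0L
  for (b in blocks) {
    if (b$type == "intslope") {
      lower[k + 2L] <- -1e3; upper[k + 2L] <- 1e3  # covariance term free
    }
    k <- k + b$npar
  }

  objective <- function(par) lmm_deviance(par, pre)$dev
  opt <- stats::nlminb(par0, objective, lower = lower, upper = upper,
                       control = list(iter.max = ctrl$iter_max,
                                      rel.tol = ctrl$rel_tol))
  par_hat <- opt$par
  pieces <- lmm_deviance(par_hat, pre, extras = TRUE)

  # numerical gradient at the optimum (central differences)
  h <- 1e-4
  grad <- vapply(seq_len(npar), function(i) {
    e <- numeric(npar); e[i] <- h
    (lmm_deviance(pmin(pmax(par_hat + e, lower), upper), pre)$dev -
       lmm_deviance(pmin(pmax(par_hat - e, lower), upper), pre)$dev) /
      (2 * h)
  }, numeric(1))
  at_bound <- par_hat <= lower + 1e-6 | par_hat >= upper - 1e-6
  grad_ok <- all(abs(grad[!at_bound]) < 1e-2 * max(1, abs(pieces$dev)))
  converged <- (opt$convergence == 0) || grad_ok

  dfree <- if (REML) n - p else n
  sigma2 <- pieces$r2 / dfree
  vc <- theta_to_varcomp(par_hat, blocks, sigma2)
  boundary <- any(vapply(seq_len(npar), function(i) {
    par_hat[i] <= -11.5 && !identical(lower[i], -1e3)
  }, logical(1)))

  beta <- as.vector(pieces$beta)
  names(beta) <- colnames(X)
  Sinv <- chol2inv(chol(pieces$S))
  vcov_beta <- sigma2 * Sinv
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))

  b_hat <- as.vector(pieces$b)
  ranef <- list()
  for (bk in blocks) {
    if (bk$type == "int") {
      v <- b_hat[bk$cols]
      names(v) <- bk$levels
      ranef[[bk$factor]] <- v
    } else {
      m <- matrix(b_hat[bk$cols], ncol = 2L, byrow = TRUE,
                  dimnames = list(bk$levels, c("(Intercept)",
                                               "slope")))
      ranef[[bk$factor]] <- m
    }
  }
  fitted_fixed <- as.vector(X %*% beta)
  fitted_all <- fitted_fixed + as.vector(Z %*% b_hat)

  out <- list(call = match.call(), formula = fixed, terms = tm,
              xlevels = stats::.getXlevels(tm, mf),
              random = random, slope = slope,
              slope_center = if (!is.null(slope))
                mean(dat[[slope$covariate]]) else NULL,
              REML = REML, criterion = if (REML) "REML" else "ML",
              n = n, p = p, q = q,
              n_levels = vapply(groups, nlevels, 1L),
              fixed_names = colnames(X),
              beta = beta, se = sqrt(diag(vcov_beta)),
              vcov_beta = vcov_beta,
              varcomp = vc, sigma2 = sigma2,
              theta = par_hat, deviance = pieces$dev,
              logLik = -pieces$dev / 2,
              df_model = p + npar + 1L,
              converged = converged, boundary = boundary,
              opt = list(convergence = opt$convergence,
                         message = opt$message, gradient = grad,
                         iterations = opt$iterations),
              ranef = ranef,
              ranef_index = lapply(groups, as.character),
              ranef_x = if (!is.null(slope))
                stats::setNames(list(slope_x), slope$factor) else list(),
              fitted_fixed = fitted_fixed, fitted = fitted_all,
              residuals = y - fitted_all, y_name = deparse(fixed[[2]]))
  class(out) <- "cstl_lmm"
  out
}

# Relative covariance factor Lambda (q x q, lower triangular) from the
# unconstrained parameter vector: diagonal entries exp(par), the
# slope-intercept covariance entry raw.
build_lambda <- function(par, blocks, q) {
  di <- rep(1, q)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  k <- 0L
  for (b in blocks) {
    if (b$type == "int") {
      di[b$cols] <- exp(par[k + 1L])
      k <- k + 1L
    } else {
      ti <- exp(par[k + 1L]); cv <- par[k + 2L]; ts <- exp(par[k + 3L])
      icols <- b$cols[seq(1L, length(b$cols), by = 2L)]
      scols <- b$cols[seq(2L, length(b$cols), by = 2L)]
      di[icols] <- ti
      di[scols] <- ts
      ii <- c(ii, scols); jj <- c(jj, icols)
      xx <- c(xx, rep(cv, length(icols)))
      k <- k + 3L
    }
  }
  Matrix::sparseMatrix(i = c(seq_len(q), ii), j = c(seq_len(q), jj),
                       x = c(di, xx), dims = c(q, q))
}

# Profiled deviance (-2 log likelihood, ML or REML) and, optionally, the
# solution pieces at the given variance parameters.
lmm_deviance <- function(par, pre, extras = FALSE) {
  n <- pre$n; p <- pre$p; q <- pre$q
  if (pre$diag_only) {
    # diagonal Lambda: scale rows/cols directly
    d <- rep(1, q)
    k <- 0L
    for (b in pre$blocks) { d[b$cols] <- exp(par[k + 1L]); k <- k + 1L }
    if (pre$dense) {
      A <- pre$ZtZ * tcrossprod(d)
      diag(A) <- diag(A) + 1
      cu <- d * pre$Zty
      B <- d * pre$ZtX
    } else {
      D <- Matrix::Diagonal(x = d)
      A <- D %*% pre$ZtZ %*% D + Matrix::Diagonal(q)
      cu <- d * pre$Zty
      B <- d * pre$ZtX
    }
    Lam <- NULL
  } else {
    Lam <- build_lambda(par, pre$blocks, q)
    A <- Matrix::crossprod(Lam, pre$ZtZsp %*% Lam) +
      Matrix::Diagonal(q)
    cu <- as.vector(Matrix::crossprod(Lam, pre$Zty))
    B <- as.matrix(Matrix::crossprod(Lam, pre$ZtX))
    if (pre$dense) A <- as.matrix(A)
  }

  if (pre$dense) {
    U <- chol(A)
    logdetA <- 2 * sum(log(diag(U)))
    su <- forwardsolve(t(U), cu)
    Vb <- forwardsolve(t(U), B)
    quad_u <- sum(su^2)
    BtAiB <- crossprod(Vb)
    BtAicu <- as.vector(crossprod(Vb, su))
  } else {
    A <- Matrix::forceSymmetric(A)
    ch <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
    logdetA <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
    Aicu <- as.vector(Matrix::solve(ch, cu, system = "A"))
    AiB <- as.matrix(Matrix::solve(ch, B, system = "A"))
    quad_u <- sum(cu * Aicu)
    BtAiB <- crossprod(as.matrix(B), AiB)
    BtAicu <- as.vector(crossprod(as.matrix(B), Aicu))
  }

  S <- pre$XtX - BtAiB
  S <- (S + t(S)) / 2
  Rx <- chol(S)
  logdetS <- 2 * sum(log(diag(Rx)))
  tvec <- pre$Xty - BtAicu
  beta <- backsolve(Rx, forwardsolve(t(Rx), tvec))
  r2 <- max(pre$yty - quad_u - sum(tvec * beta), 1e-10)

  dev <- if (pre$REML) {
    logdetA + logdetS + (n - p) * (1 + log(2 * pi * r2 / (n - p)))
  } else {
    logdetA + n * (1 + log(2 * pi * r2 / n))
  }
  if (!extras) return(list(dev = dev))

  # random-effect solution u*: A u = cu - B beta, then b = Lambda u
  rhs <- cu - as.vector(B %*% beta)
  if (pre$dense) {
    u <- backsolve(U, forwardsolve(t(U), rhs))
  } else {
    u <- as.vector(Matrix::solve(ch, rhs, system = "A"))
  }
  b <- if (pre$diag_only) {
    d <- rep(1, q); k <- 0L
    for (bk in pre$blocks) { d[bk$cols] <- exp(par[k + 1L]); k <- k + 1L }
    d * u
  } else as.vector(Lam %*% u)
  list(dev = dev, logdetA = logdetA, logdetS = logdetS, r2 = r2,
       beta = beta, S = S, b = b)
}

# Map fitted relative-covariance parameters to variance components.
theta_to_varcomp <- function(par, blocks, sigma2) {
  rows <- list()
  k <- 0L
  for (b in blocks) {
    if (b$type == "int") {
      rows[[length(rows) + 1L]] <-
        data.frame(term = b$factor, component = "intercept",
                   variance = sigma2 * exp(par[k + 1L])^2,
                   stringsAsFactors = FALSE)
      k <- k + 1L
    } else {
      ti <- exp(par[k + 1L]); cv <- par[k + 2L]; ts <- exp(par[k + 3L])
      rows[[length(rows) + 1L]] <-
        data.frame(term = rep(b$factor, 3L),
                   component = c("intercept", "slope", "covariance"),
                   variance = sigma2 * c(ti^2, cv^2 + ts^2, ti * cv),
                   stringsAsFactors = FALSE)
      k <- k + 3L
    }
  }
  out <- do.call(rbind, rows)
  rbind(out, data.frame(term = "residual", component = "residual",
                        variance = sigma2, stringsAsFactors = FALSE))
}
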