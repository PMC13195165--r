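# Shared fixtures and independent oracles for the test suite.
# Everything here is built in code at test time; no stored data.

# small crossed-design dataset with known structure
make_crossed_data <- function(n_ind = 30, n_arm = 6, sd_ind = 1.3,
                              sd_arm = 1.1, sd_e = 1, beta_x = 0.8,
                              seed = 1) {
  set.seed(seed)
  d <- expand.grid(sample_id = sprintf("i%03d", seq_len(n_ind)),
                   arm = sprintf("a%02d", seq_len(n_arm)),
                   stringsAsFactors = TRUE)
  x_i <- stats::rnorm(n_ind)
  d$x <- x_i[as.integer(d$sample_id)]
  d$y <- 2 + beta_x * d$x +
    stats::rnorm(n_ind, 0, sd_ind)[as.integer(d$sample_id)] +
    stats::rnorm(n_arm, 0, sd_arm)[as.integer(d$arm)] +
    stats::rnorm(nrow(d), 0, sd_e)
  d
}

# Independent dense multivariate-normal log-likelihood oracle. Builds
# the full n x n covariance from the fitted variance components and
# evaluates the (restricted) Gaussian log-likelihood directly, with its
# own GLS solution for beta.
dense_loglik_oracle <- function(fit, data, fixed, random) {
  X <- stats::model.matrix(fixed, data)
  y <- stats::model.response(stats::model.frame(fixed, data))
  n <- nrow(X); p <- ncol(X)
  vc <- fit$varcomp
  V <- diag(fit$sigma2, n)
  for (g in random) {
    Zg <- stats::model.matrix(~ 0 + factor(data[[g]]))
    vg <- vc$variance[vc$term == g & vc$component == "intercept"]
    V <- V + vg * tcrossprod(Zg)
  }
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  quad <- as.numeric(t(r) %*% Vi %*% r)
  ldV <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  if (fit$REML) {
    ldS <- as.numeric(determinant(XtViX, logarithm = TRUE)$modulus)
    -0.5 * ((n - p) * log(2 * pi) + ldV + ldS + quad)
  } else {
    -0.5 * (n * log(2 * pi) + ldV + quad)
  }
}

# exact binomial tail oracle: P(K >= k) for K ~ Binomial(n, 1/2),
# written as an explicit sum over binomial coefficients
binom_tail_oracle <- function(k, n) {
  sum(exp(lchoose(n, k:n) - n * log(2)))
}

# brute-force enumeration oracle over all 2^n sign sequences
binom_tail_enumeration <- function(k, n) {
  stopifnot(n <= 15)
  signs <- as.matrix(expand.grid(rep(list(0:1), n)))
  mean(rowSums(signs) >= k)
}

# type-7 quantile oracle written out as the interpolation formula
quantile75_oracle <- function(x) {
  x <- sort(x)
  h <- (length(x) - 1) * 0.75
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[min(lo + 2, length(x))] - x[lo + 1])
}

# small cohort configs used across tests
tiny_config <- function(n = 30, seed = 1, ...) {
  sim_config(n_individuals = n, seed = seed, ...)
}
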