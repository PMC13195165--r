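# Internal helpers shared across the package.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so simulation helpers do not disturb the session.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Center x and rescale to an exact sample standard deviation.
# Degenerate inputs (no spread, or a zero target) map to all-zero effects.
scale_to_sd <- function(x, sd_target) {
  if (length(x) < 2L || sd_target <= 0) return(rep(0, length(x)))
  s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps) return(rep(0, length(x)))
  (x - mean(x)) / s * sd_target
}

# Vectorised grouped type-7 75th percentile. `group` must be an integer
# code vector; returns one value per distinct code, named by code order.
group_quantile75 <- function(values, group) {
  stopifnot(length(values) == length(group))
  o <- order(group, values)
  g <- group[o]
  v <- values[o]
  ends <- cumsum(tabulate(match(g, unique(g))))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  n <- ends - starts + 1L
  h <- (n - 1) * 0.75
  lo <- floor(h)
  frac <- h - lo
  i_lo <- starts + lo
  i_hi <- pmin(i_lo + 1L, ends)
  out <- v[i_lo] * (1 - frac) + v[i_hi] * frac
  names(out) <- unique(g)
  out
}

# Stable per-stage seed derivation from a master seed (kept < 2^31).
stage_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) + 7919 * h) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
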