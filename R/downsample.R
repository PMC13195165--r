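# Coverage titration: thin read sets to target telomeric coverage and
# quantify csTL estimation error and call completeness versus coverage.

#' Thin a read table to a target telomeric coverage
#'
#' Telomeric coverage is the mean number of supporting reads per
#' telomeric site (92 sites per diploid individual). Each read is kept
#' independently with probability target/current, per sample, so thinned
#' reads are an exact subset of the input with unchanged values.
#'
#' @param reads Read table (\code{\link{emit_reads}}).
#' @param target Target coverage (reads per site).
#' @param seed Seed for the Bernoulli thinning.
#' @param n_sites Sites per individual used in the coverage denominator.
#' @return The retained read subset.
#' @export
thin_to_coverage <- function(reads, target, seed = 1L, n_sites = 92L) {
  counts <- table(reads$sample_id)
  current <- as.numeric(counts) / n_sites
  names(current) <- names(counts)
  if (any(current < target)) {
    low <- names(current)[current < target]
    stop("target coverage ", target, "x exceeds current coverage for ",
         length(low), " sample(s), e.g. ", low[1], " (",
         signif(min(current), 3), "x)")
  }
  frac <- target / current
  frac[frac > 1] <- 1
  with_seed(seed, {
    keep <- stats::runif(nrow(reads)) < unname(frac[reads$sample_id])
    keep[is.na(keep)] <- FALSE
    out <- reads[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Error and completeness profile across down-sampled coverages
#'
#' For each thinned call set, compares csTL estimates with the
#' high-coverage estimates on arms present in both (mean absolute error
#' and Pearson correlation), and reports call completeness (mean arms per
#' sample, shared-arm count). Sets with no shared arms are flagged with
#' undefined (NA) error rather than silently zero.
#'
#' @param full_calls High-coverage collapsed arm table.
#' @param thinned_call_sets Named list of collapsed arm tables; names are
#'   taken as coverage labels (or supply \code{targets}).
#' @param targets Optional numeric coverages aligned with the list.
#' @return data.frame of class \code{coverage_profile}: one row per set
#'   with \code{target_coverage}, \code{mean_abs_error}, \code{pearson_r},
#'   \code{n_arms_mean}, \code{n_shared_arms}, \code{undefined}.
#' @export
coverage_error_profile <- function(full_calls, thinned_call_sets,
                                   targets = NULL) {
  if (is.null(targets)) {
    targets <- suppressWarnings(as.numeric(names(thinned_call_sets)))
  }
  stopifnot(length(targets) == length(thinned_call_sets))
  full_key <- paste(full_calls$sample_id, full_calls$arm, sep = "\r")
  rows <- lapply(seq_along(thinned_call_sets), function(i) {
    th <- thinned_call_sets[[i]]
    m <- match(paste(th$sample_id, th$arm, sep = "\r"), full_key)
    shared <- !is.na(m)
    n_shared <- sum(shared)
    if (n_shared == 0L) {
      return(data.frame(target_coverage = targets[i],
                        mean_abs_error = NA_real_, pearson_r = NA_real_,
                        n_arms_mean = 0, n_shared_arms = 0L,
                        undefined = TRUE))
    }
    d <- th$cstl[shared] - full_calls$cstl[m[shared]]
    r <- if (n_shared >= 3L &&
             stats::sd(th$cstl[shared]) > 0 &&
             stats::sd(full_calls$cstl[m[shared]]) > 0) {
      stats::cor(th$cstl[shared], full_calls$cstl[m[shared]])
    } else NA_real_
    data.frame(target_coverage = targets[i],
               mean_abs_error = mean(abs(d)),
               pearson_r = r,
               n_arms_mean = nrow(th) / length(unique(th$sample_id)),
               n_shared_arms = n_shared,
               undefined = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$target_coverage), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("coverage_profile", "data.frame")
  out
}

#' Run a full coverage titration experiment
#'
#' Thins a read set to each target coverage, re-estimates csTLs with the
#' same collapse procedure as the full data, and profiles error and
#' completeness versus coverage.
#'
#' @param reads Read table at high coverage.
#' @param targets Coverage targets, e.g. \code{c(25, 20, 15, 10, 5)}.
#' @param min_reads Minimum supporting reads per allele cluster.
#' @param seed Seed; each target is thinned with a seed derived from it.
#' @param mode Arm exclusion mode applied to all call sets.
#' @return \code{\link{coverage_error_profile}} result.
#' @export
run_downsampling <- function(reads, targets = c(25, 20, 15, 10, 5),
                             min_reads = 3, seed = 1L,
                             mode = "analysis") {
  collapse <- function(r) {
    exclude_arms(collapse_to_arm(r, min_reads = min_reads), mode)
  }
  full <- collapse(reads)
  sets <- lapply(seq_along(targets), function(i) {
    collapse(thin_to_coverage(reads, targets[i],
                              seed = stage_seed(seed, paste0("thin", i))))
  })
  names(sets) <- targets
  coverage_error_profile(full, sets, targets)
}
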