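# Telomere call tables: one row per allele cluster with the 75th-
# percentile TL estimate, the telomere-variant-repeat (TVR) length and
# the number of supporting reads. All lengths in bp; TSV, UTF-8, header
# required.

call_columns <- c("sample_id", "arm", "allele", "tl_p75_bp", "tvr_len_bp",
                  "n_supporting_reads")

#' Read and write telomere call tables
#'
#' Tab-separated, header required; the canonical columns are
#' \code{sample_id}, \code{arm}, \code{allele}, \code{tl_p75_bp},
#' \code{tvr_len_bp}, \code{n_supporting_reads}, plus an optional logical
#' \code{mapping_ambiguous}. Unknown columns are preserved, so
#' \code{write_calls} then \code{read_calls} round-trips the table.
#' Malformed rows (non-numeric lengths, supporting read count < 1) are
#' dropped with a warning naming their line numbers.
#'
#' @param path File path.
#' @return \code{read_calls} returns a data.frame of calls.
#' @export
read_calls <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(call_columns, names(tab))
  if (length(missing_cols))
    stop("call table format error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!nrow(tab)) return(tab)
  for (col in c("tl_p75_bp", "tvr_len_bp", "n_supporting_reads"))
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  # negative TVR lengths are a QC matter, not a format error
  bad <- !is.finite(tab$tl_p75_bp) | tab$tl_p75_bp < 0 |
    !is.finite(tab$tvr_len_bp) |
    !is.finite(tab$n_supporting_reads) | tab$n_supporting_reads < 1
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    # +1 for the header line
    warning("rejected ", sum(bad), " malformed call row(s) at line(s): ",
            paste(which(bad) + 1L, collapse = ", "))
    tab <- tab[!bad, , drop = FALSE]
    rownames(tab) <- NULL
  }
  if (is.null(tab$mapping_ambiguous)) tab$mapping_ambiguous <- FALSE
  tab$mapping_ambiguous <- as.logical(tab$mapping_ambiguous)
  tab
}

#' @rdname read_calls
#' @param calls A call table.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Quality-filter telomere calls
#'
#' Retains calls with a TL estimate of at least 100 bp (estimates shorter
#' than 100 bp are excluded), a non-negative TVR length (negative values
#' are artifacts of the TVR boundary search), and an unambiguous
#' chromosome-arm assignment. Idempotent.
#'
#' @param calls Call table (see \code{\link{read_calls}}).
#' @return The retained subset, a data.frame.
#' @examples
#' calls <- data.frame(sample_id = "s", arm = "1p", allele = 1,
#'                     tl_p75_bp = c(99, 100, 101), tvr_len_bp = 0,
#'                     n_supporting_reads = 5, mapping_ambiguous = FALSE)
#' nrow(qc_filter(calls))  # 2
#' @export
qc_filter <- function(calls) {
  amb <- calls$mapping_ambiguous %||% rep(FALSE, nrow(calls))
  amb[is.na(amb)] <- FALSE
  keep <- calls$tl_p75_bp >= 100 & calls$tvr_len_bp >= 0 & !amb
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reduce a read-level table to per-allele telomere calls
#'
#' Each allele cluster's TL estimate is the type-7 (linear interpolation)
#' 75th percentile of its supporting reads' telomere lengths; clusters
#' with fewer supporting reads than the minimum are not emitted. TVR
#' length is not modelled at read level and is reported as 0.
#'
#' @param reads Read table: \code{sample_id}, \code{arm}, \code{allele},
#'   \code{read_tl_bp} (and optionally \code{read_len_bp}).
#' @param min_reads Minimum supporting reads per cluster: a single count,
#'   or a named vector by sample id for tiered thresholds.
#' @return Call table as in \code{\link{read_calls}}.
#' @export
reads_to_calls <- function(reads, min_reads = 3) {
  if (!nrow(reads)) {
    return(data.frame(sample_id = character(), arm = character(),
                      allele = integer(), tl_p75_bp = numeric(),
                      tvr_len_bp = numeric(),
                      n_supporting_reads = integer(),
                      mapping_ambiguous = logical()))
  }
  key <- paste(reads$sample_id, reads$arm, reads$allele, sep = "\r")
  code <- match(key, unique(key))
  # order groups by code so group_quantile75's output aligns
  p75 <- group_quantile75(reads$read_tl_bp, code)
  nsup <- as.integer(table(code)[as.character(sort(unique(code)))])
  first <- !duplicated(code)
  ord <- order(code[first])
  meta <- reads[first, c("sample_id", "arm", "allele")][ord, , drop = FALSE]
  thr <- if (length(min_reads) > 1L) {
    unname(min_reads[meta$sample_id])
  } else rep(min_reads, nrow(meta))
  thr[is.na(thr)] <- max(min_reads)
  out <- data.frame(meta, tl_p75_bp = unname(p75), tvr_len_bp = 0,
                    n_supporting_reads = nsup,
                    mapping_ambiguous = FALSE,
                    stringsAsFactors = FALSE)
  out <- out[out$n_supporting_reads >= thr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse allele-level calls to one csTL per sample and arm
#'
#' When two or more allele estimates are available for an arm they are
#' averaged (arithmetic mean); a single estimate is used as is. Accepts
#' either an allele-level call table or a read-level table (which is
#' first reduced with \code{\link{reads_to_calls}}).
#'
#' @param x Call table or read table.
#' @param min_reads Passed to \code{\link{reads_to_calls}} when \code{x}
#'   is read-level.
#' @return Arm table: \code{sample_id}, \code{arm}, \code{cstl},
#'   \code{n_allele_estimates}, \code{n_supporting_reads}.
#' @examples
#' calls <- data.frame(sample_id = "s", arm = "7q", allele = 1:2,
#'                     tl_p75_bp = c(4000, 6000), tvr_len_bp = 0,
#'                     n_supporting_reads = 5)
#' collapse_to_arm(calls)$cstl  # 5000
#' @export
collapse_to_arm <- function(x, min_reads = 3) {
  if ("read_tl_bp" %in% names(x)) x <- reads_to_calls(x, min_reads)
  if (!nrow(x)) {
    return(data.frame(sample_id = character(), arm = character(),
                      cstl = numeric(), n_allele_estimates = integer(),
                      n_supporting_reads = integer()))
  }
  key <- paste(x$sample_id, x$arm, sep = "\r")
  code <- match(key, unique(key))
  sums <- rowsum(x$tl_p75_bp, code)
  counts <- rowsum(rep(1L, nrow(x)), code)
  nsup <- rowsum(as.numeric(x$n_supporting_reads), code)
  ucode <- as.integer(rownames(sums))
  first <- !duplicated(code)
  ord <- order(code[first])
  meta <- x[first, c("sample_id", "arm")][ord, , drop = FALSE]
  out <- data.frame(meta,
                    cstl = as.vector(sums)[ucode] / as.vector(counts)[ucode],
                    n_allele_estimates = as.integer(counts)[ucode],
                    n_supporting_reads = as.integer(nsup)[ucode],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Resolve individuals sequenced on more than one platform or run
#'
#' Keeps exactly one run's calls per individual: PacBio platforms are
#' preferred over ONT; among PacBio runs, the run with more distinct arm
#' estimates wins; remaining ties break lexicographically by platform
#' name then run id, so the resolution is deterministic.
#'
#' @param calls Call table whose \code{sample_id} identifies a run.
#' @param metadata data.frame with columns \code{sample_id},
#'   \code{individual_id}, \code{platform} (\code{"ONT"} or a PacBio
#'   platform name), and optionally \code{run_id} (defaults to
#'   \code{sample_id}).
#' @return The call subset for the retained runs.
#' @export
resolve_duplicate_samples <- function(calls, metadata) {
  stopifnot(all(c("sample_id", "individual_id", "platform") %in%
                  names(metadata)))
  if (is.null(metadata$run_id)) metadata$run_id <- metadata$sample_id
  n_arms <- tapply(calls$arm, calls$sample_id,
                   function(a) length(unique(a)))
  metadata$n_arms <- as.integer(n_arms[metadata$sample_id])
  metadata$n_arms[is.na(metadata$n_arms)] <- 0L
  keep <- unlist(lapply(split(metadata, metadata$individual_id),
                        function(m) {
    if (nrow(m) > 2L)
      stop("individual ", m$individual_id[1], " has ", nrow(m),
           " runs; only duplicate (two-run) individuals are modeled")
    if (nrow(m) == 1L) return(m$sample_id)
    is_pacbio <- m$platform != "ONT"
    if (sum(is_pacbio) == 1L) return(m$sample_id[is_pacbio])
    # same platform class: more arm estimates wins, then lexicographic
    o <- order(-m$n_arms, m$platform, m$run_id)
    m$sample_id[o[1]]
  }), use.names = FALSE)
  out <- calls[calls$sample_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude chromosome arms from an arm table
#'
#' Mode \code{"acrocentric_p"} removes the acrocentric short arms (13p,
#' 14p, 15p, 21p, 22p); mode \code{"analysis"} additionally removes the
#' sex-chromosome arms, leaving the 39 autosomal analysis arms. Samples
#' left without any arm are dropped and counted in the
#' \code{"n_samples_dropped"} attribute.
#'
#' @param table Arm table (any data.frame with \code{sample_id} and
#'   \code{arm}).
#' @param mode \code{"analysis"} or \code{"acrocentric_p"}.
#' @return Filtered table.
#' @export
exclude_arms <- function(table, mode = c("analysis", "acrocentric_p")) {
  mode <- match.arg(mode)
  drop <- acrocentric_p_arms()
  if (mode == "analysis") drop <- c(drop, sex_chromosome_arms())
  out <- table[!(as.character(table$arm) %in% drop), , drop = FALSE]
  lost <- setdiff(unique(table$sample_id), unique(out$sample_id))
  if (length(lost))
    message(length(lost), " sample(s) dropped: no arms left after '",
            mode, "' exclusion")
  rownames(out) <- NULL
  attr(out, "n_samples_dropped") <- length(lost)
  out
}

#' Per-sample telomere summaries
#'
#' Telomeric coverage (total supporting reads), number of arms with an
#' estimate, mean TL across measured arms, and the shortest TL (the
#' minimum csTL per individual, a candidate disease biomarker).
#'
#' @param arm_table Collapsed arm table (\code{\link{collapse_to_arm}} or
#'   \code{\link{true_arm_table}}).
#' @return data.frame: \code{sample_id}, \code{telomeric_coverage},
#'   \code{n_arms_with_estimate}, \code{mean_tl}, \code{shortest_tl}.
#' @export
sample_summaries <- function(arm_table) {
  ids <- unique(arm_table$sample_id)
  code <- match(arm_table$sample_id, ids)
  cov <- if (!is.null(arm_table$n_supporting_reads)) {
    as.vector(rowsum(as.numeric(arm_table$n_supporting_reads), code))
  } else rep(NA_real_, length(ids))
  data.frame(
    sample_id = ids,
    telomeric_coverage = cov,
    n_arms_with_estimate = as.vector(rowsum(rep(1L, nrow(arm_table)),
                                            code)),
    mean_tl = as.vector(rowsum(arm_table$cstl, code)) /
      as.vector(rowsum(rep(1, nrow(arm_table)), code)),
    shortest_tl = as.vector(tapply(arm_table$cstl, code, min)),
    stringsAsFactors = FALSE)
}

#' Per-arm call rate
#'
#' Proportion of samples with a csTL estimate for each chromosome arm,
#' optionally within groups (e.g. batches). Arms with no estimate in a
#' group report 0.
#'
#' @param arm_table Collapsed arm table.
#' @param group Optional vector of group labels aligned with
#'   \code{arm_table} rows, or the name of a column in \code{arm_table}.
#' @param arms Arm universe (default the 48 collapsed labels).
#' @return data.frame: \code{group}, \code{arm}, \code{call_rate}.
#' @export
arm_call_rate <- function(arm_table, group = NULL, arms = arm_labels()) {
  if (is.character(group) && length(group) == 1L &&
      group %in% names(arm_table)) group <- arm_table[[group]]
  if (is.null(group)) group <- rep("all", nrow(arm_table))
  group <- as.character(group)
  out <- do.call(rbind, lapply(unique(group), function(g) {
    sub <- arm_table[group == g, , drop = FALSE]
    n <- length(unique(sub$sample_id))
    hits <- table(factor(as.character(sub$arm), levels = arms))
    data.frame(group = g, arm = arms,
               call_rate = if (n > 0) as.vector(hits) / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
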