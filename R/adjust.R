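# Batch adjustment: depth-PC residualization of average TL with
# data-driven PC count, and categorical-batch residualization of csTL.

#' Principal components of a binned sequencing-depth matrix
#'
#' Bins with zero variance are dropped, the remaining bins are
#' standardized (z-scored by default) and decomposed by singular values;
#' scores are ordered by decreasing explained variance and are mutually
#' orthogonal.
#'
#' @param depth_matrix Samples x bins numeric matrix (>= 2 samples).
#' @param n_components Number of components to return (default all).
#' @param scale. Standardize bins before the SVD (default TRUE).
#' @return Object of class \code{depth_pcs}: list with \code{scores}
#'   (samples x k), \code{sdev}, \code{var_explained}, \code{rotation}.
#' @export
depth_pcs <- function(depth_matrix, n_components = NULL, scale. = TRUE) {
  X <- as.matrix(depth_matrix)
  if (nrow(X) < 2L) stop("need at least 2 samples")
  v <- apply(X, 2L, stats::var)
  X <- X[, v > .Machine$double.eps, drop = FALSE]
  X <- scale(X, center = TRUE, scale = scale.)
  kmax <- min(dim(X))
  if (is.null(n_components)) n_components <- kmax
  if (n_components > kmax)
    stop("n_components (", n_components, ") exceeds min(samples, bins) = ",
         kmax)
  sv <- svd(X, nu = n_components, nv = n_components)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)],
                          nrow = n_components)
  rownames(scores) <- rownames(depth_matrix)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  out <- list(scores = scores,
              sdev = sv$d / sqrt(nrow(X) - 1),
              var_explained = sv$d^2 / sum(sv$d^2),
              rotation = sv$v)
  class(out) <- "depth_pcs"
  out
}

#' @export
print.depth_pcs <- function(x, ...) {
  k <- ncol(x$scores)
  cat(sprintf("Depth principal components: %d samples x %d components\n",
              nrow(x$scores), k))
  ve <- utils::head(x$var_explained, min(5, k))
  cat("  leading variance fractions:",
      paste(sprintf("%.3f", ve), collapse = ", "), "\n")
  invisible(x)
}

#' Select the number of depth PCs and adjust average TL
#'
#' For each candidate k, average TL is regressed on the first k depth PC
#' scores and the residuals' absolute Pearson correlation with age is
#' recorded; the returned adjustment uses the k that maximizes this
#' correlation (smallest k on ties, with k = 0 meaning mean-centering
#' only). A stronger age correlation after adjustment indicates that
#' batch-driven technical variance masked the biological age signal.
#'
#' @param tl Average TL vector (bp).
#' @param pcs \code{\link{depth_pcs}} object or a score matrix.
#' @param age Age vector, years.
#' @param k_grid Candidate component counts (default 0:50, capped at the
#'   available components).
#' @return Object of class \code{tl_adjustment}: \code{adjusted}
#'   (residuals at the selected k), \code{k_used}, and the full
#'   \code{curve} (k versus |cor with age|).
#' @export
select_k_and_adjust <- function(tl, pcs, age, k_grid = 0:50) {
  scores <- if (inherits(pcs, "depth_pcs")) pcs$scores else as.matrix(pcs)
  stopifnot(length(tl) == nrow(scores), length(age) == length(tl))
  if (stats::sd(tl) < .Machine$double.eps)
    stop("average TL is constant; correlation with age is undefined")
  k_grid <- sort(unique(pmin(k_grid, ncol(scores))))
  res_at <- function(k) {
    if (k == 0L) return(tl - mean(tl))
    stats::lm.fit(cbind(1, scores[, seq_len(k), drop = FALSE]),
                  tl)$residuals
  }
  curve <- data.frame(k = k_grid, abs_cor = vapply(k_grid, function(k) {
    r <- res_at(k)
    if (stats::sd(r) < .Machine$double.eps) return(NA_real_)
    abs(stats::cor(r, age))
  }, numeric(1)))
  best <- curve$k[which.max(curve$abs_cor)]  # first max = smallest k
  out <- list(adjusted = res_at(best), k_used = best, curve = curve)
  class(out) <- "tl_adjustment"
  out
}

#' @export
print.tl_adjustment <- function(x, ...) {
  cat(sprintf("Depth-PC adjusted TL: k = %d components removed\n",
              x$k_used))
  cat(sprintf("  |cor(residual, age)| = %.3f (raw: %.3f at k = 0)\n",
              max(x$curve$abs_cor, na.rm = TRUE),
              x$curve$abs_cor[x$curve$k == 0]))
  invisible(x)
}

#' Residualize csTL on categorical batch
#'
#' Fits a means model on batch (one mean per batch level) and returns
#' the residuals as batch-adjusted csTL, isolating biological variation.
#' Within-batch residual means are zero by construction. A singleton
#' batch contributes a zero residual with a warning.
#'
#' @param arm_table Arm table with \code{cstl} and \code{batch} columns.
#' @param value Name of the column to adjust (default \code{"cstl"}).
#' @return \code{arm_table} with an added \code{cstl_adj} column and a
#'   \code{"k_used"} attribute (number of batch levels).
#' @export
residualize_on_batch <- function(arm_table, value = "cstl") {
  batch <- as.factor(arm_table$batch)
  if (nlevels(droplevels(batch)) < 1L) stop("no batch levels")
  y <- arm_table[[value]]
  counts <- table(batch)[as.character(batch)]
  singleton <- as.vector(counts) == 1L
  if (any(singleton))
    warning(sum(singleton), " record(s) in singleton batches: residual ",
            "set to 0")
  res <- y - stats::ave(y, batch)
  res[singleton] <- 0
  arm_table$cstl_adj <- res
  attr(arm_table, "k_used") <- nlevels(droplevels(batch))
  arm_table
}
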