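#' Restrict omics matrices to their shared samples
#'
#' All downstream integration assumes that row i refers to the same patient in
#' every modality. This takes a list of samples x features matrices (sample IDs
#' as rownames) and restricts each to the intersection of sample IDs, in one
#' canonical order: the order in which the shared IDs appear in the first
#' matrix.
#'
#' @param matrices named list of numeric matrices with sample IDs as rownames.
#' @return list of matrices, all with identical rownames in identical order.
#' @export
align_samples <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  ids <- lapply(matrices, rownames)
  if (any(vapply(ids, is.null, logical(1L))))
    stop("every matrix must carry sample IDs as rownames")
  shared <- Reduce(intersect, ids)
  if (length(shared) == 0L)
    stop("no samples shared across all modalities")
  canonical <- ids[[1L]][ids[[1L]] %in% shared]
  lapply(matrices, function(m) m[canonical, , drop = FALSE])
}

#' Impute missing values from nearest features
#'
#' Each missing entry (sample i, feature j) is replaced by the mean of sample
#' i's values in the k features nearest to feature j. Feature-feature distance
#' is Euclidean over commonly observed samples, rescaled for missingness as in
#' [stats::dist()] (pairwise-complete with upweighting). This is the
#' probe-neighbour imputation convention used for methylation arrays.
#'
#' @param m numeric matrix, samples x features, `NA` marking missing entries.
#' @param k number of neighbouring features to average; effective k is
#'   `min(k, number of available candidate features)`. Default 100.
#' @return matrix of the same shape with no missing entries; observed entries
#'   are untouched.
#' @export
knn_impute <- function(m, k = 100L) {
  stopifnot(is.matrix(m), is.numeric(m), k >= 1L)
  if (!anyNA(m)) return(m)
  fully_missing <- colSums(!is.na(m)) == 0L
  if (any(fully_missing))
    stop("feature(s) with no observed values: ",
         paste(colnames(m)[fully_missing], collapse = ", "))
  # pairwise-complete Euclidean distance between features
  d <- as.matrix(stats::dist(t(m)))
  diag(d) <- Inf
  out <- m
  for (j in which(colSums(is.na(m)) > 0L)) {
    for (i in which(is.na(m[, j]))) {
      candidates <- which(!is.na(m[i, ]) & is.finite(d[j, ]))
      if (length(candidates) == 0L)
        stop("no observed neighbour available to impute sample ", i,
             ", feature ", j)
      kk <- min(k, length(candidates))
      nn <- candidates[order(d[j, candidates])[seq_len(kk)]]
      out[i, j] <- mean(m[i, nn])
    }
  }
  out
}

#' Keep the most variable features
#'
#' Retains the `ceiling(keep_fraction * p)` features with largest sample
#' variance (divisor n-1). Ties are broken by input feature order, and the
#' survivors keep their original column order, so the result is deterministic
#' and invariant to sample reordering.
#'
#' @param m numeric matrix, samples x features, no missing values.
#' @param keep_fraction fraction of features to retain; default 0.75.
#' @return matrix restricted to the retained feature columns.
#' @export
variance_filter <- function(m, keep_fraction = 0.75) {
  stopifnot(is.matrix(m), ncol(m) >= 2L,
            keep_fraction > 0, keep_fraction <= 1)
  v <- apply(m, 2L, stats::var)
  n_keep <- ceiling(keep_fraction * ncol(m))
  ranked <- order(-v, seq_along(v))   # ties broken by input order
  keep <- sort(ranked[seq_len(n_keep)])
  m[, keep, drop = FALSE]
}

#' Standardize features to zero mean and unit variance
#'
#' Per-feature centering and scaling, `(f - mean(f)) / sd(f)`, with the sample
#' standard deviation (divisor n-1). Zero-variance features carry no distance
#' information and are dropped with a warning.
#'
#' @param m numeric matrix, samples x features, no missing values.
#' @return matrix whose every column has mean 0 and variance 1.
#' @export
standardize <- function(m) {
  stopifnot(is.matrix(m), !anyNA(m))
  sds <- apply(m, 2L, stats::sd)
  degenerate <- sds == 0
  if (all(degenerate))
    stop("all features have zero variance")
  if (any(degenerate)) {
    warning("dropping ", sum(degenerate), " zero-variance feature(s): ",
            paste(utils::head(colnames(m)[degenerate], 5L), collapse = ", "))
    m <- m[, !degenerate, drop = FALSE]
    sds <- sds[!degenerate]
  }
  scale(m, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Standard per-modality preprocessing chain
#'
#' Applies the modality-wise pipeline in the fixed order
#' align -> impute -> variance filter -> standardize. Filtering sees complete
#' data; standardization runs last so graph kernels operate on unit-scale
#' features.
#'
#' @param matrices named list of samples x features matrices.
#' @param keep_fraction variance-filter retention fraction (default 0.75).
#' @param impute_k neighbours for kNN imputation (default 100).
#' @return list of preprocessed matrices with aligned, identically ordered
#'   samples.
#' @export
preprocess_modalities <- function(matrices, keep_fraction = 0.75,
                                  impute_k = 100L) {
  matrices <- align_samples(matrices)
  lapply(matrices, function(m)
    standardize(variance_filter(knn_impute(m, k = impute_k),
                                keep_fraction = keep_fraction)))
}
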