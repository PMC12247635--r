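#' Heat-kernel patient similarity graph with adaptive bandwidth
#'
#' Builds the pairwise similarity matrix
#' \deqn{S_{ij} = \exp(-\|x_i - x_j\|^2 / (\sigma_i \sigma_j)), \quad S_{ii}=0,}
#' where \eqn{\sigma_i} is the Euclidean distance from patient i to its
#' `nn`-th nearest neighbour (self excluded; capped at N-1 neighbours). The
#' per-point bandwidth makes neighbourhoods density-adaptive, so sparse and
#' dense regions of the patient cloud are treated comparably.
#'
#' Duplicate profiles would give \eqn{\sigma_i = 0}; such bandwidths are
#' replaced by the smallest positive neighbour distance. If all points are
#' identical no scale exists and an error is raised.
#'
#' @param m numeric matrix, samples x features, no missing values.
#' @param nn neighbour rank defining the bandwidth; default 7.
#' @return object of class `similarity_graph`: list with `S` (N x N symmetric,
#'   zero diagonal) and `sigma` (per-sample bandwidths).
#' @export
heat_kernel_graph <- function(m, nn = 7L) {
  stopifnot(is.matrix(m), nrow(m) >= 3L, !anyNA(m), nn >= 1L)
  n <- nrow(m)
  d <- as.matrix(stats::dist(m))
  rank_used <- min(nn, n - 1L)
  if (all(d == 0)) stop("all points are identical; no bandwidth scale")
  sigma <- vapply(seq_len(n), function(i) {
    nbr <- sort(d[i, -i])
    s <- nbr[rank_used]
    if (s == 0) {
      # duplicated profiles: fall back to the smallest positive neighbour
      # distance of this point (global smallest positive if it has none)
      pos <- nbr[nbr > 0]
      s <- if (length(pos)) pos[1L] else min(d[d > 0])
    }
    s
  }, numeric(1L))
  S <- exp(-d^2 / outer(sigma, sigma))
  diag(S) <- 0
  structure(list(S = S, sigma = sigma), class = "similarity_graph")
}

#' Symmetric normalized graph Laplacian
#'
#' Computes \eqn{L = I - D^{-1/2} S D^{-1/2}} with \eqn{D_{ii} = \sum_j S_{ij}}.
#' Its eigenvalues lie in `[0, 2]` and \eqn{D^{1/2}\mathbf{1}} spans the
#' null space on a connected graph.
#'
#' @param g a `similarity_graph`.
#' @return object of class `graph_laplacian`: list with `L` (N x N symmetric)
#'   and `degree` (the row sums of S).
#' @export
normalized_laplacian <- function(g) {
  stopifnot(inherits(g, "similarity_graph"))
  S <- g$S
  deg <- rowSums(S)
  if (any(deg <= 0)) {
    bad <- rownames(S)[deg <= 0]
    if (is.null(bad)) bad <- which(deg <= 0)
    stop("isolated sample(s) with zero degree: ", paste(bad, collapse = ", "))
  }
  inv_sqrt <- 1 / sqrt(deg)
  L <- diag(nrow(S)) - (inv_sqrt * S) %*% diag(inv_sqrt)
  L <- (L + t(L)) / 2  # enforce exact symmetry
  dimnames(L) <- dimnames(S)
  structure(list(L = L, degree = deg), class = "graph_laplacian")
}

# deterministic eigenvector orientation: largest-magnitude entry nonnegative
fix_eigen_signs <- function(U) {
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  U
}

#' Spectral subspace embedding of a Laplacian
#'
#' Returns the k eigenvectors of L with smallest eigenvalues, as an
#' orthonormal-column matrix: one point on the Grassmann manifold G(k, N).
#' Eigenvector signs are fixed by forcing the largest-magnitude entry of each
#' column nonnegative, making the embedding deterministic across linear
#' algebra backends (the subspace itself is basis-independent).
#'
#' @param l a `graph_laplacian`, or a symmetric numeric matrix.
#' @param k subspace dimension, `1 <= k < N`.
#' @return object of class `subspace_embedding`: list with `U` (N x k,
#'   orthonormal columns ordered by ascending eigenvalue), `values` (the k
#'   retained eigenvalues) and `k`.
#' @export
spectral_embed <- function(l, k) {
  L <- if (inherits(l, "graph_laplacian")) l$L else l
  stopifnot(is.matrix(L), nrow(L) == ncol(L))
  n <- nrow(L)
  if (k < 1L || k >= n) stop("require 1 <= k < N (k = ", k, ", N = ", n, ")")
  e <- eigen(L, symmetric = TRUE)      # eigenvalues descending
  idx <- seq(n, n - k + 1L)            # k smallest, ascending
  U <- fix_eigen_signs(e$vectors[, idx, drop = FALSE])
  rownames(U) <- rownames(L)
  structure(list(U = U, values = e$values[idx], k = k),
            class = "subspace_embedding")
}

#' Squared projection-Frobenius distance between subspaces
#'
#' The Grassmann distance used for merging:
#' \deqn{d^2_{proj}(U, V) = k - tr(U U^\top V V^\top),}
#' which equals the sum of squared sines of the principal angles between the
#' two k-dimensional subspaces. It is basis-independent, symmetric, and lies
#' in `[0, k]`.
#'
#' @param u,v `subspace_embedding` objects (or orthonormal-column matrices)
#'   with equal N and k.
#' @return nonnegative scalar.
#' @export
grassmann_distance <- function(u, v) {
  Uu <- if (inherits(u, "subspace_embedding")) u$U else u
  Uv <- if (inherits(v, "subspace_embedding")) v$U else v
  if (!all(dim(Uu) == dim(Uv)))
    stop("subspace dimension mismatch: ", paste(dim(Uu), collapse = "x"),
         " vs ", paste(dim(Uv), collapse = "x"))
  k <- ncol(Uu)
  # tr(UU' VV') = ||U'V||_F^2
  k - sum(crossprod(Uu, Uv)^2)
}

#' Merge modality subspaces on the Grassmann manifold
#'
#' Solves the joint objective
#' \deqn{\min_{U^\top U = I} \sum_m tr(U^\top L^{(m)} U)
#'       + \alpha \sum_m d^2_{proj}(U, U^{(m)})}
#' in closed form: the minimizer spans the k eigenvectors with smallest
#' eigenvalues of the modified Laplacian
#' \deqn{L_{mod} = \sum_m L^{(m)} - \alpha \sum_m U^{(m)} U^{(m)\top}.}
#' The first term preserves each modality's local graph structure; the second
#' pulls the consensus towards the individual subspaces, with alpha trading
#' the two off. All modalities enter with equal weight.
#'
#' @param laplacians list of `graph_laplacian` objects, one per modality.
#' @param embeddings list of `subspace_embedding` objects, same length and
#'   all of dimension k.
#' @param alpha nonnegative trade-off weight; default 0.5.
#' @param k consensus subspace dimension.
#' @return object of class `merged_subspace`: list with `Lmod`, `U`
#'   (a `subspace_embedding`), `alpha`, `k`.
#' @export
merge_subspaces <- function(laplacians, embeddings, alpha = 0.5, k) {
  stopifnot(length(laplacians) >= 1L,
            length(laplacians) == length(embeddings), alpha >= 0)
  ns <- vapply(laplacians, function(l) nrow(l$L), integer(1L))
  if (length(unique(ns)) != 1L)
    stop("modalities disagree on N: ", paste(ns, collapse = ", "))
  if (!all(vapply(embeddings, function(e) e$k, numeric(1L)) == k))
    stop("all embeddings must have dimension k = ", k)
  Lsum <- Reduce(`+`, lapply(laplacians, `[[`, "L"))
  Psum <- Reduce(`+`, lapply(embeddings, function(e) tcrossprod(e$U)))
  Lmod <- Lsum - alpha * Psum
  Lmod <- (Lmod + t(Lmod)) / 2
  structure(list(Lmod = Lmod, U = spectral_embed(Lmod, k),
                 alpha = alpha, k = k),
            class = "merged_subspace")
}

# rows of U scaled to unit Euclidean norm (spectral-clustering convention)
normalize_rows <- function(U) {
  norms <- sqrt(rowSums(U^2))
  if (any(norms == 0)) stop("row(s) of U with zero norm: cannot normalize")
  U / norms
}

#' Cluster patients in a merged subspace
#'
#' Rows of the consensus embedding U are scaled to unit Euclidean norm and
#' partitioned by K-means (Euclidean, `restarts` random initializations, up
#' to 300 iterations, best within-cluster sum of squares wins). The seed makes
#' the restarts, and hence the labels, deterministic.
#'
#' @param ms a `merged_subspace` (or an N x k matrix of embedding rows).
#' @param k number of clusters, `2 <= k < N`.
#' @param restarts K-means restarts; default 10.
#' @param seed integer seed.
#' @return integer vector of cluster labels in `1..k`, named by sample.
#' @export
cluster_merged <- function(ms, k, restarts = 10L, seed = 1L) {
  U <- if (inherits(ms, "merged_subspace")) ms$U$U else ms
  stopifnot(k >= 2L, k < nrow(U))
  Un <- normalize_rows(U)
  set.seed(seed)
  km <- stats::kmeans(Un, centers = k, nstart = restarts, iter.max = 300L)
  stats::setNames(km$cluster, rownames(U))
}

#' Integrate modalities and select the number of clusters by silhouette
#'
#' The full integration loop. For each candidate k the modality subspaces are
#' re-embedded at dimension k, merged, and clustered; the mean silhouette
#' width (Euclidean, on the row-normalized consensus embedding) scores the
#' partition. The k with the highest mean silhouette wins and its labels are
#' returned together with the full silhouette trace.
#'
#' Subspace dimension is tied to the candidate cluster number, the standard
#' spectral-clustering coupling.
#'
#' @param matrices list of preprocessed samples x features matrices with
#'   aligned identical rownames (see [preprocess_modalities()]).
#' @param alpha Grassmann trade-off weight; default 0.5.
#' @param k_range candidate cluster numbers; default `2:8`.
#' @param nn heat-kernel bandwidth neighbour rank; default 7.
#' @param restarts K-means restarts per k; default 10.
#' @param seed integer seed (each candidate k derives its own stream).
#' @return object of class `cluster_result`: list with `labels`,
#'   `k_selected`, `silhouette_by_k` (named numeric over all candidates),
#'   `alpha`, `seed`.
#' @export
select_k <- function(matrices, alpha = 0.5, k_range = 2:8, nn = 7L,
                     restarts = 10L, seed = 1L) {
  stopifnot(length(matrices) >= 1L)
  n <- nrow(matrices[[1L]])
  if (!all(vapply(matrices, nrow, integer(1L)) == n))
    stop("matrices must share an identical aligned sample set")
  if (n <= max(k_range))
    stop("N = ", n, " too small for k up to ", max(k_range))
  if (n < nn + 1L)
    stop("N = ", n, " too small for the ", nn,
         "-NN bandwidth; reduce nn")
  laplacians <- lapply(matrices, function(m)
    normalized_laplacian(heat_kernel_graph(m, nn = nn)))
  sil <- stats::setNames(numeric(length(k_range)), k_range)
  labels_by_k <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    embeddings <- lapply(laplacians, spectral_embed, k = k)
    ms <- merge_subspaces(laplacians, embeddings, alpha = alpha, k = k)
    lab <- cluster_merged(ms, k = k, restarts = restarts, seed = seed + k)
    Un <- normalize_rows(ms$U$U)
    sw <- cluster::silhouette(as.integer(lab), stats::dist(Un))
    sil[i] <- mean(sw[, "sil_width"])
    labels_by_k[[i]] <- lab
  }
  best <- which.max(sil)
  structure(list(labels = labels_by_k[[best]],
                 k_selected = k_range[best],
                 silhouette_by_k = sil,
                 alpha = alpha, nn = nn, restarts = restarts, seed = seed),
            class = "cluster_result")
}
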