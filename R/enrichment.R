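#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability of drawing at least `x` annotated genes when `n`
#' genes are selected without replacement from a universe of `N` genes of
#' which `K` carry the annotation:
#' \deqn{p = \sum_{i=x}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}.}
#' Evaluated in log space for numerical stability.
#'
#' @param x overlap count.
#' @param K term size.
#' @param n selected-list size.
#' @param N universe size.
#' @return the one-sided (over-representation) p-value.
#' @export
hypergeom_test <- function(x, K, n, N) {
  if (K > N || n > N || x > min(K, n) || x < 0)
    stop("invalid hypergeometric configuration (x=", x, ", K=", K,
         ", n=", n, ", N=", N, ")")
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene list
#'
#' Tests every annotation term for enrichment of the selected gene list by
#' the one-sided hypergeometric test, adjusts across terms with
#' Benjamini-Hochberg, and reports `qscore = -log10(p_adj)`. The universe is
#' the annotation's gene universe (typically all features that survived
#' preprocessing); selected genes outside it are dropped with a warning.
#' Terms outside `[min_size, max_size]` are not tested.
#'
#' @param genes character vector of selected genes (e.g. DEGs).
#' @param annotation list with `universe` (character vector) and `terms`
#'   (named list of gene vectors, each a subset of the universe).
#' @param fdr significance threshold on the adjusted p; default 0.05.
#' @param min_size,max_size term-size filter; defaults 5 and 2000.
#' @return data.frame sorted by ascending p with columns term_id, K,
#'   n_selected, overlap, p, p_adj, qscore, significant.
#' @export
enrich <- function(genes, annotation, fdr = 0.05, min_size = 5L,
                   max_size = 2000L) {
  stopifnot(is.list(annotation), length(annotation$terms) >= 1L)
  universe <- annotation$universe
  outside <- setdiff(genes, universe)
  if (length(outside) == length(genes))
    stop("no selected gene is in the annotation universe")
  if (length(outside) > 0L)
    warning(length(outside), " selected gene(s) outside the universe dropped")
  genes <- unique(intersect(genes, universe))
  sizes <- lengths(annotation$terms)
  terms <- annotation$terms[sizes >= min_size & sizes <= max_size]
  if (length(terms) == 0L)
    stop("no terms within the size bounds [", min_size, ", ", max_size, "]")
  N <- length(universe)
  n <- length(genes)
  res <- data.frame(
    term_id = names(terms),
    K = lengths(terms),
    n_selected = n,
    overlap = vapply(terms, function(tg)
      length(intersect(tg, genes)), integer(1L)),
    row.names = NULL)
  res$p <- mapply(hypergeom_test, res$overlap, res$K,
                  MoreArgs = list(n = n, N = N))
  res$p_adj <- bh_adjust(res$p)
  res$qscore <- -log10(res$p_adj)
  res$significant <- res$p_adj < fdr
  res[order(res$p, res$term_id), , drop = FALSE]
}

#' Read a GMT gene-set file
#'
#' GMT: one term per line, tab-separated `term_id`, description, then gene
#' IDs. The universe defaults to the union of all term genes unless given.
#'
#' @param path GMT file path.
#' @param universe optional character vector overriding the universe.
#' @return annotation list (`universe`, `terms`) as consumed by [enrich()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  terms <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(terms) <- vapply(parts, `[[`, character(1L), 1L)
  if (is.null(universe)) universe <- sort(unique(unlist(terms)))
  list(universe = universe, terms = terms)
}

#' Write a GMT gene-set file
#'
#' @param annotation list with `terms` (named list of gene vectors) and
#'   optionally per-term descriptions in `descriptions`.
#' @param path output path.
#' @export
write_gmt <- function(annotation, path) {
  desc <- annotation$descriptions
  if (is.null(desc)) desc <- rep("na", length(annotation$terms))
  lines <- mapply(function(id, d, genes)
    paste(c(id, d, genes), collapse = "\t"),
    names(annotation$terms), desc, annotation$terms)
  writeLines(lines, path)
  invisible(path)
}
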