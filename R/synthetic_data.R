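#' Simulate a multi-omics cohort with a planted patient partition
#'
#' Generates M samples x features matrices that share one ground-truth
#' partition of the patients, with modality-specific informative features and
#' Gaussian noise. Within each modality the informative features are split
#' into one block per cluster; features in block g have mean
#' `effect_size * noise_sd` for patients of cluster g and 0 otherwise, so the
#' cluster centroids sit on the vertices of a regular simplex and every pair
#' of clusters is separated by the same standardized effect. Nuisance
#' features are label-independent noise. With `noise_sd = 0` the shift equals
#' `effect_size` outright, so same-cluster patients collapse onto identical
#' points.
#'
#' @param n_patients total number of patients; at least 8 per cluster.
#' @param n_clusters number of planted clusters (>= 2).
#' @param modalities list of per-modality descriptors, each a list with
#'   `name`, `n_features`, `n_informative`, `effect_size` (standardized mean
#'   shift, units of `noise_sd`) and `noise_sd`.
#' @param seed integer seed; identical spec + seed gives identical output.
#' @return list with `matrices` (named list of matrices, identical rownames
#'   `P0001...` in identical order), `labels` (integer vector named by
#'   patient) and `modalities` (the descriptors used).
#' @export
simulate_multiomics <- function(n_patients, n_clusters, modalities, seed = 1L) {
  stopifnot(n_clusters >= 2L, length(modalities) >= 1L)
  if (n_patients < 8L * n_clusters)
    stop("need at least 8 patients per cluster (", n_patients, " for ",
         n_clusters, " clusters)")
  set.seed(seed)
  ids <- sprintf("P%04d", seq_len(n_patients))
  labels <- stats::setNames(rep(seq_len(n_clusters), length.out = n_patients),
                            ids)
  mats <- lapply(modalities, function(mod) {
    stopifnot(mod$n_informative <= mod$n_features)
    delta <- if (mod$noise_sd > 0) mod$effect_size * mod$noise_sd
             else mod$effect_size
    mu <- matrix(0, n_clusters, mod$n_features)
    if (mod$n_informative > 0L) {
      block <- rep(seq_len(n_clusters), length.out = mod$n_informative)
      for (g in seq_len(n_clusters))
        mu[g, which(block == g)] <- delta
    }
    x <- mu[labels, , drop = FALSE] +
      matrix(stats::rnorm(n_patients * mod$n_features, sd = mod$noise_sd),
             n_patients, mod$n_features)
    dimnames(x) <- list(ids, sprintf("%s_f%04d", mod$name,
                                     seq_len(mod$n_features)))
    x
  })
  names(mats) <- vapply(modalities, `[[`, character(1L), "name")
  list(matrices = mats, labels = labels, modalities = modalities)
}

# convenience constructor for a homogeneous modality descriptor list
modality_spec <- function(names, n_features, n_informative, effect_size,
                          noise_sd = 1) {
  lapply(names, function(nm)
    list(name = nm, n_features = n_features, n_informative = n_informative,
         effect_size = effect_size, noise_sd = noise_sd))
}

#' Simulate genotypes, covariates and an EHR event stream
#'
#' Dosages are drawn per variant as Binomial(2, maf), i.e. Hardy-Weinberg
#' proportions. Case status for each phecode follows
#' `logit P(case) = beta0 + beta * dosage + covariate terms` with age, sex
#' and six principal components as covariates. The EHR stream then emits two
#' or more distinct-date phecode instances for every case, exactly one
#' instance for a designated fraction of non-cases (to exercise the
#' one-instance rule), and none otherwise.
#'
#' @param n_participants cohort size.
#' @param mafs named numeric vector of minor-allele frequencies in (0, 0.5].
#' @param betas variants x phecodes matrix of per-allele log-odds (dimnames
#'   required); a vector is treated as one phecode per variant pairing is not
#'   implied -- supply a matrix for multiple phecodes.
#' @param beta0 per-phecode intercept (baseline log-odds), recycled.
#' @param covar_betas list of covariate log-odds: `age` (per decade), `sex`,
#'   `pcs` (length 6). Defaults to zeros.
#' @param sex_restriction optional named character vector phecode ->
#'   `"male"`/`"female"` for sex-specific phecodes.
#' @param frac_single fraction of non-cases given exactly one phecode
#'   instance; default 0.05.
#' @param confound_pcs if TRUE the first PC is correlated with mean dosage,
#'   to exercise covariate adjustment; default FALSE (independent PCs).
#' @param seed integer seed.
#' @return list with `genotypes` (participants x variants integer matrix),
#'   `covariates` (data.frame: participant_id, age, sex, PC1..PC6), `events`
#'   (data.frame: participant_id, phecode, date), `truth` (list: `status`
#'   logical matrix participants x phecodes of simulated case status,
#'   `single_instance` participant IDs per phecode, `betas`),
#'   `sex_restriction`.
#' @export
simulate_geno_pheno <- function(n_participants, mafs, betas,
                                beta0 = -2,
                                covar_betas = list(age = 0, sex = 0,
                                                   pcs = rep(0, 6L)),
                                sex_restriction = NULL,
                                frac_single = 0.05,
                                confound_pcs = FALSE,
                                seed = 1L) {
  stopifnot(all(mafs > 0), all(mafs <= 0.5), is.matrix(betas))
  set.seed(seed)
  ids <- sprintf("S%05d", seq_len(n_participants))
  variants <- names(mafs)
  if (is.null(variants)) variants <- sprintf("rs%06d", seq_along(mafs))
  stopifnot(nrow(betas) == length(mafs))
  phecodes <- colnames(betas)
  if (is.null(phecodes)) phecodes <- sprintf("%05.1f", seq_len(ncol(betas)))
  geno <- vapply(mafs, function(q) stats::rbinom(n_participants, 2L, q),
                 integer(n_participants))
  dimnames(geno) <- list(ids, variants)
  age <- round(stats::runif(n_participants, 45, 95))
  sex <- stats::rbinom(n_participants, 1L, 0.5)  # 1 = male, 0 = female
  pcs <- matrix(stats::rnorm(n_participants * 6L), n_participants, 6L,
                dimnames = list(ids, paste0("PC", 1:6)))
  if (confound_pcs)
    pcs[, 1L] <- pcs[, 1L] + scale(rowMeans(geno))[, 1L]
  covariates <- data.frame(participant_id = ids, age = age, sex = sex, pcs,
                           row.names = NULL, check.names = FALSE)
  beta0 <- rep_len(beta0, length(phecodes))
  eta_cov <- covar_betas$age * (age - 65) / 10 + covar_betas$sex * sex +
    drop(pcs %*% covar_betas$pcs)
  status <- matrix(NA, n_participants, length(phecodes),
                   dimnames = list(ids, phecodes))
  for (j in seq_along(phecodes)) {
    eta <- beta0[j] + drop(geno %*% betas[, j]) + eta_cov
    status[, j] <- stats::rbinom(n_participants, 1L, stats::plogis(eta)) == 1L
  }
  # EHR stream: cases get >= 2 distinct dates, designated non-cases exactly 1
  base_date <- as.Date("2018-01-01")
  ev <- vector("list", length(phecodes))
  single <- vector("list", length(phecodes))
  names(single) <- phecodes
  for (j in seq_along(phecodes)) {
    cases <- ids[status[, j]]
    noncases <- ids[!status[, j]]
    n_single <- floor(frac_single * length(noncases))
    singles <- if (n_single > 0L) sample(noncases, n_single) else character(0L)
    single[[j]] <- singles
    n_inst <- 2L + stats::rpois(length(cases), 1L)
    ev[[j]] <- rbind(
      if (length(cases)) data.frame(
        participant_id = rep(cases, n_inst),
        phecode = phecodes[j],
        date = as.character(base_date +
          unlist(lapply(n_inst, function(m) sample.int(2000L, m)))),
        row.names = NULL),
      if (length(singles)) data.frame(
        participant_id = singles,
        phecode = phecodes[j],
        date = as.character(base_date + sample.int(2000L, length(singles),
                                                   replace = TRUE)),
        row.names = NULL))
  }
  events <- do.call(rbind, ev)
  if (is.null(events))
    events <- data.frame(participant_id = character(0L),
                         phecode = character(0L), date = character(0L))
  list(genotypes = geno, covariates = covariates, events = events,
       truth = list(status = status, single_instance = single, betas = betas),
       sex_restriction = sex_restriction)
}

#' Simulate a gene-set annotation with one planted enriched term
#'
#' Builds a gene universe, a set of random annotation terms, and a "selected"
#' gene list (e.g. DEGs) constructed so that one planted term overlaps the
#' list far beyond its hypergeometric expectation, while all other terms are
#' drawn independently of the list.
#'
#' @param universe_size number of genes in the universe.
#' @param n_terms total number of terms including the planted one.
#' @param term_size genes per term (recycled).
#' @param n_selected size of the selected gene list.
#' @param planted_overlap overlap between the planted term and the selected
#'   list; must be feasible and strictly above the null expectation
#'   `term_size * n_selected / universe_size`.
#' @param seed integer seed.
#' @return list with `universe`, `terms` (named list of gene vectors,
#'   planted term first), `selected` (the gene list), `planted_term`.
#' @export
simulate_annotation <- function(universe_size, n_terms = 20L, term_size = 50L,
                                n_selected = 100L, planted_overlap = 20L,
                                seed = 1L) {
  term_size <- rep_len(term_size, n_terms)
  stopifnot(universe_size >= max(term_size), n_selected <= universe_size)
  k1 <- term_size[1L]
  if (planted_overlap > min(k1, n_selected) ||
      universe_size - n_selected < k1 - planted_overlap)
    stop("planted overlap ", planted_overlap, " infeasible for term size ",
         k1, ", list size ", n_selected, ", universe ", universe_size)
  if (planted_overlap <= k1 * n_selected / universe_size)
    stop("planted overlap must strictly exceed its null expectation ",
         signif(k1 * n_selected / universe_size, 3L))
  set.seed(seed)
  universe <- sprintf("g%05d", seq_len(universe_size))
  selected <- sample(universe, n_selected)
  planted <- c(sample(selected, planted_overlap),
               sample(setdiff(universe, selected), k1 - planted_overlap))
  terms <- c(list(sample(planted)),   # shuffle within the term
             lapply(term_size[-1L], function(sz) sample(universe, sz)))
  names(terms) <- c("TERM_PLANTED",
                    sprintf("TERM_%03d", seq_len(n_terms - 1L)))
  list(universe = universe, terms = terms, selected = selected,
       planted_term = "TERM_PLANTED")
}
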