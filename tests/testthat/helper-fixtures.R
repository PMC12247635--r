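# Shared fixtures and independent oracles used across the suite.

# three-modality simulation at the standard study conditions
std_multiomics <- function(seed = 1L, n = 80L, k = 2L, effect = 4,
                           n_features = 120L, n_informative = 40L,
                           noise_sd = 1) {
  mods <- lapply(c("rna", "prot", "meth"), function(nm)
    list(name = nm, n_features = n_features, n_informative = n_informative,
         effect_size = effect, noise_sd = noise_sd))
  simulate_multiomics(n, k, mods, seed = seed)
}

# adjusted Rand index between two partitions
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# random orthonormal-column matrix via QR
random_orthonormal <- function(n, k) {
  qr.Q(qr(matrix(stats::rnorm(n * k), n, k)))[, seq_len(k), drop = FALSE]
}

# independent step-up BH reference (sort, cummin from the top, map back)
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- running
  }
  adj
}

# hypergeometric upper tail by explicit enumeration of all draws (small N)
hyper_enum <- function(x, K, n, N) {
  draws <- utils::combn(N, n)
  annotated <- seq_len(K)
  overlaps <- apply(draws, 2L, function(d) sum(d %in% annotated))
  mean(overlaps >= x)
}

# brute-force heat-kernel similarity (double loop, no vectorization)
heat_kernel_oracle <- function(m, nn = 7L) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) d[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
  sigma <- numeric(n)
  for (i in 1:n) sigma[i] <- sort(d[i, -i])[min(nn, n - 1L)]
  S <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    if (i != j) S[i, j] <- exp(-d[i, j]^2 / (sigma[i] * sigma[j]))
  S
}

# sum of squared sines of principal angles via SVD of U'V
grassmann_svd_oracle <- function(U, V) {
  s <- svd(crossprod(U, V))$d
  s <- pmin(pmax(s, -1), 1)
  sum(1 - s^2)
}

# builds a complete synthetic input bundle on disk and returns a config
write_pipeline_bundle <- function(dir, seed = 1L, with_phewas = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- std_multiomics(seed = seed, n = 60, n_features = 80,
                        n_informative = 30)
  omics <- list()
  for (nm in names(sim$matrices)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_omics_tsv(sim$matrices[[nm]], p)
    omics[[nm]] <- p
  }
  # annotation whose universe is the rna feature space, enriched term planted
  # on the informative features (the expected DEGs)
  rna_features <- colnames(sim$matrices$rna)
  set.seed(seed + 1)
  terms <- c(list(TERM_PLANTED = c(rna_features[1:25],
                                   sample(rna_features[31:80], 5))),
             lapply(1:10, function(i) sample(rna_features, 20)))
  names(terms)[-1] <- sprintf("TERM_%03d", 1:10)
  gmt <- file.path(dir, "ann.gmt")
  write_gmt(list(terms = terms), gmt)
  cfg <- default_config(seed = seed)
  cfg$omics <- omics
  cfg$gmt <- gmt
  cfg$k_max <- 4L
  if (with_phewas) {
    gp <- simulate_geno_pheno(
      800, mafs = c(rs000001 = 0.3, rs000002 = 0.2),
      betas = matrix(c(log(1.8), 0), 2, 1,
                     dimnames = list(c("rs000001", "rs000002"), "250.2")),
      beta0 = -1.3, seed = seed + 2)
    write_tab <- function(df, p) utils::write.table(
      df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    write_omics_tsv(gp$genotypes, file.path(dir, "geno.tsv"))
    write_tab(gp$covariates, file.path(dir, "pcov.tsv"))
    write_tab(gp$events, file.path(dir, "events.tsv"))
    # eQTL table keyed to the rna informative features called as DEGs
    eqtl <- data.frame(variant_id = c("rs000001", "rs000002"),
                       gene = rna_features[1:2],
                       effect = c(0.4, -0.2), fdr = c(1e-6, 1e-7))
    write_tab(eqtl, file.path(dir, "eqtl.tsv"))
    cfg$genotypes <- file.path(dir, "geno.tsv")
    cfg$pheno_covariates <- file.path(dir, "pcov.tsv")
    cfg$events <- file.path(dir, "events.tsv")
    cfg$eqtl_table <- file.path(dir, "eqtl.tsv")
  }
  list(cfg = cfg, sim = sim)
}
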