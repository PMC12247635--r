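#' Default pipeline configuration
#'
#' Returns the full configuration list with every tunable at its default.
#' Input paths are `NULL` and must be filled in; the PheWAS inputs are
#' optional (the stage is skipped when they are absent). The configuration
#' round-trips through YAML unchanged.
#'
#' @param seed mandatory integer seed driving every stochastic step.
#' @return named list of configuration entries.
#' @export
default_config <- function(seed) {
  stopifnot(!missing(seed), is.numeric(seed))
  list(
    omics = NULL,           # named list modality -> TSV path
    covariates = NULL,      # optional TSV: sample_id + covariate columns
    gmt = NULL,             # optional GMT annotation for enrichment
    eqtl_table = NULL,      # optional TSV: variant_id, gene, effect, fdr
    genotypes = NULL,       # optional TSV dosage matrix
    pheno_covariates = NULL,# optional TSV: participant_id, age, sex, PC1..6
    events = NULL,          # optional TSV: participant_id, phecode, date
    alpha = 0.5, k_min = 2L, k_max = 8L, nn = 7L, restarts = 10L,
    keep_fraction = 0.75, impute_k = 100L,
    fdr = 0.05, lfc = 0.7, use_raw_p = FALSE,
    enrich_min_size = 5L, enrich_max_size = 2000L,
    eqtl_per_gene = 3L, eqtl_fdr = 1e-4,
    phecode_min_count = 20L, phewas_raw_cut = 1e-4,
    one_instance = "missing",
    seed = as.integer(seed))
}

# deterministic per-stage seeds derived from the one configured seed
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, integrate = 23L, de = 37L, enrich = 41L,
               phewas = 53L)
  (as.integer(seed) * 97L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates preprocess -> subspace merge (with silhouette model
#' selection) -> per-modality differential expression -> enrichment, and,
#' when genotype/EHR inputs are configured, the eQTL PheWAS stage. Every
#' intermediate table is written under `out_dir`, and a manifest records the
#' configuration hash, seed and an MD5 checksum of every artifact, so two
#' runs with the same configuration and seed are bit-identical.
#'
#' @param config configuration list (see [default_config()]) or the path of
#'   a YAML file holding one.
#' @param out_dir run directory; created if needed.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$seed), !is.null(config$omics))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0L)
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv(df, path)
    artifacts <<- c(artifacts, name)
    path
  }
  log_line <- function(stage, msg)
    message(sprintf("[%s] %s", stage, msg))

  # --- preprocess + integrate ------------------------------------------
  raw <- lapply(config$omics, read_omics_tsv)
  log_line("preprocess", sprintf("%d modalities, N in {%s}", length(raw),
           paste(unique(vapply(raw, nrow, integer(1L))), collapse = ",")))
  prep <- preprocess_modalities(raw, keep_fraction = config$keep_fraction,
                                impute_k = config$impute_k)
  cr <- select_k(prep, alpha = config$alpha,
                 k_range = seq(config$k_min, config$k_max),
                 nn = config$nn, restarts = config$restarts,
                 seed = stage_seed(config$seed, "integrate"))
  log_line("integrate", sprintf("selected k = %d", cr$k_selected))
  put(data.frame(sample_id = names(cr$labels), cluster = unname(cr$labels)),
      "clusters.tsv")
  sil_path <- file.path(out_dir, "silhouette.json")
  jsonlite::write_json(list(silhouette_by_k = as.list(cr$silhouette_by_k),
                            k_selected = cr$k_selected,
                            alpha = config$alpha, seed = config$seed),
                       sil_path, auto_unbox = TRUE, digits = NA)
  artifacts <- c(artifacts, "silhouette.json")

  # --- differential expression (two largest clusters) ------------------
  tab_counts <- sort(table(cr$labels), decreasing = TRUE)
  top2 <- names(tab_counts)[1:2]
  in_de <- cr$labels %in% top2
  group <- factor(cr$labels[in_de], levels = top2)
  covar <- NULL
  if (!is.null(config$covariates)) {
    cv <- read_tsv(config$covariates)
    cv <- cv[match(names(cr$labels)[in_de], cv$sample_id), , drop = FALSE]
    covar <- cv[, setdiff(names(cv), "sample_id"), drop = FALSE]
  }
  degs <- character(0L)
  for (mod in names(prep)) {
    de <- run_diffexpr(prep[[mod]][in_de, , drop = FALSE], group,
                       covariates = covar, fdr = config$fdr,
                       lfc = config$lfc, use_raw_p = config$use_raw_p)
    log_line("de", sprintf("%s: %d significant of %d features", mod,
                           sum(de$significant), nrow(de)))
    put(de, paste0("de_", mod, ".tsv"))
    degs <- union(degs, de$feature_id[de$significant])
  }
  writeLines(sort(degs), file.path(out_dir, "degs.txt"))
  artifacts <- c(artifacts, "degs.txt")

  # --- enrichment -------------------------------------------------------
  if (!is.null(config$gmt) && length(degs) > 0L) {
    ann <- read_gmt(config$gmt)
    enr <- enrich(degs, ann, fdr = config$fdr,
                  min_size = config$enrich_min_size,
                  max_size = config$enrich_max_size)
    log_line("enrich", sprintf("%d terms tested, %d significant",
                               nrow(enr), sum(enr$significant)))
    put(enr, "enrichment.tsv")
  } else {
    log_line("enrich", "skipped (no annotation or no DEGs)")
  }

  # --- PheWAS (optional) ------------------------------------------------
  phewas_inputs <- c("eqtl_table", "genotypes", "pheno_covariates", "events")
  if (all(vapply(phewas_inputs, function(f) !is.null(config[[f]]),
                 logical(1L)))) {
    eqtl <- read_tsv(config$eqtl_table)
    sel <- select_eqtls(eqtl, degs, per_gene = config$eqtl_per_gene,
                        fdr_cut = config$eqtl_fdr)
    if (nrow(sel) == 0L) {
      log_line("phewas", "skipped (no qualifying eQTL for the DEGs)")
    } else {
      geno <- read_omics_tsv(config$genotypes)
      pcov <- read_tsv(config$pheno_covariates)
      events <- read_tsv(config$events)
      roster <- pcov[, c("participant_id", "sex")]
      pheno <- build_phecode_table(events, roster,
                                   min_count = config$phecode_min_count,
                                   one_instance = config$one_instance)
      scan <- logistic_scan(geno[, unique(sel$variant_id), drop = FALSE],
                            pheno, pcov)
      scan <- correct_and_report(scan, raw_cut = config$phewas_raw_cut)
      log_line("phewas", sprintf("%d tests, %d reported at p < %g",
                                 sum(!is.na(scan$p)), sum(scan$reported),
                                 config$phewas_raw_cut))
      put(scan, "phewas.tsv")
      put(sel, "eqtl_selection.tsv")
    }
  } else {
    log_line("phewas", "skipped (genotype/EHR inputs not configured)")
  }

  # --- manifest ---------------------------------------------------------
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  checksums <- as.list(tools::md5sum(file.path(out_dir, artifacts)))
  names(checksums) <- artifacts
  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   seed = config$seed, artifacts = checksums)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
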