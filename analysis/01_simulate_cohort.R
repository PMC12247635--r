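#!/usr/bin/env Rscript

# Simulate the synthetic study cohort: three omics modalities (expression,
# proteomics, methylation) over one patient population with a planted
# two-subtype structure, plus the annotation and genotype/EHR inputs the
# downstream stages need. Everything is written as plain TSV/GMT under
# results/inputs/ so later scripts (and anyone inspecting the run) can read
# them back.

suppressPackageStartupMessages(library(grassmerge))

seed <- 20260901L
out <- "results/inputs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

modalities <- lapply(c("rna", "prot", "meth"), function(nm)
  list(name = nm, n_features = 200L, n_informative = 60L,
       effect_size = 4, noise_sd = 1))
sim <- simulate_multiomics(n_patients = 80L, n_clusters = 2L,
                           modalities = modalities, seed = seed)

for (nm in names(sim$matrices))
  write_omics_tsv(sim$matrices[[nm]], file.path(out, paste0(nm, ".tsv")))
write.table(data.frame(sample_id = names(sim$labels),
                       true_cluster = unname(sim$labels)),
            file.path(out, "true_labels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# annotation over the expression feature space with one planted term covering
# the informative (hence differentially expressed) features
rna_features <- colnames(sim$matrices$rna)
set.seed(seed + 1L)
terms <- c(list(SYNAPSE_LIKE_PLANTED = c(rna_features[1:40],
                                         sample(rna_features[61:200], 10))),
           lapply(1:19, function(i) sample(rna_features, 30)))
names(terms)[-1] <- sprintf("RANDOM_TERM_%02d", 1:19)
write_gmt(list(terms = terms), file.path(out, "annotation.gmt"))

# genotype / EHR bundle: two eQTLs tied to expression DEGs, one with a real
# phenotype effect (per-allele OR 1.8) and one null
gp <- simulate_geno_pheno(
  n_participants = 2000L,
  mafs = c(rs000001 = 0.3, rs000002 = 0.2),
  betas = matrix(c(log(1.8), 0, 0, 0), 2, 2,
                 dimnames = list(c("rs000001", "rs000002"),
                                 c("250.2", "401.1"))),
  beta0 = c(-1.6, -2.0), seed = seed + 2L)
write_omics_tsv(gp$genotypes, file.path(out, "genotypes.tsv"))
write.table(gp$covariates, file.path(out, "participant_covariates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(gp$events, file.path(out, "ehr_events.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(variant_id = c("rs000001", "rs000002"),
                       gene = rna_features[1:2],
                       effect = c(0.42, -0.17), fdr = c(3e-7, 8e-6)),
            file.path(out, "eqtl_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("cohort: ", length(sim$labels), " patients, ",
        length(sim$matrices), " modalities; ",
        nrow(gp$covariates), " genotyped participants; inputs under ", out)
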