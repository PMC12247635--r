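#!/usr/bin/env Rscript

# eQTL PheWAS stage: select the top eQTLs of the DEGs (FDR < 1e-4, at most
# three per gene), build phecode case/control phenotypes from the EHR event
# stream (>= 2 distinct instances = case, single instance excluded,
# < 20 cases-or-controls dropped), and scan each (variant, phecode) pair
# with logistic regression adjusted for age, sex and six PCs.

suppressPackageStartupMessages(library(grassmerge))

inp <- "results/inputs"
out <- "results"

degs <- readLines(file.path(out, "degs.txt"))
eqtl <- read.delim(file.path(inp, "eqtl_summary.tsv"))
sel <- select_eqtls(eqtl, degs, per_gene = 3L, fdr_cut = 1e-4)
message(nrow(sel), " eQTLs selected for ", length(unique(sel$gene)),
        " DEG(s)")

geno <- read_omics_tsv(file.path(inp, "genotypes.tsv"))
covars <- read.delim(file.path(inp, "participant_covariates.tsv"),
                     check.names = FALSE)
events <- read.delim(file.path(inp, "ehr_events.tsv"),
                     colClasses = c(phecode = "character"))

pheno <- build_phecode_table(events,
                             covars[, c("participant_id", "sex")],
                             min_count = 20L)
message(ncol(pheno$status), " phecodes retained (",
        length(pheno$dropped), " dropped by the 20/20 filter)")

scan <- logistic_scan(geno[, unique(sel$variant_id), drop = FALSE],
                      pheno, covars)
scan <- correct_and_report(scan, raw_cut = 1e-4)
write.table(scan, file.path(out, "phewas.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sum(!is.na(scan$p)), " association tests; ",
        sum(scan$reported), " reported at p < 1e-4; ",
        sum(scan$eqtl_significant), " significant under per-eQTL BH")
print(scan[order(scan$p), c("variant", "phecode", "OR", "p",
                            "p_adj_global", "p_adj_eqtl")],
      row.names = FALSE, digits = 3)
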