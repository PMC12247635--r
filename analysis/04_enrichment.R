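#!/usr/bin/env Rscript

# Hypergeometric over-representation analysis of the expression DEGs against
# the annotation, BH-adjusted across terms, qscore = -log10(adjusted p).

suppressPackageStartupMessages(library(grassmerge))

out <- "results"
degs <- readLines(file.path(out, "degs.txt"))
ann <- read_gmt(file.path(out, "inputs", "annotation.gmt"))

# the annotation universe is the expression feature space; DEGs from other
# modalities are outside it and are dropped by enrich() with a warning
res <- suppressWarnings(enrich(degs, ann, fdr = 0.05))
write.table(res, file.path(out, "enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message(nrow(res), " terms tested, ", sum(res$significant), " significant")
message("top terms:")
print(head(res[, c("term_id", "K", "overlap", "p_adj", "qscore")], 5),
      row.names = FALSE)
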