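#!/usr/bin/env Rscript

# Moderated-t differential expression between the two discovered patient
# clusters, run independently per modality (as for brain expression,
# proteomics and methylation), with the FDR < 0.05 and |logFC| >= 0.7
# calling rule. Writes one DE table per modality and the pooled DEG list.

suppressPackageStartupMessages(library(grassmerge))

inp <- "results/inputs"
out <- "results"

raw <- lapply(c(rna = "rna", prot = "prot", meth = "meth"),
              function(nm) read_omics_tsv(file.path(inp, paste0(nm, ".tsv"))))
prep <- preprocess_modalities(raw)
clusters <- read.delim(file.path(out, "clusters.tsv"))
group <- factor(clusters$cluster[match(rownames(prep$rna),
                                       clusters$sample_id)])

degs <- character(0)
for (nm in names(prep)) {
  de <- run_diffexpr(prep[[nm]], group, fdr = 0.05, lfc = 0.7)
  write.table(de, file.path(out, paste0("de_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  n_up <- sum(de$significant & de$direction == "up")
  n_down <- sum(de$significant & de$direction == "down")
  message(sprintf("%-5s %4d features: %d significant (%d up, %d down)",
                  nm, nrow(de), sum(de$significant), n_up, n_down))
  degs <- union(degs, de$feature_id[de$significant])
}
writeLines(sort(degs), file.path(out, "degs.txt"))
message(length(degs), " DEGs pooled across modalities -> results/degs.txt")
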