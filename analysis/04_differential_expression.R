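#!/usr/bin/env Rscript

# Step 4 — differential expression over the 13-point growth curve: each
# TSSaRNA is represented by the tiling probe best covering it without
# crossing its 3' end; V(t) = M_probe(t) - M_cognate(t) on the log10 scale
# is evaluated at the time point with the second-largest |V|, and the call
# additionally needs a 2-fold difference from an upstream control region.

suppressPackageStartupMessages(library(tssarna))

indir <- "results/synthetic"
annotation <- load_annotation(file.path(indir, "genome.gff3"))
calls <- readr::read_tsv("results/tssarna_calls_primary.tsv",
                         show_col_types = FALSE)
probes <- readr::read_tsv(file.path(indir, "probes.tsv"),
                          show_col_types = FALSE)
truth <- readr::read_tsv(file.path(indir, "truth.tsv"), show_col_types = FALSE)

de <- de_call_all(calls, probes, annotation, de_params())
flat <- de[, setdiff(names(de), c("v_gene", "v_upstream"))]
readr::write_tsv(flat, "results/tssarna_de_calls.tsv")

cat(sprintf("%d of %d evaluable TSSaRNAs called differentially expressed\n",
            sum(de$is_de, na.rm = TRUE), sum(de$status == "ok")))
print(table(status = de$status))
m <- match(de$gene_id, truth$gene_id)
print(table(planted = truth$is_de[m], called = de$is_de, useNA = "ifany"))
updown <- table(de$direction[de$is_de])
cat("direction of DE calls:\n")
print(updown)
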