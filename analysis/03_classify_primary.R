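#!/usr/bin/env Rscript

# Step 3 — primary-transcript classification: for every call, count 5' ends
# at the TSS in the TEX-treated and untreated libraries and flag calls with
# at least 95% library-size-normalized TEX+ enrichment as primary
# transcripts.

suppressPackageStartupMessages(library(tssarna))

indir <- "results/synthetic"
calls <- readr::read_tsv("results/tssarna_calls.tsv", show_col_types = FALSE)
tex_plus <- load_reads(file.path(indir, "tex_plus.bed"))
tex_minus <- load_reads(file.path(indir, "tex_minus.bed"))
truth <- readr::read_tsv(file.path(indir, "truth.tsv"), show_col_types = FALSE)

cls <- classify_primary(calls, tex_plus, tex_minus, threshold = 0.95)
readr::write_tsv(cls, "results/tssarna_calls_primary.tsv")

cat(sprintf("%d of %d TSSaRNAs classified primary (threshold 0.95)\n",
            sum(cls$is_primary), nrow(cls)))
m <- match(cls$gene_id, truth$gene_id)
agree <- sum(cls$is_primary == truth$is_primary[m])
cat(sprintf("agreement with planted primary flags: %d / %d\n",
            agree, nrow(cls)))
cat(sprintf("enrichment: primary %.3f-%.3f, processed %.3f-%.3f\n",
            min(cls$enrichment[cls$is_primary]),
            max(cls$enrichment[cls$is_primary]),
            min(cls$enrichment[!cls$is_primary]),
            max(cls$enrichment[!cls$is_primary])))
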