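#!/usr/bin/env Rscript

# Step 1 — build the synthetic study: a toy replicon with annotated CDSs,
# planted TSSaRNA read populations (one abundant full-length species plus
# truncated cognate-gene reads sharing the 5' start, plus background noise),
# a TEX+/TEX- dRNA-seq pair, and a 13-time-point tiling-probe matrix.
# Everything downstream (steps 02-04) reads the files written here.

suppressPackageStartupMessages(library(tssarna))

seed <- 20140901L
outdir <- "results/synthetic"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

genome <- synth_genome(n_genes = 30, replicon_length = 90000,
                       seed = seed, dir = outdir)
plants <- random_plants(genome$annotation, seed = seed + 1)
syn <- synth_reads(genome$annotation, plants, genome$replicon_length,
                   noise_rate = 5, seed = seed + 2)
tex <- synth_tex_pair(syn$truth, depletion_factor = 100)
probes <- synth_probe_matrix(genome$annotation, syn$truth,
                             genome$replicon_length, seed = seed + 3)

write_reads_bed(syn$reads, file.path(outdir, "smallrna_reads.bed"))
write_reads_bed(tex$tex_plus, file.path(outdir, "tex_plus.bed"))
write_reads_bed(tex$tex_minus, file.path(outdir, "tex_minus.bed"))
readr::write_tsv(probes$probes, file.path(outdir, "probes.tsv"))
truth <- syn$truth
truth$replicon_length <- genome$replicon_length
readr::write_tsv(truth, file.path(outdir, "truth.tsv"))

cat(sprintf(
  "simulated %d genes on a %d bp replicon; planted %d TSSaRNAs (%d primary, %d DE)\n",
  nrow(genome$annotation), genome$replicon_length, nrow(syn$truth),
  sum(syn$truth$is_primary), sum(syn$truth$is_de)))
cat(sprintf("reads: %d small-RNA (incl. noise), %d TEX+, %d TEX-; probes: %d\n",
            nrow(syn$reads), nrow(tex$tex_plus), nrow(tex$tex_minus),
            nrow(probes$probes)))
cat("wrote", outdir, "\n")
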