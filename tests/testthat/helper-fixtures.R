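# strand-mirror helpers: reflect every coordinate about a replicon of
# length L (0-based half-open intervals map [s, e) -> [L - e, L - s))

mirror_reads <- function(reads, L) {
  aligned_reads(
    replicon = reads$replicon,
    start = L - reads$end,
    end = L - reads$start,
    strand = ifelse(reads$strand == "+", "-", "+")
  )
}

mirror_annotation <- function(ann, L) {
  out <- tibble::tibble(
    gene_id = ann$gene_id,
    replicon = ann$replicon,
    strand = ifelse(ann$strand == "+", "-", "+"),
    cds_start = L - ann$cds_end,
    cds_end = L - ann$cds_start
  )
  out$length <- out$cds_end - out$cds_start
  out
}

# one planted TSS population built directly: n_species identical reads of
# species_len plus cognate reads of distinct longer lengths, all sharing the
# 5' start
plant_reads_at <- function(replicon, tss, strand, species_len, n_species,
                           cognate_lens) {
  lens <- c(rep(species_len, n_species), cognate_lens)
  if (strand == "+") {
    aligned_reads(replicon, rep(tss, length(lens)), tss + lens, strand)
  } else {
    aligned_reads(replicon, tss + 1L - lens, rep(tss + 1L, length(lens)), strand)
  }
}

one_gene_annotation <- function(strand = "+", cds_start = 2000L,
                                cds_end = 3000L) {
  tibble::tibble(gene_id = "G1", replicon = "chr", strand = strand,
                 cds_start = cds_start, cds_end = cds_end,
                 length = cds_end - cds_start)
}

write_sam_fixture <- function(path) {
  # two plus-strand 27-mers at 0-based start 995, one minus-strand read with
  # 5' end at 1021, one unmapped record (flag 4) that must be skipped
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr\tLN:50000",
    paste("r1", 0, "chr", 996, 42, "27M", "*", 0, 0,
          strrep("A", 27), "*", sep = "\t"),
    paste("r2", 0, "chr", 996, 42, "27M", "*", 0, 0,
          strrep("A", 27), "*", sep = "\t"),
    paste("r3", 16, "chr", 1000, 42, "22M", "*", 0, 0,
          strrep("A", 22), "*", sep = "\t"),
    paste("r4", 4, "*", 0, 0, "*", "*", 0, 0, strrep("A", 20), "*", sep = "\t")
  )
  writeLines(lines, path)
  path
}
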