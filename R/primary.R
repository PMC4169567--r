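#' TEX+ enrichment score
#'
#' Fraction of library-size-normalized signal at a TSS that is TEX-resistant:
#' with `n+ = tex_plus_count / lib_size_plus` and
#' `n- = tex_minus_count / lib_size_minus`, the score is `n+ / (n+ + n-)`.
#' Defined as 0 when both normalized counts are 0 (absence of evidence never
#' creates a primary call). Vectorized.
#'
#' @param tex_plus_count,tex_minus_count reads at the TSS in the TEX-treated
#'   and untreated libraries.
#' @param lib_size_plus,lib_size_minus total aligned reads per library.
#' @return Enrichment proportion(s) in \[0, 1\].
#' @export
enrichment_score <- function(tex_plus_count, tex_minus_count,
                             lib_size_plus = 1, lib_size_minus = 1) {
  if (any(tex_plus_count < 0) || any(tex_minus_count < 0)) {
    stop("read counts must be non-negative")
  }
  if (any(lib_size_plus <= 0) || any(lib_size_minus <= 0)) {
    stop("library sizes must be positive")
  }
  np <- tex_plus_count / lib_size_plus
  nm <- tex_minus_count / lib_size_minus
  ifelse(np + nm == 0, 0, np / (np + nm))
}

#' Classify TSSaRNAs as primary transcripts
#'
#' Counts, for each call, the reads in the TEX-treated and untreated dRNA-seq
#' libraries whose 5' end falls at the call's TSS (within `fuzz` bp) on its
#' strand, and flags the call primary when the TEX+ enrichment is at least
#' `threshold`.
#'
#' @param calls calls tibble from [detect_tssarnas()].
#' @param tex_plus_reads,tex_minus_reads read tibbles from [load_reads()].
#' @param threshold enrichment needed for a primary call (default 0.95).
#' @param normalize divide counts by library size before comparing
#'   (default TRUE).
#' @param fuzz half-width in bp of the 5'-end matching window (default 0:
#'   exact single-base equality).
#' @return `calls` with added columns `tex_plus_count`, `tex_minus_count`,
#'   `enrichment`, `is_primary`.
#' @export
classify_primary <- function(calls, tex_plus_reads, tex_minus_reads,
                             threshold = 0.95, normalize = TRUE, fuzz = 0L) {
  count_at <- function(reads, call) {
    sum(reads$replicon == call$replicon & reads$strand == call$strand &
          abs(reads$five_prime - call$tss) <= fuzz)
  }
  lp <- if (normalize) max(nrow(tex_plus_reads), 1L) else 1
  lm <- if (normalize) max(nrow(tex_minus_reads), 1L) else 1
  np <- integer(nrow(calls))
  nm <- integer(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    np[i] <- count_at(tex_plus_reads, calls[i, ])
    nm[i] <- count_at(tex_minus_reads, calls[i, ])
  }
  calls$tex_plus_count <- np
  calls$tex_minus_count <- nm
  calls$enrichment <- enrichment_score(np, nm, lp, lm)
  calls$is_primary <- calls$enrichment >= threshold
  calls
}
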