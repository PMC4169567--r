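#' Detection parameters
#'
#' Thresholds of the TSSaRNA calling procedure. The TSS search window starts
#' `upstream_window` bp upstream of the translation start site and extends
#' `floor(cds_fraction * length)` bp into the CDS. A TSS is retained only if
#' its start-coordinate pileup sums to strictly more than `min_tss_count`
#' reads; the TSSaRNA species must be shorter than `max_read_len` and carry
#' at least `min_tssarna_count` identical reads.
#'
#' @param upstream_window bp upstream of the start codon searched (default 50).
#' @param cds_fraction fraction of the CDS length searched downstream of the
#'   start codon (default 0.20).
#' @param min_tss_count strict lower bound on total reads at the TSS
#'   (default 20: "more than 20").
#' @param max_read_len TSSaRNA species must be shorter than this (default 151,
#'   the sequencing cycle limit).
#' @param min_tssarna_count inclusive lower bound on full-length species reads
#'   (default 10: "at least 10").
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(upstream_window = 50L, cds_fraction = 0.20,
                             min_tss_count = 20L, max_read_len = 151L,
                             min_tssarna_count = 10L) {
  stopifnot(upstream_window > 0, cds_fraction > 0, cds_fraction <= 1,
            min_tss_count > 0, max_read_len > 0, min_tssarna_count > 0)
  structure(list(
    upstream_window = as.integer(upstream_window),
    cds_fraction = cds_fraction,
    min_tss_count = as.integer(min_tss_count),
    max_read_len = as.integer(max_read_len),
    min_tssarna_count = as.integer(min_tssarna_count)
  ), class = "detection_params")
}

#' TSS search window for one gene
#'
#' Strand-aware interval around the translation start: `upstream_window` bp
#' upstream of the start codon plus `floor(cds_fraction * length)` bp into
#' the CDS. On the minus strand the interval is mirrored about the gene's
#' 5' end.
#'
#' @param gene one annotation row (list or single-row tibble).
#' @param params [detection_params()].
#' @return A list with `start`, `end` (0-based half-open) and `anchor`
#'   (the start-codon coordinate, i.e. the gene's 5'-most base).
#' @export
search_window <- function(gene, params = detection_params()) {
  len <- gene$cds_end - gene$cds_start
  ingene <- as.integer(floor(params$cds_fraction * len))
  if (gene$strand == "+") {
    anchor <- gene$cds_start
    list(start = anchor - params$upstream_window, end = anchor + ingene,
         anchor = anchor)
  } else {
    anchor <- gene$cds_end - 1L
    list(start = gene$cds_end - ingene, end = gene$cds_end + params$upstream_window,
         anchor = anchor)
  }
}

# find_tss with the rejection reason; used by detect_tssarnas for the audit
find_tss_detail <- function(gene, profile, params) {
  win <- search_window(gene, params)
  st <- profile$starts
  st <- st[st$replicon == gene$replicon & st$strand == gene$strand &
             st$coord >= win$start & st$coord < win$end, , drop = FALSE]
  if (nrow(st) == 0) {
    return(list(tss = NA_integer_, reason = "no_window_signal"))
  }
  best <- max(st$count)
  if (best <= params$min_tss_count) {
    return(list(tss = NA_integer_, reason = "below_tss_threshold"))
  }
  cand <- st$coord[st$count == best]
  if (length(cand) > 1) {
    # tie: closest to the start codon, then the more upstream coordinate
    d <- abs(cand - win$anchor)
    cand <- cand[d == min(d)]
    if (length(cand) > 1) {
      cand <- if (gene$strand == "+") min(cand) else max(cand)
    }
  }
  list(tss = as.integer(cand[1]), reason = NA_character_)
}

#' Locate the TSS of one gene
#'
#' Returns the coordinate inside [search_window()] with the maximal read
#' 5'-start count, provided that count exceeds `min_tss_count` (strict);
#' `NA` otherwise. Ties go to the coordinate closest to the start codon,
#' then the more upstream one.
#'
#' @inheritParams search_window
#' @param profile a [compute_start_profile()] object built from reads on the
#'   gene's replicon.
#' @return Genomic coordinate (0-based) or `NA`.
#' @export
find_tss <- function(gene, profile, params = detection_params()) {
  find_tss_detail(gene, profile, params)$tss
}

empty_calls <- function() {
  tibble::tibble(
    gene_id = character(), replicon = character(), strand = character(),
    tss = integer(), tssarna_end = integer(), tssarna_length = integer(),
    tssarna_count = integer(), tss_total_count = integer(),
    cognate_count = integer(), distance_to_start_codon = integer()
  )
}

#' Split the read population at a TSS into TSSaRNA and cognate reads
#'
#' Groups the reads sharing the 5' start `tss` by their exact (5', 3')
#' extent. Among species shorter than `max_read_len`, the most abundant one
#' is the TSSaRNA full-length sequence (ties: the shorter species); all other
#' reads at the TSS belong to the cognate gene. A call is returned only if
#' the species carries at least `min_tssarna_count` reads.
#'
#' @inheritParams search_window
#' @param tss genomic coordinate of the shared 5' start.
#' @param reads_at_tss tibble of reads whose `five_prime` equals `tss` and
#'   whose strand matches the gene.
#' @return A single-row calls tibble, or `NULL` when no species qualifies.
#' @export
call_tssarna <- function(gene, tss, reads_at_tss, params = detection_params()) {
  call_tssarna_detail(gene, tss, reads_at_tss, params)$call
}

call_tssarna_detail <- function(gene, tss, reads_at_tss, params) {
  stopifnot(all(reads_at_tss$five_prime == tss),
            all(reads_at_tss$strand == gene$strand))
  total <- nrow(reads_at_tss)
  species <- dplyr::count(reads_at_tss, .data$start, .data$end, name = "count")
  species$len <- species$end - species$start
  short <- species[species$len < params$max_read_len, , drop = FALSE]
  if (nrow(short) == 0) {
    return(list(call = NULL, reason = "no_short_species"))
  }
  short <- short[order(-short$count, short$len), , drop = FALSE]
  top <- short[1, ]
  if (top$count < params$min_tssarna_count) {
    return(list(call = NULL, reason = "below_tssarna_threshold"))
  }
  anchor <- if (gene$strand == "+") gene$cds_start else gene$cds_end - 1L
  dist <- if (gene$strand == "+") tss - anchor else anchor - tss
  call <- tibble::tibble(
    gene_id = gene$gene_id,
    replicon = gene$replicon,
    strand = gene$strand,
    tss = as.integer(tss),
    tssarna_end = as.integer(if (gene$strand == "+") top$end - 1L else top$start),
    tssarna_length = as.integer(top$len),
    tssarna_count = as.integer(top$count),
    tss_total_count = as.integer(total),
    cognate_count = as.integer(total - top$count),
    distance_to_start_codon = as.integer(dist)
  )
  list(call = call, reason = NA_character_)
}

#' Detect TSSaRNAs over a whole annotation
#'
#' Applies [search_window()], [find_tss()] and [call_tssarna()] to every
#' gene. At most one TSSaRNA is called per gene. Output is ordered by
#' (replicon, tss).
#'
#' @param annotation tibble from [load_annotation()].
#' @param reads tibble from [load_reads()] / [aligned_reads()].
#' @param params [detection_params()].
#' @return A list with `calls` (one row per TSSaRNA; columns `gene_id`,
#'   `replicon`, `strand`, `tss`, `tssarna_end`, `tssarna_length`,
#'   `tssarna_count`, `tss_total_count`, `cognate_count`,
#'   `distance_to_start_codon`) and `audit` (one row per gene with the call
#'   status or rejection reason).
#' @export
detect_tssarnas <- function(annotation, reads, params = detection_params()) {
  if (nrow(annotation) == 0 || nrow(reads) == 0) {
    return(list(calls = empty_calls(),
                audit = tibble::tibble(gene_id = annotation$gene_id,
                                       status = rep("no_window_signal",
                                                    nrow(annotation)))))
  }
  profile <- compute_start_profile(reads)
  rows <- vector("list", nrow(annotation))
  status <- character(nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    gene <- annotation[i, ]
    hit <- find_tss_detail(gene, profile, params)
    if (is.na(hit$tss)) {
      status[i] <- hit$reason
      next
    }
    at_tss <- reads[reads$replicon == gene$replicon &
                      reads$strand == gene$strand &
                      reads$five_prime == hit$tss, , drop = FALSE]
    res <- call_tssarna_detail(gene, hit$tss, at_tss, params)
    if (is.null(res$call)) {
      status[i] <- res$reason
      next
    }
    rows[[i]] <- res$call
    status[i] <- "called"
  }
  calls <- dplyr::bind_rows(rows)
  if (nrow(calls) == 0) calls <- empty_calls()
  calls <- dplyr::arrange(calls, .data$replicon, .data$tss)
  list(calls = calls,
       audit = tibble::tibble(gene_id = annotation$gene_id, status = status))
}
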