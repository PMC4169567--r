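#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

# All coordinates inside the package are 0-based half-open; GFF3 and SAM/BAM
# (1-based) are converted on ingest and egress. BED6 is taken as-is.

#' Build a tibble of aligned reads
#'
#' Constructor used by loaders, generators and tests. Coordinates are 0-based
#' half-open. The 5' end of a read is its `start` on the plus strand and
#' `end - 1` on the minus strand.
#'
#' @param replicon character vector of replicon names.
#' @param start,end integer genomic coordinates, 0-based half-open.
#' @param strand character vector of `"+"`/`"-"`.
#' @return A tibble with columns `replicon`, `start`, `end`, `strand`,
#'   `five_prime`, `length`.
#' @export
aligned_reads <- function(replicon, start, end, strand) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start >= end)) {
    stop("invalid read interval: start must be < end (0-length records are not allowed)")
  }
  if (!all(strand %in% c("+", "-"))) {
    stop("read strand must be '+' or '-'")
  }
  tibble::tibble(
    replicon = as.character(replicon),
    start = start,
    end = end,
    strand = as.character(strand),
    five_prime = ifelse(strand == "+", start, end - 1L),
    length = end - start
  )
}

#' Load a CDS annotation
#'
#' Reads a GFF3 file (via rtracklayer) or a tab-delimited CDS table with
#' columns `gene_id`, `replicon`, `strand`, `start`, `end` (1-based inclusive,
#' as in GFF3). Coordinates are converted to the internal 0-based half-open
#' convention.
#'
#' @param path path to a `.gff`/`.gff3` file or a tab-delimited table.
#' @return A tibble with columns `gene_id`, `replicon`, `strand`,
#'   `cds_start`, `cds_end`, `length`.
#' @export
load_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    if (length(gr) == 0) return(empty_annotation())
    is_cds <- !is.null(gr$type) && any(gr$type == "CDS")
    if (is_cds) gr <- gr[gr$type == "CDS"]
    ids <- gr$ID
    if (is.null(ids)) ids <- gr$locus_tag
    if (is.null(ids) || anyNA(ids)) stop("GFF3 features must carry an ID attribute")
    ann <- tibble::tibble(
      gene_id = as.character(ids),
      replicon = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      cds_start = GenomicRanges::start(gr) - 1L,
      cds_end = GenomicRanges::end(gr)
    )
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    needed <- c("gene_id", "replicon", "strand", "start", "end")
    if (!all(needed %in% names(tab))) {
      stop("CDS table must have columns: ", paste(needed, collapse = ", "))
    }
    if (nrow(tab) == 0) return(empty_annotation())
    ann <- tibble::tibble(
      gene_id = as.character(tab$gene_id),
      replicon = as.character(tab$replicon),
      strand = as.character(tab$strand),
      cds_start = as.integer(tab$start) - 1L,
      cds_end = as.integer(tab$end)
    )
  }
  validate_annotation(ann)
}

empty_annotation <- function() {
  tibble::tibble(
    gene_id = character(), replicon = character(), strand = character(),
    cds_start = integer(), cds_end = integer(), length = integer()
  )
}

validate_annotation <- function(ann) {
  if (!all(ann$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  bad <- which(ann$cds_start >= ann$cds_end)
  if (length(bad)) {
    stop("invalid CDS interval (start >= end after conversion) for gene ",
         ann$gene_id[bad[1]])
  }
  dup <- unique(ann$gene_id[duplicated(ann$gene_id)])
  if (length(dup)) {
    stop("duplicated gene_id in annotation: ", paste(dup, collapse = ", "))
  }
  ann$length <- ann$cds_end - ann$cds_start
  ann
}

#' Write an annotation to GFF3
#'
#' @param annotation tibble as returned by [load_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$replicon,
    ranges = IRanges::IRanges(start = annotation$cds_start + 1L,
                              end = annotation$cds_end),
    strand = annotation$strand
  )
  gr$type <- "CDS"
  gr$ID <- annotation$gene_id
  gr$source <- "tssarna"
  gr$phase <- 0L
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Load aligned reads
#'
#' Accepts BED6 (0-based half-open, taken as-is), SAM or BAM (1-based POS,
#' converted). Records without a strand are skipped; the number skipped is
#' reported as a warning.
#'
#' @param path path to a `.bed`, `.sam` or `.bam` file.
#' @return A tibble of reads as from [aligned_reads()].
#' @export
load_reads <- function(path) {
  if (!file.exists(path)) stop("read file not found: ", path)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "bed")
  } else if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE)) {
    bam <- path
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
      bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                              indexDestination = FALSE)
    }
    gr <- read_bam_granges(bam)
  } else {
    stop("unrecognised read file format (expected .bed, .sam or .bam): ", path)
  }
  str <- as.character(GenomicRanges::strand(gr))
  n_skipped <- sum(!str %in% c("+", "-"))
  if (n_skipped > 0) {
    warning(n_skipped, " record(s) without strand skipped")
    gr <- gr[str %in% c("+", "-")]
    str <- str[str %in% c("+", "-")]
  }
  if (length(gr) == 0) {
    return(aligned_reads(character(), integer(), 1L, character())[0, ])
  }
  aligned_reads(
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = str
  )
}

# BAM ingestion kept in one place; scanBam suffices for plain ungapped
# small-RNA alignments.
read_bam_granges <- function(bam) {
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "qwidth", "cigar"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  width <- cigar_ref_width(res$cigar, res$qwidth)
  GenomicRanges::GRanges(
    seqnames = as.character(res$rname),
    ranges = IRanges::IRanges(start = res$pos, width = width),
    strand = as.character(res$strand)
  )
}

# reference-space width from CIGAR (M/D/N/=/X consume reference)
cigar_ref_width <- function(cigar, qwidth) {
  vapply(seq_along(cigar), function(i) {
    cg <- cigar[i]
    if (is.na(cg) || cg == "*") return(as.integer(qwidth[i]))
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    kinds <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
    sum(lens[kinds %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}

#' Write reads to BED6
#'
#' @param reads tibble of reads as from [aligned_reads()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  df <- data.frame(
    chrom = reads$replicon,
    start = reads$start,
    end = reads$end,
    name = sprintf("read%06d", seq_len(nrow(reads))),
    score = 0L,
    strand = reads$strand
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Compute strand-aware 5'-start and coverage profiles
#'
#' Tallies, per (replicon, strand), how many reads have their 5' end at each
#' genomic coordinate (the "start profile"), and the depth of coverage at
#' each coordinate.
#'
#' @param reads tibble of reads as from [aligned_reads()].
#' @return An object of class `start_profile`: a list with tibbles `starts`
#'   and `coverage`, each with columns `replicon`, `strand`, `coord`, `count`
#'   (zero-count coordinates omitted).
#' @export
compute_start_profile <- function(reads) {
  if (nrow(reads) == 0) stop("no reads supplied")
  starts <- reads %>%
    dplyr::count(.data$replicon, .data$strand, coord = .data$five_prime,
                 name = "count") %>%
    dplyr::arrange(.data$replicon, .data$strand, .data$coord)
  coverage <- reads %>%
    dplyr::group_by(.data$replicon, .data$strand) %>%
    dplyr::group_modify(function(d, key) {
      cov <- IRanges::coverage(IRanges::IRanges(start = d$start + 1L,
                                                end = d$end))
      pos <- which(as.integer(cov) > 0)
      tibble::tibble(coord = pos - 1L, count = as.integer(cov)[pos])
    }) %>%
    dplyr::ungroup()
  structure(list(starts = starts, coverage = coverage),
            class = "start_profile")
}

#' @export
print.start_profile <- function(x, ...) {
  n_rep <- length(unique(x$starts$replicon))
  cat("<start_profile> ", sum(x$starts$count), " read starts over ",
      n_rep, " replicon(s)\n", sep = "")
  invisible(x)
}
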