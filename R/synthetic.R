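#' @importFrom stats runif median
NULL

# triangular sampler used for study-like TSSaRNA length draws
rtri <- function(n, lo, mode, hi) {
  u <- runif(n)
  fc <- (mode - lo) / (hi - lo)
  x <- ifelse(u < fc,
              lo + sqrt(u * (hi - lo) * (mode - lo)),
              hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
  as.integer(round(x))
}

#' Generate a toy genome and CDS annotation
#'
#' Places non-overlapping genes of varied length on both strands of a single
#' replicon, with gaps wide enough for upstream search windows and upstream
#' control regions. Deterministic per seed.
#'
#' @param n_genes number of genes.
#' @param replicon_length replicon size, bp.
#' @param seed integer seed.
#' @param replicon replicon name.
#' @param gene_len 2-vector, min/max gene length, bp.
#' @param min_gap minimum intergenic gap, bp (default 700, leaving room for
#'   the 420-bp upstream control span plus probe tiling).
#' @param dir if non-NULL, write `genome.gff3` and `genome.fasta` there.
#' @return A list with `annotation` (tibble as from [load_annotation()]),
#'   `sequence` (a [Biostrings::DNAStringSet]), `replicon_length`, and
#'   `paths` when `dir` was given.
#' @export
synth_genome <- function(n_genes, replicon_length, seed, replicon = "chrS",
                         gene_len = c(400, 2400), min_gap = 700L, dir = NULL) {
  out <- withr::with_seed(seed, {
    if (n_genes > 0) {
      lens <- sample(seq(gene_len[1], gene_len[2]), n_genes, replace = TRUE)
      strands <- sample(c("+", "-"), n_genes, replace = TRUE)
      if (n_genes >= 2) { # both strands represented
        strands[1] <- "+"
        strands[2] <- "-"
      }
      gaps <- min_gap + sample(0:300, n_genes, replace = TRUE)
      starts <- 500L + cumsum(gaps) + c(0L, cumsum(lens[-n_genes]))
      ends <- starts + lens
      if (max(ends) > replicon_length - 500L) {
        stop("infeasible packing: ", n_genes, " genes do not fit in ",
             replicon_length, " bp at the requested spacing")
      }
      ann <- tibble::tibble(
        gene_id = sprintf("SYN%04d", seq_len(n_genes)),
        replicon = replicon, strand = strands,
        cds_start = as.integer(starts), cds_end = as.integer(ends),
        length = as.integer(lens)
      )
    } else {
      ann <- empty_annotation()
    }
    seq <- paste(sample(c("A", "C", "G", "T"), replicon_length,
                        replace = TRUE), collapse = "")
    list(annotation = ann, seq = seq)
  })
  dna <- Biostrings::DNAStringSet(out$seq)
  names(dna) <- replicon
  res <- list(annotation = out$annotation, sequence = dna,
              replicon_length = as.integer(replicon_length))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    gff <- file.path(dir, "genome.gff3")
    fa <- file.path(dir, "genome.fasta")
    write_annotation_gff3(out$annotation, gff)
    Biostrings::writeXStringSet(dna, fa)
    res$paths <- c(gff = gff, fasta = fa)
  }
  res
}

#' Draw a study-like plant specification
#'
#' One planted TSSaRNA per selected gene, with lengths from a triangular
#' distribution on \[16, 146\] nt with mode 27 nt (echoing the observed
#' 16-146 nt range and 27 nt median), counts above the detection thresholds,
#' and primary/differential-expression flags.
#'
#' @param annotation tibble from [synth_genome()] / [load_annotation()].
#' @param seed integer seed.
#' @param genes gene_ids to plant on (default: all).
#' @param tssarna_count 2-vector count range for the full-length species.
#' @param cognate_count 2-vector count range for cognate reads at the TSS.
#' @param frac_primary fraction of plants flagged primary.
#' @param frac_de fraction flagged differentially expressed.
#' @param de_fold linear fold for DE plants (default 16, the largest
#'   regulation magnitude observed on the growth curve; comfortably above
#'   the 10-fold calling threshold so array noise does not straddle it).
#' @param len_range,len_mode triangular length distribution parameters, nt.
#' @param min_de_len only plants at least this long are eligible for the DE
#'   flag (default 24 nt: a tiling probe must fit wholly inside the TSSaRNA
#'   for it to have a representative probe at the default 20-bp/5-bp tiling,
#'   the same physical constraint the array imposes).
#' @return A plants tibble consumable by [synth_reads()].
#' @export
random_plants <- function(annotation, seed, genes = annotation$gene_id,
                          tssarna_count = c(25L, 60L),
                          cognate_count = c(12L, 30L),
                          frac_primary = 0.6, frac_de = 0.5, de_fold = 16,
                          len_range = c(16L, 146L), len_mode = 27L,
                          min_de_len = 24L) {
  n <- length(genes)
  withr::with_seed(seed, {
    lens <- rtri(n, len_range[1], len_mode, len_range[2])
    eligible <- which(lens >= min_de_len)
    n_de <- min(round(frac_de * n), length(eligible))
    de_idx <- sample(eligible, n_de)
    tibble::tibble(
      gene_id = genes,
      tss_offset = 0L, # leaderless transcripts: TSS at the start codon
      tssarna_length = lens,
      tssarna_count = sample(seq(tssarna_count[1], tssarna_count[2]), n, TRUE),
      cognate_count = sample(seq(cognate_count[1], cognate_count[2]), n, TRUE),
      is_primary = seq_len(n) %in% sample(n, round(frac_primary * n)),
      is_de = seq_len(n) %in% de_idx,
      de_fold = de_fold,
      de_direction = sample(c("up", "down"), n, TRUE)
    )
  })
}

plant_tss <- function(gene, tss_offset) {
  if (gene$strand == "+") gene$cds_start + tss_offset
  else (gene$cds_end - 1L) - tss_offset
}

#' Emit planted small-RNA reads with a truth table
#'
#' At each planted TSS: `tssarna_count` identical reads of the planted
#' length, plus `cognate_count` reads of assorted longer lengths (uniform on
#' `(tssarna_length, max_read_len]`, drawn without replacement while
#' possible) sharing the same 5' start; plus uniform background noise reads.
#'
#' @param annotation tibble from [synth_genome()].
#' @param plants tibble from [random_plants()] (columns `gene_id`,
#'   `tss_offset`, `tssarna_length`, `tssarna_count`, `cognate_count`, and
#'   optionally `is_primary`, `is_de`, `de_fold`, `de_direction`).
#' @param replicon_length replicon size, bp (for noise placement).
#' @param noise_rate background reads per kb (default 0).
#' @param max_read_len sequencing length limit, nt (default 151).
#' @param seed integer seed.
#' @return A list with `reads` (tibble as from [aligned_reads()]) and
#'   `truth` (one row per plant with the planted values detection must
#'   recover).
#' @export
synth_reads <- function(annotation, plants, replicon_length,
                        noise_rate = 0, max_read_len = 151L, seed = 1L) {
  missing_genes <- setdiff(plants$gene_id, annotation$gene_id)
  if (length(missing_genes)) {
    stop("plants reference unknown gene(s): ",
         paste(missing_genes, collapse = ", "))
  }
  withr::with_seed(seed, {
    read_rows <- list()
    truth_rows <- list()
    for (i in seq_len(nrow(plants))) {
      pl <- plants[i, ]
      gene <- annotation[annotation$gene_id == pl$gene_id, ][1, ]
      tss <- plant_tss(gene, pl$tss_offset)
      avail <- seq(pl$tssarna_length + 1L, max_read_len)
      if (length(avail) == 0) stop("planted length must be below max_read_len")
      cog_lens <- if (pl$cognate_count <= length(avail)) {
        sample(avail, pl$cognate_count)
      } else {
        sample(avail, pl$cognate_count, replace = TRUE)
      }
      lens <- c(rep(pl$tssarna_length, pl$tssarna_count), cog_lens)
      if (gene$strand == "+") {
        r <- aligned_reads(gene$replicon, tss, tss + lens, "+")
      } else {
        r <- aligned_reads(gene$replicon, tss + 1L - lens, tss + 1L, "-")
      }
      read_rows[[i]] <- r
      truth_rows[[i]] <- tibble::tibble(
        gene_id = pl$gene_id, replicon = gene$replicon, strand = gene$strand,
        tss = as.integer(tss),
        tssarna_end = as.integer(if (gene$strand == "+")
          tss + pl$tssarna_length - 1L else tss + 1L - pl$tssarna_length),
        tssarna_length = as.integer(pl$tssarna_length),
        tssarna_count = as.integer(pl$tssarna_count),
        cognate_count = as.integer(pl$cognate_count),
        tss_total_count = as.integer(pl$tssarna_count + pl$cognate_count),
        distance_to_start_codon = as.integer(pl$tss_offset),
        is_primary = if ("is_primary" %in% names(pl)) pl$is_primary else NA,
        is_de = if ("is_de" %in% names(pl)) pl$is_de else NA,
        de_fold = if ("de_fold" %in% names(pl)) pl$de_fold else NA_real_,
        de_direction = if ("de_direction" %in% names(pl))
          pl$de_direction else NA_character_
      )
    }
    n_noise <- round(noise_rate * replicon_length / 1000)
    if (n_noise > 0) {
      nl <- sample(16:max_read_len, n_noise, replace = TRUE)
      ns <- sample(seq(0L, replicon_length - max_read_len - 1L), n_noise,
                   replace = TRUE)
      read_rows[[length(read_rows) + 1]] <-
        aligned_reads(annotation$replicon[1] %||% "chrS", ns, ns + nl,
                      sample(c("+", "-"), n_noise, replace = TRUE))
    }
    reads <- dplyr::bind_rows(read_rows)
    if (nrow(reads) == 0) {
      reads <- aligned_reads(character(), integer(), 1L, character())[0, ]
    }
    list(reads = reads, truth = dplyr::bind_rows(truth_rows))
  })
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Emit a TEX+/TEX- dRNA-seq library pair
#'
#' TEX degrades processed (5'-monophosphate) RNAs, so a primary
#' (5'-triphosphate) TSSaRNA survives the treated library while a processed
#' one is depleted there. The pair is constructed directly in count space:
#' a primary plant keeps its full count in TEX+ and contributes only
#' `count / depletion_factor` reads to TEX-
#' (enrichment `depletion / (depletion + 1)`, e.g. 0.99 at 100-fold);
#' a processed plant gets equal counts in both libraries (enrichment 0.5 at
#' equal library sizes; safely below the 0.95 threshold under library-size
#' normalization either way).
#'
#' @param truth truth tibble from [synth_reads()] (needs `is_primary`).
#' @param depletion_factor TEX- depletion of primary species (default 100).
#' @param seed integer seed (construction is deterministic; kept for the
#'   generator contract).
#' @return A list with `tex_plus`, `tex_minus` (read tibbles) and
#'   `expected` (per-gene expected enrichment).
#' @export
synth_tex_pair <- function(truth, depletion_factor = 100, seed = 1L) {
  stopifnot(!anyNA(truth$is_primary))
  mk <- function(count_fun) {
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      tr <- truth[i, ]
      n <- count_fun(tr)
      if (n == 0) return(NULL)
      if (tr$strand == "+") {
        aligned_reads(tr$replicon, rep(tr$tss, n),
                      rep(tr$tss + tr$tssarna_length, n), "+")
      } else {
        aligned_reads(tr$replicon, rep(tr$tss + 1L - tr$tssarna_length, n),
                      rep(tr$tss + 1L, n), "-")
      }
    })
    out <- dplyr::bind_rows(rows)
    if (nrow(out) == 0) out <- aligned_reads(character(), integer(), 1L,
                                             character())[0, ]
    out
  }
  tex_plus <- mk(function(tr) tr$tssarna_count)
  tex_minus <- mk(function(tr) {
    if (tr$is_primary) as.integer(round(tr$tssarna_count / depletion_factor))
    else tr$tssarna_count
  })
  np <- truth$tssarna_count
  nm <- ifelse(truth$is_primary, round(np / depletion_factor), np)
  expected <- tibble::tibble(
    gene_id = truth$gene_id,
    enrichment = enrichment_score(np, nm,
                                  max(nrow(tex_plus), 1),
                                  max(nrow(tex_minus), 1))
  )
  list(tex_plus = tex_plus, tex_minus = tex_minus, expected = expected)
}

#' Emit a tiling-probe intensity matrix over a growth curve
#'
#' Tiles both strands of the replicon at a fixed step and assigns
#' log10-scale intensity profiles: probes wholly within a planted TSSaRNA
#' carry the TSSaRNA profile (the cognate profile times the planted fold at
#' `n_de_timepoints` time points for DE plants; identical to the cognate
#' profile for co-varying non-DE plants); probes over the cognate CDS beyond
#' the TSSaRNA 3' end carry the cognate profile; all other probes are flat
#' background. Multiplicative log-normal noise (sd `noise_sd` on the log10
#' scale) is applied to every intensity.
#'
#' @param annotation tibble from [synth_genome()].
#' @param truth truth tibble from [synth_reads()] (needs `is_de`, `de_fold`,
#'   `de_direction`).
#' @param replicon_length replicon size, bp.
#' @param probe_len probe length, bp (default 20; at most the shortest
#'   planted TSSaRNA so an admissible probe exists).
#' @param probe_step tiling step, bp (default 5; with `probe_len` this
#'   guarantees a contained probe for TSSaRNAs of at least
#'   `probe_len + probe_step - 1` nt).
#' @param n_timepoints growth-curve points (default 13).
#' @param n_de_timepoints time points at which DE plants differ (default 3).
#' @param baseline reference-condition intensity (default 1000).
#' @param cognate_amp log10 amplitude of the shared cognate expression
#'   profile (default 0: flat).
#' @param noise_sd log10 sd of multiplicative intensity noise (default 0.05).
#' @param seed integer seed.
#' @return A list with `probes` (tibble: `probe_id`, `replicon`, `strand`,
#'   `start`, `end`, `ref`, `t01`..) and `de_truth` (per plant: `is_de`,
#'   the DE time points used).
#' @export
synth_probe_matrix <- function(annotation, truth, replicon_length,
                               probe_len = 20L, probe_step = 5L,
                               n_timepoints = 13L, n_de_timepoints = 3L,
                               baseline = 1000, cognate_amp = 0,
                               noise_sd = 0.05, seed = 1L) {
  bad <- truth$is_de & (truth$tssarna_length < probe_len + probe_step - 1L)
  if (any(bad)) {
    stop("no admissible probe possible for DE plant(s) ",
         paste(truth$gene_id[bad], collapse = ", "),
         ": TSSaRNA shorter than probe_len + probe_step - 1")
  }
  withr::with_seed(seed, {
    starts <- seq(0L, replicon_length - probe_len, by = probe_step)
    probes <- tibble::tibble(
      replicon = annotation$replicon[1] %||% "chrS",
      strand = rep(c("+", "-"), each = length(starts)),
      start = as.integer(rep(starts, 2)),
      end = as.integer(rep(starts, 2) + probe_len)
    )
    probes$probe_id <- sprintf("P%s%06d", ifelse(probes$strand == "+", "p", "m"),
                               seq_len(nrow(probes)))
    probes <- probes[, c("probe_id", "replicon", "strand", "start", "end")]

    tp <- seq_len(n_timepoints)
    # shared cognate log10 profile (flat when cognate_amp = 0)
    log_profiles <- matrix(0, nrow(probes), n_timepoints)
    de_rows <- list()
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      cog_log <- cognate_amp * sin(2 * pi * (tp - 1) / n_timepoints +
                                     2 * pi * i / nrow(truth))
      gene <- annotation[annotation$gene_id == tr$gene_id, ][1, ]
      iv <- if (tr$strand == "+") c(tr$tss, tr$tssarna_end + 1L)
            else c(tr$tssarna_end, tr$tss + 1L)
      on_strand <- probes$strand == tr$strand
      inside <- on_strand & probes$start >= iv[1] & probes$end <= iv[2]
      if (tr$strand == "+") {
        beyond <- on_strand & probes$start > tr$tssarna_end &
          probes$end <= gene$cds_end
      } else {
        beyond <- on_strand & (probes$end - 1L) < tr$tssarna_end &
          probes$start >= gene$cds_start
      }
      tss_log <- cog_log
      de_tp <- integer(0)
      if (isTRUE(tr$is_de)) {
        de_tp <- sort(sample(n_timepoints, n_de_timepoints))
        sgn <- if (identical(tr$de_direction, "down")) -1 else 1
        tss_log[de_tp] <- tss_log[de_tp] + sgn * log10(tr$de_fold)
      }
      if (any(beyond)) {
        log_profiles[beyond, ] <- matrix(cog_log, sum(beyond), n_timepoints,
                                         byrow = TRUE)
      }
      if (any(inside)) {
        log_profiles[inside, ] <- matrix(tss_log, sum(inside), n_timepoints,
                                         byrow = TRUE)
      }
      if (isTRUE(tr$is_de) && !any(inside)) {
        stop("no admissible probe generated for DE plant ", tr$gene_id)
      }
      de_rows[[i]] <- tibble::tibble(
        gene_id = tr$gene_id, is_de = isTRUE(tr$is_de),
        de_timepoints = list(de_tp),
        de_direction = if (isTRUE(tr$is_de)) tr$de_direction else NA_character_
      )
    }
    inten <- baseline * 10^log_profiles
    if (noise_sd > 0) {
      inten <- inten * 10^matrix(stats::rnorm(length(inten), 0, noise_sd),
                                 nrow(inten))
      ref <- baseline * 10^stats::rnorm(nrow(probes), 0, noise_sd)
    } else {
      ref <- rep(baseline, nrow(probes))
    }
    colnames(inten) <- sprintf("t%02d", tp)
    probes$ref <- ref
    probes <- dplyr::bind_cols(probes, tibble::as_tibble(inten))
    list(probes = probes, de_truth = dplyr::bind_rows(de_rows))
  })
}
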