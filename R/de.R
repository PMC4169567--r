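#' Differential-expression parameters
#'
#' Thresholds and geometry of the tiling-array differential-expression test:
#' the TSSaRNA probe must differ from the cognate-gene reference by at least
#' `fold_gene` (log10; default 1 = 10-fold) at the time point with the
#' `rank_select`-th largest |V|, and from an upstream control region by at
#' least `fold_upstream` (default log10(2) = 2-fold) at that region's own
#' rank-selected time point. The upstream control is `upstream_len` bp long
#' and `upstream_gap` bp away from the TSSaRNA start, unless an annotated
#' gene lies closer than `adjacent_gene_dist` bp, in which case the adjacent
#' CDS is used instead.
#'
#' @param fold_gene log10 fold threshold vs the cognate gene (default 1).
#' @param fold_upstream log10 fold threshold vs the upstream control
#'   (default `log10(2)`).
#' @param upstream_len length of the upstream control region, bp (default 300).
#' @param upstream_gap gap between TSSaRNA start and the control region, bp
#'   (default 120).
#' @param adjacent_gene_dist distance under which an annotated gene replaces
#'   the fixed window, bp (default 200).
#' @param rank_select which ordinal of |V| picks the evaluation time point
#'   (default 2: the second most different).
#' @return A list of class `de_params`.
#' @export
de_params <- function(fold_gene = 1, fold_upstream = log10(2),
                      upstream_len = 300L, upstream_gap = 120L,
                      adjacent_gene_dist = 200L, rank_select = 2L) {
  stopifnot(fold_gene > 0, fold_upstream > 0, upstream_len > 0,
            upstream_gap > 0, adjacent_gene_dist > 0, rank_select >= 1)
  structure(list(
    fold_gene = fold_gene, fold_upstream = fold_upstream,
    upstream_len = as.integer(upstream_len),
    upstream_gap = as.integer(upstream_gap),
    adjacent_gene_dist = as.integer(adjacent_gene_dist),
    rank_select = as.integer(rank_select)
  ), class = "de_params")
}

#' Relative intensity on the log10 scale
#'
#' `M = log10(I_t / I_ref)`; both intensities must be positive.
#'
#' @param i_t intensity at a growth-curve time point (vectorized).
#' @param i_ref intensity at the reference condition.
#' @return log10 ratio(s).
#' @export
relative_intensity <- function(i_t, i_ref) {
  if (any(i_t <= 0) || any(i_ref <= 0)) {
    stop("intensities must be positive to form log-ratios")
  }
  log10(i_t / i_ref)
}

probe_meta_cols <- c("probe_id", "replicon", "strand", "start", "end")

probe_time_cols <- function(probes, ref_col) {
  setdiff(names(probes), c(probe_meta_cols, ref_col))
}

# M vectors (probes x time points) for a probe sub-table
probe_m_matrix <- function(probes, ref_col, time_cols) {
  m <- as.matrix(probes[, time_cols, drop = FALSE])
  relative_intensity(m, matrix(probes[[ref_col]], nrow(m), length(time_cols)))
}

# genomic interval [lo, hi) of a TSSaRNA call
call_interval <- function(call) {
  if (call$strand == "+") c(call$tss, call$tssarna_end + 1L)
  else c(call$tssarna_end, call$tss + 1L)
}

#' Select the tiling probe representing a TSSaRNA
#'
#' Admissible probes lie on the call's strand and replicon and do not cover
#' any base beyond the TSSaRNA 3' end; among them the probe overlapping the
#' TSSaRNA over the most bases wins (ties: the most 5' probe).
#'
#' @param call one row of a calls tibble.
#' @param probes probe tibble (`probe_id`, `replicon`, `strand`, `start`,
#'   `end`, a reference-intensity column, then one intensity column per time
#'   point); coordinates 0-based half-open.
#' @return The selected probe row, or `NULL` if no probe overlaps.
#' @export
select_probe <- function(call, probes) {
  iv <- call_interval(call)
  p <- probes[probes$replicon == call$replicon & probes$strand == call$strand, ,
              drop = FALSE]
  if (call$strand == "+") {
    p <- p[p$end <= iv[2], , drop = FALSE] # no base beyond the 3' end
  } else {
    p <- p[p$start >= iv[1], , drop = FALSE]
  }
  if (nrow(p) == 0) return(NULL)
  ov <- pmax(0L, pmin(p$end, iv[2]) - pmax(p$start, iv[1]))
  p <- p[ov > 0, , drop = FALSE]
  ov <- ov[ov > 0]
  if (nrow(p) == 0) return(NULL)
  best <- ov == max(ov)
  p <- p[best, , drop = FALSE]
  if (nrow(p) > 1) {
    p <- if (call$strand == "+") p[which.min(p$start), ] else p[which.max(p$end), ]
  }
  p[1, ]
}

#' Cognate-gene reference profile
#'
#' Per-time-point median of M over the cognate gene's probes that start
#' (5'-wise) beyond the TSSaRNA 3' end and overlap the CDS.
#'
#' @inheritParams select_probe
#' @param gene the cognate gene's annotation row.
#' @param ref_col name of the reference-intensity column (default `"ref"`).
#' @return Numeric vector of M per time point, or `NULL` when no probe
#'   qualifies (the call is unevaluable).
#' @export
cognate_reference <- function(call, probes, gene, ref_col = "ref") {
  p <- probes[probes$replicon == call$replicon & probes$strand == call$strand, ,
              drop = FALSE]
  if (call$strand == "+") {
    keep <- p$start > call$tssarna_end & p$start < gene$cds_end &
      p$end > gene$cds_start
  } else {
    keep <- (p$end - 1L) < call$tssarna_end & p$end > gene$cds_start &
      p$start < gene$cds_end
  }
  p <- p[keep, , drop = FALSE]
  if (nrow(p) == 0) return(NULL)
  tc <- probe_time_cols(probes, ref_col)
  m <- probe_m_matrix(p, ref_col, tc)
  unname(apply(m, 2, stats::median))
}

#' Upstream-control reference profile
#'
#' If no annotated gene (other than the cognate) lies within
#' `adjacent_gene_dist` bp upstream of the TSS, probes wholly inside the
#' strand-aware window `upstream_len` bp long and `upstream_gap` bp upstream
#' of the TSS are used; otherwise all probes over the adjacent CDS are used.
#' Per-time-point median of M across the qualifying probes.
#'
#' @inheritParams cognate_reference
#' @param annotation full annotation tibble.
#' @param params [de_params()].
#' @return Numeric vector of M per time point, or `NULL` when no probe
#'   qualifies.
#' @export
upstream_reference <- function(call, probes, annotation,
                               params = de_params(), ref_col = "ref") {
  others <- annotation[annotation$replicon == call$replicon &
                         annotation$gene_id != call$gene_id, , drop = FALSE]
  p <- probes[probes$replicon == call$replicon & probes$strand == call$strand, ,
              drop = FALSE]
  adjacent <- NULL
  if (nrow(others) > 0) {
    if (call$strand == "+") {
      up <- others[others$cds_end <= call$tss, , drop = FALSE]
      if (nrow(up) > 0) {
        d <- call$tss - up$cds_end
        if (min(d) < params$adjacent_gene_dist) adjacent <- up[which.min(d), ]
      }
    } else {
      up <- others[others$cds_start > call$tss, , drop = FALSE]
      if (nrow(up) > 0) {
        d <- up$cds_start - (call$tss + 1L)
        if (min(d) < params$adjacent_gene_dist) adjacent <- up[which.min(d), ]
      }
    }
  }
  if (is.null(adjacent)) {
    if (call$strand == "+") {
      lo <- call$tss - params$upstream_gap - params$upstream_len
      hi <- call$tss - params$upstream_gap
    } else {
      lo <- call$tss + 1L + params$upstream_gap
      hi <- lo + params$upstream_len
    }
    keep <- p$start >= lo & p$end <= hi
  } else {
    keep <- p$start < adjacent$cds_end & p$end > adjacent$cds_start
  }
  p <- p[keep, , drop = FALSE]
  if (nrow(p) == 0) return(NULL)
  tc <- probe_time_cols(probes, ref_col)
  m <- probe_m_matrix(p, ref_col, tc)
  unname(apply(m, 2, stats::median))
}

# index of the rank-th largest |v| (stable under ties)
rank_select_index <- function(v, rank) {
  order(-abs(v))[rank]
}

#' Differential-expression call for one TSSaRNA
#'
#' Computes `V(t) = M_probe(t) - M_cognate(t)` over all time points and
#' evaluates it at the time point with the `rank_select`-th largest |V|
#' (default: the second most different). The call is differentially expressed
#' when `|V|` at that point is at least `fold_gene` and the analogous
#' upstream-control statistic, at its own rank-selected time point, is at
#' least `fold_upstream`.
#'
#' @inheritParams upstream_reference
#' @return A one-row tibble: `gene_id`, `status` (`"ok"` or why the call was
#'   unevaluable), `selected_probe`, `t_selected`, `v_gene_selected`,
#'   `v_upstream_selected`, `is_de`, `direction`, plus list-columns
#'   `v_gene` and `v_upstream` holding the full vectors.
#' @export
de_call <- function(call, probes, annotation, params = de_params(),
                    ref_col = "ref") {
  out <- tibble::tibble(
    gene_id = call$gene_id, status = "ok",
    selected_probe = NA_character_, t_selected = NA_integer_,
    v_gene_selected = NA_real_, v_upstream_selected = NA_real_,
    is_de = NA, direction = NA_character_,
    v_gene = list(NULL), v_upstream = list(NULL)
  )
  tc <- probe_time_cols(probes, ref_col)
  if (length(tc) < params$rank_select) {
    stop("need at least ", params$rank_select, " time points, got ", length(tc))
  }
  probe <- select_probe(call, probes)
  if (is.null(probe)) {
    out$status <- "no_admissible_probe"
    return(out)
  }
  gene <- annotation[annotation$gene_id == call$gene_id, , drop = FALSE]
  if (nrow(gene) == 0) stop("call's gene_id absent from annotation: ", call$gene_id)
  m_cog <- cognate_reference(call, probes, gene[1, ], ref_col)
  if (is.null(m_cog)) {
    out$status <- "no_cognate_probe"
    return(out)
  }
  m_up <- upstream_reference(call, probes, annotation, params, ref_col)
  if (is.null(m_up)) {
    out$status <- "no_upstream_probe"
    return(out)
  }
  m_probe <- unname(drop(probe_m_matrix(probe, ref_col, tc)))
  v_gene <- m_probe - m_cog
  v_up <- m_probe - m_up
  t_sel <- rank_select_index(v_gene, params$rank_select)
  t_up <- rank_select_index(v_up, params$rank_select)
  out$selected_probe <- probe$probe_id
  out$t_selected <- t_sel
  out$v_gene_selected <- v_gene[t_sel]
  out$v_upstream_selected <- v_up[t_up]
  out$is_de <- abs(v_gene[t_sel]) >= params$fold_gene &&
    abs(v_up[t_up]) >= params$fold_upstream
  out$direction <- if (v_gene[t_sel] >= 0) "up" else "down"
  out$v_gene <- list(v_gene)
  out$v_upstream <- list(v_up)
  out
}

#' Differential-expression calls for a set of TSSaRNAs
#'
#' @inheritParams de_call
#' @param calls calls tibble from [detect_tssarnas()].
#' @return A tibble with one [de_call()] row per call; unevaluable calls are
#'   retained with their `status` reason.
#' @export
de_call_all <- function(calls, probes, annotation, params = de_params(),
                        ref_col = "ref") {
  dplyr::bind_rows(lapply(seq_len(nrow(calls)), function(i) {
    de_call(calls[i, ], probes, annotation, params, ref_col)
  }))
}
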