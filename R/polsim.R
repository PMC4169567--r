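#' @useDynLib tssarna, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Configuration of the RNA polymerase pausing simulator
#'
#' The biogenesis model: a new polymerase initiates at position 1 every
#' `dtau` time units ("intrinsic transcription initiation interval") and
#' elongates at `v` bp per unit, spending 1 unit per position except at a
#' pause site, where it dwells `stall` units ("stalled time") before moving
#' on. A polymerase blocked one base pair behind a stalled one detaches
#' immediately, releasing the transcript synthesized so far — a truncated
#' transcript one base short of the pause position, the modeled TSSaRNA.
#' Reaching position `L` releases a full-length transcript. The model is
#' fully deterministic.
#'
#' @param L gene length, bp.
#' @param pauses data frame (or list) with columns/fields `position`
#'   (1-based bp along the gene, strictly increasing) and `stall` (extra
#'   dwell in time units; a stall below 1 means the default 1-unit wait).
#' @param dtau intrinsic transcription initiation interval, time units.
#' @param v elongation velocity, bp per time unit (default 1).
#' @param T total simulated time, time units.
#' @param burn_in time units excluded from rate estimates (default
#'   `L / v + 10 * max(dtau, stall)`: the pipeline-fill transit time plus a
#'   queueing allowance, enough to pass the transient).
#' @return A list of class `polsim_config`.
#' @export
polsim_config <- function(L, pauses = NULL, dtau, v = 1L, T = NULL,
                          burn_in = NULL) {
  if (is.null(pauses) || (is.data.frame(pauses) && nrow(pauses) == 0)) {
    pauses <- data.frame(position = integer(), stall = integer())
  } else {
    pauses <- as.data.frame(pauses)
    stopifnot(all(c("position", "stall") %in% names(pauses)))
    pauses <- pauses[order(pauses$position), , drop = FALSE]
  }
  stopifnot(L >= 1, dtau >= 1, v >= 1,
            all(pauses$position >= 1), all(pauses$position <= L),
            all(diff(pauses$position) > 0), all(pauses$stall >= 0))
  max_stall <- if (nrow(pauses)) max(pauses$stall, 1) else 1
  if (is.null(burn_in)) {
    burn_in <- as.integer(ceiling(L / v) + 10L * max(dtau, max_stall))
  }
  if (is.null(T)) T <- burn_in + 500L * as.integer(max(dtau, max_stall))
  stopifnot(T > burn_in)
  structure(list(
    L = as.integer(L),
    pauses = data.frame(position = as.integer(pauses$position),
                        stall = as.integer(pauses$stall)),
    dtau = as.integer(dtau), v = as.integer(v),
    T = as.integer(T), burn_in = as.integer(burn_in)
  ), class = "polsim_config")
}

#' Run the pausing simulator
#'
#' @param config a [polsim_config()].
#' @param stop_after_full optionally stop once this many full-length
#'   transcripts have been released after the burn-in (default: run to `T`).
#' @return A list of class `polsim_result`: `initiations`,
#'   `full_length_count`, `truncated_counts` (tibble `length`/`count` over
#'   the whole run; length 0 records initiation attempts blocked at an
#'   occupied position 1), `in_progress`, `first_full_release_time`,
#'   `rates` (post-burn-in per-time-unit rates: `initiation`, `full_length`,
#'   `truncated`), `window` (time units the rates were measured over) and
#'   the `config`.
#' @export
polsim <- function(config, stop_after_full = NA) {
  stopifnot(inherits(config, "polsim_config"))
  saf <- if (is.na(stop_after_full)) -1L else as.integer(stop_after_full)
  raw <- .polsim_run(config$L, config$pauses$position, config$pauses$stall,
                     config$dtau, config$v, config$T, config$burn_in, saf)
  window <- raw$post$window
  structure(list(
    initiations = raw$initiations,
    full_length_count = raw$full_length_count,
    truncated_counts = tibble::tibble(length = raw$truncated_lengths,
                                      count = raw$truncated_counts),
    in_progress = raw$in_progress,
    first_full_release_time = raw$first_full_release_time,
    rates = c(initiation = raw$post$initiations / window,
              full_length = raw$post$full_length / window,
              truncated = raw$post$truncated / window),
    window = window,
    t_end = raw$t_end,
    config = config
  ), class = "polsim_result")
}

#' @export
print.polsim_result <- function(x, ...) {
  cat("<polsim_result> initiations:", x$initiations,
      " full-length:", x$full_length_count,
      " truncated:", sum(x$truncated_counts$count),
      " in progress:", x$in_progress, "\n")
  cat("  steady-state rates (per time unit): full",
      signif(x$rates[["full_length"]], 4), "| truncated",
      signif(x$rates[["truncated"]], 4), "\n")
  invisible(x)
}

#' Closed-form steady-state rates for a single pause
#'
#' With one pause of stalled time `stall` and velocity 1, the pause passes
#' one polymerase per `max(dtau, stall)` time units, so the full-length rate
#' is `1 / max(dtau, stall)`; every other initiation terminates one base
#' behind the pause, giving a truncated rate of
#' `max(0, 1/dtau - 1/max(dtau, stall))`.
#'
#' @param dtau initiation interval, time units.
#' @param stall stalled time at the pause, time units.
#' @return Named numeric vector with `full_length` and `truncated` rates.
#' @export
polsim_closed_form <- function(dtau, stall) {
  bottleneck <- pmax(dtau, pmax(stall, 1))
  c(full_length = 1 / bottleneck,
    truncated = pmax(0, 1 / dtau - 1 / bottleneck))
}

#' Truncated-transcript length histogram
#'
#' Census of early-terminated transcript lengths. With velocity 1 these
#' cluster exactly one base short of each pause position. Length-0 records
#' (blocked initiation attempts) are excluded.
#'
#' @param result a [polsim()] result.
#' @return A list with `histogram` (tibble `length`/`count`) and `modes`
#'   (lengths of local count maxima, most abundant first).
#' @export
length_histogram <- function(result) {
  h <- result$truncated_counts
  h <- h[h$length > 0, , drop = FALSE]
  h <- h[order(h$length), , drop = FALSE]
  # every occupied length is a band of its own: with v = 1 all mass sits
  # exactly one base behind a pause, so modes are the lengths themselves,
  # most abundant first
  list(histogram = h, modes = h$length[order(-h$count)])
}

#' Scan the (dtau, stall) parameter plane
#'
#' Runs the simulator to steady state over a grid of initiation intervals
#' and stalled times and reports, per cell, the TSSaRNA level (truncated
#' rate by default) and cognate-gene level (full-length rate) as log2 fold
#' changes versus a designated reference cell.
#'
#' @param dtau_grid,stall_grid numeric vectors of parameter values.
#' @param config_base [polsim_config()] supplying `L`, pause position(s),
#'   `v`; its `dtau` and stall values are overridden per cell.
#' @param reference length-2 vector `c(dtau, stall)` of the reference cell
#'   (must be on the grid).
#' @param tssarna_level `"truncated"` (default: the truncated-transcript
#'   production rate) or `"coverage"` (truncated plus full-length rate, i.e.
#'   probe-style coverage of the TSSaRNA interval, which every transcript
#'   traverses).
#' @param steady_factor steady-state run length in units of
#'   `max(dtau, stall)` (default 500).
#' @return A tibble with one row per cell: `dtau`, `stall`, `tssarna_rate`,
#'   `full_rate`, `log2_tssarna_fold`, `log2_cognate_fold`.
#' @export
polsim_scan <- function(dtau_grid, stall_grid, config_base,
                        reference = c(dtau_grid[1], stall_grid[1]),
                        tssarna_level = c("truncated", "coverage"),
                        steady_factor = 500L) {
  tssarna_level <- match.arg(tssarna_level)
  stopifnot(length(dtau_grid) >= 1, length(stall_grid) >= 1)
  grid <- expand.grid(dtau = dtau_grid, stall = stall_grid,
                      KEEP.OUT.ATTRS = FALSE)
  one <- function(dtau, stall) {
    pauses <- config_base$pauses
    if (nrow(pauses) == 0) stop("config_base must define at least one pause")
    pauses$stall <- stall
    m <- max(dtau, stall, 1)
    bi <- as.integer(ceiling(config_base$L / config_base$v) + 10 * m)
    cfg <- polsim_config(L = config_base$L, pauses = pauses, dtau = dtau,
                         v = config_base$v,
                         T = as.integer(bi + steady_factor * m),
                         burn_in = bi)
    r <- polsim(cfg)
    tr <- r$rates[["truncated"]]
    fl <- r$rates[["full_length"]]
    c(tssarna = if (tssarna_level == "truncated") tr else tr + fl,
      full = fl)
  }
  lev <- t(mapply(one, grid$dtau, grid$stall))
  ref <- one(reference[1], reference[2])
  tibble::tibble(
    dtau = grid$dtau, stall = grid$stall,
    tssarna_rate = lev[, "tssarna"], full_rate = lev[, "full"],
    log2_tssarna_fold = log2(lev[, "tssarna"] / ref[["tssarna"]]),
    log2_cognate_fold = log2(lev[, "full"] / ref[["full"]])
  )
}

#' Simulate TSSaRNA/cognate expression profiles over a growth curve
#'
#' One steady-state simulation per growth-curve time point, with `dtau` and
#' the stalled time(s) varying per point ("varying pausing rhythm"), reported
#' as log2(I_t / I_ref) profiles in the same shape as the experimental
#' differential-expression profiles.
#'
#' @param schedule tibble with columns `timepoint`, `dtau`, `stall` (`stall`
#'   is recycled over all pause sites; use a list-column of vectors for
#'   per-site stalls).
#' @param config_base [polsim_config()] supplying `L`, pause positions, `v`.
#' @param ref_timepoint which `timepoint` value is the reference condition.
#' @param tssarna_level,steady_factor see [polsim_scan()].
#' @return A tibble with `timepoint`, `tssarna_rate`, `cognate_rate`,
#'   `tssarna_log2`, `cognate_log2`.
#' @export
polsim_growth_curve <- function(schedule, config_base, ref_timepoint,
                                tssarna_level = c("truncated", "coverage"),
                                steady_factor = 500L) {
  tssarna_level <- match.arg(tssarna_level)
  stopifnot(all(c("timepoint", "dtau", "stall") %in% names(schedule)),
            ref_timepoint %in% schedule$timepoint)
  one <- function(i) {
    pauses <- config_base$pauses
    st <- schedule$stall[[i]]
    pauses$stall <- rep_len(st, nrow(pauses))
    m <- max(schedule$dtau[i], max(pauses$stall), 1)
    bi <- as.integer(ceiling(config_base$L / config_base$v) + 10 * m)
    cfg <- polsim_config(L = config_base$L, pauses = pauses,
                         dtau = schedule$dtau[i], v = config_base$v,
                         T = as.integer(bi + steady_factor * m),
                         burn_in = bi)
    r <- polsim(cfg)
    tr <- r$rates[["truncated"]]
    fl <- r$rates[["full_length"]]
    c(tssarna = if (tssarna_level == "truncated") tr else tr + fl, full = fl)
  }
  lev <- t(vapply(seq_len(nrow(schedule)), one, c(tssarna = 0, full = 0)))
  ref <- lev[match(ref_timepoint, schedule$timepoint), ]
  tibble::tibble(
    timepoint = schedule$timepoint,
    tssarna_rate = lev[, "tssarna"],
    cognate_rate = lev[, "full"],
    tssarna_log2 = log2(lev[, "tssarna"] / ref[["tssarna"]]),
    cognate_log2 = log2(lev[, "full"] / ref[["full"]])
  )
}
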