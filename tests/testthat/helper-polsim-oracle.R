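# Independent brute-force stepper for the polymerase traffic model, kept in
# plain R and deliberately separate from the package kernel. Returns the full
# event log so tests can check event times, not just totals.
brute_polsim <- function(L, pause_pos, pause_stall, dtau, T, v = 1L) {
  pos <- integer(0)
  dw <- integer(0)
  ev_t <- integer(0)
  ev_type <- character(0) # "trunc", "full", "blocked_init"
  ev_len <- integer(0)
  dwell_at <- function(p) {
    i <- match(p, pause_pos)
    if (!is.na(i)) max(pause_stall[i], 1L) else 1L
  }
  for (t in seq_len(T)) {
    npos <- integer(0)
    ndw <- integer(0)
    ahead <- L + 1L
    for (i in seq_along(pos)) {
      d <- dw[i] - 1L
      if (d > 0) {
        npos <- c(npos, pos[i]); ndw <- c(ndw, d); ahead <- pos[i]
        next
      }
      tgt <- pos[i] + v
      pp <- pause_pos[pause_pos > pos[i] & pause_pos <= pos[i] + v]
      if (length(pp)) tgt <- min(pp)
      if (tgt >= ahead) {
        ev_t <- c(ev_t, t); ev_type <- c(ev_type, "trunc")
        ev_len <- c(ev_len, ahead - 1L)
      } else if (tgt >= L) {
        ev_t <- c(ev_t, t); ev_type <- c(ev_type, "full")
        ev_len <- c(ev_len, L)
      } else {
        npos <- c(npos, tgt); ndw <- c(ndw, dwell_at(tgt)); ahead <- tgt
      }
    }
    pos <- npos; dw <- ndw
    if ((t - 1L) %% dtau == 0L) {
      if (length(pos) && pos[length(pos)] == 1L) {
        ev_t <- c(ev_t, t); ev_type <- c(ev_type, "blocked_init")
        ev_len <- c(ev_len, 0L)
      } else {
        pos <- c(pos, 1L); dw <- c(dw, dwell_at(1L))
      }
    }
  }
  list(events = tibble::tibble(t = ev_t, type = ev_type, len = ev_len),
       in_progress = length(pos))
}
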